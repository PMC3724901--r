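## Geographic population-divergence models: population trees in coalescent
## units over the five refugial regions, plus the tip-to-population binding.

#' Default region set
#'
#' North America Interior, North America Cascadia/Coast, Beringia, Central
#' Asia & Siberia, Japan — the five putative refugial regions of the
#' north-Pacific arc, ordered along the geographic chain.
#' @export
REGIONS <- c("NAI", "NAC", "BER", "CAS", "JAP")

#' Default per-region sample sizes of the study design (46 samples).
#' @export
REGION_SAMPLES <- c(NAI = 15L, NAC = 6L, BER = 11L, CAS = 11L, JAP = 3L)

#' Construct a population-divergence model
#'
#' Builds a population tree (regions as tips, divergence depths in
#' coalescent units, 1 unit = 2Ne generations) either from a named preset
#' or from an explicit Newick topology over the region labels.
#'
#' Presets over the chain NAI–NAC–BER–CAS–JAP:
#' \describe{
#'   \item{REFUGIA}{simultaneous fragmentation of one ancestral population
#'     among all refugia: a hard polytomy (star) at a single depth.}
#'   \item{SRM}{southern Rocky Mountain origin with stepwise westward
#'     dispersal: pectinate `(NAI,(NAC,(BER,(CAS,JAP))))`.}
#'   \item{JAPAN_I / JAPAN_II}{Japanese origin with northward/eastward
#'     spread: pectinate chains rooted at JAP; the two variants differ in
#'     the order of the final colonisation steps into North America.}
#'   \item{CAS_I / CAS_II}{central-Asian origin with southward and eastward
#'     spread: pectinate chains rooted at CAS.}
#' }
#' The non-SRM chain variants are best-effort defaults (the original
#' branching orders are figure-only); any preset can be replaced by an
#' explicit topology.
#'
#' @param spec Preset name (one of `REFUGIA`, `SRM`, `JAPAN_I`, `JAPAN_II`,
#'   `CAS_I`, `CAS_II`) or an explicit Newick string over the region labels.
#' @param depths Divergence depths in coalescent units, strictly decreasing
#'   toward the present, one per divergence event rootmost-first (a single
#'   depth for `REFUGIA`). Defaults to evenly spaced depths from 5 to 2.
#' @param samples Named integer vector of per-region sample counts
#'   (defaults to [REGION_SAMPLES] when the regions are the default five,
#'   otherwise 1 each).
#' @param regions Region label set (default [REGIONS]).
#' @return An object of class `"pop_tree"`: a list with `phy` (the
#'   population tree, branch lengths in coalescent units) and `samples`.
#' @examples
#' divergence_model("REFUGIA", depths = 5)
#' divergence_model("SRM")
#' @export
divergence_model <- function(spec, depths = NULL, samples = NULL,
                             regions = NULL) {
  stopifnot(is.character(spec), length(spec) == 1L)
  presets <- c("REFUGIA", "SRM", "JAPAN_I", "JAPAN_II", "CAS_I", "CAS_II")
  is_newick <- grepl("(", spec, fixed = TRUE)
  if (is.null(regions)) {
    ## explicit topologies define their own region set; presets use the
    ## default five regions
    regions <- if (is_newick) {
      tmp <- ape::read.tree(text = if (grepl(";\\s*$", spec)) spec
                                   else paste0(spec, ";"))
      if (is.null(tmp)) stop2("could not parse model topology")
      tmp$tip.label
    } else REGIONS
  }
  if (!is_newick && !(spec %in% presets)) {
    stop2("unknown model spec '", spec, "'; expected one of ",
          paste(presets, collapse = ", "), " or an explicit Newick string")
  }
  if (is_newick) {
    topo <- spec
    if (!grepl(";\\s*$", topo)) topo <- paste0(topo, ";")
    phy <- tryCatch(ape::read.tree(text = topo),
                    error = function(e) NULL)
    if (is.null(phy)) stop2("could not parse model topology")
  } else {
    if (!identical(sort(regions), sort(REGIONS)) && spec != "REFUGIA") {
      stop2("named presets other than REFUGIA are defined for the default ",
            "five regions only")
    }
    topo <- switch(spec,
      REFUGIA  = paste0("(", paste(regions, collapse = ","), ");"),
      SRM      = "(NAI,(NAC,(BER,(CAS,JAP))));",
      JAPAN_I  = "(JAP,(CAS,(BER,(NAC,NAI))));",
      JAPAN_II = "(JAP,(CAS,(NAC,(BER,NAI))));",
      CAS_I    = "(CAS,(JAP,(BER,(NAC,NAI))));",
      CAS_II   = "(CAS,(JAP,(NAC,(BER,NAI))));")
    phy <- ape::read.tree(text = topo)
  }
  if (anyDuplicated(phy$tip.label) || anyDuplicated(regions) ||
      !setequal(phy$tip.label, regions) ||
      length(phy$tip.label) != length(regions)) {
    stop2("model topology must contain each region exactly once")
  }
  n_div <- phy$Nnode
  if (is.null(depths)) {
    depths <- if (n_div == 1L) 3 else seq(5, 2, length.out = n_div)
  }
  if (length(depths) != n_div) {
    stop2("need ", n_div, " divergence depth(s), got ", length(depths))
  }
  if (any(depths <= 0) || (n_div > 1L && any(diff(depths) >= 0))) {
    stop2("divergence depths must be positive and strictly decreasing ",
          "toward the present")
  }
  ## assign depths to internal nodes rootmost-first (preorder on internals)
  ntip <- length(regions)
  ints <- unique(tree_preorder_nodes(phy))
  ints <- ints[ints > ntip]
  age <- numeric(ntip + n_div) # age above present
  ## order internal nodes so that ancestors precede descendants
  age[ints] <- depths[seq_along(ints)]
  ## check depths consistent with topology (parent older than child)
  phy$edge.length <- age[phy$edge[, 1]] - age[phy$edge[, 2]]
  if (any(phy$edge.length <= 0)) {
    stop2("depths are inconsistent with the topology ",
          "(a parent node would be younger than its child)")
  }
  if (is.null(samples)) {
    samples <- if (setequal(regions, REGIONS)) REGION_SAMPLES[regions] else
      setNames(rep(1L, length(regions)), regions)
  }
  if (is.null(names(samples)) || !setequal(names(samples), regions)) {
    stop2("'samples' must be named by region")
  }
  samples <- samples[regions]
  if (any(samples < 0) || any(samples != round(samples))) {
    stop2("sample counts must be nonnegative integers")
  }
  structure(list(phy = phy, samples = setNames(as.integer(samples), regions),
                 regions = regions, name = if (is_newick) "custom" else spec,
                 depths = depths),
            class = "pop_tree")
}

## preorder node sequence (root first) for a phylo object
tree_preorder_nodes <- function(phy) {
  if (nrow(phy$edge) == 1L) return(c(phy$edge[1, 1], phy$edge[1, 2]))
  edge <- phy$edge[rev(ape::postorder(phy)), , drop = FALSE]
  c(edge[1, 1], edge[, 2])
}

#' @export
print.pop_tree <- function(x, ...) {
  cat("Population-divergence model '", x$name, "'\n", sep = "")
  cat("  topology: ", ape::write.tree(x$phy), "\n", sep = "")
  cat("  divergence depths (coalescent units): ",
      paste(signif(x$depths, 4), collapse = ", "), "\n", sep = "")
  cat("  samples: ",
      paste(names(x$samples), x$samples, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Load a tip-to-population assignment table
#'
#' @param file Path to a two-column TSV (`tip`, `region`), with or without a
#'   header line, or a data.frame with those two columns.
#' @param regions Permitted region labels (default [REGIONS]).
#' @return A named character vector mapping tip label to region, of class
#'   `"sample_assignment"`.
#' @export
load_assignment <- function(file, regions = REGIONS) {
  if (is.data.frame(file)) {
    df <- file[, 1:2]
  } else {
    df <- read.delim(file, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop2("empty assignment table")
    if (identical(tolower(as.character(df[1, 1])), "tip")) df <- df[-1, ]
  }
  if (nrow(df) == 0L) stop2("assignment table contains no samples")
  tips <- as.character(df[[1]]); regs <- as.character(df[[2]])
  if (anyDuplicated(tips)) {
    stop2("duplicate tip in assignment: '", tips[duplicated(tips)][1], "'")
  }
  bad <- setdiff(unique(regs), regions)
  if (length(bad)) stop2("unknown region(s): ", paste(bad, collapse = ", "))
  structure(setNames(regs, tips), class = "sample_assignment")
}

#' Build an assignment from per-region counts
#'
#' Generates tip labels `REGION_01 ...` for a sampling design, e.g. the
#' default 46-sample design `NAI=15, NAC=6, BER=11, CAS=11, JAP=3`.
#'
#' @param samples Named integer vector of per-region counts.
#' @return A `"sample_assignment"`.
#' @export
assignment_from_counts <- function(samples = REGION_SAMPLES) {
  stopifnot(!is.null(names(samples)), all(samples >= 0))
  tips <- unlist(lapply(names(samples), function(r) {
    if (samples[[r]] == 0L) return(character())
    sprintf("%s_%02d", r, seq_len(samples[[r]]))
  }))
  regs <- rep(names(samples), times = samples)
  structure(setNames(regs, tips), class = "sample_assignment")
}
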