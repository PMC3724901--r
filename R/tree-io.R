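## Tree I/O: thin, validating wrappers around ape's Newick/NEXUS readers and
## writers. All downstream modules consume plain ape "phylo" objects.

#' Parse a rooted Newick string
#'
#' Wraps [ape::read.tree()] with the validation the rest of the pipeline
#' relies on: a single rooted tree, unique tip labels, non-negative branch
#' lengths. Edges without a length are assigned length 1 with a warning.
#'
#' @param text A single Newick statement ending in `;`.
#' @return An object of class `"phylo"`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2):0;")
#' max(node_depths(tr))
#' @seealso [write_newick()], [read_nexus_trees()]
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";", text, fixed = TRUE)) {
    stop2("Newick parse error: no terminating ';' found")
  }
  ## balance check first: ape can silently mis-read malformed strings
  chars <- strsplit(text, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0) {
    bad <- which(depth < 0)[1]
    stop2("Newick parse error: unbalanced parentheses near character ",
          if (is.na(bad)) length(chars) else bad)
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop2("Newick parse error: ape could not parse the statement")
  }
  validate_tree(tr, fill_lengths = TRUE)
}

#' Serialise a tree to Newick
#'
#' @param tree A `"phylo"` object.
#' @param digits Significant digits for branch lengths (default 12, enough
#'   for exact round trips at double precision in practice).
#' @return A single Newick string.
#' @export
write_newick <- function(tree, digits = 12L) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

#' Validate a phylo object for pipeline use
#'
#' @param tree `"phylo"` object.
#' @param fill_lengths if `TRUE`, missing branch lengths are set to 1 with a
#'   warning; otherwise they are an error.
#' @return The validated (possibly length-filled) tree.
#' @export
validate_tree <- function(tree, fill_lengths = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    dup <- tree$tip.label[duplicated(tree$tip.label)][1]
    stop2("duplicate tip label: '", dup, "'")
  }
  if (is.null(tree$edge.length)) {
    if (!fill_lengths) stop2("tree has no branch lengths")
    warning("tree has no branch lengths; defaulting all to 1.0",
            call. = FALSE)
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (!fill_lengths) stop2("tree has missing branch lengths")
    warning("missing branch lengths defaulted to 1.0", call. = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 1
  }
  if (any(tree$edge.length < 0)) stop2("negative branch length")
  tree
}

#' Read a NEXUS TREES block as a tree sample
#'
#' Reads a NEXUS file (e.g. a post-burn-in MrBayes sample) via
#' [ape::read.nexus()], which applies any TRANSLATE table, and validates
#' that all trees share one taxon set.
#'
#' @param file Path to a NEXUS file containing a TREES block.
#' @return A `tree_sample` (see [tree_sample()]).
#' @export
read_nexus_trees <- function(file) {
  trees <- tryCatch(ape::read.nexus(file),
                    error = function(e) stop2("NEXUS parse error: ",
                                              conditionMessage(e)))
  if (inherits(trees, "phylo")) trees <- c(trees)
  tree_sample(trees)
}

#' Construct a tree sample
#'
#' An ordered collection of trees over one shared taxon set, as produced by
#' Bayesian tree inference after burn-in removal. Stored as an ape
#' `multiPhylo` with class `tree_sample` prepended.
#'
#' @param trees A list of `"phylo"` objects or a `multiPhylo`.
#' @return A `tree_sample` object.
#' @export
tree_sample <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  ## extract via the multiPhylo method so compressed tip labels (shared
  ## TipLabel attribute, as read.nexus produces) are reattached
  trees <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    stopifnot(inherits(tr, "phylo"))
    tr
  })
  if (length(trees) == 0L) stop2("empty tree sample")
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref)) {
      stop2("tree ", i, " has a different tip label set")
    }
  }
  class(trees) <- c("tree_sample", "multiPhylo")
  trees
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("Tree sample: ", length(x), " trees over ",
      length(x[[1]]$tip.label), " tips\n", sep = "")
  invisible(x)
}

#' Write a tree list as a NEXUS TREES block
#'
#' @param trees A `tree_sample`, `multiPhylo`, or list of `phylo`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_nexus_trees <- function(trees, file) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  cls <- class(trees)
  class(trees) <- setdiff(cls, "tree_sample")
  ape::write.nexus(trees, file = file, translate = TRUE)
  ## drop the writer's timestamp comment so identical samples produce
  ## byte-identical files
  txt <- readLines(file)
  writeLines(txt[!grepl("^\\[R-package", txt)], file)
  invisible(file)
}
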