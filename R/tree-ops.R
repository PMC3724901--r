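## Structural tree operations: depths, ultrametricity, polytomy resolution,
## time scaling, MRCA lookup.

#' Root-to-node depths
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return Numeric vector of length `Ntip + Nnode`, the path length from the
#'   root to every node (tips first, in `tip.label` order).
#' @export
node_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  ape::node.depth.edgelength(tree)
}

#' Test ultrametricity at a relative tolerance
#'
#' @param tree `"phylo"` object.
#' @param tol Relative tolerance on the spread of tip depths (default 1e-6).
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  mx <- max(d)
  if (mx == 0) return(TRUE)
  (mx - min(d)) / mx <= tol
}

#' Resolve polytomies into random bifurcations
#'
#' Multifurcating nodes are expanded into a random sequence of bifurcations
#' (via [ape::multi2di()]); the inserted edges have length zero, so node
#' depths and total tree length are unchanged and continuous-time
#' likelihoods are unaffected.
#'
#' @param tree `"phylo"` object.
#' @param seed Integer seed controlling the (otherwise arbitrary) resolution
#'   order; mandatory so runs are reproducible.
#' @return A strictly bifurcating `"phylo"`.
#' @export
resolve_polytomies <- function(tree, seed) {
  stopifnot(inherits(tree, "phylo"))
  if (missing(seed)) stop2("'seed' is required for polytomy resolution")
  if (ape::is.binary(tree)) return(tree)
  with_seed(seed, ape::multi2di(tree, random = TRUE))
}

#' Scale a tree to a fixed root age
#'
#' Linearly rescales branch lengths so all root-to-tip depths equal
#' `root_age` (e.g. to put a substitution-rate tree on an absolute time
#' axis). Ultrametric input is scaled by one global factor. Non-ultrametric
#' input is accepted only with `allow_nonultrametric = TRUE`, in which case
#' each root-to-tip path is stretched independently (each node is placed at
#' `root_age * depth / (depth + height)`, with `height` its maximum
#' distance to a descendant tip); relative node order along every path is
#' preserved but absolute internal ages are then only as good as that
#' stretching, which is logged with a warning.
#'
#' @param tree `"phylo"` object with branch lengths.
#' @param root_age Target root-to-tip depth, in the caller's time unit
#'   (strictly positive).
#' @param allow_nonultrametric Permit per-path stretching of
#'   non-ultrametric trees.
#' @param tol Relative ultrametricity tolerance (default 1e-6).
#' @return A `"phylo"` with all tip depths equal to `root_age`.
#' @export
scale_to_age <- function(tree, root_age, allow_nonultrametric = FALSE,
                         tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (!is.numeric(root_age) || length(root_age) != 1L || root_age <= 0) {
    stop2("'root_age' must be a single positive number")
  }
  depth <- node_depths(tree)
  ntip <- ape::Ntip(tree)
  if (is_ultrametric(tree, tol)) {
    tree$edge.length <- tree$edge.length * (root_age / max(depth[1:ntip]))
    return(tree)
  }
  if (!allow_nonultrametric) {
    stop2("tree is not ultrametric; pass allow_nonultrametric = TRUE ",
          "to stretch each root-to-tip path independently")
  }
  warning("non-ultrametric input: stretching each root-to-tip path ",
          "linearly to the target root age", call. = FALSE)
  ## height[v]: max distance from v down to a descendant tip
  nn <- ntip + tree$Nnode
  height <- numeric(nn)
  for (k in ape::postorder(tree)) {
    p <- tree$edge[k, 1]; c <- tree$edge[k, 2]
    height[p] <- max(height[p], height[c] + tree$edge.length[k])
  }
  newdep <- ifelse(depth + height > 0, root_age * depth / (depth + height), 0)
  tree$edge.length <- newdep[tree$edge[, 2]] - newdep[tree$edge[, 1]]
  tree
}

#' Most recent common ancestor of a tip set
#'
#' @param tree `"phylo"` object.
#' @param tips Character vector of tip labels (nonempty subset of the
#'   taxon set). A single tip returns the tip node itself.
#' @return Integer node index (ape numbering).
#' @export
mrca_node <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"), is.character(tips), length(tips) >= 1L)
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop2("unknown tip(s): ",
                        paste(tips[is.na(idx)], collapse = ", "))
  if (length(unique(idx)) == 1L) return(idx[1])
  ape::getMRCA(tree, unique(idx))
}
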