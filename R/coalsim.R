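## Multispecies-coalescent simulation of gene trees inside a population
## tree. Within each population branch, k lineages coalesce with
## exponential waiting times at rate k(k-1)/2 per coalescent unit;
## uncoalesced lineages enter the parent population at the divergence time,
## and the root population extends indefinitely. The simulator works on a
## compact parent-vector representation (also used by the deep-coalescence
## scorer, so null distributions avoid building full phylo objects).

## Precompute the branch traversal structure of a population tree.
## Species node ages: tips 0, internal nodes at their divergence depth,
## root branch extends to +Inf.
msc_struct <- function(model) {
  stopifnot(inherits(model, "pop_tree"))
  phy <- model$phy
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  age <- numeric(nn)
  po <- if (nrow(phy$edge) == 1L) 1L else ape::postorder(phy)
  for (k in po) {
    age[phy$edge[k, 1]] <- age[phy$edge[k, 2]] + phy$edge.length[k]
  }
  parent <- integer(nn)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  top <- rep(Inf, nn)
  top[parent > 0L] <- age[parent[parent > 0L]]
  children <- vector("list", nn)
  for (k in seq_len(nrow(phy$edge))) {
    p <- phy$edge[k, 1]
    children[[p]] <- c(children[[p]], phy$edge[k, 2])
  }
  ## node sequence with every child preceding its parent, root last
  node_order <- integer(0)
  visit <- function(v) {
    for (ch in children[[v]]) visit(ch)
    node_order <<- c(node_order, v)
  }
  visit(root)
  list(phy = phy, ntip = ntip, nn = nn, age = age, top = top,
       parent = parent, root = root, children = children,
       order = node_order, tips = phy$tip.label)
}

## One MSC realisation on the compact representation.
## counts: per-species-tip gene sample counts aligned to st$tips.
## Returns parent vector (0 at gene root), node times, and per-gene-tip
## species-tip index. Internal gene node ids increase rootward, so id
## 2n-1 is the gene root.
sim_msc_events <- function(st, counts) {
  n <- sum(counts)
  if (n < 1L) stop2("zero samples overall")
  parent <- integer(2L * n - 1L)
  time <- numeric(2L * n - 1L)
  tip_sp <- rep(seq_along(counts), times = counts)
  offsets <- c(0L, cumsum(counts))
  nxt <- n
  pool <- vector("list", st$nn) # surviving lineages per species node
  for (v in st$order) {
    if (v <= st$ntip) {
      L <- if (counts[v] > 0L) (offsets[v] + 1L):(offsets[v] + counts[v])
           else integer(0)
    } else {
      L <- unlist(pool[st$children[[v]]], use.names = FALSE)
    }
    t <- st$age[v]; tp <- st$top[v]
    k <- length(L)
    while (k > 1L) {
      t <- t + rexp(1L, k * (k - 1L) / 2)
      if (t > tp) break
      ij <- sample.int(k, 2L)
      nxt <- nxt + 1L
      parent[L[ij]] <- nxt
      time[nxt] <- t
      L <- c(L[-ij], nxt)
      k <- k - 1L
    }
    pool[[v]] <- L
  }
  list(parent = parent, time = time, tip_sp = tip_sp, n = n)
}

## Convert a simulation record to an ape phylo. Internal ids are remapped
## so the gene root becomes ntip+1 (ape convention).
events_to_phylo <- function(ev, tip_labels) {
  n <- ev$n
  if (n == 1L) stop2("cannot build a tree from a single sample")
  ## internal ids increase rootward; 3n - id reverses them so that the
  ## gene root (old id 2n-1) becomes n+1 and ids decrease tipward
  remap <- integer(2L * n - 1L)
  remap[seq_len(n)] <- seq_len(n)
  remap[(n + 1L):(2L * n - 1L)] <- 3L * n - ((n + 1L):(2L * n - 1L))
  parent_new <- integer(2L * n - 1L)
  time_new <- numeric(2L * n - 1L)
  for (v in seq_len(2L * n - 1L)) {
    time_new[remap[v]] <- ev$time[v]
    if (ev$parent[v] > 0L) parent_new[remap[v]] <- remap[ev$parent[v]]
  }
  nodes <- seq_len(2L * n - 1L)
  child <- nodes[parent_new > 0L]
  edge <- cbind(parent_new[child], child)
  len <- time_new[edge[, 1]] - time_new[edge[, 2]]
  tr <- structure(list(edge = edge, edge.length = len,
                       tip.label = tip_labels, Nnode = n - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

## Expand an assignment into aligned per-species-tip counts and labels.
assignment_counts <- function(st, assignment) {
  stopifnot(inherits(assignment, "sample_assignment") ||
            (is.character(assignment) && !is.null(names(assignment))))
  regs <- as.character(assignment)
  bad <- setdiff(unique(regs), st$tips)
  if (length(bad)) {
    stop2("assignment uses population(s) absent from the model: ",
          paste(bad, collapse = ", "))
  }
  ord <- order(match(regs, st$tips))
  labels <- names(assignment)[ord]
  counts <- as.integer(table(factor(regs, levels = st$tips)))
  list(counts = counts, labels = labels)
}

#' Simulate one gene tree under the multispecies coalescent
#'
#' @param model A `"pop_tree"` (see [divergence_model()]).
#' @param assignment A `"sample_assignment"` mapping gene-tree tip labels to
#'   populations; defaults to labelled tips generated from the model's
#'   sample counts.
#' @param seed Optional integer seed.
#' @return An ultrametric `"phylo"` in coalescent units, with the
#'   assignment attached as attribute `"assignment"`.
#' @examples
#' m <- divergence_model("SRM")
#' g <- simulate_msc(m, seed = 1)
#' @export
simulate_msc <- function(model, assignment = NULL, seed = NULL) {
  st <- msc_struct(model)
  if (is.null(assignment)) assignment <- assignment_from_counts(model$samples)
  ac <- assignment_counts(st, assignment)
  ev <- with_seed(seed, sim_msc_events(st, ac$counts))
  tr <- events_to_phylo(ev, ac$labels)
  attr(tr, "assignment") <- assignment
  tr
}

#' Simulate a null sample of gene trees
#'
#' @inheritParams simulate_msc
#' @param n_sims Number of independent gene trees (>= 1).
#' @return A [tree_sample()] of `n_sims` gene trees.
#' @export
simulate_null <- function(model, assignment = NULL, n_sims, seed = NULL) {
  if (!is_count(n_sims)) stop2("'n_sims' must be a positive integer")
  st <- msc_struct(model)
  if (is.null(assignment)) assignment <- assignment_from_counts(model$samples)
  ac <- assignment_counts(st, assignment)
  trees <- with_seed(seed, lapply(seq_len(n_sims), function(i) {
    events_to_phylo(sim_msc_events(st, ac$counts), ac$labels)
  }))
  tree_sample(trees)
}
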