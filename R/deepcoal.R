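## Deep-coalescence reconciliation cost and the simulation-based test of
## population-divergence models.
##
## The cost is the minimal number of "extra" gene lineages that must
## persist through population-tree branches to reconcile the gene tree
## with the population tree, attributing all discordance to incomplete
## lineage sorting. It is computed from the LCA mapping: each gene node
## maps to the most recent population-tree node whose cluster contains all
## populations of its descendant tips; each population-tree edge then
## carries (lineages crossing its rootward end - 1) extra lineages.
## Branch lengths play no role (purely topological cost).

## Precompute the scoring structure for a population tree + assignment.
## Uses bitmasks over populations (<= 30 populations).
dc_struct <- function(model, assignment) {
  st <- msc_struct(model)
  k <- st$ntip
  if (k > 30L) stop2("deep-coalescence scoring supports at most 30 populations")
  nn <- st$nn
  ## cluster bitmask of each population-tree node
  mask <- integer(nn)
  mask[seq_len(k)] <- bitwShiftL(1L, seq_len(k) - 1L)
  for (v in st$order) {
    if (v > k) {
      for (ch in st$children[[v]]) mask[v] <- bitwOr(mask[v], mask[ch])
    }
  }
  ## node-count depth from the root (root = 0)
  ndepth <- integer(nn)
  for (v in rev(st$order)) {
    if (v != st$root) ndepth[v] <- ndepth[st$parent[v]] + 1L
  }
  ## minimal containing node for every nonzero population mask; clusters
  ## are laminar so the first containing node in child-before-parent order
  ## is the LCA
  lookup <- integer(bitwShiftL(1L, k))
  for (m in seq_len(bitwShiftL(1L, k) - 1L)) {
    for (v in st$order) {
      if (bitwAnd(mask[v], m) == m) { lookup[m + 1L] <- v; break }
    }
  }
  ac <- assignment_counts(st, assignment)
  if (any(ac$counts == 0L)) {
    stop2("deep-coalescence scoring requires at least one sample in ",
          "every population (empty: ",
          paste(st$tips[ac$counts == 0L], collapse = ", "), ")")
  }
  ## per-gene-tip species index in simulator tip order
  tip_sp_sim <- rep(seq_len(k), times = ac$counts)
  list(st = st, k = k, mask = mask, ndepth = ndepth, lookup = lookup,
       n_edges = nn - 1L, counts = ac$counts, labels = ac$labels,
       tip_sp_sim = tip_sp_sim)
}

## Score a simulated gene tree in its compact event representation.
## DC = sum over non-root gene nodes of (depth[M(node)] - depth[M(parent)])
##      + depth[M(gene root)] - (#population-tree edges),
## which totals (lineages - 1) over all population-tree edges, counting
## lineages at the rootward end of each edge (the gene-root lineage is
## extended to the population-tree root).
dc_score_events <- function(ds, ev) {
  n <- ev$n
  nv <- 2L * n - 1L
  mask <- integer(nv)
  mask[seq_len(n)] <- bitwShiftL(1L, ev$tip_sp - 1L)
  for (v in seq_len(nv - 1L)) {
    p <- ev$parent[v]
    mask[p] <- bitwOr(mask[p], mask[v])
  }
  mdep <- ds$ndepth[ds$lookup[mask + 1L]]
  sum(mdep[seq_len(nv - 1L)] - mdep[ev$parent[seq_len(nv - 1L)]]) +
    mdep[nv] - ds$n_edges
}

#' Deep-coalescence reconciliation cost
#'
#' Minimal number of extra gene lineages needed to reconcile a gene tree
#' with a population tree under incomplete lineage sorting. Gene-tree
#' branch lengths are ignored; the population tree may be binary or a star
#' (polytomies in the population tree are scored directly).
#'
#' @param gene_tree A `"phylo"` gene tree whose tips are all assigned.
#' @param model A `"pop_tree"`.
#' @param assignment A `"sample_assignment"` covering every gene-tree tip
#'   (defaults to the assignment attached to `gene_tree`, if any).
#' @return A nonnegative integer count of extra lineages.
#' @examples
#' m <- divergence_model("((A,B),C);", depths = c(2, 1),
#'                       samples = c(A = 1, B = 1, C = 1),
#'                       regions = c("A", "B", "C"))
#' g <- read_newick("((a:1,c:1):1,b:2):0;")
#' asg <- load_assignment(data.frame(tip = c("a", "b", "c"),
#'                                   region = c("A", "B", "C")),
#'                        regions = c("A", "B", "C"))
#' deep_coalescence_cost(g, m, asg) # 1 extra lineage
#' @export
deep_coalescence_cost <- function(gene_tree, model, assignment = NULL) {
  stopifnot(inherits(gene_tree, "phylo"))
  if (is.null(assignment)) assignment <- attr(gene_tree, "assignment")
  if (is.null(assignment)) stop2("no assignment given or attached")
  miss <- setdiff(gene_tree$tip.label, names(assignment))
  if (length(miss)) {
    stop2("unassigned gene-tree tip(s): ", paste(miss, collapse = ", "))
  }
  ds <- dc_struct(model, assignment[gene_tree$tip.label])
  ntip <- ape::Ntip(gene_tree)
  nv <- ntip + gene_tree$Nnode
  sp_idx <- match(as.character(assignment[gene_tree$tip.label]), ds$st$tips)
  mask <- integer(nv)
  mask[seq_len(ntip)] <- bitwShiftL(1L, sp_idx - 1L)
  po <- ape::postorder(gene_tree)
  for (e in po) {
    p <- gene_tree$edge[e, 1]; ch <- gene_tree$edge[e, 2]
    mask[p] <- bitwOr(mask[p], mask[ch])
  }
  mdep <- ds$ndepth[ds$lookup[mask + 1L]]
  root <- gene_tree$edge[po[length(po)], 1]
  sum(mdep[gene_tree$edge[, 2]] - mdep[gene_tree$edge[, 1]]) +
    mdep[root] - ds$n_edges
}

#' Simulation test of a population-divergence model
#'
#' Scores the observed gene tree against a population-divergence model with
#' the deep-coalescence cost, builds a null distribution of costs from gene
#' trees simulated under the multispecies coalescent within that same
#' model, and reports a lower-tail p-value: the model is supported when the
#' observed discordance is significantly *smaller* than expected under the
#' model's own lineage sorting, i.e. the observed tree fits the model
#' better than chance. The p-value uses the add-one correction
#' `p = (1 + #\{null <= observed\}) / (1 + n_sims)` with ties counted
#' toward the tail (conservative).
#'
#' @param observed Observed gene tree (`"phylo"`).
#' @param model A `"pop_tree"` divergence model.
#' @param assignment A `"sample_assignment"`; defaults to the one attached
#'   to `observed`.
#' @param n_sims Number of null simulations (>= 100; a warning is issued
#'   below 1000).
#' @param alpha Significance level for the support decision (default 0.05).
#' @param seed Optional integer seed.
#' @return An object of class `"dc_test"` with fields `observed_dc`,
#'   `null_values`, `null_mean`, `null_sd`, `p_value`, `decision`
#'   (`"supported"` or `"rejected"`), `model_name`, `n_sims`, `alpha`.
#' @examples
#' m <- divergence_model("SRM")
#' g <- simulate_msc(m, seed = 7)
#' dc_model_test(g, m, n_sims = 200, seed = 1)
#' @export
dc_model_test <- function(observed, model, assignment = NULL,
                          n_sims = 1000L, alpha = 0.05, seed = NULL) {
  if (!is_count(n_sims) || n_sims < 100) {
    stop2("'n_sims' must be an integer >= 100")
  }
  if (n_sims < 1000) {
    warning("n_sims < 1000: the null distribution will be coarse",
            call. = FALSE)
  }
  if (is.null(assignment)) assignment <- attr(observed, "assignment")
  obs_dc <- deep_coalescence_cost(observed, model, assignment)
  ds <- dc_struct(model, assignment)
  null_values <- with_seed(seed, vapply(seq_len(n_sims), function(i) {
    dc_score_events(ds, sim_msc_events(ds$st, ds$counts))
  }, numeric(1)))
  p <- (1 + sum(null_values <= obs_dc)) / (1 + n_sims)
  structure(list(observed_dc = obs_dc,
                 null_values = as.integer(null_values),
                 null_mean = mean(null_values),
                 null_sd = sd(null_values),
                 p_value = p,
                 decision = if (p < alpha) "supported" else "rejected",
                 model_name = model$name, n_sims = n_sims, alpha = alpha),
            class = "dc_test")
}

#' @export
print.dc_test <- function(x, ...) {
  cat("Deep-coalescence model test (model '", x$model_name, "')\n", sep = "")
  cat(sprintf("  observed DC: %d\n", x$observed_dc))
  cat(sprintf("  null: mean %.2f, sd %.2f (%d simulations)\n",
              x$null_mean, x$null_sd, x$n_sims))
  cat(sprintf("  p = %.4g  ->  %s at alpha = %g\n",
              x$p_value, x$decision, x$alpha))
  invisible(x)
}
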