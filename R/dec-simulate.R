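## Forward simulation under the (stratified) DEC model, for parameter
## recovery experiments and synthetic fixtures.

#' Simulate tip ranges under a DEC model
#'
#' Forward-simulates geographic range evolution down a time-scaled binary
#' tree: a root range is drawn (uniformly over permissible nonempty ranges
#' unless given), cladogenetic inheritance is sampled at every node from
#' [cladogenesis_distribution()], and anagenetic dispersal/extinction
#' events are sampled along branches by the Gillespie algorithm with rates
#' switching at stratum boundaries. A lineage whose range hits the
#' absorbing null range has gone globally extinct, which the fixed tree
#' cannot represent; the whole simulation is then retried (up to
#' `max_retries`, with the retry count recorded in the result attributes).
#'
#' @param tree Binary ultrametric `"phylo"` with depth `model$root_age`.
#' @param model A `"dec_model"`.
#' @param params `c(d = , e = )` true rates.
#' @param seed Optional integer seed.
#' @param root_state Optional fixed root range (character areas or bitmask).
#' @param max_retries Retry cap for extinction (default 100).
#' @return A `"range_data"` matrix (tips x areas) with attributes
#'   `"params"`, `"root_state"` and `"retries"`.
#' @export
simulate_dec <- function(tree, model, params, seed = NULL,
                         root_state = NULL, max_retries = 100L) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "dec_model"))
  if (!ape::is.binary(tree)) stop2("DEC simulation requires a binary tree")
  ntip <- ape::Ntip(tree)
  depth <- node_depths(tree)
  if (abs(max(depth[1:ntip]) - model$root_age) > 1e-6 * model$root_age) {
    stop2("tree depth does not match the model root_age")
  }
  age <- pmax(model$root_age - depth, 0)
  k <- length(model$areas)
  nonempty <- model$states[model$states != 0L]
  root_mask <- if (is.null(root_state)) NULL
    else if (is.character(root_state)) range_mask(root_state, model$areas)
    else as.integer(root_state)
  if (!is.null(root_mask) && !(root_mask %in% nonempty)) {
    stop2("root_state is not a permissible nonempty range")
  }
  po <- ape::postorder(tree)
  pre <- rev(po) # rootward-first edges
  root <- tree$edge[pre[1], 1]
  d <- params[["d"]]; e <- params[["e"]]
  strata <- model$strata
  ns <- length(strata)
  so <- vapply(strata, `[[`, numeric(1), "older")
  sy <- vapply(strata, `[[`, numeric(1), "younger")
  ## stratum covering the instant just *below* t, so a lineage sitting on
  ## a boundary always advances into the younger stratum
  stratum_at <- function(t) {
    for (i in seq_len(ns)) {
      if (t > sy[i] + 1e-12 && t <= so[i] + 1e-12) return(i)
    }
    ns
  }
  evolve_branch <- function(mask, t_old, t_yng) {
    t <- t_old
    while (t > t_yng + 1e-12) {
      s <- stratum_at(t)
      seg_end <- max(sy[s], t_yng)
      D <- strata[[s]]$D
      repeat {
        occ <- which(bitwAnd(bitwShiftR(mask, 0:(k - 1)), 1L) == 1L)
        gains <- numeric(0); gain_a <- integer(0)
        if (length(occ) < model$max_range_size) {
          for (a in setdiff(seq_len(k), occ)) {
            r <- d * sum(D[occ, a])
            if (r > 0) { gains <- c(gains, r); gain_a <- c(gain_a, a) }
          }
        }
        loss <- rep(e, length(occ))
        tot <- sum(gains) + sum(loss)
        if (tot <= 0) { t <- seg_end; break }
        dt <- rexp(1L, tot)
        if (t - dt < seg_end) { t <- seg_end; break }
        t <- t - dt
        ev <- sample.int(length(gains) + length(loss), 1L,
                         prob = c(gains, loss) / tot)
        if (ev <= length(gains)) {
          mask <- bitwOr(mask, bitwShiftL(1L, gain_a[ev] - 1L))
        } else {
          a <- occ[ev - length(gains)]
          mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, a - 1L)))
          if (mask == 0L) return(0L) # global extinction
        }
      }
    }
    mask
  }
  retries <- 0L
  ## evolve a branch conditional on the lineage not going globally
  ## extinct: a lineage hitting the null range is recorded and that
  ## branch is resimulated from its start state (per-lineage retry)
  evolve_surviving <- function(start, t_old, t_yng) {
    for (i in seq_len(max_retries + 1L)) {
      res <- evolve_branch(start, t_old, t_yng)
      if (res != 0L) return(res)
      retries <<- retries + 1L
    }
    stop2("extinction retry cap exceeded (", max_retries,
          ") on a single branch")
  }
  sim_once <- function() {
    state <- integer(ntip + tree$Nnode)
    state[root] <- if (is.null(root_mask)) {
      nonempty[sample.int(length(nonempty), 1L)]
    } else root_mask
    daughters <- vector("list", ntip + tree$Nnode)
    out <- clado_outcomes(state[root], k)
    pick <- sample.int(length(out$prob), 1L, prob = out$prob)
    daughters[[root]] <- c(out$left[pick], out$right[pick])
    slot <- integer(ntip + tree$Nnode) # next daughter slot per parent
    for (eidx in pre) {
      p <- tree$edge[eidx, 1]; chn <- tree$edge[eidx, 2]
      slot[p] <- slot[p] + 1L
      start <- daughters[[p]][slot[p]]
      res <- evolve_surviving(start, age[p], age[chn])
      state[chn] <- res
      if (chn > ntip) {
        out <- clado_outcomes(res, k)
        pick <- sample.int(length(out$prob), 1L, prob = out$prob)
        daughters[[chn]] <- c(out$left[pick], out$right[pick])
      }
    }
    state[seq_len(ntip)]
  }
  with_seed(seed, {
    tips <- sim_once()
    m <- t(vapply(tips, function(msk) {
      as.integer(bitwAnd(bitwShiftR(msk, 0:(k - 1)), 1L))
    }, integer(k)))
    dimnames(m) <- list(tree$tip.label, model$areas)
    out <- range_data(m)
    attr(out, "params") <- params
    attr(out, "retries") <- retries
    out
  })
}
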