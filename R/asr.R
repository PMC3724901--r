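## Prior-calibrated marginal ancestral-state reconstruction of binary
## characters over a posterior tree sample.
##
## Characters evolve under a two-state continuous-time Markov chain with
## overall rate r and stationary bias pi1 (default 0.5, symmetric):
## q01 = r*pi1, q10 = r*(1-pi1). Rates are drawn from a gamma(alpha, beta)
## prior (beta = scale, mean alpha*beta) estimated per character by MCMC
## over the tree sample; node-state posteriors are exact pruning marginals
## averaged over trees and prior draws.

#' Define a binary character
#'
#' @param name Character name (e.g. `"Habit"`).
#' @param data Named vector over taxa: values must be the two `states`
#'   labels, 0/1, or `NA` (missing, marginalised over).
#' @param states Two state labels, order = (state0, state1).
#' @return An object of class `"binary_character"`.
#' @export
binary_character <- function(name, data, states = c("0", "1")) {
  stopifnot(is.character(name), length(states) == 2L,
            !is.null(names(data)))
  v <- as.character(data)
  v[v %in% c("?", "-", "")] <- NA
  ok <- is.na(v) | v %in% states | v %in% c("0", "1")
  if (!all(ok)) {
    stop2("character '", name, "': invalid state(s) ",
          paste(unique(v[!ok]), collapse = ", "))
  }
  idx <- ifelse(is.na(v), NA_integer_,
                ifelse(v == states[2] | v == "1", 1L, 0L))
  if (all(is.na(idx))) stop2("character '", name, "' is entirely missing")
  structure(list(name = name, states = states,
                 data = setNames(idx, names(data))),
            class = "binary_character")
}

#' @export
print.binary_character <- function(x, ...) {
  tab <- table(factor(x$data, levels = 0:1, labels = x$states),
               useNA = "ifany")
  cat("Binary character '", x$name, "': ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Gamma prior on the substitution rate
#'
#' `alpha` is the shape and `beta` the scale, so the prior mean is
#' `alpha * beta` (the parameterisation in which rate priors are usually
#' reported for stochastic-mapping analyses). A degenerate (point-mass)
#' prior is available via `fixed`.
#'
#' @param alpha,beta Shape and scale (> 0).
#' @param fixed If non-`NULL`, a fixed rate: draws return exactly this
#'   value (used for exactness checks).
#' @return An object of class `"rate_prior"`.
#' @export
rate_prior <- function(alpha, beta, fixed = NULL) {
  if (is.null(fixed)) {
    stopifnot(alpha > 0, beta > 0)
  } else {
    stopifnot(is.numeric(fixed), fixed >= 0)
    alpha <- NA_real_; beta <- NA_real_
  }
  structure(list(alpha = alpha, beta = beta, fixed = fixed),
            class = "rate_prior")
}

#' @export
print.rate_prior <- function(x, ...) {
  if (!is.null(x$fixed)) {
    cat("Rate prior: fixed at", x$fixed, "\n")
  } else {
    cat(sprintf("Rate prior: gamma(alpha = %.4g, beta = %.4g), mean %.4g\n",
                x$alpha, x$beta, x$alpha * x$beta))
  }
  invisible(x)
}

draw_rates <- function(prior, n) {
  if (!is.null(prior$fixed)) rep(prior$fixed, n)
  else rgamma(n, shape = prior$alpha, scale = prior$beta)
}

## 2x2 transition matrix for overall rate r, bias pi1, time t
p2 <- function(r, pi1, t) {
  ex <- exp(-r * t)
  matrix(c(1 - pi1 * (1 - ex), pi1 * (1 - ex),
           (1 - pi1) * (1 - ex), 1 - (1 - pi1) * (1 - ex)),
         2, 2, byrow = TRUE)
}

## pruning partials (down pass); returns list(D = partials matrix,
## loglik, root). Missing tips get partial (1,1).
char_partials <- function(tree, char, rate, bias = 0.5) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  D <- matrix(1, nn, 2)
  st <- char$data[tree$tip.label]
  has <- !is.na(st)
  D[cbind(which(has), st[has] + 1L)] <- 1
  D[cbind(which(has), 2L - st[has])] <- 0
  po <- ape::postorder(tree)
  logscale <- 0
  for (e in po) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    P <- p2(rate, bias, tree$edge.length[e])
    up <- P %*% D[ch, ]
    D[p, ] <- D[p, ] * up
    mx <- max(D[p, ])
    if (mx > 0 && mx < 1e-200) { # guard against underflow on big trees
      D[p, ] <- D[p, ] / mx
      logscale <- logscale + log(mx)
    }
  }
  root <- tree$edge[po[length(po)], 1]
  prior <- c(1 - bias, bias)
  lik <- sum(prior * D[root, ])
  list(D = D, root = root, po = po,
       loglik = if (lik > 0) log(lik) + logscale else -Inf)
}

## exact marginal posterior of the state at `node`, via down + up pass
char_marginal <- function(tree, char, rate, node, bias = 0.5) {
  dp <- char_partials(tree, char, rate, bias)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  U <- matrix(0, nn, 2)
  U[dp$root, ] <- c(1 - bias, bias)
  kids <- vector("list", nn)
  for (e in dp$po) {
    p <- tree$edge[e, 1]
    kids[[p]] <- c(kids[[p]], e)
  }
  for (e in rev(dp$po)) { # rootward-first
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    P <- p2(rate, bias, tree$edge.length[e])
    sibs <- setdiff(kids[[p]], e)
    contrib <- U[p, ]
    for (se in sibs) {
      sch <- tree$edge[se, 2]
      Ps <- p2(rate, bias, tree$edge.length[se])
      contrib <- contrib * as.vector(Ps %*% dp$D[sch, ])
    }
    U[ch, ] <- as.vector(contrib %*% P)
  }
  m <- dp$D[node, ] * U[node, ]
  m / sum(m)
}

#' Estimate a gamma rate prior by MCMC
#'
#' Samples the overall substitution rate of a binary character under the
#' two-state model, integrating over the tree sample: a
#' Metropolis-Hastings chain alternates log-scale random-walk moves on the
#' rate (flat prior on the rate up to `rate_max`) with uniform redraws of
#' the tree index. A gamma(alpha, beta) prior is then fitted to the
#' post-burn-in rate sample by moment matching (`alpha = mean^2/var`,
#' `beta = var/mean`).
#'
#' @param char A `"binary_character"` whose taxa are tips of the trees.
#' @param trees A [tree_sample()].
#' @param n_iter Total MCMC iterations (default 2000; first 25% burn-in).
#' @param seed Optional integer seed.
#' @param bias Stationary frequency of state 1 (default 0.5, symmetric).
#' @param rate_max Upper bound of the flat rate prior, in expected
#'   changes per unit branch length (default 5, appropriate for trees
#'   scaled to unit depth: beyond a handful of expected changes per tree
#'   depth the two-state likelihood saturates and rates are
#'   indistinguishable, so an unbounded flat prior would leave the
#'   posterior dominated by its tail; rescale for other time units).
#' @param step Proposal standard deviation on the log-rate scale.
#' @return A `"rate_prior"` with the fitted `alpha`, `beta`; the rate
#'   sample and acceptance rate are attached as attributes. An invariant
#'   (single observed state) character yields a warning and the default
#'   prior `gamma(1, 1)`.
#' @export
estimate_rate_prior <- function(char, trees, n_iter = 2000L, seed = NULL,
                                bias = 0.5, rate_max = 5, step = 0.6) {
  stopifnot(inherits(char, "binary_character"),
            inherits(trees, "tree_sample"))
  miss <- setdiff(names(char$data), trees[[1]]$tip.label)
  if (length(miss)) stop2("character taxa not in trees: ",
                          paste(miss, collapse = ", "))
  obs <- char$data[!is.na(char$data)]
  if (length(unique(obs)) < 2L) {
    warning("character '", char$name,
            "' is invariant; returning default prior gamma(1, 1)",
            call. = FALSE)
    return(rate_prior(1, 1))
  }
  with_seed(seed, {
    nt <- length(trees)
    ti <- sample.int(nt, 1L)
    r <- 0.5
    ll <- char_partials(trees[[ti]], char, r, bias)$loglik
    keep <- numeric(n_iter)
    acc <- 0L
    for (it in seq_len(n_iter)) {
      ## rate move (log-scale walk; Hastings ratio r'/r for the flat prior)
      rp <- r * exp(stats::rnorm(1, 0, step))
      if (rp <= rate_max) {
        llp <- char_partials(trees[[ti]], char, rp, bias)$loglik
        if (log(runif(1)) < llp - ll + log(rp / r)) {
          r <- rp; ll <- llp; acc <- acc + 1L
        }
      }
      ## tree move (uniform independence proposal)
      tj <- sample.int(nt, 1L)
      if (tj != ti) {
        llj <- char_partials(trees[[tj]], char, r, bias)$loglik
        if (log(runif(1)) < llj - ll) {
          ti <- tj; ll <- llj
        }
      }
      keep[it] <- r
    }
    post <- keep[-seq_len(floor(n_iter / 4))]
    m <- mean(post); v <- var(post)
    if (v <= 0) v <- (0.1 * m)^2
    out <- rate_prior(alpha = m^2 / v, beta = v / m)
    attr(out, "samples") <- post
    attr(out, "acceptance") <- acc / n_iter
    out
  })
}

#' Marginal ancestral state at a clade
#'
#' For every tree in the sample and every rate drawn from the prior,
#' computes the exact pruning marginal posterior of the character state at
#' the most recent common ancestor of the clade's tips, and averages. In
#' trees where the clade is not monophyletic the MRCA of the tip set is
#' used (it then subtends extra tips); the number of such trees is
#' reported.
#'
#' @inheritParams estimate_rate_prior
#' @param prior A `"rate_prior"`.
#' @param clade Character vector of tip labels defining the clade.
#' @param n_draws Rate draws per tree (default 10).
#' @param threshold Posterior probability for the significance call
#'   (default 0.95).
#' @param clade_id Optional clade label for reporting.
#' @return An object of class `"asr_result"`: `clade`, `posterior` (named
#'   per state, sums to 1), `significant`, `state` (the modal state),
#'   `n_nonmonophyletic`, `n_trees`, `n_draws`.
#' @export
marginal_asr <- function(char, trees, prior, clade, n_draws = 10L,
                         seed = NULL, bias = 0.5, threshold = 0.95,
                         clade_id = NULL) {
  stopifnot(inherits(char, "binary_character"),
            inherits(trees, "tree_sample"), inherits(prior, "rate_prior"))
  unknown <- setdiff(clade, trees[[1]]$tip.label)
  if (length(unknown)) stop2("unknown clade tip(s): ",
                             paste(unknown, collapse = ", "))
  if (!is_count(n_draws)) stop2("'n_draws' must be a positive integer")
  with_seed(seed, {
    acc <- c(0, 0)
    nonmono <- 0L
    for (tr in trees) {
      node <- mrca_node(tr, clade)
      ntip <- ape::Ntip(tr)
      desc <- if (node <= ntip) tr$tip.label[node] else
        ape::extract.clade(tr, node)$tip.label
      if (length(desc) != length(unique(clade))) nonmono <- nonmono + 1L
      for (r in draw_rates(prior, n_draws)) {
        acc <- acc + char_marginal(tr, char, r, node, bias)
      }
    }
    post <- acc / sum(acc)
    names(post) <- char$states
    structure(list(clade = clade, clade_id = clade_id %||% "clade",
                   character = char$name, posterior = post,
                   state = char$states[which.max(post)],
                   significant = max(post) > threshold,
                   threshold = threshold,
                   n_nonmonophyletic = nonmono,
                   n_trees = length(trees), n_draws = n_draws),
              class = "asr_result")
  })
}

#' @export
print.asr_result <- function(x, ...) {
  cat("Ancestral state for ", x$clade_id, " / '", x$character, "': ",
      sep = "")
  cat(sprintf("%s=%.3f %s=%.3f%s\n",
              names(x$posterior)[1], x$posterior[1],
              names(x$posterior)[2], x$posterior[2],
              if (x$significant) sprintf("  [significant > %.2f]",
                                         x$threshold) else ""))
  if (x$n_nonmonophyletic > 0) {
    cat("  (clade non-monophyletic in", x$n_nonmonophyletic, "of",
        x$n_trees, "trees; MRCA of the tip set used)\n")
  }
  invisible(x)
}

#' Prune a tree sample to one tip per taxon
#'
#' @param trees A [tree_sample()].
#' @param keep Character vector of tip labels to retain (e.g. one
#'   representative individual per taxon); degree-2 nodes are suppressed
#'   and their branch lengths summed.
#' @return A pruned `tree_sample`.
#' @export
prune_to_one_per_taxon <- function(trees, keep) {
  stopifnot(inherits(trees, "tree_sample"), is.character(keep))
  miss <- setdiff(keep, trees[[1]]$tip.label)
  if (length(miss)) stop2("tip(s) absent from trees: ",
                          paste(miss, collapse = ", "))
  tree_sample(lapply(trees, ape::keep.tip, tip = keep))
}

#' Prior-scaling sensitivity scan
#'
#' Repeats [marginal_asr()] with the prior mean scaled by each factor
#' (the scale `beta` is multiplied, the shape `alpha` kept fixed) to check
#' whether significance calls are prior-driven.
#'
#' @inheritParams marginal_asr
#' @param factors Prior-mean scaling factors (default `c(0.1, 1, 10)`).
#' @return A data.frame with one row per factor (`factor`, per-state
#'   posteriors, `state`, `significant`) plus attribute
#'   `"calls_stable"`: `TRUE` when the significance call is identical
#'   across factors.
#' @export
sensitivity_scan <- function(char, trees, prior, clade,
                             factors = c(0.1, 1, 10), n_draws = 10L,
                             seed = NULL, bias = 0.5, threshold = 0.95,
                             clade_id = NULL) {
  if (any(factors <= 0)) stop2("scaling factors must be positive")
  if (!is.null(prior$fixed)) stop2("sensitivity scan needs a gamma prior")
  seeds <- spawn_seeds(seed %||% sample.int(1e6, 1), length(factors))
  rows <- lapply(seq_along(factors), function(i) {
    p <- rate_prior(prior$alpha, prior$beta * factors[i])
    r <- marginal_asr(char, trees, p, clade, n_draws, seed = seeds[i],
                      bias = bias, threshold = threshold,
                      clade_id = clade_id)
    data.frame(factor = factors[i],
               p0 = unname(r$posterior[1]), p1 = unname(r$posterior[2]),
               state = r$state, significant = r$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- char$states
  calls <- paste(out$significant, ifelse(out$significant, out$state, ""))
  attr(out, "calls_stable") <- length(unique(calls)) == 1L
  out
}

#' Read a binary character matrix
#'
#' Reads either a TSV (first column taxon, one column per character,
#' entries the state labels, 0/1 or `?` for missing) or a NEXUS characters
#' block (via [ape::read.nexus.data()]).
#'
#' @param file Path to the TSV or NEXUS file.
#' @return A named list of `"binary_character"` objects.
#' @export
read_characters <- function(file) {
  first <- readLines(file, n = 1L)
  if (grepl("^#NEXUS", first, ignore.case = TRUE)) {
    dat <- ape::read.nexus.data(file)
    taxa <- names(dat)
    nchar_ <- length(dat[[1]])
    chars <- lapply(seq_len(nchar_), function(j) {
      v <- vapply(dat, `[[`, character(1), j)
      binary_character(paste0("char", j), setNames(v, taxa))
    })
    names(chars) <- paste0("char", seq_len(nchar_))
    return(chars)
  }
  df <- read.delim(file, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  taxa <- as.character(df[[1]])
  chars <- lapply(names(df)[-1], function(nm) {
    binary_character(nm, setNames(as.character(df[[nm]]), taxa))
  })
  names(chars) <- names(df)[-1]
  chars
}

#' @rdname read_characters
#' @param chars Named list of `"binary_character"` objects sharing taxa.
#' @param file Output TSV path.
#' @export
write_characters <- function(chars, file) {
  taxa <- names(chars[[1]]$data)
  df <- data.frame(taxon = taxa, check.names = FALSE)
  for (ch in chars) {
    v <- ch$data[taxa]
    df[[ch$name]] <- ifelse(is.na(v), "?", as.character(v))
  }
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read / write clade definitions as JSON
#'
#' Clades are named tip-label sets (e.g. the well-supported sub-clades of
#' a phylogeny at which ancestral states are reconstructed), stored as a
#' JSON object mapping clade id to an array of tip labels.
#'
#' @param clades Named list of character vectors of tip labels.
#' @param file JSON path.
#' @return `write_clades()` returns `file` invisibly; `read_clades()`
#'   returns the named list.
#' @export
write_clades <- function(clades, file) {
  stopifnot(is.list(clades), !is.null(names(clades)))
  jsonlite::write_json(clades, file, auto_unbox = FALSE, pretty = TRUE)
  invisible(file)
}

#' @rdname write_clades
#' @export
read_clades <- function(file) {
  clades <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (is.null(names(clades)) || any(names(clades) == "")) {
    stop2("clade definitions must be a named JSON object")
  }
  lapply(clades, as.character)
}
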