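## DEC likelihood by postorder pruning, maximum-likelihood fitting, and
## model comparison.

#' Read / write a tip range matrix
#'
#' Range matrices are TSV files with tips as rows and areas as columns,
#' entries 0/1 (1 = tip occupies the area), first column holding the tip
#' label.
#'
#' @param file TSV path.
#' @param areas Expected area labels; if supplied, the columns are checked
#'   and reordered to match.
#' @return A 0/1 integer matrix with tip rownames, class `"range_data"`.
#' @export
read_range_matrix <- function(file, areas = NULL) {
  df <- read.delim(file, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  rn <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- rn
  range_data(m, areas)
}

#' @rdname read_range_matrix
#' @param ranges 0/1 matrix (tips x areas) with rownames and colnames.
#' @export
range_data <- function(ranges, areas = NULL) {
  m <- as.matrix(ranges)
  storage.mode(m) <- "integer"
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop2("range matrix needs tip rownames and area colnames")
  }
  if (!all(m %in% c(0L, 1L))) stop2("range matrix entries must be 0/1")
  if (any(rowSums(m) == 0L)) {
    stop2("tip(s) with empty range: ",
          paste(rownames(m)[rowSums(m) == 0L], collapse = ", "))
  }
  if (!is.null(areas)) {
    if (!setequal(colnames(m), areas)) {
      stop2("range matrix areas do not match the model's areas")
    }
    m <- m[, areas, drop = FALSE]
  }
  structure(m, class = c("range_data", class(m)))
}

#' @rdname read_range_matrix
#' @param x A `"range_data"` matrix.
#' @export
write_range_matrix <- function(x, file) {
  df <- data.frame(tip = rownames(x), unclass(x), check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

## tip state indices for a model, from a range matrix
tip_state_indices <- function(model, ranges) {
  m <- ranges[, model$areas, drop = FALSE]
  masks <- as.integer(m %*% bitwShiftL(1L, seq_along(model$areas) - 1L))
  idx <- match(masks, model$states)
  if (anyNA(idx)) {
    bad <- rownames(m)[is.na(idx)]
    stop2("tip range larger than max_range_size for: ",
          paste(bad, collapse = ", "))
  }
  setNames(idx, rownames(m))
}

## shared pruning engine. Returns log state partials at the root (bottom,
## i.e. after the root cladogenesis) plus the log scaling constant.
dec_root_partials <- function(tree, ranges, model, params) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "dec_model"))
  if (!ape::is.binary(tree)) stop2("DEC requires a strictly binary tree")
  if (!is_ultrametric(tree, 1e-6)) stop2("DEC requires an ultrametric tree")
  ntip <- ape::Ntip(tree)
  depth <- node_depths(tree)
  if (abs(max(depth[1:ntip]) - model$root_age) >
      1e-6 * model$root_age) {
    stop2("tree depth (", signif(max(depth[1:ntip]), 6),
          ") does not match the model root_age (", model$root_age, ")")
  }
  miss <- setdiff(tree$tip.label, rownames(ranges))
  if (length(miss)) stop2("tip(s) without a range: ",
                          paste(miss, collapse = ", "))
  age <- pmax(model$root_age - depth, 0)
  tipidx <- tip_state_indices(model, ranges)[tree$tip.label]
  ns <- length(model$states)
  qs <- stratum_qs(model, params)
  ct <- clado_table(model)
  nn <- ntip + tree$Nnode
  L <- matrix(0, nn, ns)   # bottom partials (post-cladogenesis)
  L[cbind(seq_len(ntip), tipidx)] <- 1
  logscale <- 0
  po <- ape::postorder(tree)
  kids <- matrix(0L, nn, 2L)
  for (e in po) {
    p <- tree$edge[e, 1]
    kids[p, if (kids[p, 1] == 0L) 1L else 2L] <- tree$edge[e, 2]
  }
  ## internal nodes in child-before-parent order: an internal node's
  ## leading edge appears in the postorder list after the leading edges of
  ## all its internal descendants; the root (no leading edge) goes last
  ch <- tree$edge[po, 2]
  internal <- c(ch[ch > ntip], tree$edge[po[length(po)], 1])
  for (p in internal) {
    tops <- lapply(1:2, function(j) {
      ch <- kids[p, j]
      P <- branch_p(model, qs, age[p], age[ch])
      as.vector(P %*% L[ch, ])
    })
    v <- numeric(ns)
    for (i in seq_len(ns)) {
      tab <- ct[[i]]
      if (is.null(tab)) next
      v[i] <- sum(tab$w * tops[[1]][tab$left] * tops[[2]][tab$right])
    }
    mx <- max(v)
    if (mx <= 0) {
      return(list(log_partials = rep(-Inf, ns), impossible = TRUE))
    }
    L[p, ] <- v / mx
    logscale <- logscale + log(mx)
  }
  root <- internal[length(internal)]
  lp <- rep(-Inf, ns)
  pos <- L[root, ] > 0
  lp[pos] <- log(L[root, pos]) + logscale
  list(log_partials = lp, impossible = FALSE)
}

#' DEC negative log-likelihood
#'
#' Postorder pruning likelihood of tip ranges under a (possibly
#' time-stratified) DEC model. At the root the likelihood is the sum of
#' the root state partials over all permissible nonempty ranges (weight 1
#' each, the convention under which every root-constrained `-lnL` is at
#' least the global `-lnL`); pass `root_state` to constrain the root.
#'
#' @param tree Binary ultrametric `"phylo"` with depth equal to the model's
#'   `root_age`.
#' @param ranges A `"range_data"` matrix covering every tip.
#' @param model A `"dec_model"`.
#' @param params `c(d = , e = )` dispersal/extinction rates.
#' @param root_state Optional root range (character vector of areas or
#'   bitmask) to constrain the root.
#' @return The negative log-likelihood (`Inf` when the data are impossible
#'   under the parameters, e.g. discordant tips with `d = 0`).
#' @export
dec_loglik <- function(tree, ranges, model, params, root_state = NULL) {
  rp <- dec_root_partials(tree, ranges, model, params)
  lp <- rp$log_partials
  if (is.null(root_state)) {
    keep <- model$states != 0L
  } else {
    mask <- if (is.character(root_state)) {
      range_mask(root_state, model$areas)
    } else as.integer(root_state)
    keep <- model$states == mask
    if (!any(keep)) stop2("root_state is not in the state space")
  }
  lp <- lp[keep]
  mx <- max(lp)
  if (!is.finite(mx)) return(Inf)
  -(mx + log(sum(exp(lp - mx))))
}

#' Maximum-likelihood DEC fit
#'
#' Fits the global dispersal and extinction rates by bounded
#' maximum likelihood (L-BFGS-B on log-rates, multistart), and tabulates
#' the root-state support: the `-lnL` obtained when the root is
#' constrained to each permissible range, sorted ascending.
#'
#' @inheritParams dec_loglik
#' @param lower,upper Box constraints on both rates (defaults 1e-9 and
#'   100; boundary estimates are reported as such).
#' @param n_starts Number of optimiser starts (>= 1; the first starts are
#'   a fixed coarse grid, further ones are seeded jitter).
#' @param seed Optional integer seed for the extra starts.
#' @return An object of class `"dec_fit"`: `params`, `neg_loglik`,
#'   `root_table` (data.frame `root`, `neg_loglik`), `model`,
#'   `convergence`, `at_bound`.
#' @export
fit_dec <- function(tree, ranges, model, lower = 1e-9, upper = 100,
                    n_starts = 4L, seed = NULL) {
  obj <- function(lpar) {
    nll <- dec_loglik(tree, ranges, model,
                      c(d = exp(lpar[1]), e = exp(lpar[2])))
    if (!is.finite(nll)) 1e10 else nll
  }
  grid <- list(c(-4, -4), c(-2, -4), c(-4, -2), c(-1, -1))
  span <- model$strata[[1]]$older
  ## centre the grid on rates of order 1/span so it adapts to time units
  grid <- lapply(grid, function(g) g + log(10 / span))
  starts <- grid[seq_len(min(n_starts, length(grid)))]
  if (n_starts > length(grid)) {
    extra <- with_seed(seed, lapply(seq_len(n_starts - length(grid)),
      function(i) runif(2, log(lower) * 0.5, log(upper) * 0.5)))
    starts <- c(starts, extra)
  }
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, log(lower)), log(upper))
    fit <- tryCatch(
      optim(s, obj, method = "L-BFGS-B",
            lower = log(lower), upper = log(upper),
            control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) stop2("all optimiser starts failed")
  params <- c(d = exp(best$par[1]), e = exp(best$par[2]))
  rp <- dec_root_partials(tree, ranges, model, params)
  keep <- model$states != 0L
  rt <- data.frame(root = model$state_labels[keep],
                   neg_loglik = -rp$log_partials[keep],
                   stringsAsFactors = FALSE)
  rt <- rt[order(rt$neg_loglik), ]
  rownames(rt) <- NULL
  structure(list(params = params, neg_loglik = best$value,
                 root_table = rt, model = model,
                 convergence = best$convergence,
                 at_bound = any(abs(best$par - log(upper)) < 1e-6) ||
                            any(abs(best$par - log(lower)) < 1e-6)),
            class = "dec_fit")
}

#' @export
print.dec_fit <- function(x, digits = 4, ...) {
  cat("DEC maximum-likelihood fit (model '", x$model$name, "')\n", sep = "")
  cat(sprintf("  -lnL = %.*f   d = %.*g   e = %.*g%s\n", 2, x$neg_loglik,
              digits, x$params[["d"]], digits, x$params[["e"]],
              if (x$at_bound) "   [at parameter bound]" else ""))
  cat("  root-state support (best 5):\n")
  print(head(x$root_table, 5), row.names = FALSE)
  invisible(x)
}

#' @export
coef.dec_fit <- function(object, ...) object$params

#' @export
logLik.dec_fit <- function(object, ...) {
  structure(-object$neg_loglik, df = 2L, class = "logLik")
}

#' @export
summary.dec_fit <- function(object, ...) {
  cat("Model:", object$model$name, "\n")
  cat("Areas:", paste(object$model$areas, collapse = ", "), "\n")
  cat("Strata:", length(object$model$strata), " root age:",
      object$model$root_age, "\n")
  print(object)
  invisible(object)
}

#' Rank a set of DEC fits
#'
#' @param fits List of `"dec_fit"` objects on the same data (>= 2).
#' @param window Log-likelihood confidence window (default 2 units).
#' @return Data.frame ranked by `-lnL`, with `delta` from the best model
#'   and `within_window` flagging models inside the window.
#' @export
compare_models <- function(fits, window = 2) {
  if (!is.list(fits) || length(fits) < 2L) {
    stop2("need at least two fits to compare")
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "dec_fit")))
  nm <- names(fits) %||% vapply(fits, function(f) f$model$name, character(1))
  tab <- data.frame(
    model = vapply(fits, function(f) f$model$name, character(1)),
    neg_loglik = vapply(fits, function(f) f$neg_loglik, numeric(1)),
    dispersal = vapply(fits, function(f) f$params[["d"]], numeric(1)),
    extinction = vapply(fits, function(f) f$params[["e"]], numeric(1)),
    best_root = vapply(fits, function(f) f$root_table$root[1], character(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$neg_loglik), ]
  tab$delta <- tab$neg_loglik - tab$neg_loglik[1]
  tab$within_window <- tab$delta <= window
  rownames(tab) <- NULL
  tab
}
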