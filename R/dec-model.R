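## Dispersal-extinction-cladogenesis (DEC) model machinery: range state
## space, time-stratified dispersal constraints, anagenetic rate matrices,
## branch transition probabilities and the cladogenetic scenario set.
##
## Geographic ranges are subsets of an ordered area list, held as integer
## bitmasks. The empty set is the absorbing "null range" (global
## extinction). Ancestral ranges are capped at `max_range_size` areas.

#' Enumerate the range state space
#'
#' @param n_areas Number of areas (>= 1).
#' @param max_size Largest permitted range size (1..n_areas).
#' @return Integer vector of bitmasks in canonical order: the null range,
#'   then all singletons in area order, then size-2 subsets in
#'   lexicographic order, and so on.
#' @examples
#' length(enumerate_ranges(5, 2)) # 16 states
#' @export
enumerate_ranges <- function(n_areas, max_size) {
  if (!is_count(n_areas)) stop2("'n_areas' must be a positive integer")
  if (!is_count(max_size) || max_size > n_areas) {
    stop2("'max_size' must be an integer in 1..n_areas")
  }
  states <- 0L
  for (sz in seq_len(max_size)) {
    sets <- combn(n_areas, sz)
    states <- c(states,
                apply(sets, 2, function(ix) sum(bitwShiftL(1L, ix - 1L))))
  }
  as.integer(states)
}

## human-readable label of a range bitmask
range_label <- function(mask, areas) {
  if (mask == 0L) return("0")
  paste(areas[bitwAnd(bitwShiftR(mask, seq_along(areas) - 1L), 1L) == 1L],
        collapse = "/")
}

range_labels <- function(masks, areas) {
  vapply(masks, range_label, character(1), areas = areas)
}

## bitmask of one range given as a character vector of area names
range_mask <- function(range, areas) {
  idx <- match(range, areas)
  if (anyNA(idx)) stop2("unknown area(s): ",
                        paste(range[is.na(idx)], collapse = ", "))
  sum(bitwShiftL(1L, unique(idx) - 1L))
}

#' Construct a time-stratified DEC model
#'
#' @param areas Ordered area labels (default [REGIONS]).
#' @param strata List of strata, each a list with elements `older`,
#'   `younger` (stratum bounds, time before present in the caller's time
#'   unit) and `D`, an `n_areas` x `n_areas` nonnegative matrix whose entry
#'   `D[b, a]` scales the base dispersal rate from area `b` into area `a`
#'   (the diagonal is ignored; an all-zero matrix forbids dispersal, as in
#'   glacial strata). Strata must tile `[span, 0]` without gaps or
#'   overlaps, given in any order. Defaults to a single unstratified
#'   stratum over `[root_age, 0]` with all dispersal allowed.
#' @param max_range_size Largest permitted ancestral range (default 2).
#' @param root_age Root age of the trees the model will be applied to; the
#'   strata must cover at least `[root_age, 0]`.
#' @param name Optional model name.
#' @return An object of class `"dec_model"`.
#' @examples
#' m <- dec_model(areas = c("A", "B"), root_age = 1)
#' @export
dec_model <- function(areas = REGIONS, strata = NULL, max_range_size = 2L,
                      root_age, name = "custom") {
  stopifnot(is.character(areas), length(areas) >= 1L,
            !anyDuplicated(areas))
  if (missing(root_age) || !is.numeric(root_age) || root_age <= 0) {
    stop2("'root_age' must be a single positive number")
  }
  k <- length(areas)
  if (!is_count(max_range_size) || max_range_size > k) {
    stop2("'max_range_size' must be an integer in 1..n_areas")
  }
  if (is.null(strata)) {
    strata <- list(list(older = root_age, younger = 0,
                        D = matrix(1, k, k)))
  }
  strata <- lapply(strata, function(s) {
    stopifnot(is.list(s), all(c("older", "younger", "D") %in% names(s)))
    D <- as.matrix(s$D)
    if (!all(dim(D) == c(k, k))) stop2("stratum D must be ", k, "x", k)
    if (any(D < 0)) stop2("stratum D entries must be >= 0")
    dimnames(D) <- list(from = areas, to = areas)
    list(older = as.numeric(s$older), younger = as.numeric(s$younger), D = D)
  })
  ord <- order(vapply(strata, `[[`, numeric(1), "older"), decreasing = TRUE)
  strata <- strata[ord]
  old <- vapply(strata, `[[`, numeric(1), "older")
  yng <- vapply(strata, `[[`, numeric(1), "younger")
  if (any(old <= yng)) stop2("each stratum needs older > younger")
  if (yng[length(yng)] != 0) stop2("youngest stratum must end at 0")
  if (length(strata) > 1L &&
      any(abs(yng[-length(yng)] - old[-1]) > 1e-9 * max(old))) {
    stop2("strata must tile the time span without gaps or overlaps")
  }
  if (old[1] < root_age - 1e-9 * root_age) {
    stop2("strata cover [", old[1], ", 0] but root_age is ", root_age)
  }
  states <- enumerate_ranges(k, max_range_size)
  structure(list(areas = areas, strata = strata,
                 max_range_size = as.integer(max_range_size),
                 root_age = as.numeric(root_age), name = name,
                 states = states,
                 state_labels = range_labels(states, areas)),
            class = "dec_model")
}

#' @export
print.dec_model <- function(x, ...) {
  cat("DEC model '", x$name, "': ", length(x$areas), " areas (",
      paste(x$areas, collapse = ", "), "), max range size ",
      x$max_range_size, ", ", length(x$states), " states\n", sep = "")
  cat("  root age ", x$root_age, "; ", length(x$strata),
      " strata:\n", sep = "")
  for (s in x$strata) {
    cat(sprintf("    [%g, %g]  dispersal pairs: %d\n", s$older, s$younger,
                sum(s$D[upper.tri(s$D) | lower.tri(s$D)] > 0)))
  }
  invisible(x)
}

## Build a 0/1 dispersal matrix from directed steps "A>B".
dispersal_matrix <- function(areas, steps, symmetric = FALSE) {
  k <- length(areas)
  D <- matrix(0, k, k, dimnames = list(from = areas, to = areas))
  for (s in steps) {
    ab <- strsplit(s, ">", fixed = TRUE)[[1]]
    D[ab[1], ab[2]] <- 1
    if (symmetric) D[ab[2], ab[1]] <- 1
  }
  D
}

#' The five stratified glacial-cycle models
#'
#' Builds the five time-stratified DEC models used to test origins of the
#' north-Pacific arc clade: dispersal is possible between adjacent areas of
#' the chain NAI-NAC-BER-CAS-JAP during interglacials (0-10, 90-130,
#' 190-240 kya, direction set by each model's hypothesised origin) and
#' forbidden during glacials (10-90, 130-190 kya). The REF model forbids
#' all dispersal before 10 kya and allows symmetric adjacent dispersal in
#' the Holocene. Matrices are defaults and can be replaced by constructing
#' [dec_model()] directly.
#'
#' @param root_age Tree root age in ky (default 220).
#' @param max_range_size Largest ancestral range (default 2).
#' @return Named list of `"dec_model"` objects
#'   (`SRM`, `BER`, `JAP`, `CAS`, `REF`).
#' @export
glacial_model_set <- function(root_age = 220, max_range_size = 2L) {
  areas <- REGIONS
  span <- max(240, root_age)
  steps <- list(
    SRM = c("NAI>NAC", "NAC>BER", "BER>CAS", "CAS>JAP"),
    BER = c("BER>NAC", "BER>CAS", "NAC>NAI", "CAS>JAP"),
    JAP = c("JAP>CAS", "CAS>BER", "BER>NAC", "NAC>NAI"),
    CAS = c("CAS>BER", "CAS>JAP", "BER>NAC", "NAC>NAI"))
  zero <- matrix(0, 5, 5, dimnames = list(from = areas, to = areas))
  adj_sym <- dispersal_matrix(areas, c("NAI>NAC", "NAC>BER", "BER>CAS",
                                       "CAS>JAP"), symmetric = TRUE)
  windows <- list(c(span, 190), c(190, 130), c(130, 90), c(90, 10),
                  c(10, 0))
  glacial <- c(FALSE, TRUE, FALSE, TRUE, FALSE)
  mk <- function(ig_matrix, holocene_only = FALSE) {
    strata <- lapply(seq_along(windows), function(i) {
      D <- if (glacial[i]) zero
           else if (holocene_only && windows[[i]][2] != 0) zero
           else ig_matrix
      list(older = windows[[i]][1], younger = windows[[i]][2], D = D)
    })
    strata
  }
  models <- lapply(names(steps), function(nm) {
    dec_model(areas, mk(dispersal_matrix(areas, steps[[nm]])),
              max_range_size, root_age, name = nm)
  })
  names(models) <- names(steps)
  models$REF <- dec_model(areas, mk(adj_sym, holocene_only = TRUE),
                          max_range_size, root_age, name = "REF")
  models
}

#' Anagenetic rate matrix for one stratum
#'
#' Builds the instantaneous rate matrix over range states: range expansion
#' into area `a` at rate `d * sum(D[b, a])` over occupied areas `b`
#' (capped at `max_range_size`), loss of any occupied area at rate `e`
#' (singletons pass to the absorbing null range).
#'
#' @param model A `"dec_model"`.
#' @param params Numeric `c(d = , e = )`: global dispersal and extinction
#'   rates per lineage per time unit.
#' @param stratum Stratum index (1 = oldest).
#' @return Square rate matrix over the model's states (rows sum to zero).
#' @export
build_q <- function(model, params, stratum = 1L) {
  stopifnot(inherits(model, "dec_model"))
  d <- params[["d"]]; e <- params[["e"]]
  if (d < 0 || e < 0) stop2("rates must be nonnegative")
  if (stratum < 1L || stratum > length(model$strata)) stop2("invalid stratum")
  D <- model$strata[[stratum]]$D
  states <- model$states
  ns <- length(states)
  k <- length(model$areas)
  idx <- integer(max(states) + 1L) # mask -> state index
  idx[states + 1L] <- seq_len(ns)
  Q <- matrix(0, ns, ns, dimnames = list(model$state_labels,
                                         model$state_labels))
  sizes <- vapply(states, function(m) sum(bitwAnd(bitwShiftR(m, 0:(k - 1)),
                                                  1L)), numeric(1))
  for (i in seq_len(ns)) {
    R <- states[i]
    if (R == 0L) next # null range is absorbing
    occ <- which(bitwAnd(bitwShiftR(R, 0:(k - 1)), 1L) == 1L)
    ## dispersal gains
    if (sizes[i] < model$max_range_size) {
      for (a in setdiff(seq_len(k), occ)) {
        rate <- d * sum(D[occ, a])
        if (rate > 0) {
          j <- idx[bitwOr(R, bitwShiftL(1L, a - 1L)) + 1L]
          Q[i, j] <- Q[i, j] + rate
        }
      }
    }
    ## extinction losses
    for (a in occ) {
      j <- idx[bitwAnd(R, bitwNot(bitwShiftL(1L, a - 1L))) + 1L]
      Q[i, j] <- Q[i, j] + e
    }
    Q[i, i] <- -sum(Q[i, -i])
  }
  Q
}

## per-stratum Q matrices for fixed params (likelihood inner loop), with a
## cached eigendecomposition so expm(Q t) for many branch durations costs
## two small matrix products. Directional dispersal matrices often make Q
## defective (repeated eigenvalues, near-singular eigenvector basis), so
## the cache is only used when the eigensystem is well conditioned;
## otherwise each exponential is computed by uniformisation with
## scaling-and-squaring, which is unconditionally stable for generators.
stratum_qs <- function(model, params) {
  lapply(seq_along(model$strata), function(s) {
    Q <- build_q(model, params, s)
    eig <- tryCatch(eigen(Q), error = function(e) NULL)
    if (!is.null(eig)) {
      Vinv <- tryCatch(solve(eig$vectors), error = function(e) NULL)
      cond_ok <- !is.null(Vinv) &&
        max(Mod(eig$vectors)) * max(Mod(Vinv)) < 1e7 &&
        max(Mod(eig$vectors %*% (eig$values * Vinv) - Q)) <=
          1e-10 * max(1, max(abs(Q)))
      if (!cond_ok) eig <- NULL else eig$Vinv <- Vinv
    }
    list(Q = Q, eig = eig)
  })
}

## expm(Q t) by uniformisation: P(dt) with dt small enough that the
## truncated series converges fast, then repeated squaring
expm_uniform <- function(Q, t) {
  ns <- nrow(Q)
  if (t <= 0) return(diag(ns))
  lam <- max(-diag(Q))
  if (lam <= 0) return(diag(ns))
  ## scale so lam * dt <= 0.5, then square back up
  s <- max(0L, ceiling(log2(lam * t / 0.5)))
  dt <- t / 2^s
  M <- diag(ns) + Q / lam
  x <- lam * dt
  P <- diag(ns)
  term <- diag(ns)
  w <- exp(-x)
  acc <- P * w
  k <- 0
  repeat {
    k <- k + 1
    term <- term %*% M
    w <- w * x / k
    acc <- acc + w * term
    if (w < 1e-18 || k > 60) break
  }
  P <- acc
  for (i in seq_len(s)) P <- P %*% P
  P[P < 0] <- 0
  P
}

## expm(Q * t) via the cached eigendecomposition (or stable fallback)
q_expm <- function(qc, t) {
  if (is.null(qc$eig)) return(expm_uniform(qc$Q, t))
  P <- Re(qc$eig$vectors %*% (exp(qc$eig$values * t) * qc$eig$Vinv))
  P[P < 0] <- 0
  P
}

## transition matrix along a branch segment [older, younger], multiplying
## per-stratum matrix exponentials rootward -> tipward
branch_p <- function(model, qs, older, younger) {
  ns <- length(model$states)
  P <- diag(ns)
  if (older == younger) return(P)
  for (s in seq_along(model$strata)) {
    so <- model$strata[[s]]$older; sy <- model$strata[[s]]$younger
    a <- min(older, so); b <- max(younger, sy)
    if (a > b + 1e-12) {
      P <- P %*% q_expm(qs[[s]], a - b)
    }
  }
  P
}

#' Transition probabilities along a branch
#'
#' Probability matrix of range evolution along a branch running from
#' `older` to `younger` (times before present), segmenting the branch at
#' stratum boundaries and multiplying the per-segment matrix exponentials
#' in rootward-to-tipward order.
#'
#' @inheritParams build_q
#' @param older,younger Branch endpoint times (`older >= younger >= 0`).
#' @return Row-stochastic matrix over the model's states.
#' @export
branch_transition <- function(model, params, older, younger) {
  stopifnot(inherits(model, "dec_model"))
  span <- model$strata[[1]]$older
  if (younger < 0 || older < younger || older > span + 1e-9 * span) {
    stop2("branch endpoints must satisfy 0 <= younger <= older <= ", span)
  }
  branch_p(model, stratum_qs(model, params), older, younger)
}

#' Cladogenetic range-inheritance distribution
#'
#' The classic DEC scenario set at a speciation event. A single-area range
#' is inherited identically by both daughters. A widespread range `R`
#' splits with equal probability over the ordered outcomes of vicariance
#' (`{a}` vs `R \ {a}` for each occupied `a`, both orders) and
#' peripheral-isolate/subset sympatry (`{a}` vs `R`, both orders);
#' widespread sympatry (`R`, `R`) is excluded.
#'
#' @param parent_range Character vector of occupied areas, or an integer
#'   bitmask over `model$areas`.
#' @param model A `"dec_model"` (used for area naming).
#' @return A data.frame with columns `left`, `right` (range labels) and
#'   `prob`, summing to 1.
#' @examples
#' m <- dec_model(areas = c("A", "B"), root_age = 1)
#' cladogenesis_distribution(c("A", "B"), m) # 6 outcomes, each 1/6
#' @export
cladogenesis_distribution <- function(parent_range, model) {
  stopifnot(inherits(model, "dec_model"))
  mask <- if (is.character(parent_range)) {
    range_mask(parent_range, model$areas)
  } else as.integer(parent_range)
  if (mask == 0L) stop2("the null range cannot speciate")
  out <- clado_outcomes(mask, length(model$areas))
  data.frame(left = range_labels(out$left, model$areas),
             right = range_labels(out$right, model$areas),
             prob = out$prob, stringsAsFactors = FALSE)
}

## ordered daughter outcomes (bitmasks) for a parent mask
clado_outcomes <- function(mask, k) {
  occ <- which(bitwAnd(bitwShiftR(mask, 0:(k - 1)), 1L) == 1L)
  if (length(occ) == 1L) {
    return(list(left = mask, right = mask, prob = 1))
  }
  left <- integer(0); right <- integer(0)
  for (a in occ) {
    bit <- bitwShiftL(1L, a - 1L)
    rest <- bitwAnd(mask, bitwNot(bit))
    left <- c(left, bit, rest, bit, mask)
    right <- c(right, rest, bit, mask, bit)
  }
  key <- paste(left, right)
  keep <- !duplicated(key)
  left <- left[keep]; right <- right[keep]
  list(left = left, right = right, prob = rep(1 / length(left), length(left)))
}

## cladogenesis table over the whole state space: for each parent state
## index, integer matrix of (left index, right index) plus weight vector
clado_table <- function(model) {
  states <- model$states
  k <- length(model$areas)
  idx <- integer(max(states) + 1L)
  idx[states + 1L] <- seq_along(states)
  lapply(seq_along(states), function(i) {
    if (states[i] == 0L) return(NULL)
    out <- clado_outcomes(states[i], k)
    list(left = idx[out$left + 1L], right = idx[out$right + 1L],
         w = out$prob)
  })
}

#' Read / write a DEC model configuration as JSON
#'
#' The JSON holds `areas`, `max_range_size`, `root_age`, `name` and a
#' `strata` array of `{older, younger, D}` entries (`D` row-major, rows =
#' source area), so stratified models can be audited and shared outside R.
#'
#' @param model A `"dec_model"`.
#' @param file JSON path.
#' @return `write_dec_model()` returns `file` invisibly;
#'   `read_dec_model()` returns a `"dec_model"`.
#' @export
write_dec_model <- function(model, file) {
  stopifnot(inherits(model, "dec_model"))
  cfg <- list(name = model$name, areas = model$areas,
              max_range_size = model$max_range_size,
              root_age = model$root_age,
              strata = lapply(model$strata, function(s) {
                list(older = s$older, younger = s$younger,
                     D = unname(s$D))
              }))
  jsonlite::write_json(cfg, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_dec_model
#' @export
read_dec_model <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  k <- length(cfg$areas)
  strata <- lapply(seq_len(nrow(cfg$strata)), function(i) {
    D <- cfg$strata$D[[i]]
    if (!is.matrix(D)) D <- matrix(unlist(D), k, k, byrow = TRUE)
    list(older = cfg$strata$older[i], younger = cfg$strata$younger[i],
         D = D)
  })
  dec_model(areas = cfg$areas, strata = strata,
            max_range_size = cfg$max_range_size, root_age = cfg$root_age,
            name = cfg$name %||% "custom")
}
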