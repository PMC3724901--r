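# Binary-character machinery: exact pruning marginals (vs the transfer-
# matrix oracle), the MCMC rate prior, pruning of tree samples, and the
# prior-scaling sensitivity scan.

test_that("symmetric two-tip case gives exactly one half", {
  tr <- read_newick("(A:1,B:1):0;")
  ch <- binary_character("x", c(A = "0", B = "1"))
  res <- marginal_asr(ch, tree_sample(list(tr)), rate_prior(fixed = 0.8),
                      clade = c("A", "B"), n_draws = 1, seed = 1)
  expect_equal(unname(res$posterior), c(0.5, 0.5))
  expect_false(res$significant)
})

test_that("a vanishing rate forces the observed state", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1):0;")
  ch <- binary_character("x", c(A = "0", B = "0", C = "0", D = "0"))
  res <- marginal_asr(ch, tree_sample(list(tr)), rate_prior(fixed = 1e-8),
                      clade = c("A", "B", "C", "D"), n_draws = 1, seed = 1)
  expect_gt(res$posterior[1], 0.999999)
  expect_true(res$significant)
})

test_that("pruning marginals equal the transfer-matrix oracle", {
  set.seed(61)
  for (i in 1:12) {
    n <- sample(3:6, 1)
    tr <- ape::rcoal(n)
    states <- as.character(rbinom(n, 1, 0.5))
    names(states) <- tr$tip.label
    if (length(unique(states)) < 2) states[1] <- as.character(
      1 - as.integer(states[1]))
    ch <- binary_character("x", states)
    rate <- runif(1, 0.2, 3)
    clade <- sample(tr$tip.label, sample(2:n, 1))
    node <- mrca_node(tr, clade)
    res <- marginal_asr(ch, tree_sample(list(tr)),
                        rate_prior(fixed = rate), clade = clade,
                        n_draws = 1, seed = 1)
    want <- asr_oracle_marginal(tr, ch, rate, node)
    expect_equal(unname(res$posterior), want, tolerance = 1e-10)
  }
})

test_that("missing data are marginalised, posteriors sum to one", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1):0;")
  ch <- binary_character("x", c(A = "0", B = "?", C = "1", D = "1"))
  res <- marginal_asr(ch, tree_sample(list(tr)), rate_prior(fixed = 0.5),
                      clade = c("A", "B"), n_draws = 3, seed = 2)
  expect_equal(sum(res$posterior), 1, tolerance = 1e-9)
})

test_that("rate-prior estimation is seeded and guards edge cases", {
  b <- generate_fixture(seed = 77)
  ts <- tree_sample(b$posterior[1:5])
  ch <- b$characters[[1]]
  p1 <- estimate_rate_prior(ch, ts, n_iter = 400, seed = 5)
  p2 <- estimate_rate_prior(ch, ts, n_iter = 400, seed = 5)
  expect_equal(p1$alpha, p2$alpha)
  expect_equal(p1$beta, p2$beta)
  expect_gt(p1$alpha, 0); expect_gt(p1$beta, 0)
  inv <- binary_character("flat",
                          setNames(rep("0", 46), names(b$assignment)))
  expect_warning(pd <- estimate_rate_prior(inv, ts), "invariant")
  expect_equal(c(pd$alpha, pd$beta), c(1, 1))
  expect_error(binary_character("gone",
                                setNames(rep("?", 3), c("a", "b", "c"))),
               "entirely missing")
})

test_that("the fitted prior mean tracks the simulating rate", {
  ## A single binary character carries little rate information (the
  ## log-likelihood varies by only a few nats across the whole plausible
  ## rate range on a 46-tip tree), so point recovery is loose: the
  ## frozen bound below comes from simulation at this design. The
  ## discrimination property (fast characters get larger fitted prior
  ## means than slow ones) is the sharper check.
  b <- generate_fixture(seed = 77)
  tr1 <- b$posterior[[1]]
  ts <- tree_sample(list(tr1))
  fit_mean <- function(r_true, sd) {
    ch <- refugia:::with_seed(sd, refugia:::sim_binary_character(tr1, r_true, "z"))
    if (length(unique(stats::na.omit(ch$data))) < 2) return(NA_real_)
    pr <- suppressWarnings(estimate_rate_prior(ch, ts, n_iter = 3000,
                                               seed = sd))
    pr$alpha * pr$beta
  }
  errs <- refugia:::with_seed(5, vapply(1:10, function(i) {
    r_true <- runif(1, 1, 2.5)
    est <- fit_mean(r_true, 900 + i)
    abs(est - r_true) / r_true
  }, numeric(1)))
  expect_lt(median(errs, na.rm = TRUE), 0.75)
  slow <- vapply(1:5, function(i) fit_mean(0.4, 70 + i), numeric(1))
  fast <- vapply(1:5, function(i) fit_mean(3.0, 80 + i), numeric(1))
  expect_gt(mean(fast, na.rm = TRUE), mean(slow, na.rm = TRUE))
})

test_that("ASR output is Monte-Carlo stable in the draw count", {
  b <- generate_fixture(seed = 77)
  ts <- tree_sample(b$posterior[1:10])
  ch <- b$characters[[2]]
  clade <- names(b$assignment)[b$assignment == "NAI"]
  pr <- rate_prior(3, 0.4)
  a <- marginal_asr(ch, ts, pr, clade, n_draws = 10, seed = 3)
  bb <- marginal_asr(ch, ts, pr, clade, n_draws = 20, seed = 3)
  expect_lt(max(abs(a$posterior - bb$posterior)), 0.02)
})

test_that("more clade tips in a state can only raise its posterior", {
  ## star tree: the marginal at the root is monotone in the state counts
  tr <- read_newick(paste0("(", paste0("t", 1:6, ":1", collapse = ","),
                           "):0;"))
  prev <- -1
  for (k in 0:6) {
    states <- c(rep("0", k), rep("1", 6 - k))
    names(states) <- paste0("t", 1:6)
    if (length(unique(states)) < 2) {
      states <- states # invariant ok for marginal with fixed rate
    }
    ch <- binary_character("x", states)
    res <- marginal_asr(ch, tree_sample(list(tr)),
                        rate_prior(fixed = 1), clade = paste0("t", 1:6),
                        n_draws = 1, seed = 1)
    expect_gte(res$posterior[[1]], prev - 1e-12)
    prev <- res$posterior[[1]]
  }
})

test_that("pruning to one tip per taxon preserves path lengths", {
  b <- generate_fixture(seed = 77)
  ts <- tree_sample(b$posterior[1:3])
  keep <- names(b$assignment)[seq(1, 46, by = 2)]
  out <- prune_to_one_per_taxon(ts, keep)
  expect_equal(ape::Ntip(out[[1]]), length(keep))
  d_full <- ape::cophenetic.phylo(ts[[1]])[keep, keep]
  d_sub <- ape::cophenetic.phylo(out[[1]])[keep, keep]
  expect_equal(d_sub, d_full, tolerance = 1e-10)
  expect_error(prune_to_one_per_taxon(ts, c(keep, "ghost")), "absent")
})

test_that("the sensitivity scan scales the prior mean through beta", {
  b <- generate_fixture(seed = 77)
  ts <- tree_sample(b$posterior[1:5])
  ch <- b$characters[[1]]
  clade <- names(b$assignment)[b$assignment %in% c("NAI", "NAC")]
  pr <- rate_prior(4, 0.3)
  sc <- sensitivity_scan(ch, ts, pr, clade, factors = c(0.1, 1, 10),
                         n_draws = 5, seed = 11)
  expect_equal(nrow(sc), 3)
  base <- marginal_asr(ch, ts, pr, clade, n_draws = 5,
                       seed = refugia:::spawn_seeds(11, 3)[2])
  expect_equal(sc[[2]][2], unname(base$posterior[1]), tolerance = 1e-12)
  expect_error(sensitivity_scan(ch, ts, pr, clade, factors = c(-1, 1)),
               "positive")
  ## a strong-signal character (the indicator of a genuine clade of the
  ## tree in hand) keeps its significance call at every prior scale
  tr1 <- ts[[1]]
  node <- ape::Ntip(tr1) + 10L
  clade_tips <- ape::extract.clade(tr1, node)$tip.label
  strong <- binary_character("s", setNames(
    ifelse(tr1$tip.label %in% clade_tips, "1", "0"), tr1$tip.label))
  ssc <- sensitivity_scan(strong, tree_sample(list(tr1)),
                          rate_prior(2, 0.2), clade_tips,
                          factors = c(0.1, 1, 10), n_draws = 5, seed = 12)
  expect_true(attr(ssc, "calls_stable"))
  expect_true(all(ssc$significant))
})

test_that("character matrices round trip through TSV and NEXUS", {
  b <- generate_fixture(seed = 77)
  f <- tempfile(fileext = ".tsv")
  write_characters(b$characters[1:3], f)
  back <- read_characters(f)
  expect_length(back, 3)
  expect_equal(back[[1]]$data, b$characters[[1]]$data)
  ## NEXUS route
  nex <- tempfile(fileext = ".nex")
  dat <- lapply(names(b$characters[[1]]$data), function(t) {
    as.character(c(b$characters[[1]]$data[t], b$characters[[2]]$data[t]))
  })
  names(dat) <- names(b$characters[[1]]$data)
  ape::write.nexus.data(dat, nex, format = "standard", interleaved = FALSE)
  nback <- read_characters(nex)
  expect_length(nback, 2)
  expect_equal(unname(nback[[1]]$data[names(b$characters[[1]]$data)]),
               unname(b$characters[[1]]$data))
})

test_that("clade definitions round trip through JSON", {
  clades <- list(nai = c("NAI_01", "NAI_02"), all = c("NAI_01", "JAP_01"))
  f <- tempfile(fileext = ".json")
  write_clades(clades, f)
  expect_equal(read_clades(f), clades)
  bad <- tempfile(); writeLines('["a","b"]', bad)
  expect_error(read_clades(bad), "named")
})
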