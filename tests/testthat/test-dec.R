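# DEC machinery: state space, rate matrices, transitions, cladogenesis,
# pruning likelihood (vs the enumeration oracle), fitting and simulation.

two_area <- function(...) dec_model(areas = c("A", "B"), root_age = 1, ...)

rng2 <- function(a, b) {
  range_data(matrix(c(a, b), 2, 2, byrow = TRUE,
                    dimnames = list(c("t1", "t2"), c("A", "B"))))
}

test_that("range enumeration has the right size and order", {
  expect_length(enumerate_ranges(5, 2), 16) # 1 + 5 + 10
  expect_length(enumerate_ranges(2, 2), 4)
  expect_length(enumerate_ranges(3, 3), 8)
  s <- enumerate_ranges(3, 2)
  expect_equal(s[1], 0L)            # null first
  expect_equal(s[2:4], c(1L, 2L, 4L)) # singletons in area order
  expect_error(enumerate_ranges(5, 0), "1..n_areas")
  expect_error(enumerate_ranges(5, 6), "1..n_areas")
})

test_that("the rate matrix implements gain/loss rates and a generator", {
  m <- two_area()
  Q <- build_q(m, c(d = 0.1, e = 0.05))
  lab <- m$state_labels
  expect_equal(Q["A", "A/B"], 0.1)   # gain B from A
  expect_equal(Q["A", "0"], 0.05)    # singleton loss to null
  expect_equal(Q["A/B", "A"], 0.05)
  expect_equal(Q["A/B", "B"], 0.05)
  expect_true(all(Q["0", ] == 0))    # null absorbing
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  ## blocked dispersal: an all-zero D permits no gains anywhere
  mb <- dec_model(areas = c("A", "B"),
                  strata = list(list(older = 1, younger = 0,
                                     D = matrix(0, 2, 2))),
                  root_age = 1)
  Qb <- build_q(mb, c(d = 0.5, e = 0))
  expect_true(all(Qb == 0))
})

test_that("branch transitions are stochastic and respect the semigroup", {
  m <- two_area()
  pars <- c(d = 0.3, e = 0.2)
  expect_equal(branch_transition(m, pars, 0.4, 0.4), diag(4))
  P <- branch_transition(m, pars, 1, 0)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  ## two strata with identical D == one stratum (semigroup property)
  ms <- dec_model(areas = c("A", "B"),
                  strata = list(
                    list(older = 1, younger = 0.35, D = matrix(1, 2, 2)),
                    list(older = 0.35, younger = 0, D = matrix(1, 2, 2))),
                  root_age = 1)
  expect_lt(max(abs(branch_transition(ms, pars, 1, 0) - P)), 1e-10)
  expect_error(branch_transition(m, pars, 0.2, 0.5), "endpoints")
})

test_that("stratified transition matrices stay stochastic", {
  models <- glacial_model_set()
  pars <- c(d = 0.04, e = 0.01)
  for (m in models) {
    for (span in list(c(220, 0), c(200, 5), c(130, 90), c(95, 85))) {
      P <- branch_transition(m, pars, span[1], span[2])
      expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    }
  }
})

test_that("cladogenesis follows the classic DEC scenario set", {
  m <- two_area()
  cd <- cladogenesis_distribution(c("A", "B"), m)
  expect_equal(nrow(cd), 6)
  expect_equal(cd$prob, rep(1 / 6, 6))
  expect_setequal(paste(cd$left, cd$right),
                  c("A B", "B A", "A A/B", "A/B A", "B A/B", "A/B B"))
  single <- cladogenesis_distribution("A", m)
  expect_equal(nrow(single), 1)
  expect_equal(single$prob, 1)
  expect_error(cladogenesis_distribution(0L, m), "null range")
  ## normalisation over every parent state of the 5-area model
  m5 <- dec_model(root_age = 220)
  for (s in m5$states[m5$states != 0]) {
    expect_equal(sum(cladogenesis_distribution(s, m5)$prob), 1)
  }
})

test_that("degenerate likelihoods behave as forced", {
  m <- two_area()
  tr <- read_newick("(t1:1,t2:1):0;")
  expect_equal(dec_loglik(tr, rng2(c(1, 0), c(1, 0)), m, c(d = 0, e = 0)),
               0)
  ## discordant tips with no dispersal: reachable only by vicariance from
  ## a widespread root, probability 1/6
  expect_equal(dec_loglik(tr, rng2(c(1, 0), c(0, 1)), m, c(d = 0, e = 0)),
               log(6))
  ## ... and impossible when the root is constrained to a singleton or
  ## when widespread ranges are excluded altogether
  expect_equal(dec_loglik(tr, rng2(c(1, 0), c(0, 1)), m, c(d = 0, e = 0),
                          root_state = "A"), Inf)
  m1 <- dec_model(areas = c("A", "B"), max_range_size = 1, root_age = 1)
  expect_equal(dec_loglik(tr, rng2(c(1, 0), c(0, 1)), m1,
                          c(d = 0, e = 0)), Inf)
})

test_that("pruning equals the 2-tip closed-path oracle", {
  m <- two_area()
  tr <- read_newick("(t1:1,t2:1):0;")
  pars <- c(d = 0.1, e = 0.05)
  got <- dec_loglik(tr, rng2(c(1, 0), c(0, 1)), m, pars)
  want <- dec_oracle_loglik(tr, rng2(c(1, 0), c(0, 1)), m, pars)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("constrained-root likelihoods bound the global one", {
  m <- dec_model(areas = c("A", "B", "C"), root_age = 1)
  set.seed(8)
  tr <- scale_to_age(ape::rcoal(12), 1)
  rg <- simulate_dec(tr, m, c(d = 0.4, e = 0.1), seed = 3)
  fit <- fit_dec(tr, rg, m, n_starts = 2, seed = 1)
  expect_true(all(fit$root_table$neg_loglik >= fit$neg_loglik - 1e-9))
  expect_false(is.unsorted(fit$root_table$neg_loglik))
})

test_that("fitting recovers the dispersal rate on a 50-tip tree", {
  m <- dec_model(root_age = 220, max_range_size = 5)
  true <- c(d = 0.1, e = 0.03)
  tr <- scale_to_age(refugia:::with_seed(21, ape::rphylo(50, 0.03, 0)),
                     220)
  rg <- simulate_dec(tr, m, true, seed = 22)
  fit <- fit_dec(tr, rg, m, n_starts = 2, seed = 23)
  expect_lt(abs(fit$params[["d"]] - true[["d"]]) / true[["d"]], 0.5)
})

test_that("forbidding needed dispersal wrecks the likelihood", {
  ## ranges simulated under SRM (dispersal during all interglacials) are
  ## far less likely under REF (no dispersal before 10 kya)
  models <- glacial_model_set()
  b <- generate_fixture(seed = 314)
  srm <- fit_dec(b$gene_tree, b$ranges, models$SRM, n_starts = 2, seed = 1)
  ref <- fit_dec(b$gene_tree, b$ranges, models$REF, n_starts = 2, seed = 1)
  expect_gt(ref$neg_loglik, srm$neg_loglik + 2)
})

test_that("model ranking flags the 2-unit confidence window", {
  fake <- function(nll, name) {
    structure(list(params = c(d = 1, e = 1), neg_loglik = nll,
                   root_table = data.frame(root = "NAI",
                                           neg_loglik = nll),
                   model = list(name = name)),
              class = "dec_fit")
  }
  tab <- compare_models(list(fake(51.91, "SRM"), fake(54.73, "BER")))
  expect_equal(tab$model, c("SRM", "BER"))
  expect_equal(tab$within_window, c(TRUE, FALSE))
  tab2 <- compare_models(list(fake(10, "X"), fake(10, "Y")))
  expect_true(all(tab2$within_window))
  expect_error(compare_models(list(fake(1, "X"))), "at least two")
})

test_that("forward simulation honours degenerate and seeded cases", {
  m <- dec_model(areas = c("A", "B", "C"), root_age = 1)
  set.seed(4)
  tr <- scale_to_age(ape::rcoal(10), 1)
  r0 <- simulate_dec(tr, m, c(d = 0, e = 0), seed = 9)
  expect_equal(length(unique(apply(unclass(r0), 1, paste, collapse = ""))),
               1L) # every tip equals the root singleton
  expect_equal(sum(r0), 10) # a single area each
  r1 <- simulate_dec(tr, m, c(d = 0.5, e = 0.1), seed = 10)
  r2 <- simulate_dec(tr, m, c(d = 0.5, e = 0.1), seed = 10)
  expect_identical(unclass(r1)[, ], unclass(r2)[, ])
  expect_gte(attr(r1, "retries"), 0)
})

test_that("saturating dispersal fills ranges to the cap", {
  ## long-branch cherry: with d large the expm route puts almost all
  ## probability mass on maximal ranges, and the simulator agrees
  m <- dec_model(areas = c("A", "B", "C"), root_age = 1)
  tr <- read_newick("(t1:1,t2:1):0;")
  P <- branch_transition(m, c(d = 8, e = 0), 1, 0)
  full <- vapply(m$states, function(s) sum(bitwAnd(bitwShiftR(s, 0:2), 1L)),
                 numeric(1)) == 2
  expect_gt(min(rowSums(P[-1, full])), 0.9)
  sizes <- vapply(1:100, function(i) {
    rowSums(simulate_dec(tr, m, c(d = 8, e = 0), seed = 6000 + i))
  }, c(t1 = 0, t2 = 0))
  expect_gt(mean(sizes == 2), 0.85) # max_range_size = 2
})

test_that("range matrices validate and round trip", {
  rg <- rng2(c(1, 0), c(1, 1))
  f <- tempfile(fileext = ".tsv")
  write_range_matrix(rg, f)
  back <- read_range_matrix(f, areas = c("A", "B"))
  expect_equal(unclass(back)[, ], unclass(rg)[, ])
  expect_error(range_data(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE,
                                 dimnames = list(c("a", "b"),
                                                 c("A", "B")))),
               "empty range")
  expect_error(suppressWarnings(read_range_matrix(tempfile())),
               "cannot open|No such")
})

test_that("DEC model configurations round trip through JSON", {
  m <- glacial_model_set()$SRM
  f <- tempfile(fileext = ".json")
  write_dec_model(m, f)
  back <- read_dec_model(f)
  expect_equal(back$areas, m$areas)
  expect_equal(back$max_range_size, m$max_range_size)
  expect_equal(back$root_age, m$root_age)
  expect_length(back$strata, length(m$strata))
  for (i in seq_along(m$strata)) {
    expect_equal(unname(back$strata[[i]]$D), unname(m$strata[[i]]$D))
    expect_equal(back$strata[[i]]$older, m$strata[[i]]$older)
  }
  ## likelihood-relevant behaviour identical
  pars <- c(d = 0.03, e = 0.01)
  expect_equal(branch_transition(back, pars, 220, 0),
               branch_transition(m, pars, 220, 0), tolerance = 1e-12)
})
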