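# Deep-coalescence cost: worked small cases frozen from the brute-force
# lineage-history oracle (helper-oracles.R), plus the model-test contract.

test_that("worked small cases match the history-enumeration oracle", {
  m3 <- abc_model()
  asg <- abc_assignment()
  congruent <- read_newick("((a:1,b:1):1,c:2):0;")
  discordant <- read_newick("((a:1,c:1):1,b:2):0;")
  names(asg) <- c("a", "b", "c") # tips a,b,c in pops A,B,C
  asg <- structure(setNames(c("A", "B", "C"), c("a", "b", "c")),
                   class = "sample_assignment")
  expect_equal(deep_coalescence_cost(congruent, m3, asg), 0)
  expect_equal(deep_coalescence_cost(discordant, m3, asg), 1)
  expect_equal(dc_oracle(discordant, m3, asg), 1)

  ## two samples per population on a 2-population tree: each population
  ## contributes one uncoalesced extra lineage (oracle-derived value 2)
  m2 <- divergence_model("(A,B);", depths = 1, samples = c(A = 2, B = 2),
                         regions = c("A", "B"))
  asg2 <- assignment_from_counts(c(A = 2, B = 2))
  g <- read_newick("((A_01:1,B_01:1):1,(A_02:1,B_02:1):1):0;")
  expect_equal(deep_coalescence_cost(g, m2, asg2), 2)
  expect_equal(dc_oracle(g, m2, asg2), 2)
})

test_that("the cost ignores branch lengths", {
  m <- abc_model()
  asg <- assignment_from_counts(c(A = 2, B = 2, C = 2))
  set.seed(31)
  for (i in 1:10) {
    g <- ape::rtree(6, tip.label = sample(names(asg)))
    g2 <- g
    g2$edge.length <- runif(nrow(g$edge), 0.01, 50)
    expect_equal(deep_coalescence_cost(g, m, asg),
                 deep_coalescence_cost(g2, m, asg))
  }
})

test_that("star population trees are scored directly", {
  m <- divergence_model("REFUGIA", depths = 2)
  asg <- assignment_from_counts(setNames(rep(1L, 5), REGIONS))
  g <- read_newick(
    "((NAI_01:1,NAC_01:1):1,((BER_01:1,CAS_01:1):1,JAP_01:2):1):1;")
  expect_equal(deep_coalescence_cost(g, m, asg), 0)
  star3 <- divergence_model("(A,B,C);", depths = 1.5,
                            samples = c(A = 2, B = 1, C = 1),
                            regions = c("A", "B", "C"))
  asg3 <- assignment_from_counts(c(A = 2, B = 1, C = 1))
  g3 <- read_newick("((A_01:1,B_01:1):1,(A_02:1,C_01:1):1):0;")
  expect_equal(deep_coalescence_cost(g3, star3, asg3),
               dc_oracle(g3, star3, asg3))
})

test_that("adding a discordant sample never decreases the cost", {
  m <- abc_model()
  base_asg <- structure(setNames(c("A", "B", "C"), c("a", "b", "c")),
                        class = "sample_assignment")
  base <- read_newick("((a:1,c:1):1,b:2):0;")
  dc0 <- deep_coalescence_cost(base, m, base_asg)
  ## graft an extra A-sample next to c (deepening the discordance)
  asg2 <- structure(setNames(c("A", "A", "B", "C"),
                             c("a", "a2", "b", "c")),
                    class = "sample_assignment")
  g2 <- read_newick("((a:1,(c:0.5,a2:0.5):0.5):1,b:2):0;")
  expect_gte(deep_coalescence_cost(g2, m, asg2), dc0)
  expect_equal(deep_coalescence_cost(g2, m, asg2),
               dc_oracle(g2, m, asg2))
})

test_that("unassigned tips and empty populations are rejected", {
  m <- abc_model()
  g <- read_newick("((a:1,b:1):1,c:2):0;")
  expect_error(deep_coalescence_cost(g, m, NULL), "no assignment")
  asg <- structure(setNames(c("A", "B"), c("a", "b")),
                   class = "sample_assignment")
  expect_error(deep_coalescence_cost(g, m, asg), "unassigned")
})

test_that("dc_model_test honours its p-value contract", {
  m <- divergence_model("((A,B),C);", depths = c(1, 0.5),
                        samples = c(A = 4, B = 4, C = 4),
                        regions = c("A", "B", "C"))
  obs <- simulate_msc(m, seed = 404)
  x <- suppressWarnings(dc_model_test(obs, m, n_sims = 300, seed = 1))
  expect_s3_class(x, "dc_test")
  expect_equal(x$p_value,
               (1 + sum(x$null_values <= x$observed_dc)) / (1 + 300))
  expect_identical(x$decision,
                   if (x$p_value < x$alpha) "supported" else "rejected")
  expect_length(x$null_values, 300)
  ## determinism
  y <- suppressWarnings(dc_model_test(obs, m, n_sims = 300, seed = 1))
  expect_identical(x$null_values, y$null_values)
  expect_identical(x$p_value, y$p_value)
})

test_that("a perfectly sorted tree against a shallow model is extreme", {
  ## observed DC = 0 while the shallow null almost surely exceeds 0:
  ## p collapses to its minimum 1/(n+1) and the model is supported
  shallow <- divergence_model("((A,B),C);", depths = c(0.1, 0.05),
                              samples = c(A = 3, B = 3, C = 3),
                              regions = c("A", "B", "C"))
  sorted <- read_newick(paste0(
    "(((A_01:1,A_02:1):1,A_03:2):4,((B_01:1,B_02:1):1,B_03:2):2,",
    "((C_01:1,C_02:1):1,C_03:2):2):0;"))
  asg <- assignment_from_counts(c(A = 3, B = 3, C = 3))
  ## resolve the artificial polytomy so the gene tree is binary
  sorted <- resolve_polytomies(sorted, seed = 1)
  x <- suppressWarnings(dc_model_test(sorted, shallow, asg,
                                      n_sims = 200, seed = 2))
  expect_equal(x$observed_dc, 0)
  if (min(x$null_values) > 0) {
    expect_equal(x$p_value, 1 / 201)
    expect_identical(x$decision, "supported")
  }
})

test_that("simulation counts are validated", {
  m <- abc_model()
  g <- simulate_msc(m, assignment_from_counts(c(A = 1, B = 1, C = 1)),
                    seed = 1)
  expect_error(dc_model_test(g, m, n_sims = 50), ">= 100")
  expect_warning(dc_model_test(g, m, n_sims = 150, seed = 1),
                 "coarse")
})
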