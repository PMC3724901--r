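## Orchestration of the three analyses: divergence-model testing,
## stratified DEC fitting, and prior-calibrated ASR. Each runner takes the
## relevant inputs, fans one seed out across its stages, and returns a
## result object with a report table that can be written as TSV/JSON.

#' Test a set of population-divergence models
#'
#' Runs [dc_model_test()] for each candidate model against one observed
#' gene tree.
#'
#' @param gene_tree Observed gene tree (`"phylo"`).
#' @param assignment A `"sample_assignment"` (defaults to the one attached
#'   to the tree).
#' @param models Named list of `"pop_tree"` models; defaults to the six
#'   presets (REFUGIA, SRM, JAPAN_I/II, CAS_I/II) with default depths and
#'   the assignment's sample counts.
#' @param n_sims Null simulations per model (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed fanned out over models.
#' @return A list of class `"dc_report"`: `tests` (per-model
#'   `"dc_test"` objects) and `table` (one row per model).
#' @export
run_dc_analysis <- function(gene_tree, assignment = NULL, models = NULL,
                            n_sims = 1000L, alpha = 0.05, seed = NULL) {
  if (is.null(assignment)) assignment <- attr(gene_tree, "assignment")
  if (is.null(assignment)) stop2("no assignment given or attached")
  if (is.null(models)) {
    counts <- table(factor(as.character(assignment), levels = REGIONS))
    counts <- setNames(as.integer(counts), REGIONS)
    presets <- c("REFUGIA", "SRM", "JAPAN_I", "JAPAN_II", "CAS_I", "CAS_II")
    models <- lapply(presets, divergence_model, samples = counts)
    names(models) <- presets
  }
  seeds <- spawn_seeds(seed %||% sample.int(1e6, 1), length(models))
  tests <- lapply(seq_along(models), function(i) {
    dc_model_test(gene_tree, models[[i]], assignment, n_sims = n_sims,
                  alpha = alpha, seed = seeds[i])
  })
  names(tests) <- names(models)
  table <- data.frame(
    model = names(models),
    observed_dc = vapply(tests, `[[`, numeric(1), "observed_dc"),
    null_mean = vapply(tests, `[[`, numeric(1), "null_mean"),
    null_sd = vapply(tests, `[[`, numeric(1), "null_sd"),
    p_value = vapply(tests, `[[`, numeric(1), "p_value"),
    decision = vapply(tests, `[[`, character(1), "decision"),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(tests = tests, table = table, n_sims = n_sims,
                 alpha = alpha), class = "dc_report")
}

#' @export
print.dc_report <- function(x, ...) {
  cat("Deep-coalescence tests (", x$n_sims, " simulations per model, ",
      "alpha = ", x$alpha, ")\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fit and rank a set of stratified DEC models
#'
#' @param tree Time-scaled binary ultrametric tree.
#' @param ranges A `"range_data"` matrix.
#' @param models Named list of `"dec_model"` objects; defaults to
#'   [glacial_model_set()] at the tree's depth.
#' @param seed Integer seed for the optimiser multistart.
#' @param n_starts Optimiser starts per model.
#' @param window Log-likelihood confidence window (default 2).
#' @return A list of class `"dec_report"`: `fits` and `table` (ranked as
#'   in [compare_models()], plus each model's best root states).
#' @export
run_dec_analysis <- function(tree, ranges, models = NULL, seed = NULL,
                             n_starts = 4L, window = 2) {
  if (is.null(models)) {
    models <- glacial_model_set(root_age = max(node_depths(tree)))
  }
  seeds <- spawn_seeds(seed %||% sample.int(1e6, 1), length(models))
  fits <- lapply(seq_along(models), function(i) {
    fit_dec(tree, ranges, models[[i]], n_starts = n_starts,
            seed = seeds[i])
  })
  names(fits) <- names(models)
  structure(list(fits = fits, table = compare_models(fits, window),
                 window = window), class = "dec_report")
}

#' @export
print.dec_report <- function(x, ...) {
  cat("Stratified DEC model comparison (", x$window,
      " log-likelihood unit window)\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Prior-calibrated ASR over clades and characters
#'
#' For each character: estimates the gamma rate prior by MCMC over the
#' tree sample, then reconstructs the marginal ancestral state at each
#' clade and runs the prior-scaling sensitivity scan.
#'
#' @param chars Named list of `"binary_character"` objects.
#' @param trees A [tree_sample()] (post-burn-in posterior sample).
#' @param clades Named list of tip-label vectors defining the clades.
#' @param n_draws Rate draws per tree in the ASR averaging.
#' @param factors Prior-scaling factors for the sensitivity scan; use
#'   `NULL` to skip the scan.
#' @param threshold Posterior-probability significance level (default
#'   0.95; the report also marks 0.90).
#' @param n_iter MCMC iterations per character prior.
#' @param seed Integer seed fanned out over characters.
#' @return A list of class `"asr_report"`: `priors` (per character),
#'   `results` (clade x character `"asr_result"`), `table` (one row per
#'   clade x character with posteriors, significance markers at
#'   0.90/0.95, and sensitivity stability), `sensitivity`.
#' @export
run_asr_analysis <- function(chars, trees, clades, n_draws = 10L,
                             factors = c(0.1, 1, 10), threshold = 0.95,
                             n_iter = 2000L, seed = NULL) {
  stopifnot(is.list(chars), is.list(clades), length(clades) >= 1L)
  if (is.null(names(clades))) {
    names(clades) <- paste0("clade", seq_along(clades))
  }
  seeds <- spawn_seeds(seed %||% sample.int(1e6, 1),
                       length(chars) * (2L + length(clades)))
  si <- 0L
  priors <- list(); results <- list(); sens <- list(); rows <- list()
  for (ci in seq_along(chars)) {
    ch <- chars[[ci]]
    si <- si + 1L
    priors[[ch$name]] <- estimate_rate_prior(ch, trees, n_iter = n_iter,
                                             seed = seeds[si])
    for (ki in seq_along(clades)) {
      si <- si + 1L
      res <- marginal_asr(ch, trees, priors[[ch$name]], clades[[ki]],
                          n_draws = n_draws, seed = seeds[si],
                          threshold = threshold,
                          clade_id = names(clades)[ki])
      results[[paste(names(clades)[ki], ch$name, sep = ".")]] <- res
      stable <- NA
      if (!is.null(factors) && is.null(priors[[ch$name]]$fixed)) {
        sc <- sensitivity_scan(ch, trees, priors[[ch$name]], clades[[ki]],
                               factors = factors, n_draws = n_draws,
                               seed = seeds[si], threshold = threshold,
                               clade_id = names(clades)[ki])
        sens[[paste(names(clades)[ki], ch$name, sep = ".")]] <- sc
        stable <- attr(sc, "calls_stable")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        clade = names(clades)[ki], character = ch$name,
        state0 = ch$states[1], p0 = unname(res$posterior[1]),
        state1 = ch$states[2], p1 = unname(res$posterior[2]),
        modal_state = res$state,
        over_090 = max(res$posterior) > 0.90,
        over_095 = max(res$posterior) > 0.95,
        prior_calls_stable = stable,
        n_nonmonophyletic = res$n_nonmonophyletic,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(priors = priors, results = results, sensitivity = sens,
                 table = do.call(rbind, rows), threshold = threshold),
            class = "asr_report")
}

#' @export
print.asr_report <- function(x, ...) {
  cat("Ancestral-state reconstruction report (threshold ", x$threshold,
      ")\n", sep = "")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a report table as TSV (and optionally JSON)
#'
#' @param report A `"dc_report"`, `"dec_report"`, `"asr_report"`, or a
#'   plain data.frame.
#' @param file Output TSV path.
#' @param json Optional JSON path mirroring the table.
#' @return `file`, invisibly.
#' @export
write_report <- function(report, file, json = NULL) {
  tab <- if (is.data.frame(report)) report else report$table
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(tab, json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(file)
}
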