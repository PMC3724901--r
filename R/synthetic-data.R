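## Synthetic fixture generation: produces an internally consistent bundle
## of all pipeline inputs (population model, 46-tip gene tree, posterior-
## like tree sample, DEC range matrix, 16 binary characters) with the
## statistical structure the analyses assume, so every stage runs and is
## testable without external data.

## default per-character gamma rate priors for the 16 synthetic binary
## characters (shape alpha, scale beta; prior means ~0.9-1.9 changes per
## unit tree depth, the range over which binary morphological characters
## are typically informative but not saturated)
default_char_priors <- function(n_char = 16L) {
  alpha <- rep(c(5.4, 3.5, 2.8, 3.0, 5.0, 2.9, 4.2, 3.8), length.out = n_char)
  beta <- rep(c(0.24, 0.35, 0.68, 0.44, 0.27, 0.72, 0.31, 0.40),
              length.out = n_char)
  data.frame(character = sprintf("char%02d", seq_len(n_char)),
             alpha = alpha, beta = beta)
}

#' Fixture configuration
#'
#' Defaults encode the study design the pipeline emulates: a 5-region
#' sampling of 46 individuals (NAI 15, NAC 6, BER 11, CAS 11, JAP 3), an
#' SRM (southern Rocky Mountain origin) divergence history with splits at
#' 5/4/3/2 coalescent units, a gene tree scaled to a root age of 220 ky,
#' DEC ranges evolved under the stratified SRM model with dispersal
#' `d = 0.05` and extinction `e = 0.005` per lineage per ky (rates of
#' order 10^-2/ky so range evolution has signal over a 220-ky tree), and
#' 16 binary characters with gamma rate priors.
#'
#' @param model Divergence-model preset or Newick (default `"SRM"`).
#' @param depths Divergence depths in coalescent units.
#' @param samples Named per-region sample counts.
#' @param root_age Gene-tree root age in ky (default 220).
#' @param n_posterior Size of the posterior-like tree sample (default 50).
#' @param dec_d,dec_e True DEC rates per ky.
#' @param dec_root Root range for the DEC simulation (default `"NAI"`,
#'   the SRM origin).
#' @param n_char Number of binary characters (default 16).
#' @param char_priors Data.frame (`character`, `alpha`, `beta`) of
#'   per-character gamma rate priors.
#' @return A list of class `"fixture_config"`.
#' @export
fixture_config <- function(model = "SRM", depths = c(5, 4, 3, 2),
                           samples = REGION_SAMPLES, root_age = 220,
                           n_posterior = 50L, dec_d = 0.05, dec_e = 0.005,
                           dec_root = "NAI", n_char = 16L,
                           char_priors = default_char_priors(n_char)) {
  cfg <- list(model = model, depths = depths, samples = samples,
              root_age = root_age, n_posterior = as.integer(n_posterior),
              dec_d = dec_d, dec_e = dec_e, dec_root = dec_root,
              n_char = as.integer(n_char), char_priors = char_priors)
  if (cfg$n_posterior < 1L) stop2("n_posterior must be >= 1")
  if (nrow(char_priors) != n_char) {
    stop2("char_priors must have one row per character")
  }
  structure(cfg, class = "fixture_config")
}

#' Generate a synthetic fixture bundle
#'
#' Simulates, from one master seed: (1) a gene tree under the multispecies
#' coalescent within the configured divergence model, scaled to the target
#' root age; (2) a posterior-like tree sample by re-simulating gene trees
#' from the same model (a stand-in for Bayesian topological uncertainty),
#' scaled to unit depth for character work; (3) a DEC range matrix evolved
#' forward along the gene tree under the stratified glacial-cycle model;
#' (4) binary characters evolved on the unit-depth gene tree at rates
#' drawn from the per-character gamma priors.
#'
#' @param config A [fixture_config()].
#' @param seed Master integer seed (mandatory: bundles are reproducible).
#' @return An object of class `"fixture_bundle"`; see Details for fields.
#' @export
generate_fixture <- function(config = fixture_config(), seed) {
  stopifnot(inherits(config, "fixture_config"))
  if (missing(seed)) stop2("'seed' is required")
  seeds <- spawn_seeds(seed, 4L + config$n_char)
  pop <- divergence_model(config$model, depths = config$depths,
                          samples = config$samples)
  assignment <- assignment_from_counts(pop$samples)
  gene_cu <- simulate_msc(pop, assignment, seed = seeds[1])
  gene_tree <- scale_to_age(gene_cu, config$root_age)
  attr(gene_tree, "assignment") <- assignment
  posterior <- simulate_null(pop, assignment, config$n_posterior,
                             seed = seeds[2])
  posterior <- tree_sample(lapply(posterior, scale_to_age, root_age = 1))
  dec_mod <- if (setequal(pop$regions, REGIONS)) {
    glacial_model_set(root_age = config$root_age)[[
      if (config$model %in% c("SRM", "REFUGIA")) "SRM" else "BER"]]
  } else {
    ## custom region sets get an unstratified all-dispersal model
    dec_model(areas = pop$regions, root_age = config$root_age,
              max_range_size = min(2L, length(pop$regions)),
              name = "unstratified")
  }
  dec_root <- if (config$dec_root %in% dec_mod$areas) config$dec_root
              else dec_mod$areas[1]
  ranges <- simulate_dec(gene_tree, dec_mod,
                         c(d = config$dec_d, e = config$dec_e),
                         seed = seeds[3], root_state = dec_root)
  unit_tree <- scale_to_age(gene_cu, 1)
  char_rates <- numeric(config$n_char)
  chars <- lapply(seq_len(config$n_char), function(j) {
    pr <- config$char_priors[j, ]
    with_seed(seeds[3L + j], {
      rate <- rgamma(1, shape = pr$alpha, scale = pr$beta)
      char_rates[j] <<- rate
      sim_binary_character(unit_tree, rate, name = pr$character)
    })
  })
  names(chars) <- names(char_rates) <- config$char_priors$character
  structure(list(pop_model = pop, assignment = assignment,
                 gene_tree = gene_tree, posterior = posterior,
                 dec_model = dec_mod, ranges = ranges, characters = chars,
                 manifest = list(seed = seed, sub_seeds = seeds,
                                 config = unclass(config),
                                 true_dec = c(d = config$dec_d,
                                              e = config$dec_e),
                                 true_char_rates = char_rates)),
            class = "fixture_bundle")
}

## simulate one binary character down a tree under the symmetric
## two-state chain at the given overall rate
sim_binary_character <- function(tree, rate, name, bias = 0.5) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  po <- ape::postorder(tree)
  state <- integer(nn)
  root <- tree$edge[po[length(po)], 1]
  state[root] <- rbinom(1, 1, bias)
  for (e in rev(po)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    P <- p2(rate, bias, tree$edge.length[e])
    state[ch] <- rbinom(1, 1, P[state[p] + 1L, 2])
  }
  binary_character(name, setNames(as.character(state[seq_len(ntip)]),
                                  tree$tip.label))
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("Synthetic fixture bundle (seed ", x$manifest$seed, ")\n", sep = "")
  cat("  divergence model: ", x$pop_model$name, "; ",
      ape::Ntip(x$gene_tree), " tips; root age ",
      x$manifest$config$root_age, "\n", sep = "")
  cat("  posterior-like sample: ", length(x$posterior), " trees\n", sep = "")
  cat("  DEC model '", x$dec_model$name, "', true d = ",
      x$manifest$true_dec[["d"]], ", e = ", x$manifest$true_dec[["e"]],
      "\n", sep = "")
  cat("  characters: ", length(x$characters), "\n", sep = "")
  invisible(x)
}

#' Write a fixture bundle to disk
#'
#' Writes the bundle as plain-text files (`gene_tree.nwk`,
#' `posterior_trees.nex`, `assignment.tsv`, `ranges.tsv`,
#' `characters.tsv`, `manifest.json`) and a manifest recording the seeds,
#' true parameters and per-file MD5 hashes, so the bundle can be
#' regenerated and verified byte for byte.
#'
#' @param bundle A `"fixture_bundle"`.
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(gene_tree = file.path(dir, "gene_tree.nwk"),
             posterior = file.path(dir, "posterior_trees.nex"),
             assignment = file.path(dir, "assignment.tsv"),
             ranges = file.path(dir, "ranges.tsv"),
             characters = file.path(dir, "characters.tsv"))
  writeLines(write_newick(bundle$gene_tree), paths["gene_tree"])
  write_nexus_trees(bundle$posterior, paths["posterior"])
  write.table(data.frame(tip = names(bundle$assignment),
                         region = as.character(bundle$assignment)),
              paths["assignment"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_range_matrix(bundle$ranges, paths["ranges"])
  write_characters(bundle$characters, paths["characters"])
  hashes <- tools::md5sum(unname(paths))
  names(hashes) <- basename(unname(paths))
  manifest <- bundle$manifest
  ## named vectors serialise as JSON objects, not bare arrays
  manifest$true_dec <- as.list(manifest$true_dec)
  manifest$true_char_rates <- as.list(manifest$true_char_rates)
  manifest$config$samples <- as.list(manifest$config$samples)
  manifest <- c(manifest, list(files = as.list(hashes)))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Read a fixture bundle directory
#'
#' @param dir Directory written by [write_bundle()].
#' @return A list with the gene tree, posterior sample, assignment, range
#'   matrix, characters and manifest.
#' @export
read_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  regions <- names(manifest$config$samples) %||% REGIONS
  assignment <- load_assignment(file.path(dir, "assignment.tsv"),
                                regions = regions)
  gene_tree <- read_newick(readLines(file.path(dir, "gene_tree.nwk"))[1])
  attr(gene_tree, "assignment") <- assignment
  list(gene_tree = gene_tree,
       posterior = read_nexus_trees(file.path(dir, "posterior_trees.nex")),
       assignment = assignment,
       ranges = read_range_matrix(file.path(dir, "ranges.tsv")),
       characters = read_characters(file.path(dir, "characters.tsv")),
       manifest = manifest)
}
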