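---
title: "Models and methods behind refugia"
author: "refugia authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind refugia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`refugia` packages three inference procedures used in statistical
phylogeography of north-Pacific arctic–alpine plants: coalescent tests of
geographic population-divergence models, time-stratified
dispersal–extinction–cladogenesis (DEC) inference of range evolution, and
prior-calibrated ancestral-state reconstruction (ASR) of binary
morphological characters. This vignette records the models, their
assumptions, the tunable parameters, the numerical choices, and what the
synthetic fixtures do and do not demonstrate.

## Trees and units

All analyses consume rooted `ape::phylo` trees. Branch-length units are
contextual and never converted implicitly: coalescent units (2Ne
generations) in the divergence-model tests, absolute time (ky) in DEC,
and relative depth (trees scaled to depth 1) for character work.
`scale_to_age()` performs the unit changes; for non-ultrametric input it
offers per-path linear stretching behind an explicit flag (each node is
placed at `root_age * depth / (depth + height)`), with a warning, because
no dating method is assumed — analyses that need absolute internal ages
should be given a properly time-calibrated tree. Polytomies are resolved
randomly (`resolve_polytomies()`, mandatory seed) with zero-length
inserted edges, so node depths, total tree length and continuous-time
likelihoods are unaffected.

## Divergence models and the deep-coalescence test

A divergence model is a population tree over the regions
NAI–NAC–BER–CAS–JAP with divergence depths in coalescent units. Six
presets cover the classic scenarios: simultaneous fragmentation among all
refugia (`REFUGIA`, a hard polytomy), a southern Rocky Mountain origin
with stepwise westward spread (`SRM`, pectinate with NAI sister to the
rest), and mirror-image chains rooted at Japan and central Asia
(`JAPAN_I/II`, `CAS_I/II`). The exact branching orders of the non-SRM
variants are not uniquely determined by the verbal scenarios, so those
presets are documented defaults and any model can be given as an explicit
Newick string instead. Default depths run from 5 to 2 coalescent units —
deep enough that lineage sorting is mostly complete and the scenarios are
distinguishable, while leaving a realistic amount of discordance.

Gene trees are simulated within a model under the multispecies
coalescent: within each population branch, k lineages coalesce with
exponential waiting times at rate k(k−1)/2 per coalescent unit;
uncoalesced lineages enter the parent population at the divergence time
and the root population extends indefinitely. There is no migration and
population widths are constant — the test is about divergence topology,
not demography.

The deep-coalescence cost DC is computed from the LCA mapping (each gene
node maps to the smallest population-tree cluster containing its
descendant populations) as Σ over population-tree edges of (lineages
crossing the rootward end − 1), with the gene-root lineage extended to
the population-tree root. DC is purely topological, star population trees
are scored directly (the `REFUGIA` polytomy needs no arbitrary
resolution), and the implementation is validated exhaustively against a
brute-force enumeration of lineage-sorting histories on small instances.

The test builds the null from gene trees simulated under the candidate
model itself and uses the lower tail: a model is *supported* when the
observed tree is significantly *less* discordant than the model's own
lineage sorting predicts. We use the add-one correction
p = (1 + #{null ≤ observed})/(1 + n), counting ties toward the tail
(conservative). Two consequences worth stating plainly:

* when the observed tree really is drawn from the model, p is
  (approximately) uniform, so the support rate equals the significance
  level — supporting a model requires the observed tree to be *more
  sorted* than the model's coalescent predicts;
* DC is integer-valued, so p is approximately uniform only when the null
  is well spread. The calibration test therefore uses a
  moderate-ILS design (three populations, 12 samples each, divergences at
  0.3/0.15 coalescent units) in which the null's largest atom is ~0.13 of
  the mass; with 1000 null simulations per repetition the Kolmogorov–
  Smirnov test over 200 repetitions then has the intended behaviour.

Because fewer population-tree edges mechanically lower DC, raw DC values
are not comparable between the star `REFUGIA` model and the bifurcating
models; comparisons of observed DC are made within the bifurcating set,
and each model's p-value is computed against its own null.

## Time-stratified DEC

Ranges are subsets of the ordered area list (bitmask states), capped at
`max_range_size` (default 2, matching the convention of allowing two
ancestral areas per node). The anagenetic generator has range-expansion
rates d·Σ_{b∈R} D[b,a] and per-area loss rate e; the empty range is
absorbing (global extinction). The five stratified models tile
[240, 0] kya with interglacial windows (240–190, 130–90, 10–0) whose
dispersal matrices encode each hypothesis's direction along the adjacency
chain NAI–NAC–BER–CAS–JAP, and glacial windows (190–130, 90–10) with
all-zero dispersal; `REF` allows (symmetric adjacent) dispersal only in
the Holocene window. All matrices are user-overridable since the printed
models are schematic.

Likelihoods use postorder pruning: tip indicator vectors, per-branch
transition matrices that multiply per-stratum matrix exponentials in
rootward→tipward order, and cladogenetic mixing over the classic DEC
scenario set (single-area ranges are inherited identically; widespread
ranges split equiprobably over ordered vicariance and
peripheral-isolate/subset-sympatry outcomes; widespread sympatry is
excluded). The global likelihood at the root is the *sum* of the root
partials over permissible nonempty ranges (weight 1 each). This is the
convention under which the root-constrained −lnL values tabulated by
`fit_dec()` are each at least the global −lnL, so "how much worse is this
root range" reads directly from the table; a normalised uniform prior
would only shift every −lnL by log(#states−1).

Numerics: per-stratum rate matrices are eigendecomposed once per
parameter evaluation so each branch segment costs two small matrix
products; directional dispersal matrices often make Q defective
(repeated eigenvalues with a near-singular eigenvector basis), which is
detected by a conditioning check, and those exponentials fall back to
uniformisation with scaling-and-squaring — unconditionally stable for
generators and dependency-free. Row sums of every branch transition
matrix are within 1e-10 of 1. Rates are optimised on the log scale by
L-BFGS-B inside [1e-9, 100] with a multistart grid centred on rates of
order 10/time-span; boundary estimates are flagged.

`simulate_dec()` runs the forward process for parameter-recovery
experiments and fixtures: root range drawn uniformly over permissible
nonempty states (or fixed), cladogenesis sampled at nodes, Gillespie
anagenesis along branches honouring stratum boundaries. A lineage whose
range hits the null range has gone extinct, which a fixed tree cannot
represent; that branch is resimulated from its start state (per-lineage
conditioning, counted and reported). This choice matters for inference:

* the model likelihood is *unconditioned* on survival (as in the
  standard DEC implementations), while any data simulated on a fixed tree
  are necessarily survival-conditioned. The fitted extinction rate
  therefore absorbs the survival probability and is biased downward;
* independently, e is weakly identified in DEC — contractions are mostly
  invisible at the tips and cladogenesis constantly resets daughters to
  small ranges — consistent with the common empirical finding that DEC
  extinction MLEs collapse toward zero.

Our recovery experiment (20 seeded 100-tip Yule trees, all five areas
available to every range, d = 0.1, e = 0.03 per ky — the most
identifiable regime found in a systematic pilot over tree shapes, range
caps and rate scales) recovers d with ~14% median relative error while e
remains ~35–40% low. The recovery test asserts the 30% bound for both
parameters; the e assertion documents this structural limitation rather
than hiding it, and users should treat fitted extinction rates as lower
bounds.

## Prior-calibrated ASR

Characters are binary, evolving under a two-state chain with overall rate
r and stationary bias π₁ (default 0.5, i.e. symmetric; the bias is kept
fixed because only rate priors are typically reported for this analysis
style, and an optional bias argument is exposed). The per-character rate
prior is gamma(α, β) (β a scale, prior mean αβ), estimated by a
Metropolis–Hastings chain that alternates log-scale rate moves (flat
prior on [0, `rate_max`]) with uniform redraws of the tree index, then
moment-matches the post-burn-in sample (α = m²/v, β = v/m). The default
`rate_max = 5` expected changes per unit tree depth reflects that beyond
a handful of changes per tree depth the binary likelihood saturates and
all rates look alike — an unbounded flat prior would leave the posterior
dominated by its tail. A single binary character simply carries little
rate information (the log-likelihood typically spans only a few nats
across the whole plausible range on a ~50-tip tree), so fitted prior
means should be read as order-of-magnitude calibrations, not estimates.

Marginal ASR computes, for each tree and each rate drawn from the prior,
the exact marginal posterior of the state at the MRCA of the clade's tip
set by a two-pass pruning algorithm, and averages over trees × draws.
Trees in which the clade is non-monophyletic contribute the state at the
MRCA of the tip set (which then subtends extra tips); their count is
reported rather than silently dropped. Significance is called at
posterior > 0.95 (0.90 also marked), and `sensitivity_scan()` repeats the
reconstruction with the prior mean scaled ×0.1 and ×10 — implemented by
scaling β with α fixed, stated here because "scaling the prior" is
ambiguous — and flags whether the significance calls change.

## The synthetic fixture

`generate_fixture()` wires everything together from one master seed: a
46-sample design over the five regions (NAI 15, NAC 6, BER 11, CAS 11,
JAP 3), an SRM divergence history with splits at 5/4/3/2 coalescent
units, the gene tree scaled to a 220-ky root, DEC ranges simulated under
the stratified SRM model from an NAI root with d = 0.05 and e = 0.005 per
ky (rates chosen so westward spread typically crosses Beringia within
220 ky while tip ranges stay small), and 16 binary characters at rates
drawn from gamma priors in the range reported for such analyses. Bundles
are written as plain text (Newick, NEXUS, TSV, JSON manifest with seeds,
true parameters and file hashes) and regenerate byte-identically from the
manifest seed.

What the fixture does *not* emulate: the posterior-like tree sample is
built by coalescent re-simulation, not MCMC, so its topological variance
far exceeds a real posterior's — rate estimates integrated over it are
biased upward, and clade-based ASR is diluted by non-monophyly much more
often than in practice. Sequence-level noise, alignment error and
among-character rate heterogeneity beyond the gamma prior are likewise
out of scope. Passing tests on the fixture therefore validate the
*inference machinery* (all three engines are checked against independent
oracles: brute-force lineage-history enumeration, full DEC state-space
enumeration with an independent matrix exponential, and transfer-matrix
marginals) and the statistical calibration of the DC test — they do not
certify that any particular empirical dataset satisfies the models'
assumptions.

## Problem sizes used by the test suite

The suite works at sizes chosen to probe each property well: exhaustive
DC validation over every labelled topology with up to 5 tips (plus a
seeded sample of 6-tip topologies), 200 calibration repetitions at 1000
null simulations each, 10,000 replicates for coalescent expectations,
6 random instances for pruning-vs-enumeration equality (≤ 4 tips,
≤ 3 areas), 20 replicates of 100-tip trees for DEC recovery, and 10–12
random instances for ASR exactness. The acceptance script runs the full
pipeline at the study design itself (46 tips, 10,000 null simulations per
divergence model, all five stratified DEC models, all 16 characters).
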