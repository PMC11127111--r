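---
title: "Biome specialization on microbial phylogenies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biome specialization on microbial phylogenies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomevol)
```

`biomevol` studies how microbial lineages specialize on biomes (land,
marine, freshwater) and transition between them over evolutionary time. It
chains four analyses that are usually run separately: clustering samples
into biomes from community composition, classifying taxa into biome
preferences from occupancy, fitting multistate Markov (Mk) models of
preference evolution, and fitting state-dependent diversification (SSE)
models that ask whether speciation tracks the preference or something
unmeasured. This vignette records the models, the tunable parameters, and
the numerical and design choices behind them.

## The data model

All phylogenies are rooted, ultrametric `ape::phylo` trees with branch
lengths in *relative* time: the root sits at time 0 and every tip at the
tree height T, and rates are only interpretable relative to each other.
Trees failing ultrametricity by more than a relative 1e-6 are rejected by
every likelihood function; `make_ultrametric()` exists as an explicit
repair (terminal-branch adjustment) but is never applied silently, because
silently rescaling a mis-calibrated tree hides upstream dating problems.
Polytomies are accepted on input and resolved deterministically
(left-to-right, zero-length edges) before likelihood work. Height
rescaling (`rescale_tree()`) is exposed as an option since relative-time
trees are sometimes normalized to unit height; nothing in the package
assumes either convention.

## Clustering samples into biomes

Samples are compared by weighted UniFrac, computed by `phyloseq` after
per-sample normalization to relative abundance. Both the raw form (a
weighted L1 distance over branches) and the normalized form (bounded in
[0, 1]) are implemented; **normalized is the default** because its scale
is comparable across data sets. Principal coordinates are computed from
the double-centered squared-distance matrix and axes with non-positive
eigenvalues are *discarded* (and counted), never projected: weighted
UniFrac matrices need not be Euclidean, and imaginary axes would corrupt
downstream clustering. Group structure is tested by PERMANOVA
(`vegan::adonis2`, 9,999 permutations by default) with the
(1 + exceedances)/(1 + permutations) convention so p is never exactly 0,
and pairwise contrasts are Benjamini–Hochberg adjusted. The number of
biomes is chosen by PAM clustering with the gap statistic: the reference
null is uniform over the per-axis bounding box of the coordinates
(B = 100 draws by default) and k is the smallest k with
Gap(k) ≥ Gap(k+1) − s(k+1), the 1-SE rule. PAM's deterministic BUILD
initialization means the seed only affects the reference draws.

## Classifying taxa into biome preferences

Availability — the share of presence records a taxon with no biome
affinity would show in each biome — is an explicit input with default
(land 0.44, marine 0.38, freshwater 0.18). It is *not* derived from
sample counts: the study design this mirrors reports availabilities that
are close to, but not exactly, its sample-count fractions (27/25/11 of
63), so the package parameterizes rather than guesses.

A taxon present in a single biome is that biome's specialist; no bootstrap
is run. Otherwise each of 1,000 replicates draws 100 presence records with
replacement from the taxon's *present-sample multiset* and computes the
per-biome share of the draws; the taxon has affinity for biome b when at
least 2.5% of replicates put its share at or above b's availability
(equivalently, the upper 97.5% bootstrap quantile reaches availability —
ties resolved with ≥, which matters only for the discrete shares a 100-draw
bootstrap can produce). The raw preference is the set of affinity biomes
(seven possible states with three biomes); for comparative analysis the
three rarest categories (full, marine+land, freshwater+marine generalists)
collapse into a single *marine generalist* state, giving five analysis
states. With three biomes whose availabilities sum to 1, every replicate
puts at least one biome at or above availability, so the affinity set is
never empty for any tail ≤ 1/3.

Per-taxon seeds are derived by hashing the root seed with the taxon id, so
classification does not depend on the order in which taxa are processed.

## Mk models of preference evolution

Transition structure is a constraint pattern over the 5×5 rate matrix:
equal rates (1 free rate), symmetric (10), all-rates-different (20), and a
stepwise model (12) in which specialists never interconvert directly and
the marine specialist cannot exchange directly with the freshwater+land
generalist — a new specialization must pass through a generalist
intermediate. Likelihoods are Felsenstein pruning with P(t) = exp(Qt); the
root prior is **uniform by default** (stationary and custom priors are
options) because the source analyses do not report one, and the choice
shifts log-likelihoods by a model-dependent amount worth surfacing.

Fitting optimizes log-rates (bounds 1e-9 to 1e3 — generous for
relative-time trees) from a parsimony-informed start (minimum changes per
unit branch length) plus seeded random perturbations. Matrix exponentials
use a per-evaluation eigendecomposition of Q with per-edge reconstruction,
falling back to scaling-and-squaring Padé whenever the eigenvector basis
is ill-conditioned (rcond < 1e-10) or the reconstructed P fails
row-stochasticity at 1e-8; the fallback makes defective or
nearly-defective Q safe, and the fast path is what makes the iterative
refit chains below affordable on hundreds of tips.

Model simplification starts from the fitted ARD model: step 0 zeroes all
rates below 1e-3 at once, each later step zeroes the single smallest
remaining rate (ties broken in row-major (from, to) order), refitting after
every step from warm starts, and the chain stops when AIC strictly
increases; equal AIC within 1e-6 prefers the simpler model and the search
continues one more step. Models are compared by Akaike weights. For the
best model, each state's source–sink ratio is the total rate *away*
divided by the total rate *into* it — values above 1 mark evolutionary
sources; a state nothing flows into reports `Inf` explicitly.

Uncertainty comes from two tree-subsampling schemes refit per iteration:
80% of tips uniformly at random, or an equal number of tips per state
(default, the smallest class size). Failed iterations are skipped and
counted; more than 10% failures abort.

## State-dependent diversification

The SSE layer works on the combined observed × hidden state space (size
S×H, combined index (s−1)H+h). Three tying patterns for speciation:
MuSSE (per observed state, H = 1), MuHiSSE (per combined state, H = 2) and
the concealed-trait (CTD) family (per *hidden* state, H = 2–4), all with a
**single extinction rate**. The CTD family is the null hypothesis for
trait-dependent diversification: it lets speciation vary across the tree
without reference to the observed trait, so a MuSSE/MuHiSSE win over CTD is
required before attributing rate variation to biome preference. Observed
transitions are fixed at the best Mk model's rates and not counted as free
parameters; all ordered hidden-state pairs are free and may be asymmetric;
dual transitions are excluded, making the combined generator
Q_obs ⊗ I_H + I_S ⊗ Q_hid. The free-parameter counts are therefore purely
structural: S+1 (MuSSE), S·H+1+H(H−1) (MuHiSSE), H+1+H(H−1) (CTD).

Along every branch the standard E/D ODE system is integrated
tipward-to-root with an adaptive Dormand–Prince RK45 (rtol 1e-8, atol
1e-10) implemented in the package's C++ core — the same design the field's
SSE packages use, because an interpreted per-branch solver makes the
refit-heavy studies below infeasible. E is clamped to [0, 1] and negative
D values are clipped to 0 and *counted*; the count is surfaced as an
attribute of the log-likelihood. A fixed-step RK4 integrator written in
plain R lives in the test suite as an independent oracle, together with
the factorization identity that a state-independent model must equal
birth–death × Mk exactly.

Tips carry observed states only: every hidden level consistent with the
observed state starts at D = ρ (the sampling fraction, shared across
states) and E = 1 − ρ. The root combines states with observed-data
(FitzJohn) weights and conditions on survival of both root lineages by
default; both are flags (`root_weighting`, `condition_on_survival`)
because the original analyses name neither choice.

Starting values follow the 27-point grid protocol: a birth–death fit to
the branching times supplies λ and μ inits (a zero μ̂ degenerates the μ
grid to {0, 1e-6, 2e-6} × the half/double multipliers to keep 27 distinct
points), the mean nonzero Mk rate supplies the hidden-rate init, all
half/×1/double combinations are scored by the likelihood, and the best six
become optimization starts. Optimization runs Nelder–Mead cycles (up to
75) followed by a bounded quasi-Newton polish on log-parameters. Because
every grid point ties the speciation rates across hidden states, it lies
exactly on the hidden-label symmetry manifold of the likelihood, where
simplex optimizers stall; each start is therefore run twice with the
log-speciation rates fanned apart in opposite orders (±log 2.5). The
optional penalty — `0.1 × Σ (log λ_i/λ̄)²` over speciation rates exceeding
10× the birth–death estimate — is this package's concrete reading of a
"log-likelihood penalty of 0.1" against runaway rates; it is documented as
an interpretation, switchable off, and the unpenalized log-likelihood is
always reported and is what AIC uses.

Model comparison tables report (model, H, k, logL, AIC, weight) and refuse
to mix fits on different data. A sampling-fraction sweep refits every
model at ρ ∈ {1, 0.5, 0.25, 0.125, 0.0625} and reports the winner per ρ,
since conclusions should not hinge on the assumed completeness of the
phylogeny.

## Synthetic data: what it emulates, and what it does not

The generators produce every input with known ground truth:

* `simulate_bd_tree()` — forward Gillespie birth–death from one lineage,
  extinct lineages pruned, conditioned on ≥2 survivors by rejection
  (explicit retry cap 10,000). n-stopped simulations truncate at a uniform
  time inside the holding interval after the extant count first hits n,
  avoiding the bias of stopping exactly at the n-th speciation.
* `simulate_mk_history()` — exponential waiting times along each branch,
  with per-branch random streams derived from the root seed, full history
  retained for oracle tests.
* `simulate_sse_tree()` — the same engine over combined states, exposing
  observed tip states and retaining hidden ones.
* `simulate_occupancy()` — Bernoulli presence with probability `p_in` in
  preferred-biome samples and `p_out` elsewhere, per-biome sample counts
  defaulting to the unequal survey design (land 27, marine 25, freshwater
  11), every taxon guaranteed ≥1 presence. `p_in`/`p_out` are synthetic
  constructs: the real survey is observational and has no known generative
  model, so recovery results calibrate the classifier's behaviour, not the
  survey's error rates.

What passing recovery tests on these data shows is that the estimators
recover the truth *under their own generating assumptions* at realistic
sizes. They do not establish robustness to phylogenetic error, unmodelled
abundance structure, spatially correlated sampling, or taxon-dependent
detection — none of which the generators emulate.

## Problem sizes and study designs used by the tests

The package's recovery studies are scaled to a single CPU: ER rate
recovery uses one 2,000-tip tree; the sparse-support study runs 50
replicates of ARD simplification on 700-tip trees with 11 of 20 true
rates nonzero — a reversible backbone of strong rates (0.6–0.9) through
the generalist hubs plus three rare shortcuts below the prune scale. The
backbone-plus-shortcuts shape matters: distinguishing the two directions
of a corridor needs realized round-trips, so per-direction support grows
slowly with tree size, and on trees of a few hundred tips AIC correctly
(but unhelpfully for a recovery study) prunes reverse rates the data
cannot see. Classifier recovery uses 500 taxa at p_in = 0.8,
p_out = 0.02;
the CTD2 recovery uses 20 replicates of ~300-tip trees and the
no-spurious-state-dependence calibration 20 replicates of 120-tip trees.
For the CTD2 study the true hidden switching rates are 0.4 (into the
fast-speciating regime) and 0.8 (back out of it): hidden regimes must
actually be realized on a 300-tip tree for their rates to be estimable,
and because fast-speciating lineages are over-represented among tips, the
return rate is set higher so the slow regime keeps a workable share of
the tree. Much slower switching leaves the minority regime with a handful
of tips and an unidentifiable speciation rate; much faster switching
averages the regimes away. This is a property of the experimental design,
chosen once. Even so, the slow regime's speciation rate is the
hardest-estimated quantity in the package: its sampling error at this
tree size is of the same order as the rate itself, and recovery studies
should expect a sizable minority of replicates to miss it by more than a
third (see the test suite for the exact study). The calibration study
uses an observed trait that mixes freely (total leave rate 1.2 on
height-2.5 trees): a slowly evolving trait clusters on clades and lets a
per-observed-state model soak up stochastic clade-level rate variation —
precisely the false-positive mode the hidden-state family exists to
control — which would turn a null calibration into a measurement of that
(real, and separately interesting) effect.

## Known limitations

* Transition-rate and diversification estimates are in relative time;
  nothing here calibrates absolute rates.
* The 7→5 state collapse is specific to three biomes; the classifier
  itself accepts any biome alphabet, but the stepwise Mk pattern and the
  collapse rule are defined only for the five analysis states.
* The SSE likelihood assumes anagenetic state change only (no cladogenetic
  change), a single global sampling fraction, and a single extinction
  rate, matching the analyses it reproduces.
* BAMM-style rate-shift detection is out of scope; rate heterogeneity is
  addressed through the CTD hidden-state family instead.
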