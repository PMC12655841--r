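---
title: "DOO-IT methods: dual-objective nuSVR model selection for DES solubility QSPR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DOO-IT methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dooit)
```

## The modelling problem

`dooit` models the decadic log mole-fraction solubility, log *x*, of
pharmaceutical carboxylic acids in deep eutectic solvents (DESs) as a
function of COSMO-RS-derived molecular descriptors, and — more
importantly — automates the *selection* of such a model. The premise is
that a single best model is ill-defined for this problem: accuracy,
parsimony (how much of the training data the kernel machine must memorize
as support vectors), and the stability of the chosen descriptors across
random train/test splits pull in different directions. The package's job
is to make that trade-off explicit and reproducible.

The regressor throughout is ν-support-vector regression with an RBF
kernel. ν is attractive for this purpose because it has a direct
complexity reading: it lower-bounds the fraction of training points that
become support vectors and upper-bounds the fraction of margin errors,
so the *support-vector ratio* (support vectors / training points in a
fold) is an intrinsic, hyperparameter-comparable complexity measure.

## Descriptor engineering

Two nested feature sets are assembled from raw per-species tables.

* **Energetic descriptors** (per solute, "API"): total intermolecular
  interaction energy E_int, its electrostatic-misfit, hydrogen-bond and
  van der Waals components, and the chemical potential μ. Units pass
  through from the source tables unchanged; the feature manifest records
  this convention once.
* **DES-side analogues**: the same five quantities for the solvent,
  formed as mole-fraction-weighted sums over the solute-free mixture
  components (hydrogen-bond acceptor, donor(s), and water when present —
  water is simply a third component in the weighting).
* **Relative descriptors**: solute minus DES differences, Δ-prefixed.
* **Computed solubility**: the COSMO-RS predicted log(x^COSMO), kept as
  an ordinary descriptor so the learner may use (or discard) the physics
  baseline.
* **σ-potential descriptors** (set 2 only): each species' σ-potential is
  supplied on the standard 61-point grid over charge densities
  [−0.03, +0.03] e/Å². Averaging over 0.005-wide intervals reduces it to
  a 12-step function spanning the hydrogen-bond-donor (HBD1–4, −0.03 to
  −0.01), hydrophobic (HH1–4, −0.01 to +0.01) and acceptor (HBA1–4,
  +0.01 to +0.03) regions. Only the *relative* (solute − mixture-weighted
  DES) versions of these 12 values enter the feature set.

Set 1 therefore has 5 + 5 + 5 + 1 = 16 columns; set 2 adds the 12 Δσ
descriptors for 28. Fusion thermodynamics use the constant-heat-capacity
approximation ΔS_fus = ΔH_fus/T_m, giving ΔG_fus(T) = ΔH_fus(1 − T/T_m);
these feed the upstream solid–liquid-equilibrium computation whose
outputs the package consumes, and are exposed as `gibbsFusion()`.

**Bin-edge convention.** The grid spacing (0.001) divides the bin width
(0.005) exactly, so bin membership at shared edges needs a convention:
bins are half-open [lo, lo + 0.005) with the final bin closed at +0.03.
Eleven bins then hold five grid points and the last holds six. Membership
is computed with a 1 × 10⁻⁹ tolerance so that floating-point grid values
land deterministically. An alternative (closing each bin on the left)
would shift bin means by one grid point; nothing downstream depends on
the choice, but it is fixed, documented, and tested against an explicit
membership-loop oracle.

## The dual-objective search

For a fixed feature subset and training split, `runDoo()` samples
hyperparameter triples (ν, C, log₁₀ γ-scale) and scores each by 5-fold
cross-validation on two objectives to be minimized jointly: mean absolute
error (accuracy) and mean support-vector ratio (complexity). The
non-dominated set of completed trials is the Pareto front
(`paretoFront()`); trials tied on both objectives are all retained, and
failed fits are excluded rather than given penalty objectives (a penalty
would distort the front's shape near the failure region).

* **γ anchoring.** Rather than searching γ absolutely, a per-cycle anchor
  γ_base = 1/median(‖xᵢ − xⱼ‖²) is computed from the standardized
  training features (the median heuristic), and the search explores a
  log₁₀ scaling factor in [−2, 2] around it. This keeps the searched
  scale physically relevant for any feature subset. For more than 2000
  rows a seeded subsample of 2000 rows bounds the quadratic pair
  enumeration; at the package's default problem sizes the computation is
  exact.
* **Sampler.** The search is a seeded uniform random search (log-uniform
  in C over [10⁻², 10³], uniform in ν over [0.05, 0.95] and in the γ
  exponent). A model-based multi-objective sampler could propose trials
  more cleverly, but no such engine exists in this package's dependency
  set, and for the front-then-1-SE selection used here a dense random
  sweep of a 3-dimensional box is an adequate and exactly reproducible
  explorer; every correctness property of the downstream machinery is
  independent of the proposal mechanism. The bounds bracket the
  optimal regions reported for this class of problem (ν ≈ 0.25,
  C ≈ 34–57, scale ≈ 0.45–0.94).
* **Standardization.** Features are standardized to zero mean and unit
  variance on training statistics only; the stored affine map is applied
  to any evaluation block. By default the standardizer is refit *inside
  each CV fold* (leakage-free); a `"global"` mode fits it once on the
  whole training split, matching the published preprocessing, and is the
  mode `reproducePublishedProtocol()` uses. Columns constant within a
  fold-train block are centered with unit scale (a guard, since a
  zero-variance column carries no information either way); columns
  constant in a whole training split are dropped with a warning.
* **Degenerate response.** A constant fold-train response makes libsvm
  return an empty model; the package substitutes the analytic limit — an
  exact constant predictor with the support-vector fraction pinned at its
  ν lower bound — so degenerate folds behave continuously.

## Iterative pruning and the 1-SE rule

`select1SE()` picks, from each front, the simplest trial whose CV MAE is
within one standard error of the most accurate trial's. The SE is the
standard error of the best trial's per-fold MAEs (sd/√k); among
qualifying trials the lowest support-vector ratio wins, with ties broken
by lower CV MAE and then lower trial id — a fully deterministic rule.

`dooitRun()` then: refits the selected trial on the full training split
(this refit provides the level's train/test metrics); ranks its features
by permutation importance — the mean MAE increase over 10 seeded
permutations, evaluated on a 20 % carve-out of the *training* split with
the importance model fitted on the other 80 %, so importances reflect
validation behaviour while the held-out test set stays untouched until
final metrics; drops the least important feature (ties: first in column
order); and repeats from the complete descriptor set down to
`min_features` (default 3, below which ranking becomes meaningless for
this descriptor family). One run thus yields one candidate per
complexity level.

## Stability analysis and final selection

The run is repeated `n_runs` times (default 50) on independent seeded
80/20 splits. `aggregateRuns()` tabulates, per descriptor count, the
frequency of runs producing a candidate there, the mean ± sd test MAE,
and each descriptor's occurrence frequency. `architecturalSelection()`
keeps counts seen in ≥ 30 % of runs whose mean test MAE is within one SE
(sd/√n at the minimizing count) of the best qualifying count — the
"basins". `finalSelection()` scores all candidates at those counts with
the composite

total = 0.5 · accuracy + 0.3 · R² + 0.2 · generalization,

where each component is min-max normalized within the finalist cohort
(accuracy from test MAE, generalization from the absolute train/test MAE
gap, both reversed so 1 is best; a metric that does not vary across the
cohort scores 1 for everyone, which also makes a single-member cohort
score 1.0). Min-max normalization within the cohort is the principal
reconstruction choice here: the three raw metrics live on incommensurate
scales, and cohort-relative normalization is the simplest map that makes
fixed weights meaningful. The absolute gap penalizes under- and
over-fitting symmetrically. Composite near-ties (Δtotal < 0.01) are
broken by descriptor stability — the mean occurrence frequency of the
candidate's descriptors at its count — favouring chemically reproducible
feature sets over split-specific ones.

## Seeding

Every random draw (splits, fold assignment, trial sampling, carve-outs,
permutations, synthetic data) derives from one master seed through a
Lehmer-style integer hash on the 2³¹ − 1 field (`deriveSeed()`), whose
products stay below 2⁵³ and are therefore exact in double arithmetic.
Identical configuration and master seed give byte-identical JSON
artifacts; no global RNG state leaks in or out of package functions.

## The synthetic generator

`generateSynthetic()` emulates the structural features of the real
modelling table that matter to model selection:

* descriptors drawn from a correlated Gaussian with compound-symmetry
  blocks (default: blocks of 3 at ρ = 0.5), mimicking the
  solute/DES/relative triplication of the energetic descriptors — the
  collinearity that makes pruning genuinely hard;
* a response that is a sparse linear function of known descriptors
  (default: one per block, effects 1.0/0.8/0.6/0.5, intercept −3 on the
  log-x scale) plus Gaussian noise, optionally with a mild quadratic and
  interaction term; when `noise_sd` is unspecified it is set so the
  signal explains a target fraction of response variance (default 0.95,
  the regime where the real models operate);
* a `log_x_cosmo` column correlated with the response (default 0.9),
  standing in for the COSMO-RS computed solubility.

Defaults mirror the study scale: 1020 records, 16 descriptor columns.
What the generator does *not* emulate: physically structured
σ-potentials (curves are sums of up to three Gaussian bumps, smooth but
not thermodynamic), heteroscedastic measurement error, temperature and
composition gradients within a solvent family, and discrete
solute/solvent identity effects. Passing tests therefore demonstrate
that the machinery recovers known structure under realistic correlation
and noise — not that any particular chemistry is predicted correctly.

## Problem sizes used by the test suite

The suite exercises every stage at sizes chosen to keep a full run in
the tens of minutes on one CPU while leaving the scientific conditions
intact: Pareto/1-SE oracles run on hundreds of randomized instances up to
500 trials; the ν-SVR contract battery uses 120 trials on a 240-record
dataset; the parameter-recovery check runs 5 generator seeds × one
DOO-IT run at n = 500 with 60 trials per pruning level (16 descriptors,
4 informative, ρ = 0.5, signal R² ≈ 0.95), requiring ≥ 3 of 4 informative
descriptors at the 4-descriptor level in ≥ 80 % of seeds; determinism is
checked by running a 2 × 40-trial pipeline twice and comparing artifact
bytes. The full published protocol (50 runs × 2000 trials on 1020
records) is available through `reproducePublishedProtocol()` and is a
multi-hour computation; it requires the study's appendix tables, which
are not redistributable with the package.

## Known limitations

* The random-search sampler explores the hyperparameter box uniformly;
  with very small trial budgets (tens of trials) the Pareto front is
  sparse and the 1-SE choice correspondingly coarser.
* Permutation importance on strongly collinear descriptors splits credit
  across a block; the stability analysis across runs is the intended
  mitigation, not a per-run fix.
* The support-vector ratio is specific to SVR-family models; the
  framework does not generalize as-is to learners without an intrinsic
  complexity reading.
* Applicability-domain analysis and residual diagnostics for the final
  model are out of scope; the final-model card carries the information
  needed to run them externally.
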