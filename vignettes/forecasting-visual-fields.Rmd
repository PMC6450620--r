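---
title: "Forecasting Humphrey visual fields from a single test: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting Humphrey visual fields from a single test: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvfcast)
library(dplyr)
```

# The problem

Glaucoma management leans on standard automated perimetry: the Humphrey
24-2 program measures light-sensitivity thresholds (in dB) at 54 points of
the central visual field, and clinicians want to anticipate how those
thresholds will evolve. Classical tools regress global indices (mean
deviation, visual field index) or individual points over a long series of
tests. `hvfcast` implements a different protocol: learn, from a large
longitudinal population, a direct mapping from a *single* field to the
field a fixed interval later, and compare that against the classical
pointwise linear baselines under a masked pointwise mean absolute error
(PMAE).

The package covers the full pipeline — data model, synthetic cohort
simulation, temporal pairing and patient-level cross-validation, three
linear baselines with a theoretical error floor, a convolutional
regression engine with interval transfer learning, and the evaluation
suite (PMAE/RMSE with cluster-bootstrap CIs, Bland–Altman agreement of
mean deviation).

# Data model

A 24-2 field is embedded in an 8×9 grid (`to_grid()`): rows are the eight
vertical eccentricities +21…−21°, columns the nine horizontal chart
positions in printout order. The lattice is ragged — row-wise point counts
4, 6, 8, 9, 9, 8, 6, 4 — and the mask of 54 valid cells is the left/right
column mirror between eyes. Invalid cells carry the sentinel 0,
consistent with the masked loss: they contribute neither value nor
gradient anywhere. Two points fall on the physiologic blind spot (15°
temporal, ±3°); they are ordinary test points (included in the 54 and in
PMAE) but excluded from mean deviation, which is therefore a 52-point
equally-weighted index:

$$\mathrm{MD} = \frac{1}{52}\sum_{i \notin \mathrm{blind\ spot}}
  \bigl(s_i - N_i(\mathrm{age})\bigr).$$

Laterality is *not* folded away by mirroring left eyes onto a right-eye
template; instead eye is available as a model covariate, which matches the
covariate-search design. Equal weighting keeps MD linear (a uniform +c dB
shift moves MD by exactly +c), unlike the device's variance-weighted MD
whose normative database is proprietary. For the same reason the package
carries its own synthetic normative surface (`normative_surface()`): a
foveal peak (34 dB at the 45-year reference age) declining 0.1 dB per
degree of eccentricity and 0.07 dB per year of age. These MD values are
internally coherent between simulation and evaluation but are *surrogate*
MDs, not the printout index; whether a study's extracted MD is recomputed
or device-reported is immaterial here because the same surface is used on
both sides of every comparison.

Sensitivities live in [0, 50] dB (0 dB = brightest stimulus not seen;
ceiling fixed at 50), recorded to 0.01 dB. The tabular interchange format
is a plain CSV (`read_fields()`/`write_fields()`) with one row per test
and the 54 sensitivities in row-major valid-cell order.

# The synthetic cohort

Real longitudinal perimetry archives are institutional; the simulator
(`generate_cohort()`) reproduces the *statistical structure* of a large
unfiltered clinical population so every downstream stage can be exercised
and tested:

* **Visit process.** Tests per eye are 1 + negative binomial, calibrated
  to mean 3.6 and SD 1.9. Inter-visit gaps are Gamma(shape 4, mean 1.35
  years); the shape avoids the near-zero gaps that the pairing step would
  discard, and the mean makes 3.6 visits span about 3.5 years of
  follow-up, matching the target population's mean follow-up. First-test
  age is truncated normal, mean 61.9, SD 14.8 years.
* **Disease archetypes.** Each eye draws one of five baseline patterns —
  normal, early arcuate defect, moderate, severe, hemifield — weighted
  0.30/0.25/0.20/0.15/0.10, each a spatially smooth depression of the
  normative surface scaled by a per-eye lognormal severity factor
  (log-SD 0.35). The case mix of an unfiltered clinic is not published,
  so these weights are a modelling choice, fixed once. The hemifield
  archetype confines all depression strictly to one side of the
  horizontal midline. The global depth multiplier was calibrated once by
  bisection on ~2,000-patient samples so the default cohort's mean MD
  lands at −6.73 dB; the frozen value is 0.92. The resulting MD spread
  (SD ≈ 7 dB) is somewhat wider than the 6.2 dB of the reference
  population — a known, accepted deviation.
* **Progression.** Point-wise decay slopes follow the Gaussian
  rate-of-progression (ROP) model with mean −0.36 and SD 0.60 dB/year
  (the Early Manifest Glaucoma Trial calibration). To give spatially
  aware models a signal to learn, the slope variance is split 25%
  global / 50% sector / 25% independent cell over a six-sector
  (arcuate/quadrant, Garway-Heath-like) map; the split preserves the
  marginal mean and SD exactly, and slopes are archetype-independent so
  the marginal Gaussian holds cohort-wide. True fields evolve linearly,
  baseline + slope·Δt, clamped to [0, 50].
* **Measurement noise.** Retest SD is heteroscedastic: 2.5 dB at 30 dB
  true sensitivity rising linearly to 5 dB at 10 dB (clamped outside),
  mirroring the 2–3 dB test–retest variability of healthy fields and the
  larger fluctuation of damaged regions. Noise is added *before*
  clamping, so the 0 dB floor censors, as on the device.

What the simulator does **not** model: learning effects, unreliable tests
(fixation losses, false positives), media opacity and post-surgical
sensitivity changes, non-linear (exponential/sigmoid) decay, and
correlations between fellow eyes. Green tests on this cohort therefore
demonstrate correctness of the pipeline and qualitative orderings, not
clinical performance on real data.

# Pairing and splits

Every ordered same-eye pair of tests with an interval in [0.75, 5.5]
years is a training/evaluation example (`make_pairs()`; a 365.25-day
year). Pairs are binned into ten 0.5-year intervals centred at 1.0, 1.5,
…, 5.5 years. Bin edges are half-open, [centre−0.25, centre+0.25), so no
interval lands in two bins; the 1-year bin is thus exactly [0.75, 1.25),
and the final bin is closed at 5.5 so the stated upper limit itself
survives. Left-closure of the bins is a convention (right-closure would
be equally defensible); it lives in one function, `assign_bin()`.

Splitting (`split_patients()`) is strictly at patient level — both eyes
and all tests of a patient travel together — into a 20% held-out test set
and 10 disjoint cross-validation folds over the remainder, as a seeded
permutation with fold sizes differing by at most one.

# Baseline models

1. **Simulated ROP** (`predict_rop()`): per point, add a draw from
   N(−0.36·t, (0.60·t)²) and clamp. With σ = 0 it is the deterministic
   EMGT drift.
2. **Empirical ROP** (`fit_empirical_rop()`): pool annualised per-point
   changes (target − input)/t across all valid cells of the training
   pairs into a single Gaussian, then predict as in model 1. A per-cell
   variant exists but is off by default, matching the pooled design.
3. **Pointwise regression** (`fit_pointwise()`): 54 independent OLS fits,
   target_i ~ intercept + input_i + t. This is the minimal per-point
   design — same-cell input plus interval — and the covariate choice is
   isolated behind the `pointwise_model` interface so richer designs can
   be swapped in. Rank-deficient cells fall back to the empirical-ROP
   forecast.

**Theoretical floor.** Under Gaussian test–retest noise with SD σ_i at
point i, even a perfect predictor of the *true* field mispredicts the
noisy measurement by |N(0, σ_i²)|, so expected PMAE is bounded below by
mean_i σ_i √(2/π) (`theoretical_pmae_floor()`). With a pooled σ ≈ 2.91 dB
the floor is ≈ 2.32 dB. The companion estimator
(`estimate_retest_sd()`) recovers σ from short-interval replicate pairs
(differences ÷ √2). A related closed form is used as an engine test: two
independent draws from the same Gaussian change model differ by
N(0, 2σ²t²), so their expected absolute gap is (2/√π)·σ·t ≈ 0.677 dB at
t = 1 for σ = 0.60.

# The deep models

Inputs are C×8×9 tensors (`encode_input()`): the masked sensitivity grid
plus, optionally, covariate faces in the fixed order age, gender, eye,
test number. Continuous covariates (age in raw years — an optional ÷100
normalisation flag exists, default off — and test number, encoded
continuously because its cardinality is unbounded) each contribute one
constant-valued face; categorical covariates (gender, eye, both binary)
contribute one-hot face pairs. Channel arithmetic: C = 1 + #continuous +
Σ cardinalities; all 2⁴ = 16 covariate subsets are enumerable with
`covariate_combinations()`.

Four architecture families (`arch_spec()`), all ending in a linear
1-channel projection to the 8×9 output:

* **cascade** — k copies of a three-convolution block (filters
  64/128/256 at full scale); every block, and the final projection,
  consumes the channel-concatenation of the original input and *all*
  previous block outputs (dense copy-concatenation connectivity).
* **residual** — the same blocks with an additive skip per block (1×1
  projection on channel mismatch).
* **fullbn** — the blocks stacked sequentially.
* **fully_connected** — flatten, one ReLU hidden layer, linear output.

Convolutions are 3×3, stride 1, zero-padded "same", ReLU-activated with
batch normalisation after each convolution. Kernel size, padding and
BN placement are fixed at the contemporaneous defaults and isolated in
`arch_spec()`. Exact per-architecture parameter totals depend on layer
bookkeeping conventions that differ between frameworks, so the package
asserts *orderings* (counts grow with k; cascade exceeds fullbn at equal
depth) and shape arithmetic instead of exact totals.

Training (`train_model()`) minimises the masked PMAE — the mean absolute
error over the 54 valid cells only; invalid cells contribute neither
value nor gradient — with Adam, batch 32, Glorot (Xavier) initialisation,
all deterministic under the configured seed. Validation PMAE is recorded
every epoch and the *best* epoch's weights are returned, because the
protocol records the highest validation accuracy rather than the final
epoch. The engine is a compact, self-contained implementation in R
matrix operations (im2col convolution, manual backpropagation); on an
8×9 grid this trains desk-scale models in seconds to minutes on one CPU.

Two scale profiles are built in (`train_config()`): `full` (1000
epochs, Adam 1e-3, filters 64/128/256, 10 folds, 10 bins) and `desk`
(50 epochs, Adam 1e-2, filters 8/16/32, typically 2 folds and 3 bins).
The desk profile's higher learning rate is its own deliberate setting:
with a few hundred optimisation steps instead of a few hundred thousand,
a 1e-3 step cannot traverse the ~25 dB output scale of the final linear
head, while 1e-2 converges reliably on these small grids.

**Protocol.** Model selection (`run_model_selection()`) trains every
candidate architecture per cross-validation fold on the 1-year bin, with
validation PMAE assessed on the fold's own 1-year pairs — the shortest
interval carries the most pairs and anchors the transfer chain, so it is
the natural selection stratum. The interval chain (`transfer_train_chain()`)
then trains one model per (bin, fold): bin 1.0 from scratch, every later
bin warm-started from the same fold's model of the immediately preceding
bin — 10 × 10 = 100 models at full scale. Prediction
(`predict_ensemble()`) averages the 10 fold models of the pair's bin and
clamps to [0, 50].

# Evaluation

`evaluate_models()` scores any predictor (baseline or deep, behind a
common function interface) on held-out pairs: per-pair PMAE and RMSE
(PMAE ≤ RMSE always, by Jensen), aggregated with equal pair weights
overall and per bin. Confidence intervals are percentile cluster
bootstraps resampling *eyes*, not pairs or points, because points within
an eye are strongly correlated; published perimetry CIs rarely state
their resampling unit, so the unit here is made explicit rather than
matched to any particular report. Mean-deviation agreement is
summarised Bland–Altman style (mean difference, ±1.96 SD limits, Pearson
r, and the adjusted R² of the actual-on-predicted MD regression). A
leakage guard refuses to score pairs whose patients are not in the test
part of the supplied split plan.

# Numerical choices and degenerate inputs

* Clamping to [0, 50] always happens after sampling/prediction
  (censoring), never before.
* Rank-deficient pointwise cells are flagged and served by the
  empirical-ROP fallback rather than dropped.
* Zero-variance MD sets make the Bland–Altman correlation undefined; it
  is reported as `NA` with a warning rather than an error.
* The interval filter is closed, [0.75, 5.5]; the bin tiling is
  half-open with the final bin capped at 5.5.
* All stochastic steps (simulation, splits, ROP sampling, initialisation,
  batch order, bootstrap) are seeded and reproducible; identical seeds
  give byte-identical cohort CSVs.

# Problem sizes used by the tests

The shipped tests run the full pipeline at reduced scale, chosen as
sensible desk sizes: cohorts of 60–100 patients for unit and training
tests, ~800 noiseless patients for parameter recovery, ~2,950 patients
(~5,000 eyes) for the cohort-moment checks, one-million-draw Monte Carlo
for the ROP moments, and desk-profile networks (filters 8/16/32, 30–250
epochs, 2 folds, 3 bins) for the training properties: identity-map
learnability, architecture ordering (cascade ≤ fully connected on
sector-correlated progression, 3-seed median), and the warm-start
benefit of the transfer chain. The 100-slot protocol structure is
instantiated with 0-epoch training on a deterministic regular-visit
cohort so all ten bins are populated in every fold.

# Known limitations

* The normative surface, and hence MD, is synthetic and self-consistent
  rather than device-matched.
* The simulator's archetype mixture and severity spread are modelling
  choices; its MD SD overshoots the reference population's by ~1 dB.
* Linear true progression only; floor censoring is the only
  non-linearity.
* Clinical-scale accuracy (PMAE near 2.5 dB) is only reachable with
  institutional archives of tens of thousands of fields and GPU-scale
  training; the package targets the reference *parameters*, the protocol
  structure, and the qualitative orderings at desk scale instead.

# A worked example

```{r example, eval = FALSE}
fields <- generate_cohort(sim_config(n_patients = 100, seed = 21))
pairs <- make_pairs(fields)
plan <- split_patients(unique(fields$patient_id), test_fraction = 0.2,
                       k = 2, seed = 21)
train <- dplyr::anti_join(pairs, dplyr::filter(plan, part == "test"),
                          by = "patient_id")
test <- dplyr::semi_join(pairs, dplyr::filter(plan, part == "test"),
                         by = "patient_id")

bundle <- transfer_train_chain(pairs = train, fields, plan,
                               spec = arch_spec("cascade", k = 2),
                               config = train_config("desk", seed = 1),
                               covariates = "age",
                               bins = c(1.0, 1.5, 2.0))
ev <- evaluate_models(
  list(deep = predictor_deep(bundle),
       simulated_rop = predictor_rop(rop_params(), seed = 1),
       pointwise = predictor_pointwise(fit_pointwise(train, fields))),
  dplyr::filter(test, bin_center <= 2.0), fields, plan = plan)
glance(ev)
autoplot(ev)
```
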