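---
title: "Infant visual-cortex EEG connectivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Infant visual-cortex EEG connectivity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
connectivity measure and its assumptions, the topographic derivations, the
inference layer, what the synthetic generator does and does not emulate, and
the numerical and design choices that were genuinely open.

## The measurement model

### From cleaned EEG to epoch spectra

The package consumes *cleaned* continuous EEG (channel × time matrix with a
sampling rate): filtering, artifact rejection, channel repair and
re-referencing are upstream preprocessing concerns and deliberately out of
scope. Per stimulus condition, the signal is cut into 1-second,
50%-overlapping epochs on a fixed grid anchored at t = 0. Epochs whose span
is covered by coded inattention intervals for *strictly more than* 50% of
their length are rejected ("more than 50%" is read literally: a half-masked
epoch survives). Participants contribute a condition only with at least 90
surviving epochs; by default the gate is applied per condition, since each
condition's connectivity estimate needs its own epochs. The 90-epoch count
is the operative criterion — with 50% overlap it corresponds to roughly 45 s
of clean signal, not 1.5 min, and the count is what the gate enforces. The
epoch grid is condition-global: it is not re-anchored after masked gaps,
which keeps segmentation deterministic.

Each epoch is tapered with a Hann window (reducing crosstalk between
overlapping epochs) and discrete-Fourier transformed; 1-s epochs give a 1 Hz
bin grid. The taper is amplitude-unnormalized: the connectivity estimator
below is scale-invariant, so taper normalization is immaterial (this is
tested). The DC bin is excluded from every band computation.

### dbWPLI

For two channels a, b, epoch j and frequency f, the cross-spectrum is
`coef_a × Conj(coef_b)` and its imaginary part `I_j` carries lag
information. The debiased weighted phase-lag index is

    dbWPLI = ((Σ I_j)² − Σ I_j²) / ((Σ |I_j|)² − Σ I_j²)

an estimator of squared phase-lagged synchronization that (i) ignores
zero-lag coupling, the dominant volume-conduction artifact at infant head
sizes, and (ii) is debiased so that independent signals score near zero even
at modest epoch counts — the test suite verifies that the null level
decreases with the number of epochs. The estimator can be negative; a zero
denominator (no imaginary coupling evidence at all) returns 0 by convention,
a bounded and conservative choice. Downstream analyses use absolute values
only — connectivity strength, not lead/lag direction.

Band scores average |dbWPLI| over the integer bins of theta (3–5 Hz), alpha
(6–8 Hz) and whole gamma (20–60 Hz) — so theta is exactly {3, 4, 5} Hz.
Whether the absolute value is taken per bin before averaging or after
averaging signed per-bin scores is not dictated by the estimator; the
default is per-bin (`abs_first = TRUE`), matching absolute scores feeding
band means, and the signed-first alternative is exposed. Pair orientation
(a, b) vs (b, a) is irrelevant after the absolute value (tested).

### Seed-anchored areas of interest

The montage is any labelled 3-D coordinate table; the two midline occipital
electrodes (Oz, POz) form the seed. Per hemisphere, non-seed electrodes are
ranked by Euclidean distance to the seed centroid and split into `n_steps`
(default 3) contiguous rank bins of as-equal-as-possible size, remainders to
the nearer bins (11 electrodes → 4/4/3). Exact distance ties break by
electrode id, making the assignment deterministic; hemispheres come from the
sign of the lateral coordinate with a midline tolerance of 1e-9 coordinate
units (exact for synthetic montages, configurable). Distance-rank binning
was chosen because it reproduces equal-sized electrode blocks
deterministically; the exact electrode membership of published AoI figures
is depicted only graphically, so a rank-tercile rule may differ
electrode-by-electrode from any one laboratory's hand-drawn blocks. The
package ships a synthetic mirror-symmetric 26-electrode occipital montage
(24 lateral + 2 seeds) as a constructed stand-in, clearly labelled
synthetic; real montages are supplied as files.

Topography construction is a three-stage average: band dbWPLI of every
non-seed electrode to each seed; mean of the two seed scores per electrode;
mean per AoI. A brute-force oracle test confirms the staged average equals
the direct pair-grouped mean.

## Topographic derivations

Each participant × band × stimulus topography (6 AoI values, ordered step3L
… step3R) is **vector-normalized** — divided by its Euclidean norm, so
patterns rather than magnitudes are compared; raw AoI scores are so strongly
inter-correlated that unnormalized values are unusable as regressors. An L1
option is exposed; L2 is the default reading of "vector normalization" and
gives the testable unit-norm invariant. All-zero vectors pass through with a
warning rather than erroring: they are a legitimate degenerate measurement.

Infant occipital connectivity is strongly unilateral, so patterns are
**flipped**: if the normalized maximum lies in a left AoI the pattern is
mirrored (left/right swapped at equal steps) so every maximum sits on the
(arbitrary) right side. The flip decision uses the normalized values' global
maximum; exact left/right ties — measure zero on real data — favour no
flip, keeping the operation deterministic and idempotent. Near- and
Far-Connectivity are then the step-1 and step-3 entries on the maxima side;
step-2 is skipped to minimize crosstalk between neighbouring scalp regions.
Near/Far values default to normalized-flipped scores (raw-flipped exposed).
Right-minus-left asymmetry, by contrast, is computed on the *unflipped*
normalized topography (default step 3), since flipping destroys hemispheric
information.

## Inference layer

**Permutation tests.** Group-difference tests shuffle the full three-group
labelling (not pairwise-only shuffles) and re-extract each pair, 10,000
times by default; stimulus-difference tests swap condition labels within
participant. Empirical two-sided p-values use the add-one estimator
p = (1 + #{|perm| ≥ |obs|}) / (B + 1), which cannot return 0. The reported
effect size is d = observed mean difference / permutation-distribution SD,
matching the simulated-distribution framing in which these comparisons are
plotted; a Cohen's-d-style standardized mean difference is used for the
Wilcoxon asymmetry comparisons. FDR families default to the 6 AoIs within
one band × stimulus comparison (per-panel correction); the family definition
is configurable because the published analyses do not pin it down.

**Selection.** All 2^12 = 4,096 subsets of the 12 variables — including the
empty and full sets — are fitted by OLS and scored by 10-fold
cross-validation with 10 repeats. Out-of-fold R² is 1 − SSE/SST; by default
residuals are pooled within a repeat (every observation is held out exactly
once per repeat, so SST is the total sum of squares), with a per-fold
variant exposed; negative values are allowed. Folds are stratified by group
label when available for small-n stability. The 100 best subsets by mean CV
R² are tallied and the 5 most frequent variables selected; frequency ties
break by the mean CV R² of the top subsets containing the variable, then
lexicographically — full determinism given the seed. Covariates do not
enter the selection models; they join at the final fit, matching the
two-stage narrative of selection-then-inference (configurable).

**Final models.** OLS with intercept; per-predictor β, two-sided t-tests,
Type-II partial sums of squares (via `car::Anova`) and partial η² =
SS_effect / (SS_effect + SS_residual). Type-II SS is the default because it
reproduces the published partial-η² worked examples from the printed ANOVA
tables; sequential SS remains available through `stats::anova`. One printed
ANOVA row (the motion-laterality predictor, SS 8.37 against residual 67.68)
is not consistent with its printed partial η² of 0.15 under this formula;
the self-consistent rows are used as worked examples and the discrepancy is
documented rather than resolved. Moderation models add predictor ×
likelihood interactions; variance-partition comparisons lay Type-II SS of
nested models side by side; the nested likelihood-ratio test is
2(ℓ_full − ℓ_reduced) on χ² with df equal to the parameter difference
(cross-checked against `lmtest::lrtest`). Saturated designs (no residual df)
are refused with an informative error; ill-conditioned designs warn with the
condition number. Analyses are complete-case, with counts recorded.

For the motion-processing outcome, the same selection machinery runs with
the Global Motion Laterality Score as outcome and the final fit takes the 5
selected connectivity predictors with no covariates — sex, age and
likelihood are expected to have been regressed out of all variables first
(`residualize()`).

## The synthetic generator

`simulate_cohort()` draws a three-group cohort (default 12/28/20 —
EL-HighADOS / EL-LowADOS / LL, n = 60, mirroring the imbalance of a realistic
infant-sibling cohort), covariates (sex Bernoulli(0.5), age ≈ N(152, 7²)
days, likelihood from group), and per-participant coupling strengths.

Recordings are synthesized in the frequency domain. Each band oscillator is
a stationary Gaussian process with a raised-cosine power spectrum over the
band (0.5 Hz rolloff margins; carriers effectively at the 4 / 7 / 40 Hz band
centres) — a filtered-noise carrier with stochastic phase, not a pure
sinusoid, so epoch-wise imaginary cross-spectra have non-degenerate
statistics. A channel coupled to the seed at strength κ receives
κ·e^{−iφ} times the seed oscillator's spectral coefficients plus
√(1−κ²) of an independent oscillator (φ = π/4 by default), then unit-SD
white sensor noise. Band amplitudes (6/5/10) were set once so that per-bin
epoch SNR is of order one — strong enough that coupling is recoverable,
weak enough that estimation error is visible. Coupling declines with step
(0.45/0.35/0.30), each participant has a random dominant side with the other
side scaled by 0.45 (producing the unilateral topographies the flip step
exists for), and the EL-HighADOS group gets +0.35 on theta/non-social step-3
coupling — the planted group effect. Per-participant jitter (SD 0.08)
creates individual differences. Inattention masks are Poisson-arriving
look-away events with exponential (mean 3 s) durations at a 20% expected
masked fraction; 180 s per condition (3 × 1-min clips) and 500 Hz sampling
are the defaults.

Because the construction is linear and Gaussian, the *population* dbWPLI of
any planted coupling follows from the epoch-coefficient covariance: the
Hann-windowed DFT coefficient variance of each band process is computed
exactly from its autocovariance, and the population band score as a function
of κ is evaluated by a fixed-seed Monte-Carlo over standardized complex
Gaussian draws (30,000 draws, cached per configuration, interpolated on a κ
grid). These population scores — not κ itself — define the generator's
ground truth: true Near/Far values are the normalized-flipped population
topographies, and the outcome model is linear in them
(CSS total = 1 + 0.9·sex + 1.0·likelihood + 5·true theta/non-social Far +
N(0, 1.3²), rounded and clamped to the 0–10 integer scale; the motion score
is 0.3·standardized true gamma/social Far + N(0, 0.9²)). The slopes and
noise levels were chosen once to emulate the effect-size regime of published
infant cohorts (outcome correlations near 0.5, motion-score correlation
near 0.3) and are not adjusted thereafter.

What the generator does *not* emulate: 1/f background spectra, volume
conduction and field spread, non-Gaussian artifacts, heteroskedastic
measurement error, drifting attention, or any realistic head geometry.
Passing recovery tests therefore demonstrates the *pipeline's* correctness
under its own assumptions — unbiased dbWPLI estimation, correct averaging,
selection and inference — not robustness to the messiness of real infant
EEG.

Hierarchical seeding derives per-participant, per-condition and per-stage
streams from one master seed (31-bit arithmetic), so any single recording
can be regenerated in isolation and whole cohorts are byte-identical across
runs. Recordings are materialized lazily through `simulate_recording()` —
a full 60-infant cohort held in memory would occupy gigabytes.
`simulate_modeling_table()` is a topography-level fast path that adds
Gaussian measurement noise (SD 0.02) directly to the population AoI scores;
it exists so inference-layer studies (permutation calibration at hundreds of
replicate cohorts) do not pay for signal synthesis, and its
normalize/flip arithmetic is tested for exact agreement with the
per-topography object path.

## Problem sizes used by the validation suites

Chosen once as the package's standing configuration for a single-CPU run:

- Permutation calibration: 500 replicate null cohorts (n = 60), 2,000
  permutations each, α = 0.05; per-AoI rejection rates are required to lie
  in the 95% binomial band around 0.05.
- End-to-end recovery: 20 replicate cohorts at n = 60 with 90 s of signal
  per condition (the config default stays at the 180 s of a full session)
  and 3 CV repeats in the selection stage. The planted theta/non-social Far
  variable must be selected in ≥ 18/20 replicates and its 95% CI must cover
  the generative slope in ≥ 16/20 (the exact binomial floor for nominal 95%
  coverage over 20 draws).
- Topography invariants: a 1,000-infant battery (unit norms within 1e-12,
  maxima on the right after flipping, flip idempotence).
- dbWPLI null: 10,000 epochs of independent white noise, |dbWPLI| < 0.02 at
  every bin.

## Known limitations

- The AoI binning rule is one defensible reading of "binned Euclidean
  distance"; electrode-level membership may differ from hand-drawn blocks.
- Near/Far variables default to normalized-flipped scores; the raw-flipped
  alternative is exposed but secondary.
- The permutation effect size d is defined against the permutation SD;
  other d conventions will differ by a factor close to the group-size
  ratio.
- EDF input is not supported (no reader among the package's dependencies);
  recordings are consumed as delimited matrices with a JSON sidecar.
- Measured Far-Connectivity carries a small positive bias at very weak
  coupling (absolute values of a near-zero debiased estimator), visible in
  the recovery suite as a slight compression of the low end of the
  measured-vs-true mapping.
- Near- and Far-Connectivity of the same band × stimulus are strongly
  negatively correlated by the unit-norm constraint (r near −0.8 in
  synthetic cohorts). When both are selected, the Far coefficient's point
  estimate can move well away from its marginal value while its confidence
  interval widens accordingly — an inherent property of regressing on
  entries of a normalized pattern, and a reason the published analyses skip
  the even-more-collinear step-2 scores.
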