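---
title: "Methods: NIR calibration for extraction-process monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR calibration for extraction-process monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nirpls)
```

# Scope

`nirpls` implements the calibration workflow used to quantify flavonoids
(naringin, hesperidin, neohesperidin) in the liquor of a batch water
extraction, monitored in-line by an NIR probe: Kennard–Stone sample
partitioning, a fixed preprocessing menu, NIPALS PLS1 with PRESS-based
latent-factor selection, SiPLS and MWPLS variable selection, and
bagging-PLS ensembles. Because no public spectra exist for this process,
the package also contains a synthetic-data generator whose defaults
emulate the pilot-scale experiment: everything downstream is developed
and tested against data with a known answer.

# The regression core

## NIPALS PLS1

For a single response, NIPALS is non-iterative per component: with
mean-centered `X` (N × P) and `y`,

* weight `w_a = X'y / ||X'y||`,
* score `t_a = X w_a`,
* loadings `p_a = X' t_a / t_a't_a`, `q_a = y' t_a / t_a't_a`,
* deflation `X ← X − t_a p_a'` (the response is not deflated; for PLS1
  this changes nothing).

Assumptions: the response is linear in absorbance (Beer–Lambert mixing),
variables share units so only centering — never autoscaling — is applied;
any scaling belongs to the explicit preprocessing step. The regression
vector of the a-factor model is `b_a = W_a (P_a'W_a)^{-1} q_a`; the
package stores the whole coefficient path so every nested model predicts
without refitting.

Numerical choices: component extraction stops when `||X'y||` falls below
`1e-12` times its initial value — the effective rank is exhausted —
and `fit_pls()` treats a request beyond that rank as an error, while
cross-validation treats it as a saturated model (see below). The P'W
system is solved directly per factor count; with A ≤ 10 this is
negligible.

## Factor selection

`loo_press()` refits the model from scratch for every left-out
calibration sample and accumulates `PRESS(a) = Σ (y_i − ŷ_{−i,a})²` for
`a = 1..a_max`. The selected count is the strict global PRESS minimizer,
ties to the smaller `a`. Folds whose resample rank saturates below
`a_max` contribute their saturated prediction to larger `a` — this makes
the curve well-defined on noiseless data, where the minimum then ties
across all `a ≥` the true rank and the tie-break returns the true rank.
`a_max` defaults to 10: routine models here use 3–8 factors, so 10 gives
headroom without inviting nonsense. A parsimony alternative (smallest `a`
within a tolerance of the minimum) was considered and rejected as the
default because the strict minimum is the convention this workflow
follows; the tie-break covers the degenerate cases.

Cross-validation is leave-one-out throughout — including inside SiPLS and
MWPLS, where each candidate subset re-selects its own factor count. That
is the most expensive faithful choice; the alternative (one shared factor
count across subsets) was rejected because it systematically favors
whichever subset suits the shared count.

## Metrics

`evaluate_pipeline()` reports RMSEC/R² on the calibration fit, RMSECV/R²
from leave-one-out within the calibration set (`RMSECV =
sqrt(PRESS/N)`), and RMSEP/R² on the held-out prediction set, all in
mg/mL. The "validation set" columns of conventional result tables are
cross-validation within the 50 calibration samples, not a third subset.
An empty prediction set yields `NA` RMSEP rather than an error.

# Sample partitioning

Kennard–Stone runs in Euclidean distance on the raw spectra — the split
is fixed once, before preprocessing is compared, so every method sees
identical samples. No PCA compression is applied first. Ties (duplicate
spectra) break to the lowest sample index, making the split fully
deterministic. The default is 50 calibration / 25 prediction out of 75.

# Preprocessing menu

Eight methods are compared: RAW, SG9, SG11 (Savitzky–Golay smoothing,
order-2 polynomial), SG11+1D, SG11+2D (derivative embedded in the SG
fit, not finite differences), Normalize, MSC, SNV.

* SG polynomial order is 2, the common chemometrics default;
  configurable.
* SG edge handling fits the same polynomial to the asymmetric end
  windows, so P stays 2800 and the 20 × 140 interval bookkeeping stays
  exact.
* Derivatives are reported per grid step (per 0.5 nm); the constant
  scaling cancels in regression.
* "Normalize" means unit L2 row norm.
* SNV uses the n−1 standard deviation.
* MSC regresses each spectrum on a reference and inverts the fitted
  affine map; the reference defaults to the calibration mean spectrum and
  is frozen for prediction data — prediction never informs the model.

The workflow always runs the full 8-method comparison and carries the
RMSECV winner forward (ties go to RAW, the cheapest method). On the
synthetic fixture the winner is typically SNV or MSC, because the
fixture's dominant artefact — multiplicative scatter, including the large
bubble excursions — is exactly the distortion those transforms remove.
On real extraction data the published experience differs (raw spectra
can win); the ranking is a property of the data, which is why the
comparison is always executed rather than assumed.

# Variable selection

`make_intervals()` partitions the P variables into `n` equidistant
half-open blocks, remainder to the leading blocks; with P = 2800 and
n = 20 every block is 140 variables = 70 nm, and block 2 is the
"870–940 nm" interval. `sipls_search()` evaluates every combination of
`combo_size` intervals (C(20,3) = 1140 by default) with per-combination
LOO factor selection, ranks by RMSECV (ties break lexicographically so
results are deterministic) and reports the full ranked table plus the
full-spectrum baseline — several good joint models are worth inspecting,
not only the winner.

`mwpls_scan()` slides windows of sizes H ∈ {13, 15, …, 41} (odd sizes:
symmetric windows; any size list is accepted) across the spectrum at a
configurable stride. Stride 1 is the test-scale default; the workflow
default is 10, which changes the map resolution but rarely the best
window. Factor counts are capped at `min(a_max, H − 1)`. The scan
reports whether any window beats the full-spectrum RMSECV; on broad,
heavily overlapping NIR bands single windows typically do not.

# Bagging ensembles

`fit_bagging()` draws B bootstrap resamples (size N, with replacement)
of the calibration set and fits one PLS member per resample; predictions
aggregate by unweighted mean (median available). The member factor count
is fixed at the base model's PRESS selection on the full calibration set
— re-selecting per member is available but not default, so the ensemble
isolates the resampling effect and 500 members stay cheap. Resamples with
zero response variance are redrawn and counted. A master seed spawns
per-member seeds, so any prefix of the ensemble is stable when B changes;
the RMSEP-versus-iterations curve is prefix aggregation of one fitted
ensemble, not a refit per B. Out-of-bag RMSE is reported for diagnostics
but never used for selection — evaluation happens on the Kennard–Stone
prediction set. When SiPLS and bagging are combined, interval selection
runs once on the full calibration set and bagging resamples within it.

# The synthetic-data generator

## What it emulates

* **Design**: three sequential water extractions of one herb charge;
  per-batch sampling schedules (dense while heating to the boil — 3–5 min
  intervals — then 4–6 min over the first hour and up to 10 min over the
  last half hour) giving exactly 75 samples (32 + 24 + 19); heating
  mapped to negative times so `time_min = 0` is "reached boil".
* **Kinetics**: first-order mass transfer `C(t) = C_inf (1 − e^{−kt})`
  per batch, plateaus non-increasing across batches (the herb depletes),
  batch-level bounded-uniform jitter on plateaus (±2%) and rates (±3%).
  Defaults are calibrated so every simulated concentration stays inside
  the published reference ranges for the three flavonoids (e.g. naringin
  0.2303–2.5504 mg/mL).
* **Spectroscopy**: analyte spectra are sums of Gaussian bands placed in
  the interval blocks where interval selection localizes these compounds
  on real data (hesperidin 870–940 / 1430–1500 / 1570–1640 nm, naringin
  1290–1360 / 1570–1640 / 1640–1710 nm, neohesperidin 940–1010 /
  1290–1360 / 1640–1710 nm), a dominant water band at 1950 nm of
  constant amplitude, per-sample multiplicative scatter (0.95–1.05),
  a per-sample linear baseline, and additive Gaussian noise at 0.5% of
  the median absorbance.
* **Matrix complexity**: four unquantified interferent compounds
  (sugar-, pectin-, phenolic- and minor-flavonoid-like) with broad
  overlapping bands and their own kinetics. A crude extract is not a
  three-component system; without these the calibration problem is
  rank-4, every model is trivially stable, and ensemble methods have
  nothing to improve — with them the fixture needs 6–10 latent factors,
  like real process data.
* **Heteroscedastic artefacts**: six samples per dataset carry a large
  extra lognormal scatter excursion (log-sd 0.3) — the spectral signature
  of bubbles or particles crossing an online probe despite in-line
  filtering. These rare, large excursions are what makes single PLS fits
  genuinely unstable, and hence what gives bootstrap aggregation its
  measurable advantage on this fixture, mirroring the qualitative
  finding that motivates bagging for process monitoring.

References are the exact simulated concentrations. Reference-assay noise
was prototyped and deliberately left out: it adds comparison noise
without changing any method ranking, and it would break the exactness
contracts of the noiseless limit.

## What it does not emulate

Real flavonoid band assignments (the bands are synthetic Gaussians with
convenient placement); temperature dependence of the water band;
instrument drift across days; wavelength-registration error; nonlinear
detector response. Consequently, passing tests demonstrate algorithmic
correctness and the expected qualitative method behaviour on plausibly
structured data — not predictive performance on any real instrument.

## Determinism

Every stochastic stage takes a seed; a master seed spawns stage seeds
deterministically, the same seed reproduces a dataset bit-for-bit, and
the generator restores the caller's RNG state.

# Problem sizes used by the test suite

Structural and oracle tests run at full scale (2800 variables) where they
are cheap. Property checks over 20 seeds — interval-truth recovery and
the ensemble comparisons — run on the same experiment at a 5 nm grid
step (280 variables) with SiPLS at 10 intervals/combination size 3
inside seed loops, and at the study's C(20,3) configuration on the
canonical fixture; these sizes keep the suite fast while preserving the
spectral structure (the 20-interval blocks still span 70 nm each). The
interval-truth fixtures disable bubble events, because under strong
uncorrected scatter a scatter-reference region (the water band) is
genuinely informative and the "all signal lies in the known intervals"
premise would be false.

# Known limitations

* PLS1 only — one analyte per model; no PLS2, kernel or orthogonalized
  variants.
* Exhaustive SiPLS scales as C(n, k) model fits; n = 20, k = 3 is
  minutes of CPU, k = 4 would be ~25 minutes per analyte.
* MWPLS at stride 1 on the full grid is the slowest stage; use the
  stride option for survey scans.
* The bagging advantage measured on the fixture depends on the presence
  of influential aberrant samples; on very clean data bagging ties
  single PLS, it does not help.
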