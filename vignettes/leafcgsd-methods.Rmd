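---
title: "Leaf-color gradation skewness analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaf-color gradation skewness analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafcgsd)
```

## The problem

Canopy color responds within hours to the weather a plant experiences:
humidity, vapor pressure and temperature shift the pigment balance and the
water status of leaves, and with them the distribution of pixel intensities
in an RGB photograph of the canopy. The classical single-number summaries
(the per-channel mean) throw away most of that distributional information.
This package works with the full 0--255 intensity histogram ("gradation
array") of the foreground pixels of a background-removed canopy image, and
summarizes each of the four channels — R, G, B and the derived gray level Y
— by five statistics: mean, median, mode, skewness and kurtosis. The
resulting 20 numbers are the color gradation skewness-distribution (CGSD)
parameters of the image.

Leaf gradation histograms are strongly non-normal (skewed), which is why
mean-only summaries are lossy and why the package ships two normality tests
to demonstrate it per image. On top of the CGSD table the package builds,
in both directions, the linking models:

* **response models** — each CGSD parameter regressed on the five hourly
  meteorological factors `T_h` (air temperature, °C), `RH_h` (relative
  humidity, %), `AP_h` (atmospheric pressure, hPa), `TD_h` (dew-point
  temperature, °C) and `VP_h` (vapor pressure, hPa);
* **inversion models** — each factor regressed on the 20 CGSD parameters,
  i.e. reading the weather back off the leaves.

## Statistical conventions

**Distribution statistics.** Skewness is `m3 / m2^1.5` and kurtosis is
`m4 / m2^2` with population central moments `m_k = mean((x - xbar)^k)`;
kurtosis is non-excess (a normal distribution scores 3). These are the
MATLAB-default conventions; at the pixel counts of real images (10^5–10^6)
the bias-corrected variants differ negligibly, but a fixed convention is
required for exact testing. Mode ties break toward the smallest intensity
level; the median of an even-sized multiset is the mean of the two central
order statistics and may be half-integer. A constant channel has undefined
skewness/kurtosis, carried as `NA`, never as a crash; downstream fits drop
such samples pairwise and log the count. The histogram-weighted fast path
(`cgsd_from_gradation()`) is algebraically identical to per-pixel
summation and is tested against it to 1e-12 relative.

**Gray conversion.** `Y = round(0.2989 R + 0.5870 G + 0.1140 B)`, rounding
half away from zero — the classic `rgb2gray` luma weights, the single gray
dialect supported. Foreground is defined by the alpha channel
(`alpha > 0` by default): background-removed PNGs use hard transparency,
so any non-zero alpha is leaf.

**Normality tests.** The Jarque–Bera statistic is
`n/6 (S^2 + (K - 3)^2 / 4)` with a chi-square(2) tail. The Lilliefors test
estimates mean and SD from the data, which invalidates the classical
Kolmogorov–Smirnov null; p-values therefore come from a seeded Monte-Carlo
null (default 10^4 standard-normal replicates of the same n, exploiting
location-scale invariance of the statistic) rather than lookup tables,
which are off-table at image-scale n. The null calibration (rejection rate
≈ alpha on normal data) is itself under test.

**Stepwise regression.** Selection follows the SPSS stepwise convention:
probability-of-F to enter 0.05, to remove 0.10 (both configurable); at
each step the excluded candidate with the smallest partial-F p-value
enters if below the entry threshold, then any included predictor whose
partial-F p-value exceeds the removal threshold leaves. Candidate order
(`T_h, RH_h, AP_h, VP_h, TD_h`; CGSD parameters channel-major) breaks
ties deterministically. If nothing ever enters the result is an explicit
`unable_to_model` status — a real outcome for signal-free responses, not
an error. Reported statistics: `R2`, adjusted `R2`, RMSE interpreted as
the regression standard error `sqrt(SSE/(n-p-1))` (the "Std. Error of the
Estimate" that SPSS prints alongside adjusted R2), the overall F and its
p-value. A rank-deficient selected design raises an error naming the
collinear predictors. Forward selection with a 0.05 entry level admits a
spurious predictor in roughly `1 - 0.95^k` of pure-noise datasets with
`k` independent null candidates; tests treat that as the procedure's
documented behavior, asserting recovery of planted predictors rather than
certainty of exact-set selection.

**Prediction accuracy.** `(1 - |predicted - measured| / |measured|) × 100`
percent. The absolute value in the denominator makes the statistic
well-defined for negative responses such as skewness. Exact predictions
score 100%, a zero prediction scores 0%, relative error above 100% goes
negative. The default outlier rule flags negative accuracies; the headline
mean accuracy excludes flagged outliers (the inclusive mean is also
reported), which is the only reading under which a validation row can
coherently combine many outliers with a meaningful mean. Near-zero
measured values (|m| ≤ 1e-9) are non-computable and counted separately.

**Temperature regimes.** Samples split into a normal-temperature group
(`T1`) and a low-temperature group (`T2`) by 1-D 2-means on `T_h`,
solved exactly: sort, scan all contiguous 2-partitions, minimize the
within-cluster sum of squares. For k = 2 in one dimension the optimum is
always contiguous, so the scan is provably optimal, deterministic, and
immune to the initialization nondeterminism of Lloyd-style iterations
(which it is tested to dominate). `T0` denotes the unsplit set; per-regime
refits are plain orchestration over the same fitting code.

## The synthetic study generator

No public canopy-image/weather dataset accompanies this problem, so the
package generates its own studies with known truth. The generator is
first-class, tested code, and its defaults are the study conditions used
throughout the test suite.

**Weather.** `T_h` = mean (default 26 °C, greenhouse summer) + a per-day
synoptic offset (SD 2 °C) + a diurnal sine (amplitude 5 °C, peak 15:00) −
an optional cold-wave deficit + noise (SD 0.5 °C). `RH_h` is anti-coupled
to temperature (3 %/°C around a 75% base, noise SD 5%, clipped to
[5, 100]). `TD_h` is computed from `T_h` and `RH_h` by the Magnus
inversion (β = 17.62, λ = 243.12 °C) and `VP_h` from `TD_h` by the Magnus
saturation formula, so the generated table is physically consistent by
construction (`TD ≤ T`, `VP > 0`, exact Magnus self-consistency). `AP_h`
drifts slowly around 1005 hPa. Those Magnus relations are a convention of
the generator only: observed CSV columns are taken as-is and never
recomputed. The default design is 7 days × 5 observation hours
(7, 9, 12, 15, 18 h) = 35 images; `winter_scenario()` switches to a
12-day × 4-hour open-air winter design with a cold wave, whose bimodal
temperature marginal is what the regime classifier expects.

**Images.** Foreground pixels are drawn per channel from a scaled
Beta(α, β) on [0, 255] — bounded support matches 8-bit gradation, and the
(mean, concentration) parameterization gives independent control of
location and skewness; an unbounded family (e.g. skew-normal) would leak
past the intensity range. The planted map acts linearly on the Beta mean:
`mu_c = a_c + Σ_f b_{c,f} · f`, with defaults R: 30 + 0.3·VP_h (κ = 10);
G: 55 + 0.2·RH_h + 0.5·VP_h (κ = 8); B: 40, flat (κ = 10) — a channel with
no weather signal, so its mean is genuinely unmodelable and exercises the
`unable_to_model` path end-to-end. Y is always derived from R, G, B via
the gray conversion, never drawn. Locations that leave the Beta domain
raise an error naming the offending factor values rather than silently
saturating. Pixel noise (SD 2 intensity levels) is added before rounding;
the foreground is a centred 100×100 rectangle (10^4 pixels) inside a
120×120 transparent canvas. All randomness derives from one scenario seed
through named substreams (weather; one per image), so any stage can be
regenerated independently.

**What the generator does not emulate.** Channels are drawn independently
pixel-by-pixel: there is no spatial texture, no leaf geometry, no
inter-channel correlation, no illumination field, and no frost/snow/glare
artifacts. Passing tests therefore demonstrate correctness of the
*computation* under the assumed statistical structure — they say nothing
about segmentation quality or camera effects in real deployments.

## Identifiability of the planted factors

The physically consistent generator makes `VP_h` an exact monotone
transform of `TD_h`, and both exact (mildly nonlinear) functions of
(`T_h`, `RH_h`). Over realistic ranges the linear correlation between
`VP_h` and `TD_h` exceeds 0.99, so a stepwise selector can identify a
planted moisture effect only up to the {`VP_h`, `TD_h`} equivalence class
— whichever representative wins the first-entry F contest is
noise-determined. Recovery tests therefore assert (i) selection of the
planted factor set up to that equivalence class, (ii) recovery of the
planted response *surface* (fitted values within 0.5 intensity units of
the planted locations on average), and (iii) bootstrap-interval coverage
of the planted coefficients on the seeds where the exact planted
representation was selected. This mirrors field practice, where published
response models swap freely between vapor pressure and dew point as the
moisture regressor.

## Numerical choices and degenerate inputs

* Image-to-hour pairing: nearest record within 30 min (configurable);
  equidistant ties go to the earlier record, matching just-after-the-hour
  shooting. Unpairable images are reported, never dropped silently.
* `TD_h > T_h` in an *observed* CSV is a warning (sensor noise); in a
  synthetic table it is an error. `AP_h` outside [800, 1100] hPa warns.
* Correlation cells with a constant column are `NA` and flagged;
  undefined-moment samples are dropped pairwise per cell with `n` reported
  per cell.
* Problem sizes in the test suite (e.g. 50 recovery scenarios of 35
  images at 10^4 pixels, 200 calibration repetitions at 2 000 null
  replicates) were chosen as the smallest designs at which the asserted
  properties are statistically stable.

## Known limitations

* Only k = 2 temperature regimes; multivariate clustering over all five
  factors is out of scope.
* No multiple-testing correction across the 100 correlation cells, by
  design (the screening is descriptive).
* The accuracy statistic is undefined at measured ≈ 0 and harsh on
  near-zero responses (skewness), which is precisely why validation
  reports outlier counts alongside means.
* Naive local timestamps; no time-zone arithmetic.
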