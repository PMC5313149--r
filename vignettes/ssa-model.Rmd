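---
title: "Modelling stem-sheath angle dynamics in rice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stem-sheath angle dynamics in rice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riceSSA)
```

## The trait and the model

The stem-sheath angle (SSA) is the angle between a rice main stem and a
leaf sheath. It anchors the inclination of the whole leaf: the blade's
tangent angle relative to the stem equals SSA plus the supplement of the
sheath-blade angle (`leaf_inclination()`), so SSA is a first-order control
on canopy openness and light interception in virtual-plant and plant-type
design work.

riceSSA predicts the SSA of each main-stem leaf rank through time from
three drivers: accumulated temperature, cultivar, and plant nitrogen
status. The model is a product of four pieces:

1. **A phyllochron power law.** The main-stem leaf count grows with
   thermal time after sowing as $L = a\,TT^{\,b}$ (`leaf_count_at()`).
   Thermal time is the running sum of daily mean temperature above a base
   of 10 °C for japonica and 12 °C for indica cultivars
   (`accumulate_thermal_time()`); daily means are taken before clipping at
   the base. The SSA of leaf $n$ starts developing when leaf $n+3$
   appears; inverting the power law places the window start at
   $ITT_n = ((n+2)/a)^{1/b}$ and its length at three appearance intervals,
   $\Delta TT_n = ((n+5)/a)^{1/b} - ((n+2)/a)^{1/b}$ (`initial_tt()`,
   `ssa_window()`). One wrinkle deserves a note: the prose definition of
   the window start ("appearance of leaf $n+3$") and its formula (which
   uses $n+2$) differ by one; the package implements the formula as
   printed, the reading consistent with the power law and with the
   calibrated coefficients.

2. **A pooled logistic development curve.** On normalized thermal time
   $NTT_n = (TT - ITT_n)/\Delta TT_n$, normalized SSA follows
   $1/(1 + SSA_a e^{-SSA_b \cdot NTT_n})$ inside the window, 0 below it
   and 1 above (`normalized_ssa()`). The defaults $SSA_a = 17.62$,
   $SSA_b = 6.88$ come from pooling all cultivars and nitrogen rates
   after normalization. The curve is implemented literally, with the
   small jump discontinuities at the window edges ($1/(1+SSA_a) \approx
   0.054$ at entry, $1 - 1/(1+SSA_a e^{-SSA_b}) \approx 0.018$ at exit)
   left in place: the calibration and validation used this printed form,
   and re-scaling it to force continuity would silently change every
   simulated angle.

3. **A rank profile of plateau angles.** The plateau SSA of leaf $n$
   relative to leaf 3, $MaxSSA_n / MaxSSA_3$, is piecewise linear in
   rank: rising over ranks 1–3 ($0.1334\,n + 0.6054$), falling over 4–9
   ($-0.1345\,n + 1.3507$), maximal at rank 3 (`rank_profile_ratio()`).
   The breakpoint is fixed between ranks 3 and 4, the two segments are
   fitted independently, and no continuity is imposed at the break — the
   calibrated coefficients themselves disagree there by design. Ranks
   above 9 are rejected rather than extrapolated, because the profile was
   never calibrated beyond rank 9.

4. **A nitrogen impact factor.** The variety parameter $MMaxSSA_3$ (58.0°
   for YD6, 50.0° for W14) is the 3rd-leaf plateau under non-limiting
   nitrogen. Under deficit it is scaled by
   $FN = \min(ANCSH/MNCSH,\,1)$, the ratio of actual to critical plant N
   concentration, with the critical value from the dilution curve
   $MNCSH = 5.18\,AGB^{-0.52}$ (% of dry weight, biomass in t ha$^{-1}$;
   `nitrogen_factor()`, `critical_n_concentration()`). $FN$ is a scalar
   per scenario: the model does not time-resolve nitrogen status, so one
   (ANCSH, AGB) pair per cultivar × N-rate group is the unit of input.
   ANCSH is interpreted as a percentage, the unit under which the
   dilution-curve coefficient 5.18 is meaningful. For pot data,
   `agb_t_ha()` converts g plant$^{-1}$ × plants m$^{-2}$ to t ha$^{-1}$.

`simulate_ssa()` composes the four pieces:
$SSA_n(TT) = MMaxSSA_3 \cdot FN \cdot (MaxSSA_n/MaxSSA_3) \cdot
f(NTT_n)$.

```{r forward}
yd6 <- default_cultivars("YD6")
tt <- seq(0, 800, by = 50)
round(simulate_ssa(3, tt, yd6, fn = 1), 2)
```

## Calibration

`calibrate_ssa_model()` re-derives the logistic and rank-profile
coefficients from an observation table the same way they were originally
obtained:

- Each (cultivar, N rate, rank) group's plateau $MaxSSA_n$ is its
  maximum observed angle (`extract_max_ssa()`) — the literal definition,
  chosen over an asymptote fit. Its known cost is noise sensitivity: the
  maximum of many noisy plateau readings is biased upward, which
  compresses every normalized value in that group. When the group's
  nitrogen inputs (or plateau angles) are known, passing them as a
  `scenario` replaces the observed maximum with the model-assigned
  plateau, which is unbiased; the parameter-recovery tests use this
  route, and the observed-maximum route remains the default for field
  calibration where no such truth exists.
- Angles are divided by their plateau and thermal times converted to
  $NTT_n$, then all groups are pooled (`normalize_observations()`).
- The logistic is fitted to the pooled in-window points ($NTT \in
  [0,1]$; points outside belong to the constant branches and carry no
  shape information) by Levenberg-Marquardt least squares
  (`fit_logistic()`), started at $(A_0, B_0) = (10, 5)$ with both
  coefficients bounded below by zero — robust starting values for
  sigmoid data on the unit square.
- The rank profile is fitted segment-wise by ordinary least squares with
  the breakpoint fixed at 3|4 (`fit_rank_profile()`); the leaf-appearance
  power law by log-log regression refined in natural space
  (`fit_leaf_appearance()`), so the reported coefficients minimize
  untransformed residuals while the log-log pass provides a stable seed.

Whether groups may be pooled is checked by `group_difference_test()`: an
analysis of variance of normalized SSA on an NTT-decile bin (absorbing
the common sigmoid trend) plus the group factor. The original variance
analysis's exact design is not documented, so this layout is a labelled
stand-in; its p-values are reported, never used as a gate.

## Validation

`validate_dataset()` follows the four-step recipe: FN from the nitrogen
inputs, $MaxSSA_3$ from the variety parameter, $MaxSSA_n$ from the rank
profile, SSA from the logistic — then compares simulated with measured
angles by RRMSE, per group and pooled. Two conventions matter:

- The RRMSE normalizer is the mean measured value (the convention of the
  crop-modelling literature; the range-based alternative was rejected for
  comparability). "Pooled" means all pairs concatenated before one RRMSE
  computation, not group values averaged — and the pooled value is *not*
  generally bracketed by the group values when group means differ, a
  counterexample the test suite keeps.
- A scenario row may supply `max_ssa3` directly instead of (ANCSH, AGB),
  bypassing the nitrogen equations — the route used when validating
  against experiments whose plateau angles are reported but whose
  N-content series are not. Groups with neither input are flagged and
  excluded from the pooled statistic rather than silently dropped.

## The synthetic-data generator

`generate_dataset()` emulates the structure of the pot experiments the
model derives from: two cultivars × three nitrogen rates × leaf ranks
1–8, four tagged plants per treatment, angles recorded every other day
over a 120-day season, with multiplicative mean-zero Gaussian error of
relative SD 5 % (the measurement protocol's repeated protractor readings
carry a relative standard error under 10 %). Weather is a half-sine
seasonal course (mean 25 °C, amplitude 5 °C, day-to-day SD 1.5 °C —
a typical Yangtze-basin rice season). The default nitrogen rates are
(ANCSH %, AGB t/ha) = (2.2, 2.0), (3.1, 2.0), (3.8, 2.0), spanning FN
≈ 0.61 to 1 at a mid-tillering biomass. Noise is multiplicative rather
than additive because the protocol's error is relative; it is truncated
at ±4 SD and angles at zero, a small documented bias source.

What the generator does *not* emulate: tillering dynamics, time-resolved
nitrogen status, planting-density effects, weather extremes, or serial
correlation in measurement error. Passing round-trip and recovery tests
on this generator therefore shows the calibration machinery is correct
and stable at realistic noise, not that the model generalizes to field
conditions beyond those its original data covered.

```{r synth}
d <- generate_dataset(ssa_scenario(ranks = 2:5, replicates = 2), seed = 1)
rep <- validate_dataset(d$observations, d$truth$cultivars,
                        scenario = d$truth$scenario)
rep
```

## Numerical choices and test scales

- Nonlinear fits use numerically differenced Jacobians inside
  Levenberg-Marquardt; no analytic gradients are needed at these sizes.
- Ranks are strictly integer; non-integer or out-of-range ranks are
  errors, not warnings.
- Test problem sizes: round-trip calibration uses one noise-free
  campaign (2 cultivars × 3 N rates × ranks 1–8, one plant, ~2900
  points); the recovery study uses 20 seeds of a one-cultivar campaign
  with ≥ 150 in-window points per seed. Both complete in seconds.

## Limitations

Tiller SSA, planting-density response, sub-daily temperature response
functions and canopy light simulation are out of scope. The thermal-time
origin is sowing; for transplanted material the origin shift is not
resolved here and validation against such data should treat early-rank
windows with caution.
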