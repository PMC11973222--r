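---
title: "Particle count and the precision of PSD percentiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle count and the precision of PSD percentiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psdcount)
```

## The problem

Electron microscopy measures particles one at a time. A number-based
particle size distribution (PSD) built from N particles carries a purely
statistical uncertainty on each of its percentiles that shrinks with N —
but imaging and analyzing more particles is expensive, and beyond some
count the other uncertainty sources (specimen preparation, day-to-day
variation, calibration, bias) dominate anyway. `psdcount` quantifies both
regimes: the count-limited precision U_N(N) with its inversion to a
minimum particle count N_m, and the total uncertainty U_cx(N) with its
breakpoint N_opt.

## The subsampling model

Given a dataset of N_tot particles, a measurand (Fmin, Fmax, MICD, ECD or
AR = Fmax/Fmin) and a percentile D10–D90, the engine draws, for each N on a
grid, `reps` random subsets of size N *with replacement* and computes the
percentile of each subset. With mean D̄ and standard deviation σ (divisor
`reps − 1`) of those values,

U_N = 2 σ / D̄   (coverage factor k = 2).

Sampling with replacement treats the dataset as an empirical estimate of
the population distribution, so U_N does not artificially vanish as N
approaches N_tot; it saturates near the dataset's own information limit
(~1/√N_tot). The flip side is that at large N the estimate tracks the
*empirical* local density around the percentile, which itself fluctuates
around the population density with relative standard deviation of roughly
(N_tot · Δp)^(-1/2), Δp ≈ √(p(1−p)/N). At N = N_tot/10 this contributes
about 5 % — the resolution limit of any resampling estimate from a single
dataset, visible as a small N-correlated wobble around the asymptotic law.

Asymptotically the sampling SE of a sample quantile is
√(p(1−p)/N) / f(x_p), giving U_N ∝ N^(−1/2): a straight line with slope
−1/2 in log-log coordinates. For the lognormal median this closed form is
U_N = 2·s·√(π/2)/√N with s the log-scale parameter (`analytic_un()`
implements the general version and serves as the oracle in the tests).

### Tunable parameters

* `reps` (default 500): repetitions per grid point. The Monte-Carlo
  relative sd of σ is ≈ (2·reps)^(−1/2) ≈ 3 % at the default.
* `n_grid` (default 30 log-spaced integers from 10 to N_tot, deduplicated,
  N_tot always included): log spacing matches the log-log analysis; the
  floor of 10 is the smallest subset for which percentile estimation is at
  all meaningful.
* `seed`: a master seed from which one substream per subset size N is
  derived deterministically, so a grid can be extended without reshuffling
  the draws at existing N. Identical inputs give bit-identical curves.
* `u_target`: the precision goal, a fraction (0.10 and 0.05 being the
  conventional reporting levels).

### Numerical choices

* **Quantile convention.** All percentiles — summaries and bootstrap alike
  — use the order statistic with linear interpolation at rank
  1 + (n−1)·p (R's type 7). For n ≳ 100 the choice among mainstream
  conventions is immaterial; fixing one keeps every internal comparison
  consistent. Ties are handled by sorting, without dithering.
* **Curve fit and inversion.** N_m is obtained by default from the OLS
  line of log₁₀ U_N on log₁₀ N, which is robust to the Monte-Carlo noise
  of individual grid points: N_m = ⌈10^((log₁₀ u − b₀)/b₁)⌉. A smoothing
  spline on the same coordinates (leave-one-out CV smoothing, then an
  isotonic correction to non-increasing) is available as `method =
  "spline"`; it is more local, at the price of sensitivity to wiggles.
  Results below the grid floor are clamped to it and flagged
  `at_grid_floor`; inversions beyond N_tot are permitted but flagged
  `extrapolated`.
* **Degenerate input.** A zero-dispersion dataset gives U_N ≡ 0; the
  log-log fit is then impossible and the engine signals a numerical-error
  condition carrying the all-zero U_N vector as a diagnostic.
* **Pre-asymptotic grid points.** At the smallest N (10–30) the outer
  percentiles are interpolations between extreme order statistics; their
  spread sits measurably below the asymptotic formula. Because the default
  inversion fits the whole grid, N_m ratios between outer and central
  percentiles (the "U-shape") come out 10–15 % below their asymptotic
  values. This is a property of the procedure itself (which deliberately
  starts at N = 10), not of the implementation.

## Polydispersity scaling and categories

Since U_N scales with the dispersion of the measurand distribution, N_m
follows a power law in IQR% = 100·(D75−D25)/D50. `fit_power_law()` fits
log N_m on log IQR% (scale-free residuals, mirroring the log-log
presentation); for lognormal populations the exponent is ≈ 2, because the
log-scale parameter s = asinh(IQR%/200)/z₇₅ is nearly linear in IQR% below
80 %. `categorize()` implements the fixed guidance partitions for size
(I: IQR% ≤ 30, II: 30–55, III: 55–80, with recommended counts 35/150,
110/450, 260/1000 at U_N = 10 %/5 %) and shape (I and II only; no
published counts). Boundaries are closed above, exactly as printed; values
beyond the partition return an explicit out-of-range result rather than a
clamp, since the grouping is anchored only by the materials it was derived
from.

## The uncertainty budget and N_opt

`budget_curve()` works on a validation design: several datasets of the
same material measured on ≥ 2 days, ideally with within-day replicates.
Per subset size N and simulation draw, one subset is drawn from each
dataset and its percentile computed; a one-way variance decomposition with
day as the grouping factor yields within-day and between-day mean squares
MS_w, MS_b, combined as

u_IP = √( max(0, (MS_b − MS_w)/r̄) + MS_w ) / D̄,

with r̄ the harmonic-mean number of replicates per day — the standard
intermediate-precision ANOVA of method-validation practice (negative
between-day components are clipped to zero; with one replicate per day the
decomposition is impossible and the total spread across datasets is used).
Trueness against a certified value is the usual bias combination
u_tr = √(Δ² + u_cert² + se²)/x_cert; when no certified value exists a fixed
relative u_tr must be supplied explicitly — there is no silent default.
Calibration enters as a constant relative u_cal. All components are
averaged over `reps` simulation draws and combined as
U_cx = 2·√(u_IP² + u_tr² + u_cal²).

The breakpoint count N_opt is found by fitting a continuous two-segment
linear function to (log₁₀ N, log₁₀ U_cx): exhaustive search of the
breakpoint over interior grid abscissae, a 10× sub-grid refinement around
the best candidate, ties resolved toward the smaller N (conservative for
measurement cost). When the two-segment fit improves the single-line SSE
by less than 5 % the breakpoint is reported as unidentifiable.

## What the synthetic generator does and does not emulate

`synthetic_spec()`/`generate_particles()` produce seeded populations with
a prescribed median and IQR%: lognormal (narrow colloids), gamma and
Weibull (right-skewed powders), a two-component lognormal mixture
(multimodal powders; parameterized by weight and separation, so its IQR%
matches the target only loosely), and rods (lognormal width, lognormal
aspect ratio ≥ 1, MICD = width, ECD from the spherocylinder projected-area
model A = W(L−W) + πW²/4 — any consistent convex-projection convention
would do, and this one is documented). For gamma and Weibull the shape
parameter is solved numerically so the population IQR% is exact; for the
lognormal the closed form s = asinh(IQR%/200)/z₇₅ is used. A validation
design adds a multiplicative lognormal between-day factor with prescribed
CV (multiplicative, so sizes stay positive; mean 1) and a global
multiplicative bias; the realized day factors are attached as attributes,
because with few days the realized spread is a wide chi-square draw and
ground-truth checks must compare against what was actually planted.

The generator emulates distribution *shapes* only. It does not emulate
image segmentation artefacts (erroneous particle merging that broadens
real distributions), magnification effects, detection limits, or
correlations between measurands beyond the built-in width–length coupling
of rods. Passing tests therefore demonstrate the statistical machinery on
known ground truth — not that any real material follows these families.

## Problem sizes used in the tests

The test suite exercises the study-scale configuration — populations of
20000 particles with 500 repetitions per grid point — for the acceptance
properties, and smaller configurations (2000–10000 particles, 100–300
repetitions) for unit-level checks; the budget checks use a 3-days ×
2-replicates design of 20000-particle datasets with a 3 % day effect and a
2 % bias. These sizes give Monte-Carlo noise of a few percent on U_N,
comfortably below the tolerances being asserted, while keeping the full
suite fast.

## Known limitations

* U_N ignores, by construction, every uncertainty source other than the
  count; regulatory use needs the full budget (that is the point of
  U_cx/N_opt).
* The empirical-density fluctuation described above limits the agreement
  between resampled U_N and the population asymptotics to ≈ 5–15 % at
  N ≳ N_tot/10, however many repetitions are used.
* The intermediate-precision and trueness estimators are the standard
  one-way-ANOVA and CRM-bias combinations; laboratories with their own
  validation methodology may differ in detail.
* Sampling bias and image-analysis bias are not modelled; rods and plates
  with preferential orientation on the grid are outside the model.
* With 2–3 days, between-day variance components are intrinsically
  imprecise; N_opt inherits that imprecision (factor ~2).
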