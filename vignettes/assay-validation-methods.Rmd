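---
title: "Methods: stability-indicating assay validation and degradation kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability-indicating assay validation and degradation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siaval)
```

## Scope and model

`siaval` implements the computational side of validating a
stability-indicating chromatographic assay (the statistics an ICH
Q2(R1)-style validation reports) and of the chemical-kinetics study such an
assay enables.  The package operates on integrated peak tables — it never
touches raw detector traces; peak integration, column chemistry and vendor
peak-purity algorithms are out of scope.

The measurement model throughout is a straight-line calibration

$$y = a + b\,x + \varepsilon, \qquad
\operatorname{sd}(\varepsilon \mid x) = \sqrt{(c_v\,\mu(x))^2 + s_0^2},$$

where $y$ is a peak area, $x$ a concentration in µg/mL, and the error
spread grows with the mean response $\mu(x)$: chromatographic responses
over a range spanning more than two orders of magnitude are almost never
homoscedastic.  Whether weighting is needed is decided by a variance-ratio
test, and the weight itself ($w = 1$, $1/x$, $1/x^2$) is selected from the
data.

## Deciding between ordinary and weighted least squares

`homoscedasticity_test()` compares the sample variances of the replicate
responses at the two extreme calibration levels,
$F_\mathrm{cal} = s^2_\mathrm{high} / s^2_\mathrm{low}$, against the F
quantile at $1-\alpha$ with $(n_\mathrm{high}-1,\, n_\mathrm{low}-1)$
degrees of freedom.  The default $\alpha = 0.01$ mirrors the conventional
$F_{2,2,0.99} = 99.0$ criterion for triplicate designs.  Note the test is
deliberately crude — two groups, extreme levels only — because that is the
form used in bioanalytical practice; with triplicates it has low power,
which is why the ratio must be enormous (it typically is: proportional
noise across a 250-fold range gives variance ratios of order $10^4$–$10^5$)
before weighting is adopted.

## Selecting the weighting factor

For each candidate weight the package refits the line and back-calculates
every calibration point, $\hat x = (y - a)/b$, scoring the scheme by
$\sum |\%RE|$ with $\%RE = 100(\hat x - x)/x$.  The smallest sum wins;
exact ties (which arise only on noiseless data) go to the simplest scheme.

Two conventions exist for *which* fit the %RE is computed from:

* **replicate-wise** (default): each replication curve — one point per
  level — is fitted separately per scheme, and the sum runs over all
  points under their own replication's fit.  This mirrors replicated
  calibration tables in which slope, intercept, $r^2$ and $\sum|\%RE|$
  are reported per replication.
* **pooled** (`per_replicate = FALSE`): a single fit on all points.

The replicate-wise convention discriminates far better at small designs.
On the default synthetic design (6 levels over 0.10–25 µg/mL, triplicate,
2% proportional noise) it selects $1/x^2$ in essentially every seeded
draw, whereas the pooled fit averages away the low-level shot noise that
separates $1/x$ from $1/x^2$ and picks $1/x^2$ in only roughly four
draws out of five.  That difference is why the replicate-wise form is
the default.

A known limitation of the $\sum|\%RE|$ criterion — worth stating plainly —
is its structural bias toward stronger weighting: the $1/x^2$ fit nearly
interpolates the lowest-level points, driving the dominant low-level %RE
terms toward zero *whatever* the true noise structure.  Under purely
additive (homoscedastic) noise the criterion therefore still tends to
choose $1/x$ or $1/x^2$ rather than the unit weight that is optimal in the
least-squares sense.  The criterion is implemented as the field uses it;
it should be read as "protects relative accuracy at the low end", not as a
consistent estimator of the variance function.  The homoscedasticity test,
not the %RE scan, is the gatekeeper for whether weighting is applied at
all.

## Linearity diagnostics

* `lack_of_fit()` decomposes the residual sum of squares of the fitted
  line into lack-of-fit (level means about the line, $df = L - 2$) and
  pure error (replicates about level means, $df = n - L$), in the fit's
  weight metric, and compares $F = MS_\mathrm{LOF}/MS_\mathrm{PE}$ to the
  F quantile at $1-\alpha$ (default $\alpha = 0.05$).  Noiseless inputs
  make both components vanish to rounding error; they are treated as zero
  below $10^{-12}$ of the response's weighted sum of squares.
* `regression_anova()` reports the regression F statistic and two-sided t
  tests of slope and intercept at 95% confidence, from the weighted
  least-squares covariance.  A valid calibration has $p_\mathrm{slope} <
  0.05$ and $p_\mathrm{intercept} > 0.05$.  Fits with essentially zero
  residual variance are flagged `degenerate` rather than reported with
  meaningless t statistics.
* `back_calc_table()` attaches the conventional acceptance bands: ±20%
  %RE at the lowest level (the quantitation limit) and ±15% elsewhere,
  with $r^2 \ge 0.995$ checked by the pipeline.

$r^2$ for weighted fits is computed on weighted residuals about the
weighted mean response — a convention choice the data cannot decide; it
reduces to the ordinary $r^2$ under unit weights.

## Detection and quantitation limits

The limits are signal-to-noise based.  `estimate_noise()` measures the
blank either peak-to-peak (default) or as rms; `signal_to_noise()` then
uses the pharmacopoeial form $S/N = 2H/h$ for peak-to-peak noise $h$ and
$S/N = H/h_\mathrm{rms}$ otherwise.  Published S/N values from vendor
software are accepted as inputs wherever recomputation from a blank trace
is impossible.  Acceptance follows the usual thresholds: mean $S/N \ge 3$
and response %CV < 15 at the LOD; $S/N \ge 10$, mean recovery within
80–110% and %CV < 15 at the LOQ.  The curve-based alternative
($3.3\sigma/S$, $10\sigma/S$) is deliberately not implemented.

## System suitability and stress bookkeeping

USP conventions are adopted for the column-efficiency metrics, since
vendor software rarely documents its formulas: $N = 5.54 (t_R/w_{1/2})^2$,
$T = W_{0.05}/(2f)$, $R_s = 2(t_{R2}-t_{R1})/(w_1+w_2)$ (baseline widths;
half-height form available).  Default limits: injection %CV < 2%, $T < 2$,
$N > 2000$, $R_s > 2$.  When a peak table carries no width columns the
instrument-reported tailing/plates columns are used as given.
Forced-degradation arithmetic is a pass-through,
$100 \cdot \text{stressed}/\text{control}$; values above 100% (response
drift) are reported unclamped.

## Degradation kinetics

`fit_order()` fits the transformed concentration ($C$, $\ln C$, $1/C$) on
time by ordinary least squares; the order is chosen by the highest mean
$r^2$ across replicates on the transformed scale (ties to the lower
order), matching the graphical order-selection method.  Points at or
below zero concentration are dropped with a warning before log/reciprocal
transforms (an `on_nonpositive = "error"` mode exists); no imputation.

Replicate aggregation follows the per-replicate convention: each
replicate is fitted separately, and both $k$ and $t_{1/2}$ are averaged
across replicates.  Because $t_{1/2} = \ln 2/k$ is convex in $k$, Jensen's
inequality makes $\overline{t_{1/2}} \ge \ln 2/\bar k$; e.g. replicate
rate constants (0.040, 0.045, 0.050) h⁻¹ give
$\overline{t_{1/2}} = 15.53$ h versus $\ln 2/\bar k = 15.40$ h.  Reported
half-lives that exceed $\ln 2/\bar k$ are therefore a signature of
per-replicate averaging, not an error.

## The synthetic-data generator

`gen_calibration()`, `gen_decay()`, `gen_suitability()` and `gen_blank()`
produce every input the pipeline consumes, deterministically given a
single integer seed (each fixture kind draws from its own named
substream, so adding fixtures never perturbs existing ones).  Defaults
encode the study conditions the package is exercised under:

* calibration: levels 0.10, 1, 3, 8, 15, 25 µg/mL, triplicate, slope
  7000 area units per µg/mL, intercept −60, 2% proportional Gaussian
  noise.  The proportional-dominant choice reproduces both the observed
  per-level %CV (≈2–3%) and the order of magnitude (~10⁵) of the
  extreme-level variance ratio; selection frequencies proved insensitive
  to adding a small additive floor (0–20 area units), so the simpler
  purely proportional default is kept.
* decay: $C_0 = 5$ µg/mL, first order, $k = 0.045$ h⁻¹ (a stomach-pH
  buffer-stability rate), 13 time points over 0–24 h, triplicate, 2%
  proportional noise.
* suitability: five injections, $t_R \approx 2.43$ min with 0.15% CV,
  area ≈ 56,000 with 0.3% CV, and an exponentially modified Gaussian
  peak ($\sigma = 0.0214$ min, $\tau = 0.004$ min) whose sampled trace
  yields measured half-height/5%-height widths — so tailing factors and
  plate counts have a numerical ground truth near $T \approx 1.1$,
  $N \approx 13{,}000$.

Noise is Gaussian (no error distribution is implied by peak tables);
non-positive draws are resampled, not clipped, so log transforms stay
valid.  What the generator does *not* emulate: retention-time drift
correlated across injections, integration errors, carry-over, day-to-day
slope changes, or non-Gaussian outliers.  Tests passing on synthetic data
therefore demonstrate the correctness of the statistics, not robustness
of the assay to those real-world effects.

## Numerical choices and degenerate inputs

* Sample ($n-1$) standard deviations everywhere; %CV is undefined (and
  flagged, not infinite) at zero mean.
* Full precision internally; rounding is applied only when rendering
  reports (2 d.p. for %CV, 3 d.p. for concentrations).
* Acceptance bounds are inclusive ("in the range of 80–110%" admits both
  endpoints).
* $x = 0$ is not a calibration point (weights $1/x$, $1/x^2$ would be
  undefined); blanks feed noise estimation instead.
* Zero variance in the homoscedasticity denominator, constant blanks,
  single-replicate levels and zero-residual fits each yield a flagged
  result rather than an error or an infinity.

Problem sizes in the test suite are desk-scale throughout: Monte-Carlo
checks use 50–200 seeded repetitions of the default designs (18-point
calibrations, 39-point decay experiments), which keeps the full suite
under half a minute on one core while holding the binomial error of a
95%-frequency check near one percentage point.

## Reproducible worked example

```{r example}
cal <- gen_calibration(calibration_sim_spec(seed = 7))
lv <- range(cal$conc)
homoscedasticity_test(cal$response[cal$conc == lv[1]],
                      cal$response[cal$conc == lv[2]])
sel <- select_weighting(cal)
sel$chosen
tcs <- gen_decay(decay_sim_spec(seed = 7))
select_order(tcs)
```
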