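---
title: "Methods: from scene stacks to phenometric products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from scene stacks to phenometric products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoscope)
```

## Scope and model

`phenoscope` estimates land surface phenology (LSP) per pixel from a dense
but irregular record of 4-band surface-reflectance scenes over a fixed
square site window. The underlying signal model is simple: each pixel's
two-band Enhanced Vegetation Index,

$$\mathrm{EVI2} = \frac{2.5\,(\rho_{NIR} - \rho_{Red})}
                       {\rho_{NIR} + 2.4\,\rho_{Red} + 1},$$

follows a smooth seasonal trajectory that sits on a stable dormant-season
floor (the *background*), interrupted by observation noise, data gaps,
cloud/shadow/haze contamination flagged by per-pixel masks, snow
excursions, and occasional strongly negative spikes. The pipeline's job is
to recover the smooth trajectory, segment it into growth cycles, and read
timing and greenness metrics off the reconstruction.

Assumptions worth making explicit:

* Geolocation error across scenes is non-systematic and small relative to
  the pixel, so same-day scenes can be averaged per pixel without
  co-registration.
* Contamination is either flagged by the provider masks (snow, shadow,
  haze, cloud) or detectable as single-date outliers; multi-week biased
  stretches (e.g. unflagged thin cirrus) are not modelled.
* Dormant-season reflectance is stationary enough across the record that a
  single background per pixel is meaningful.

## Ingest rules

Scenes are retained when catalogue metadata says standard quality, cloud
cover at most 0.5 (boundary inclusive), and ground control present. Per
pixel, a value survives only if the unusable-data mask is 0 **and** the
usable-data mask is non-zero. All surviving scenes sharing an acquisition
date are averaged per pixel and band — the mean is taken over reflectance,
and the index is computed afterwards, because the masks and the averaging
semantics are defined on reflectance; the index of a mean is not the mean
of indices, and doing it in this order keeps the composite independent of
scene ordering. The window is then split into equal rectangular tiles
(default 200). Only the tile count and area are fixed by the product
design; the rows-by-columns factorization is chosen automatically as the
feasible pair with aspect closest to the window's (10 × 20 for the default
square grid), and any equal-area factorization gives identical products —
tile independence is a tested invariant.

## Series conditioning

Screening is a *pure classification pass*: it recomputes per-observation
statuses from the raw values and the snow-mask channel, which makes it
idempotent by construction. Rules, in order:

* negative EVI2 → `negative`;
* snow-mask flag → `snow`;
* spike: deviation from the median of the ±15-day window exceeding
  `max(0.1, 0.3 × local range)` with both immediate neighbours on the same
  side. The same-side condition keeps genuinely rapid transitions (both
  neighbours straddle a real ramp) while removing single-date islands.

The background is the 10th percentile of the snow-free, non-spike,
non-negative observations, with linear interpolation between order
statistics (R quantile type 7). The percentile convention and the decision
to pool the whole multi-year record (rather than computing one background
per year) are deliberate: a single floor stabilises winters with few clear
observations, at the cost of blurring slow multi-year baseline drift.

Observations below the background are raised to it, and screened-out dates
(snow, spike, negative) are *re-admitted at the background value* rather
than dropped. Without re-admission, a snow-rich winter contributes no
observations at all and the spline is unsupported for months; with it, the
dormant season is anchored at the floor the data themselves established.

Gap-filling uses a penalized cubic smoothing spline
(`stats::smooth.spline`), the standard penalized-regression-spline
formulation with the penalty chosen per pixel by generalized
cross-validation. Two guards matter in production: a configurable lower
bound on the smoothing parameter (`spar_low`, default −0.5) prevents the
GCV criterion from chasing serially correlated noise into a wiggly
interpolant, and a fixed `lambda` or `spar` can override GCV entirely for
reproducibility studies. A pixel needs at least 10 usable observations
spanning at least a year; otherwise it carries the insufficient-data
signal that becomes QA class 4 and fill values downstream. The daily fit
is floored at the background, so the reconstruction never undershoots the
dormant floor between support points.

When the record stops early in the final calendar year (the production
analogue stops at January 31), observations from February–June of the last
full year are copied one year forward before fitting. This gives the final
target year post-season support; the copied winter/spring is a stationarity
assumption, and metrics late in the final year inherit it.

## Cycle detection

Local peaks are days that are maxima of their ±15-day neighbourhood, with
plateau ties broken to the earliest day and record endpoints excluded.
Peaks are assessed once each, in descending peak value, so dominant
seasons constrain subordinate ones; this makes the recursion order
deterministic without a tie-break table.

For a candidate peak, the greenup-side minimum is the series minimum
between the later of (record start, peak − 185 days, previous accepted
peak + 30 days) and the peak; the greendown side mirrors it. The candidate
is accepted when the rise from the flanking minimum is at least 0.1 EVI2
and at least 35% of the total series range over the 24-month window
centred on the peak's calendar year (January 1 − 183 days through
December 31 + 182 days). The amplitude criteria are enforced on **both**
flanks. Applying them on the greenup side only — a plausible reading of
the prose — turns out to be fragile: a GCV spline leaves millimetre-scale
wiggles on a broad summer plateau, and two wiggle crests more than 30 days
apart each see the full seasonal rise on their greenup side, so a single
season double-counts. Requiring the descending flank to satisfy the same
criteria removes exactly these artefacts (the descending amplitude of a
plateau wiggle is the wiggle height, not the season height) while leaving
genuine consecutive cycles — which descend to a real trough between peaks
— untouched. Cycle ranking and the `EVIamp` layer still use the
greenup-side amplitude.

Cycles are assigned to a target year by their peak date (the peak layer's
valid range of 1–366 anchors the year; the other timing layers may run
negative or past 366). Up to two cycles per year are reported, largest
amplitudes first; the full count is recorded and clamped to the product's
0–6 range only at encoding.

The choice of the *smoothed* daily series (not raw observations) for the
24-month range in the 35% criterion keeps the criterion commensurate with
the amplitudes it is compared against, which are also read off the fit.

## Phenometrics and QA

Greenup crossings are the first days at or above 15% / 50% / 90% of the
greenup amplitude above the greenup minimum, searched from cycle start to
peak; greendown crossings are the first days at or below 90% / 50% / 15%
of the descending amplitude above the greendown minimum, searched from
peak to cycle end. Referencing each side to its own minimum reconciles the
two ways the thresholds are commonly phrased (percent greenness increase
vs. percent decrease) and guarantees the crossings exist for any accepted
cycle. First-crossing-wins is the tie-break; together with integer day
grids it makes every timing metric deterministic. The ordering
OGI ≤ 50PCGI ≤ OGMx ≤ Peak ≤ OGD ≤ 50PCGD ≤ OGMn then holds by
construction and is re-checked property-style in the tests.

`EVIarea` sums the daily fitted EVI2 from the greenup-onset day through
the dormancy day inclusive; since the fit is background-floored, the sum
is bounded below by span × background. For zero-cycle pixels the annual
triple (max, range, sum over the calendar year) and `numObs` are still
reported.

QA per reported cycle: within each phase (start→peak, peak→end) compute
the Pearson correlation between clear observations and the fit at the
observation dates, and the longest gap between consecutive clear
observations. No violation in any phase → 1; exactly one of
{correlation ≤ 0.75 anywhere, gap ≥ 30 days anywhere} → 2; both → 3; no
cycle or fewer than 3 clear observations in a phase → 4. The published
class definitions overlap at the boundary (the moderate class is phrased
with *or*, the low class with *and*); "exactly one violation = 2, two
violations = 3" is the only partition consistent with both phrasings. A
zero-variance segment has no defined correlation and is counted as a
correlation violation — conservative, since a flat observed segment
carries no evidence the fit tracks the data.

## Product encoding

The 24 layers are stored as 16-bit signed integers: physical value divided
by the layer scale factor (1, 0.01, or 0.0001), rounded half away from
zero, checked against the published valid range (out-of-range → fill, with
a log entry), fill value 32767 — the maximum of the int16 range, which is
why 16-bit signed is the storage width. The QA layers are total functions
into {1,…,4} and carry no fill; a missing cycle is QA 4. Decoding inverts
within half a quantum, and encoding is monotone within each layer; both
are tested. Files are classic-model netCDF, one per site and year, with
scale/valid-range/fill attributes on every variable and the layer schema
also shipped as machine-readable JSON (`inst/extdata/product_layers.json`).

The site window is a square box gridded at the pixel size; the box side
must divide evenly, so at the native 3 m pixel the default side is 9999 m
rather than the nominal 10 km — the largest 3 m multiple not exceeding it.
Grids at coarser pixels (50 m → 200 × 200, or 1–2.5 km in the examples)
are used throughout the tests so full-stack runs finish in seconds; the
native 3333 × 3333 grid is supported but not exercised in routine testing.

## The synthetic generator

Ground truth is a double-logistic bump per cycle on a constant baseline:
greenup and greendown sigmoids sharing a plateau, with per-cycle midpoint
days, rates, and amplitude. Its value is that every threshold crossing is
available *independently of the pipeline* by root-finding on the
continuous curve (`truth_cycle_metrics()`), so recovery tests compare
against analytic truth, not against the implementation. Four families
cover the behaviours that matter: single broad seasons, two seasons per
year, many short cycles per year (the harvest-and-regrow pattern), flat
arid-like series, and a snow-heavy winter variant.

The generator emulates: irregular acquisition with random gaps, Gaussian
radiometric noise on the index, strongly negative single-date spikes,
snow excursions flagged in a mask channel, multiple same-day scenes with
overlapping partial footprints, and band values back-solved from the
target index so the downstream index computation reproduces truth plus
noise exactly. It does **not** emulate radiometric cross-calibration
differences between satellites, geolocation error, BRDF or topographic
effects, or spatially correlated cloud fields — so passing recovery tests
demonstrate algorithmic correctness under the stated noise model, not
robustness to sensor artefacts absent from the model. Mean revisit and
contamination rates are configurable; the defaults (observation every 1–3
days, a few percent spikes and snow) are plausible for a dense CubeSat
record but are not calibrated against any real catalogue.

## Numerical choices and degenerate inputs

* Acceptance comparisons use a 10⁻⁹ tolerance so that equality cases in
  the amplitude criteria ("at least") are decided inclusively under
  floating point.
* Plateau peaks collapse to their earliest day; a fully flat window yields
  no peak; constant series yield zero cycles and the annual metrics.
* Same-day duplicate observations are averaged before spline fitting.
* Insufficient data (fewer than 10 usable observations, under a year of
  span, or a daily series not covering the target year ± 180 days) is a
  value, not an error: `NULL` daily series, QA 4, fill-coded layers.
* Encoding rounds half away from zero, documented because R's default
  `round()` rounds half to even.

## Test problem sizes

The shipped suites run the full stack on 10 × 10 to 16 × 16 pixel windows
with 2–3-day acquisition cadence over 2.5–3 years, 500-pixel Monte-Carlo
recovery batteries, and 200-seed detector-versus-enumerator sweeps; these
sizes were chosen so the whole suite completes in about a minute while
still exercising every rule at realistic record lengths. The same code
paths scale to the native grid by changing `pixel_size` and `n_tiles`
only.

## Known limitations

* Only the mask channel identifies snow; there is no reflectance-based
  snow fallback when masks are absent.
* At most two cycles per year are reported, so crops with three or more
  harvests are represented by their two largest cycles plus the cycle
  count.
* The 30-day minimum peak separation suppresses very short consecutive
  cycles.
* A single whole-record background cannot follow slow baseline drift
  (e.g. succession or land-use change within the record).
* Scene serialization uses plain TIFF plus a JSON sidecar for
  georeferencing rather than GeoTIFF tags; in-memory scene objects are the
  primary interface.
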