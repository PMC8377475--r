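---
title: "Gray-value profiling of forming tree rings: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gray-value profiling of forming tree rings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xylotomo)
```

## The measurement model

X-ray CT gray values are linearly related to the density of the scanned
material. A forming tree ring, viewed as a radial profile of mean *cell-wall*
gray value (one value per tangential slice), is two-phased:

* **Cambial zone**: primary-walled cells only, so cell-wall density is at its
  minimum; density rises on both sides of the cambium as phloem- and
  xylem-side walls differentiate, making the cambium a local minimum.
* **Maturing xylem**: secondary-wall deposition and lignification raise
  cell-wall density monotonically with distance from the cambium.
* **Mature xylem**: the wall is complete; basic wall density varies in a
  narrow band (~1.4–1.5 g/cm³) across species and time, so the profile is
  constant from the transition out past the previous ring boundary.

Both landmarks the package measures are therefore *flatness* features: the
cambium is the centre of the flat valley bottom, the maturing→mature
transition is where the rising profile first becomes flat. "Flat" is
operationalized statistically: fit a penalized spline, and call a stretch
constant where the pointwise 95% confidence interval of the fitted
*derivative* contains zero. One wording of this rule in the source material
is internally contradictory (it describes constancy yet parenthesizes
"significantly different from 0"); this package adopts the constancy
reading, which is the only one consistent with the two-phase model and with
looking for plateaus.

## The spline engine

The smoother is a classic P-spline: cubic B-splines on equally spaced knots,
an order-`penalty_order` difference penalty on the coefficients, smoothing
parameter chosen by GCV on a fixed logarithmic grid, coefficient covariance
`σ²(B'B + λP)⁻¹`, and delta-method pointwise bands for the derivative
(`level = 0.95` by default; a simulation mode drawing coefficients from
`N(β̂, V_b)` is available behind a seed, for users who prefer
posterior-simulation bands — the two agree closely in practice and the
analytic band is deterministic, hence the default).

Two numerical floors matter:

* `find_constant_runs()` adds `zero_tol · max|f̂′|` (default `zero_tol =
  1e-3`) plus a machine-scale term to the containment test, so effectively
  noise-free profiles — where the band has zero width and the near-
  interpolating fit leaves geometric ripple around corners — still classify
  plateau points as constant. With any realistic noise the band width
  dominates and the floor is irrelevant.
* Monotone fits verify nondecrease on a dense grid with tolerance
  `−1e-8 × range(y)`.

**Defaults**: `basis_dim = min(20, n/2)`, `penalty_order = 2` for the general
engine. Two use sites deliberately override them:

* **Boundary detection** (`detect_cambium()`, `detect_transition()`) fits
  with a *first-order* penalty and a dense basis (`n/2`, capped at 200). The
  first-difference penalty shrinks the fit toward local constancy — exactly
  the hypothesis class of the plateau detector — and localizes the corner
  far better than the curvature penalty, whose smooth fits keep a
  significantly positive derivative tens of micrometres past the true
  transition.
* **Seasonal fits** (`fit_seasonal_curve()`) use `basis_dim = 12` for the
  typical 18-date season: enough flexibility to track a logistic to <1%
  noise-free, while keeping the early-season 5% crossing stable under
  measurement noise (a more flexible basis inflates the tail of `tb` errors).

## Monotone seasonal curves

Ring increment and mature-xylem width can only grow within a season, so
seasonal curves are fitted with a monotone-increasing shape constraint. For
B-splines, nondecreasing coefficients suffice for a nondecreasing curve, so
the constraint is the linear system `βⱼ₊₁ ≥ βⱼ` and the penalized
least-squares problem is solved exactly as a quadratic program
(`quadprog::solve.QP`), with λ taken from the unconstrained GCV fit. The
coefficient covariance reported for a constrained fit is the unconstrained
one — an approximation, acceptable because no inference is drawn from
seasonal-fit bands. Parametric growth curves (Gompertz and kin) are a
non-goal: on series like these they are known to fit poorly, which is what
motivates the data-driven monotone spline in the first place.

## Boundary detection choices

* The cambium window and the previous ring boundary are **manual
  annotations**. Automating them is out of scope; field practice marks the
  boundary on a reference image and brackets the cambium generously.
* `min_run_length` defaults to 5 grid points or 25 µm, whichever is larger —
  single-point zero crossings of the derivative band are inflection
  artifacts, not plateaus.
* Cambium = **median** position of the constant run at the valley minimum;
  with an even run the bark-ward central point is taken, so early-season
  estimates err conservative. If several runs occur, the one containing the
  minimum fitted value wins (an interpretation: the source procedure never
  specifies multi-run behavior).
* Transition = bark-ward ("left") edge of the constant run closest to the
  cambium, **refined** by a two-segment broken-stick fit of the smoothed
  curve around the raw edge. The raw CI-based edge is structurally biased
  pith-ward: the band must first lose significance, which happens a few
  resolution elements past the corner the smoother has rounded. The rounding
  is symmetric, so the broken-stick breakpoint — the centre of the rounding —
  removes the bias (measured: from ~15–20 µm to ~2–4 µm median error at 1%
  noise). `refine = FALSE` returns the raw edge.
* A constant run that **touches distance 0** from the cambium is the flat
  cambial zone itself, not mature xylem, and is skipped — unless it spans
  essentially the whole ring, which is the legitimate end-of-season case
  (fully mature ring, transition at 0, `w_maturing = 0`). Without this rule
  the locally flat density minimum would masquerade as an instant
  transition.
* If no constant run exists at all, the ring is still entirely maturing:
  `no_plateau` is flagged and `w_maturing = w_incr` (hence `w_mat = 0`).

Widths always satisfy `w_maturing + w_mat = w_incr` bit-exactly, because
`w_incr` is re-derived as the sum after detection.

## Profile extraction

Pass 1 (sample vs background) thresholds per stack: the sample/air contrast
does not change along the radius, and a per-stack threshold keeps the
profile comparable across slices. Because a whole stack's pooled histogram
is trimodal (air, lumens/primary walls, bright mature walls), the pass-1
threshold is the *lower* split of a two-threshold (three-class) Otsu;
single-threshold Otsu can latch onto the wall/lumen split instead and blank
out the cambial region. Holes (lumens) are filled by border-connected
flood fill, so the sample mask covers material *and* enclosed air.

Pass 2 (walls vs lumens) thresholds **per slice**: wall/lumen contrast rises
from nil at the cambium (primary walls are barely denser than the lumen
signal) to strong in mature xylem. A global wall threshold discards every
slice whose walls fall below it — half the maturing zone; a per-slice Otsu
adapts, and in the degenerate near-cambium case (walls ≈ lumens) any split
still yields the correct mean. Both thresholds can be overridden.

Slices whose masks come up empty are recorded as missing (NA), never as
zero; a stack with more than 50% missing slices is rejected.

## Phenology definitions

* Correction for circumferential heterogeneity: each width is multiplied by
  its sample's previous-year ring width relative to the tree mean,
  `w_cor = w_obs · w_prev / mean(w_prev)` — microcores from different stem
  positions sample different local growth rates, and `w_prev` is the
  observable proxy.
* Final width = median prediction at the last three sampling dates (the
  increment has stabilized by then; the median absorbs residual
  heterogeneity).
* `tb`/`te` = first day the daily-grid predictions reach 5%/95% of the final
  width, with linear interpolation between integer days (sub-day precision
  without pretending model support; whole-day and interpolated definitions
  agree to ±1 day). A tree that never reaches 95% keeps `te` at the last
  sampling day with an explicit censoring flag — no extrapolation.
* `d_xylo = te_mat − tb_incr`: xylogenesis opens when size growth begins and
  closes when the last-formed cells mature. (One printed formula in the
  source duplicates the size-growth duration instead; its own figure caption
  and prose define the span implemented here, and the duplicate is treated
  as a typo.)
* Species summaries are medians over trees; durations are computed per tree
  and then summarized.

## Biomass proxy and lags

`b_trunk` is the raw sum of the xylem-profile gray values across the forming
ring (cambium to previous boundary) — linear in density, arbitrary units; no
gray→density calibration is attempted. Completion curves divide each daily
prediction by its own late-season median, and the lag curve evaluates, at
each fraction f ∈ {0, 0.01, …, 1}, the day each process first reaches f
(interpolated). A fraction below the curve's first observed value means the
crossing predates the observation window: the lag is undefined there (NA)
and excluded from the mean/max summaries, rather than clamped to the first
day — clamping would fabricate a zero lag. Peak-rate timing takes the
earliest day attaining the maximum daily rate; when the near-maximum stretch
(within 1% of the peak) spans more than 7 days the peak is ambiguous and
flagged — ring-porous species with fast, flat early-season growth make this
matter.

## Method comparison

Major-axis regression treats both methods as error-prone; the slope comes
from the first eigenvector of the 2×2 covariance (closed form), the slope CI
from Jolicoeur's rotation interval, and the intercept CI is projected
through the centroid from the slope limits. With four trees per species the
CIs are very wide; they are reported as-is, never suppressed. Flags: fixed
bias if 0 lies outside the intercept CI, proportional bias if 1 lies outside
the slope CI.

The case bootstrap resamples trees, not residuals. The null construction is
not specified in the source; the default pools both groups and redraws two
groups of the original sizes, a `centered` variant recentres each group at
its own median and resamples within groups. A calibration study (500
simulated null datasets, 4 cases per group) shows the pooled scheme is
*conservative* for median differences at this group size (fraction of
ASL ≤ 0.05 ≈ 0.01), while the centered scheme is near-nominal (≈ 0.07).
Pooled remains the default — conservatism is the safe direction when
claiming method differences — and both are exposed. A further caution from
exhaustive enumeration: with fully separated tiny groups (four 0s vs four
10s) the pooled ASL is 2·(5/16)² ≈ 0.195, not "significant"; medians of four
draws are too discrete for extreme ASLs. The seed is a required argument; no
hidden RNG state.

## What the synthetic generator does and does not emulate

The generator states a world and keeps it fixed:

* **Profiles**: flat valley bottom (half-width 40 µm) centred on the
  cambium; linear rise reaching the plateau exactly at the transition;
  constant plateau; phloem-side mirror rise saturating at 60% of the span;
  primary-wall floor at `lumen + 0.15·(plateau − lumen)`; additive Gaussian
  noise; 16-bit range; 2.49 µm voxel pitch.
* **Stacks**: wall/lumen lattice (8 px cell period, 2 px walls) inside a
  background margin, walls carrying the radial curve, lumens at the air-like
  lumen gray. Real anatomy (vessels, rays, resin ducts, cracks), beam
  hardening, ring artifacts and phase-contrast effects are *not* simulated —
  green tests certify the measurement chain on clean two-phase signals, not
  robustness to anatomical heterogeneity, which field use handles by ROI
  choice.
* **Seasons**: per-tree logistic growth (default: 4 trees, 18 biweekly dates
  from DOY 75, asymptotes 0.9–1.4 mm, midpoints DOY 155–175, 20-day time
  scale, mature width at 95% of the increment asymptote lagging 25 days,
  biomass lagging 15 days, measurement noise 3% of the asymptote — a
  mid-range value for biweekly microcore series; noise draws are clamped at
  zero width, which slightly biases very early dates upward, as real
  measurements also cannot be negative). True critical dates are computed
  inside the generator by dense evaluation of the noise-free sigmoid, so
  recovery tests have an oracle that never touches the estimation path.

## Known limitations

* Detection resolution is set by the spline's knot spacing and the noise
  level; below ~1 voxel pitch the broken-stick refinement, not the CI rule,
  carries the precision.
* The cambium window is trusted: a window missing the density minimum fails
  loudly but cannot be auto-recovered.
* Monotone-fit uncertainty is approximated by the unconstrained covariance.
* `b_trunk` is an uncalibrated proxy; cross-scanner comparisons need a
  density phantom.
* The TIFF reader/writer covers exactly the uncompressed single-strip
  grayscale subset the package writes.
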