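---
title: "Depth-resolved cortical maturation trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved cortical maturation trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Primate cortex matures along two spatial gradients: a surface gradient from
sensorimotor to association cortex (the S-A axis), and a laminar,
"inside-out" gradient from deep to superficial cortical depths. The
T1w/T2w MRI ratio — a myelin-sensitive but arbitrary-unit measure — can
track both, provided three methodological ingredients are in place:

1. **Equi-volume depth sampling**, so that a "depth bin" means the same
   tissue fraction in gyral crowns and sulcal fundi;
2. **A hierarchy axis** covering the whole cortex, here the geodesic
   distance along the surface mesh from association (default-mode-like)
   seed regions, used directly or aligned with an external S-A ranking;
3. **Trajectory models** flexible enough for monotone saturating growth
   but constrained enough not to overfit small developmental cohorts:
   penalized-spline GAMs with a rank-3 age smooth, REML smoothness
   selection, a sex covariate and (for longitudinal designs) subject
   random intercepts, summarized by signed partial R², derivative
   simultaneous bands, and plateau ages.

`laminardev` implements this full pipeline and, because the motivating
cohorts are access-restricted, ships a synthetic cortical generator with
known ground truth so every stage is testable offline.

# Equi-volume depth binning

A cortical column is modeled with local area varying *linearly* from
`A_in` (white/inner boundary) to `A_out` (pial/outer boundary) across
normalized depth $\rho \in [0,1]$ — the standard local approximation for
equi-volume layering. The depth enclosing volume fraction $\alpha$ solves
a quadratic and has the closed form

$$\rho(\alpha) = \frac{-A_{in} + \sqrt{\alpha A_{out}^2 + (1-\alpha) A_{in}^2}}{A_{out} - A_{in}},$$

with $\rho = \alpha$ used whenever $|A_{out}-A_{in}| < 10^{-9}\max(A_{in},A_{out})$
to avoid catastrophic cancellation. When the outer boundary is wider
(gyral crown), volume accumulates slowly near the inner boundary and
equal-volume surfaces sit *deeper* ($\rho > \alpha$); the sulcal case is the
mirror image. Two binning configurations are provided: 6 equal-volume
bins (adult depth profiles), and 7 bins trimmed to the middle 5
(developmental analyses), dropping the bins most exposed to white-matter
and extra-cerebral contamination. The linear-taper model is an
approximation: on a spherical shell with area $\propto r^2$ (radii
0.8–1.0) its 6-bin boundaries deviate from the exact equal-shell-volume
radii by less than 0.005 depth fraction, a bound asserted in the tests
rather than hidden.

# Hierarchy axis

Geodesic distance is computed as shortest paths on the mesh edge graph
(Dijkstra, Euclidean edge weights) from seed vertices — the cited
approximation to exact surface geodesics. On icospheres the edge-graph
path overestimates the great-circle distance by a factor ≤ 1.2 that is
stable under mesh refinement; tests document it. Seeds are chosen by
k-means clustering of the association-region vertex coordinates,
retaining a random 10% of clusters and taking each cluster's
centroid-nearest member (the construction detail is unstated in the
source; coordinates and nearest-member are this package's choices, and
the number of clusters is always echoed into metadata because only the
10% fraction is stated). Parcel scores are vertex means; tripartition
sorts parcels and cuts near-equal thirds (sizes differ by ≤ 1, remainder
to the earlier groups, ties by parcel id). Orientation is explicit
everywhere: geodesic distance from association seeds *increases* toward
sensorimotor cortex, while S-A ranks run the other way, so the pipeline
carries a normalized rank (0 = sensorimotor, 1 = association) for all
regressions along the axis.

# Ratio calibration

T1w/T2w units are arbitrary, so values are calibrated by a two-point
affine map sending each subject's reference pair (ventricle-like low,
white-matter-like high) onto the group-averaged pair. The functional
form is not stated in the source; the affine map is the minimal form
consistent with two reference structures and is recorded in metadata.
Calibration leaves cross-parcel correlations untouched and reproduces
the group references exactly. The synthetic generator exercises this
end-to-end: it draws per-subject scanner gains and offsets, emits raw
values plus reference columns, and the pipeline's calibration stage
recovers the calibrated values to machine precision.

# Trajectory model

For each (parcel, depth bin) cell the model is

$$y_{ij} = \beta_0 + \beta_{sex}\,\mathrm{male}_i + f(a_{ij}) + b_i + \varepsilon_{ij},$$

with $f$ a rank-3 smooth (one unpenalized linear direction, one
penalized curvature direction, realized as orthogonal polynomials — at
this rank the difference from thin-plate or cubic bases is numerically
negligible, and unpenalized the basis reproduces any quadratic exactly),
$b_i$ optional subject random intercepts handled as a second penalized
block, and smoothing parameters maximizing the Gaussian REML criterion
on a log10 grid over $[-8, 8]$ (21 points) refined by golden-section
search (coordinate-wise when the random-intercept block is present).
Fits agree with `mgcv::gam(..., method = "REML")` on shared data to
within numerical tolerance; that agreement is a test, not an assumption.

**Age significance.** The default test is the Wald-type chi-squared
statistic $\hat\beta_f^\top V_f^{-1} \hat\beta_f$ over the age block,
with the Bayesian covariance at the selected smoothing parameter and the
block's testing degrees of freedom $2\,\mathrm{tr}(F) - \mathrm{tr}(FF)$
— the construction recommended for penalized smooths. The classical
nested-model deviance comparison (scaled RSS drop against a chi-squared
with the edf difference) is retained as `method = "deviance"` but runs
2–4 percentage points anti-conservative under smoothing-parameter
selection: in this package's flat-truth calibration world (n = 200,
σ = 0.05) the deviance test rejects at ~0.08–0.09, `mgcv::anova.gam`
at ~0.073, and the default Wald test at 0.065 (10,000-rep estimate). That measurement is the reason the Wald form is the default.

**Effect size.** Signed partial R² is
$(RSS_{red} - RSS_{full})/RSS_{red}$ clipped to $[0,1]$, signed by the
grid-mean first derivative of the fitted smooth; it is invariant to
affine rescaling of the response.

**Derivative band.** The first derivative is estimated by central finite
differences of the fitted smooth on a uniform 100-point grid (one-sided
at the ends), with a simultaneous 95% band built from 10,000 posterior
coefficient draws: the critical multiplier is the 0.95 quantile of the
maximum standardized absolute deviation over the grid. The draws are
multivariate t rather than Gaussian — each is scaled by an
inverse-chi-square factor on the residual degrees of freedom — because
with purely Gaussian draws the flat-truth false-exclusion rate measured
0.066–0.072, straddling its 7% calibration bound; propagating the
residual-variance uncertainty brings it to 0.064–0.070. The band is
deterministic under a recorded seed.

**Plateau age.** All maximal grid windows where the band excludes zero
are reported, two-sided, each tagged with its sign. The *plateau age* is
the upper end of the last window of significantly **positive**
derivative, declared only when that window ends strictly before the
final grid point; growth still significant at the oldest observed age is
right-censored. The positive-sign qualification matters: a rank-3 smooth
fitted to a strongly saturating trajectory necessarily bends downward
late (a quadratic-like artifact), and with realistic noise that spurious
decline is statistically significant — under a literal two-sided rule
every fast-maturing region would be censored by its own lack-of-fit
artifact, which both contradicts the observable (growth has stopped) and
would make plateau recovery on saturating truths impossible. Plateau
timing comparisons exclude censored cells and always report the
censoring fraction beside the ANOVA.

**Multiplicity.** Benjamini–Hochberg q-values are computed across
parcels within one species × depth-bin family (the family is unstated in
the source; the choice is recorded in result attributes).

# Synthetic ground truth

The generator states a world, then the pipeline is asked to recover it.
Each (parcel, depth) cell follows a saturating exponential
$T(a) = B + A(1 - e^{-r(a - a_0)})$ for $a \ge a_0$ — the simplest
monotone curve with a closed-form plateau age
$a_0 + \log(Ar/\delta)/r$, where $\delta$ (default $\sigma/5$ per year)
is the derivative threshold defining "flat". Measurement noise is
Gaussian, sex is an additive shift, longitudinal designs add one
Gaussian intercept per subject, and a single seed governs sexes, ages,
intercepts, scanner gains, and noise in a documented draw order.

The structured truth encodes the designed gradients: rate and amplitude
decrease from sensorimotor to association cortex and from deep to
superficial bins, the depth contrast itself weakens along the axis, and
onsets shift later toward association cortex. Numerical scales were
fixed once, at design time, by two representability constraints rather
than by tuning against test outcomes:

* the **human-like window** (ages 5.5–36 y, n = 200 cross-sectional,
  σ = 0.05) uses base rates 0.14 → 0.025 /y and amplitudes 0.65 → 0.50
  along the axis, so sensorimotor growth saturates and plateaus inside
  the window while association growth, nearly linear over the window,
  remains *detectably* positive at age 36 and is right-censored — the
  reported human phenomenology;
* the **macaque-like window** (ages 1–36 mo, 33 subjects × 5 visits, one
  with 4, subject intercept sd 0.08) uses base rates 2.0 → 0.8 /y, so
  even association cortex saturates within 3 years and plateaus are
  detected nearly everywhere. The implied macaque:human rate ratio
  (roughly 8:1) exceeds the conventional 4:1 developmental scaling
  because the human observation window begins mid-childhood, after the
  fastest growth, while the macaque window covers infancy.

A first parameterization violated these constraints (human association
fell just below detectability at 36 y, macaque association stayed
significant at 36 mo) and inverted the designed species contrast; the
recalibration above is documented here precisely because the generator's
defaults *are* the stated world. What a green end-to-end test
establishes is that the pipeline recovers a qualitative structure that
the stated world actually contains — not that real cortical data behave
this way; the generator has no spatial noise correlation, no
heteroscedasticity across depth, no age-dependent variance, and no
missingness.

# Numerical choices and degenerate inputs

* Flat-limit switch for equi-volume placement at relative area
  difference $10^{-9}$; closed form verified against numeric volume
  inversion to $10^{-7}$ over random geometries.
* REML grid log10 λ ∈ [−8, 8], 21 points, golden-section refinement to
  $10^{-3}$; random-intercept block on a 13-point [−6, 6] grid with two
  coordinate passes.
* Perfect-fit degeneracies (zero residual variance) are handled
  explicitly: derivative bands use a symmetric eigenvalue square root
  that tolerates zero covariance, and the Wald test falls back to exact
  0/1 p-values.
* Ties: k-means cluster seeds and graph-Voronoi parcel assignment break
  ties toward the lower index; tripartition breaks score ties by parcel
  id; best-overlap mapping breaks ties toward the smaller target id with
  a warning.
* Depths outside a trimmed binning's retained interval are `NA` by
  design (the trimmed bins deliberately discard those samples).

# Known limitations

* Exact polyhedral geodesics (MMP-style) are out of scope; the contract
  is graph-shortest-path, and the documented detour factor (~1.16 on
  icospheres) would bias absolute distances, not parcel rankings.
* The rank-3 smooth cannot represent sharp saturation; plateau ages
  inherit a late bias of a few years relative to the δ-threshold truth
  (rank order is preserved — tested at Spearman ≥ 0.8).
* ANOVA units are parcels, ignoring spatial autocorrelation between
  neighboring parcels; flagged in the report metadata.
* The deviance-based age test is retained for comparability but is
  anti-conservative; the default Wald test is the calibrated choice.
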