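---
title: "Models and estimators in ClusTrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators in ClusTrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClusTrack)
```

ClusTrack quantifies the plasma-membrane dynamics of a photoactivatable
single-molecule recording of a clustered membrane transporter (the
motivating system is GLUT4 in adipocytes). This vignette is the package's
account of the science: the generative model its simulator encodes, the
estimators built on top of it, the numerical and design choices that were
genuinely open, and what the passing tests do and do not establish about
real data.

## The physical picture

A photoconverted transporter molecule in the plasma membrane does one of
three things. It diffuses freely in 2D (D ≈ 0.09 µm²/s); it is captured
by a nanoscale cluster — an elongated domain of roughly 170 × 90 nm —
inside which it stays confined while still moving; or it disappears: by
photobleaching, by lateral dissociation back to the free pool, or, from
clusters, by endocytic internalization. Exocytic fusion of ~50 nm storage
vesicles feeds the system, either dispersing its cargo as monomers or
retaining it as a new cluster. Each arrow in this scheme is a first-order
rate, and the package's purpose is to recover those rates, the cluster
geometry, and the motion classes from movies.

## The simulator and what it emulates

`simulateTrajectories()` is the reference implementation of the model
above and the source of ground truth for every recovery test.

* **Free motion.** Per-coordinate Gaussian steps of variance 2·D·t_int;
  reflecting field edges.
* **Clusters.** Ellipses planted at the configured density with mean
  diameters 170 × 90 nm (30 nm spread, axes floored at 60/40 nm so no
  degenerate domain is generated). Captured molecules diffuse with a
  reflecting boundary at the ellipse. Reflection is enforced on Brownian
  substeps kept small relative to the minor semi-axis (radial folding in
  ellipse-aligned coordinates), which makes the stationary intra-cluster
  distribution uniform — the property the confinement and morphology
  estimators rest on. In `simulateConfinedTracks()` the substep scale is
  R/5, which reproduces E[r²] = R²/2 to a percent; inside
  `simulateTrajectories()` the substep count is capped at 64 because only
  membership and residency, not fine intra-cluster geometry, feed
  downstream analysis there.
* **Association.** Two modes. `"spatial"`: capture with probability
  `pCapture` (default 1 — a collision leading to immediate confinement is
  the simplest consistent reading) upon geometric entry into an ellipse.
  `"rate"` (preset default): free molecules are captured at a first-order
  hazard K_a and bound to the nearest cluster. The presets set K_a by
  detailed balance, K_a = K_d·f/(1−f) with f the condition's stationary
  clustered fraction (0.48 basal, 0.27 insulin), which gives
  K_a ≈ 0.11 min⁻¹ for both conditions — consistent with the
  experimentally reported association rate — and holds the clustered
  fraction stationary when removal is state-blind.
* **Disappearance.** Per-frame hazards applied in the order bleach →
  endocytosis (clustered only) → dissociation. Bleaching acts only over
  the illuminated fraction of each frame (rate K_b·t_exp per frame), which
  is what makes the relative exposure p = t_exp/t_int the lever of the
  kinetic decomposition. At the rates in question (≪ 1 per frame) the
  ordering is numerically irrelevant; it is fixed and documented for
  reproducibility.
* **Observation model.** Localizations are true positions plus independent
  Gaussian noise per coordinate (σ = 30 nm per axis; the per-axis reading
  is chosen because the morphology correction subtracts σ² from
  per-axis covariance eigenvalues). Blinking switches a molecule dark for
  truncated-geometric runs of at most 3 frames — matching the tracker's
  gap rule — with the switch frame counting as the first dark frame.
* **Dwell sampling.** `simulateDwellTimes()` bypasses space entirely:
  dwells are minima of competing exponential clocks (p·K_b, K_d, K_e),
  frame-quantized and right-censored at the end of acquisition. This is
  the generator behind the kinetics recovery targets, at a fraction of
  the spatial simulator's cost.

Default geometry mirrors the experimental protocols: 10 × 10 µm field,
160 nm pixels, 200 ms exposure, frame intervals of 0.2/0.5/1/2 s
(p = 1.0/0.4/0.2/0.1), bleaching 2 min⁻¹ at p = 1 (not experimentally
printed; chosen so bleaching dominates disappearance at full exposure,
which is the regime that makes extrapolation necessary; configurable).

What the simulator does **not** emulate: spectral photophysics beyond a
single photoconvert/blink/bleach channel, 3D motion, stage drift, directed
vesicle transport (an optional overlay in principle, off in
plasma-membrane presets), and spatially structured backgrounds. Passing
recovery tests therefore demonstrate estimator correctness under the
stated model, not robustness to drift, heterogeneous optics, or
non-Markovian binding.

## Motion classification

`computeMSD()` is the time-averaged MSD over all ordered pairs at each
integer lag, with pair counts kept for weighting; pairs spanning blink
gaps enter at their true lag. `fitLinearMSD()` fits MSD(t) = 4Dt + C by
weighted least squares over the first 4 lags (default): localization
noise surfaces as C = 4σ², and fitting deep into the curve would trade
confinement bias against variance. Negative D estimates are reported with
a warning rather than clamped so estimator bias stays measurable.

`buildEnvelope()` simulates ≥100 (default 1000) pure random walks matched
in length and noise, conditioned on one global D (the population average,
not per-track estimates, which would be circular), and takes per-lag
empirical 2.5/97.5% quantiles of the individual time-averaged MSD curves.
A trajectory is `directed` if its MSD exceeds the upper bound for at
least 5 consecutive lags, `confined` if below the lower bound for as
long, `free` otherwise. The consecutive-run reading of the rule is
adopted (it is the more specific of the two published phrasings) and the
run length is configurable.

One numerical choice matters here: classification uses lags only up to a
quarter of the track length (floor; minimum 6). Time-averaged MSD values
at lags comparable to the track length rest on a handful of displacement
pairs and are almost perfectly correlated between neighbouring lags, so a
single tail excursion masquerades as a sustained run; with all lags
included the free-specificity of the classifier drops from ~97.5% to
~91%. The quarter-length range is the standard MSD practice and is set
before any fitting.

`estimateConfinementSize()` inverts the disc plateau: for positions
independently uniform over a disc of radius R, E|x₁−x₂|² = R², so
diameter = 2·√(plateau − 4σ²), with the plateau averaged over lags beyond
the knee (first lag with MSD < half the free-diffusion line) and the
noise floor subtracted in quadrature; a plateau below the noise floor
clamps to zero with a warning and a flag. The disc model is one
defensible reading of estimating size "from the amplitude of MSD
fluctuations"; it recovers 60–240 nm domains within 15% at σ = 30 nm.

## Cluster morphology

Clusters are defined by residency, not image segmentation: a region is
declared where one molecule's consecutive localizations stay within a
125 nm radius (half the diffraction limit) of their running centroid for
at least 30 frames — far longer than free diffusion at 0.09 µm²/s could
linger. Runs tolerate up to 3 consecutive out-of-radius localizations,
mirroring the tracker's loss rule: with 30 nm noise, single positions of
a genuinely resident molecule in a 170 nm cluster regularly fall outside
the radius, and a strict rule would split long residencies. Overlapping
runs from different molecules merge into one region.

`fitEllipse()` uses the uniform-ellipse second-moment convention: the
positional variance of a uniform filled ellipse along a semi-axis a is
a²/4, so semi-axes are 2·√(eigenvalue). Localization scatter adds σ² to
each eigenvalue; the correction subtracts it in quadrature before
conversion (the mechanics of "corrected for localization uncertainty" are
not published; quadrature subtraction is the moment-exact choice under
independent Gaussian noise). Eigenvalues driven negative clamp to zero
with a warning. Degenerate (collinear) point sets are flagged.

`circularity()` returns 4πA/P², which normalizes a circle to exactly 1
(the alternative πA/P² form that also circulates fails that normalization
and is not used). For polygons, shoelace area and polygonal perimeter;
for reconstructed point sets, the boundary is an occupancy outline —
points rasterized at 10 nm, closed with a 50 nm disc probe, hole-filled —
measured with EBImage's shape features. The probe radius is a knob: finer
probes chase localization scatter and depress circularity, which is
exactly the regime in which reconstructed clusters report mean
circularities far below the smooth-ellipse value of ~0.86.

A caveat documented rather than hidden: end-to-end (residency-defined)
cluster reconstructions underestimate large axes somewhat, because the
125 nm grouping radius truncates the tails of the position distribution.
The geometry recovery target therefore feeds the estimator positions
drawn directly from the generating ellipses, isolating the
moment-inversion step; the end-to-end pipeline reports what it measures.

## Dwell-time kinetics

A dwell runs from a molecule's first localization inside a cluster region
to the last before an absence (or sustained departure) of **more than
three consecutive frames**; molecules resident at the end of acquisition
are censored. `fitDisappearanceRate()` defaults to the histogram method —
dwell durations binned at the frame interval, single exponential fitted —
implemented as a Poisson log-linear GLM over the *full* bin range
including empty bins. The naive alternative, least squares on log counts
of nonzero bins, silently discards the empty tail and underestimates the
rate by tens of percent; the GLM is the maximum-likelihood exponential
fit of the histogram and is exact in expectation for frame-quantized
(geometric) data. Standard errors come from a seeded bootstrap over
records (default 500). The censored-exponential MLE (with half-frame
midpoint correction) is offered as the strictly more efficient
alternative that also uses censored records; the histogram method stays
the default because it is the published procedure. Censored records are
excluded from the histogram fit, and exclusion counts are retained on the
records object.

`decomposeRates()` fits K against p by weighted least squares per branch
(weights 1/SE²), independently per branch by default with a pooled-slope
option (whether the original branches shared a bleaching slope is not
stated). The endocytosis-off intercept is K_d; the intercept difference
is K_e; slopes estimate K_b. Negative rate estimates are clamped to zero
with a warning. On noiseless linear inputs the decomposition is exact to
machine precision. Under the reference conditions — 2000 dwells per
protocol, four protocols per branch — the K_d estimator is unbiased with
a standard deviation near 0.009 min⁻¹; individual runs can land ~2 sd
from truth, which is the intrinsic information content of those
conditions, not an estimator defect.

`estimateAssociationRate()` always reports both circulating conventions,
labelled: `printed` (K_d·f_free/f_clustered) and `detailed_balance`
(K_d·f_clustered/f_free, the form under which K_a[free] = K_d[clustered]).
They differ whenever the pools are unequal, and for the insulin condition
the two differ by almost an order of magnitude; neither is silently
"corrected". `flattenedVesicleDiameter()` encodes the area-conservation
model of cluster nucleation: a sphere's surface πD² equals a flat disc's
¼πD²_cluster, so D_cluster = 2·D_GSV (100 nm for a 50 nm vesicle),
consistent with the measured cluster scale.

One genuine inconsistency in the source literature is left unreconciled
by design: the printed closed form for the evanescent-field intensity
ratio of the 405/488 nm beams evaluates neither to its own printed
magnitude (~1.6) nor to what the underlying decay law
I(z) = I₀·exp(−z/δ(λ)), δ ∝ λ, actually gives (exp(λ_b/λ_a − 1) ≈ 1.23 at
z = δ(488)). `evanescentRatio()` implements the decay law itself; the
>12-fold activation selectivity observed at 100 nm is empirical and no
generative model for it is attempted.

## Localization, linking, fusion

`localizeFrame()` assumes the sparse photoactivation regime
(0.01–0.1 µm⁻²): local maxima above threshold, pixel-integrated 2D
Gaussian least squares on a window, pairs closer than one PSF FWHM
merged, uncertainties from the Thompson photon-limited formula with
pixelation and background terms. Coordinates are continuous nm with the
origin at the top-left corner of pixel (0,0) and 0-based frames — stated
in every CSV header. `detectBleachSteps()` is a binary-segmentation
change-point search with a BIC-style penalty; exactly one downward step
to background validates single-molecule identity. `linkTrajectories()` is
greedy nearest-neighbour in order of increasing distance (which resolves
conflicts in favour of the closer pair), bridging gaps of up to 3 frames;
it was chosen over global assignment as adequate at these densities and
simple to verify, and identity swaps during close encounters are the
known, measured cost (track purity degrades before fragmentation does).

`detectFlashes()` finds reporter transients ≥5 robust sds above a rolling
10-frame mean baseline; `classifyFusion()` traces the molecule channel in
a 1 µm-radius disc. The windows are calibrated on the synthetic data, not
published values: monomers at ~0.09 µm²/s need 10–20 s to clear a 1 µm
disc, so dispersal is a decay below 40% of the plateau elevation within
20 s, retention is persistence above 60% for 30 s, and the dispersal
delay is timed on a 300 nm central disc, which empties within a frame or
two of true departure. Everything else is ambiguous — deliberately, since
an event that is neither is not evidence for either mode. The generator
enforces ≥2.5 µm between fusion sites; overlapping analysis ROIs on real
crowded recordings will raise the ambiguous rate.

## Reproducibility and problem sizes

All randomness flows from explicit integer seeds; the pipeline derives
per-stage substreams from one root seed, so stages rerun independently
yet bit-identically. The test suite and the acceptance script run on
deliberately modest problem sizes — hundreds of trajectories, thousands
of dwells, hundreds of clusters — chosen so each recovery target's
sampling error sits comfortably inside its stated tolerance; the
estimators themselves are O(n) to O(n²) in track length and scale to
much larger recordings.

## Known limitations

* Whole-trajectory classification only; no state-switching segmentation
  within a track, so a trajectory that is half free, half confined is
  assigned one label.
* Whether the published pooled D was fitted per trajectory and averaged
  or fitted on the pooled curve is unknown; the pooled-curve fit is the
  default here and the two differ slightly under heterogeneity.
* Rate-based association binds a molecule to its nearest cluster
  instantaneously — a kinetic emulation, adequate for occupancy and dwell
  statistics, not for spatial approach trajectories; use the spatial mode
  when entry dynamics matter.
* The residency definition needs activated molecules: clusters never
  visited by a photoconverted molecule are invisible, so region counts
  estimate visited clusters, not all clusters.
* The intensity-based clustered fraction assumes the diffuse pool
  dominates the image median; fields dense with puncta bias it low.
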