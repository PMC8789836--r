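---
title: "Counting DSB foci along ion tracks: model, calibration and dose"
author: "irifdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting DSB foci along ion tracks: model, calibration and dose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irifdose)
```

## The problem

A cell traversed by a high-LET ion (lithium, carbon, ...) accumulates DNA
double-strand breaks (DSBs) densely along the ion's path. Repair proteins
accumulate at each break and become visible as ionizing-radiation-induced
foci (IRIF) in fluorescence microscopy. Counting foci per unit track length
— the linear IRIF density (LID) — carries information about the ion's linear
energy transfer (LET, keV/µm), and together with the particle fluence read
off the same images it yields the absorbed dose,

$$ D = \frac{F \cdot \mathrm{LET}}{\rho}, $$

with $F$ in µm⁻², LET in keV/µm and $\rho$ the density of water
(1000 kg/m³); in these units $D = 0.1602\,F\cdot\mathrm{LET}$ Gy.

The catch is the finite focus size. A marker that decorates a focus of size
$d$ cannot separate two DSBs closer than $d$, so the measured LID
underestimates the DSB density more and more as LET grows. The package
models this saturation explicitly: DSB positions are grouped into clusters
using the measured focus size as the linkage distance, and the resulting
linear cluster density (LCD) versus LET curve — monotone but bending —
is inverted to estimate LET from a measured LID. Two focus sizes matter in
practice: about 140 nm for pDNA-PKcs foci and about 600 nm for the
conventional 53BP1 marker; the smaller marker stays informative up to much
higher LET.

## The track simulator

No public code reproduces the full Monte-Carlo track-structure machinery
that would predict DSB coordinates from first principles, so the package
ships a deliberately minimal generator whose outputs have the few properties
the clustering analysis actually consumes:

* the nucleus is a sphere (default diameter 10 µm, 6.6 Gbp DNA) irradiated
  by a parallel beam from an 80 µm² circular source tangential to it; the
  chord for impact parameter $b$ is $2\sqrt{R^2-b^2}$, and impact points
  beyond the nuclear radius give zero-chord tracks (misses);
* DSB counts along a chord are Poisson with linear density
  $\lambda(\mathrm{LET}) = k \cdot \mathrm{LET}$. The default yield
  coefficient $k = 0.0375$ µm⁻¹/(keV µm⁻¹) is pinned by the
  track-recognition convention that 0.3 DSB/µm corresponds to 8 keV/µm;
* each DSB is displaced perpendicular to the track axis by an isotropic
  Gaussian of scale 20 nm (configurable). This stands in for the radial dose
  penumbra; the clustering result is insensitive to its exact shape as long
  as it is small compared to the cluster sizes studied;
* tracks carry a single LET — no slowing down along the chord.

What the generator does **not** emulate: strand-level chemistry, chromatin
structure, LET-dependent radial broadening, DSB mobility and repair
kinetics, or ion-species differences at fixed LET. Tests passing on this
generator therefore validate the *analysis chain* (clustering, calibration,
inversion, dosimetry, image operations), not the biophysics of any
particular ion. Quantities tied to the detailed track structure — e.g. the
plateau LCD values or the exact LET caps of a production calibration — will
differ from those obtained with a full transport code, and the package
reports rather than asserts them.

## Clustering and densities

Clusters are connected components of the proximity graph that joins every
DSB pair at distance $\le d$ (single linkage at a fixed cut; ties at exactly
$d$ merge). This is implemented as a union-find sweep along the widest axis
in C++, and is checked in the tests against a brute-force
breadth-first-search oracle on random instances. Chains may grow beyond $d$
in extent; the rule is purely local, matching how one focus "absorbs" every
DSB within reach of any of its members.

The effective track length is the distance between the farthermost DSB
pair. Tracks with fewer than two DSBs have no measurable span and are
assigned a fixed mean track length of 7.6 µm, the same fallback used when a
measured track shows a single focus.

Per-track densities are LDD = n_DSB/length and LCD = n_clusters/length. For
ensemble summaries the package pools before dividing:

$$ \widehat{\mathrm{LCD}} = \frac{\sum_i C_i}{\sum_i L_i}. $$

This choice is deliberate. The mean of per-track ratios is dominated by
rare tracks whose few DSBs happen to lie close together (the ratio $C/L$
has a log-divergent tail as the span shrinks), which would corrupt the
low-LET end of the calibration exactly where the detection limit lives. The
pooled ratio is the clusters-per-micrometer rate the assay actually means,
is stable at every LET, and converges to the closed form
$\lambda e^{-\lambda d}$ for long zero-scatter tracks — the analytic
benchmark used in the tests. Per-track ratios are still computed and kept:
their pointwise 16th/84th percentiles form the calibration band.

## The calibration curve

`build_calibration()` takes per-track densities at a set of LET knots
(defaults: 15 knots from 2 to 240 keV/µm, at least 50 tracks per knot;
production builds use 500) and constructs:

* the central curve: pooled LCD per knot, made non-decreasing by isotonic
  regression and interpolated by a monotone Fritsch–Carlson piecewise cubic.
  A shape-preserving interpolant was chosen over a smoothing B-spline
  because the inverse prediction needs guaranteed monotonicity and freedom
  from overshoot, and because ensembles of hundreds of tracks per knot make
  additional smoothing unnecessary. Outside the knot range the curve is held
  constant rather than extrapolated;
* the 68% band: pointwise 16th/84th percentiles of the per-track LCD,
  linearly interpolated between knots — "contains 68% of the data points"
  without any normality assumption;
* a detection limit: the smallest LET where the central curve reaches
  0.3 µm⁻¹ (three separable foci in a 10 µm nucleus — below that a
  traversal cannot be recognised as a track). Solving
  $k\,\mathrm{LET}\,e^{-k\,\mathrm{LET}\,d} = 0.3$ gives ≈ 8.4 keV/µm for
  the defaults; the simulated value lands slightly lower (≈ 7) because on
  micrometer-scale chords the pooled rate carries a small positive edge
  term. Both are consistent with the conventional ≥ 10 keV/µm definition of
  high-LET radiation;
* a saturation limit: the largest grid LET at which the knot-to-knot slope
  is still at least 10% (configurable) of the initial slope. For the 140 nm
  cluster size the analytic density maximum sits at
  $\lambda = 1/d$, i.e. LET $\approx 1/(kd) \approx 190$ keV/µm, and the
  reported limit always stays below it; 600 nm clusters saturate far
  earlier, which is the quantitative reason the small marker is the better
  high-LET dosimeter.

`estimate_let()` inverts the central curve by leftmost-crossing bisection
(tolerance $10^{-3}$ keV/µm; at a flat plateau the smallest LET attaining
the value is returned). The uncertainty is geometric, as one would read it
off the inverted plot: the measurement box `lid ± delta_lid` is intersected
with the band envelope and ΔLET is the half-width of the LET interval where
they overlap, clipped to the calibration grid. Densities below 0.3 µm⁻¹
return status `below_detection`; densities above the plateau return
`saturated`, with no numeric estimate in either case.

Because the band reflects per-track scatter, ΔLET from a calibration of 500
tracks per knot is conservative for ensemble means: held-out ensembles of
100 tracks at 50 and 116 keV/µm are recovered within ΔLET in essentially
every repeat (the acceptance criterion asks for ≥ 68 of 100).

## Dosimetry

`dose()` applies $D = F\,\mathrm{LET}/\rho$ exactly
($0.1602176634$ Gy per unit $F\cdot\mathrm{LET}$, from
1 keV $= 1.602176634\times10^{-16}$ J). Uncertainties propagate linearly,
$\Delta D = (\mathrm{LET}/\rho)\Delta F + (F/\rho)\Delta\mathrm{LET}$ — the
non-quadrature form conventional in this assay, kept deliberately so the
worked examples reproduce to the printed digit. Mixed fields add component
doses and component uncertainties. Fluence comes from track counting:
mean tracks per nucleus over mean projected nuclear area, with the standard
error of per-nucleus ratios as its default uncertainty (a directly measured
ΔF can be supplied instead).

```{r dose-example}
dose(0.011, 66)                        # lithium via focus counting
dose_uncertainty(0.010, 0.003, 66, 19) # its printed error budget
dose(0.011, 116)                       # lithium via detector LET
```

## Imaging operations

**Focus sizing.** The Pearson autocorrelation of a 2D patch is computed at
integer pixel shifts (averaged over the two image axes; foci are round) and
fitted with $f(x)=e^{-x^2/2\sigma^2}$ by one-parameter least squares. The
ACF of a Gaussian object is Gaussian with $\sqrt2$ larger width, so the
object FWHM is $2\sqrt{\ln 2}\,\sigma_{\mathrm{fit}} =
\mathrm{FWHM}_{\mathrm{ACF}}/\sqrt2$; on exact samples the identity holds to
machine precision. Two practical caveats, both visible in the tests: the
patch should be an order of magnitude wider than the focus (the Pearson
mean-subtraction otherwise depresses the tails and shrinks the fitted
width), and shifts should not extend far beyond where the ACF has decayed.

**3D detection.** A deliberately simple stand-in for interactive spot
pickers: 3D local maxima (26-neighbourhood) above a peak threshold seed the
foci; seeds closer than one PSF FWHM (default 140 nm) are suppressed, the
higher peak winning; each focus grows over connected voxels above half its
seed intensity (configurable), with contested voxels going to the nearer
seed; centroids are intensity weighted. On high-SNR synthetic stacks with
2× FWHM spacing it is essentially exact, which is all the pipeline needs —
it is not a general-purpose segmenter for crowded or low-SNR data.

**Gating and bookkeeping.** `colocalization_filter()` keeps detections of
the small marker only within 0.3 µm (half the large-marker focus size) of a
partner focus — the double-positive rule that suppresses spurious counts.
`track_irif_stats()` measures the track length from first to last focus by
projection on the track axis (7.6 µm fallback for a single focus; an
optional 1/cos 9° correction for tilted irradiation geometry exists but is
off by default, since track lengths are conventionally reported in the
imaging plane). Per-volume densities divide each nucleus's focus count by
its own box volume (length × width × height — an overestimate of an
ellipsoid by π/6, but the convention of the assay) and average the per-cell
densities rather than re-ratioing totals, which keeps cells with atypical
volumes from dominating.

## Numerical choices and problem sizes

* Isotonic regression before interpolation guarantees an invertible central
  curve even where Monte-Carlo noise or genuine non-monotonicity (LCD
  declines beyond $\lambda = 1/d$) appears at the top of the grid.
* Curve builds are deterministic given the density table; the recorded seed
  plus configuration regenerate any curve bit-identically, and calibration
  JSON stores 17 significant digits so evaluations survive a round trip
  exactly.
* The closed-form tests use long straight segments (400–6000 µm, 2000
  tracks per rate) so that the $O(1/L)$ boundary terms of the cluster rate
  sit well below the Monte-Carlo error; the calibration and recovery tests
  use the nucleus geometry at 500 tracks per knot and 100-track held-out
  ensembles, sizes at which the whole suite completes in about a minute on
  one core.
* Band coverage is assessed over the curve's rated LET range (between the
  detection and saturation limits): below the detection limit the per-track
  LCD distribution is dominated by discrete atoms (zero-DSB and
  single-cluster tracks), where percentile bands are not meaningful.

## Known limitations

* The calibration is only as good as the generator behind it; for real
  dosimetry the curve should be rebuilt from a transport-code database or,
  preferably, measured ensembles. The curve container, inversion and limits
  are agnostic to where the densities came from.
* ΔLET from the box–band geometry is conservative for ensemble means (the
  band is per-track scatter) and is clipped at the grid boundary near the
  plateau.
* The detector assumes well-separated, roughly Gaussian foci; it will
  undercount clumped foci — which is precisely the saturation phenomenon the
  calibration models, but it means detector counts should not be treated as
  DSB counts at high LET.
* Sub-voxel accuracy of centroids and sizes is limited by the 40 × 40 ×
  160 nm voxel pitch; axial sizing in particular is not attempted.
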