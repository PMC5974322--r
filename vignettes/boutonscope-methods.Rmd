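---
title: "Models and methods behind boutonscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind boutonscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boutonscope)
```

`boutonscope` analyses wide-field spinning-disk confocal calcium-imaging
movies of thalamocortical (TC) axonal boutons — micrometre-scale presynaptic
varicosities whose fluorescence transients report the parent neuron's spikes
— and ships a fully ground-truthed synthetic-movie generator so that every
stage of the analysis can be validated without access to raw recordings.
This vignette explains the models, the tunable parameters, the numerical
choices, and what validation on synthetic data does and does not establish.

## The imaging model behind the synthetic generator

A scene is a set of axonal arbors crossing a rectangular field. Each arbor
is a cubic-smoothed random walk entering at a field edge (step 2 µm, heading
increments capped at ±0.12 rad, so curvature stays axon-like); boutons are
placed along it as a one-dimensional Poisson process. Defaults follow the
anatomy and activity of layer-1 TC arbors: **110 boutons/mm** of axon and
parent event rates of a few tens per minute. `event_rate_per_min` accepts
one rate per arbor, because activity rates differ strongly across axons in
vivo; several analyses below depend on that heterogeneity.

Each arbor has one Poisson **parent spike train**; each bouton's train is an
independent thinning of its parent with a release probability drawn
uniformly in [0.7, 1]. Boutons of one axon therefore share most — but not
all — events, which reproduces the sub-unity (~0.6–0.9) activity
correlations observed between boutons of a common axon, while boutons of
different axons are independent.

Spikes are turned into fluorescence by a difference-of-exponentials
indicator kernel normalized to unit peak. The indicator kinetics are free
parameters; the defaults (rise 0.18 s, decay 1.8 s) are typical constants
for a slow, bright indicator of the GCaMP6s class, and are overridable
everywhere.

Rendering sums, per frame: a constant baseline (default 100 a.u.); one
Gaussian spot per bouton (lateral FWHM default 1.7 µm — the apparent bouton
size at ~1 µm pixels — with peak amplitude `bouton_amp`, default 40 a.u.);
and a smooth neuropil field (a 20 µm-blurred random field) modulated by the
low-pass-filtered population activity. Bouton brightness and neuropil
amplitude are free parameters of the artifact, not measured quantities.

**Pixel noise** is the package's central noise model: to a pixel with
noise-free temporal mean $m$, independent gamma draws with shape $k$
(default 2.57) and scale $\theta = \sqrt{NR \cdot m / k}$ are *added*, so
the added noise has variance exactly $k\theta^2 = NR \cdot m$. The noise
ratio $NR$ — the slope of pixel variance against pixel mean — summarizes
the mean-proportional noise of the camera/photon chain; 3.71 is the
reference value for the 8K spinning-disk data this model emulates.

What the generator does *not* emulate: light scattering and depth-dependent
blur inside tissue (except in the bead-phantom module), motion beyond rigid
translation, photobleaching, and out-of-focus activity from structures other
than the smooth neuropil field. Tests passing on synthetic movies therefore
validate the *algorithms* under the stated noise and correlation structure;
they do not certify performance on real tissue.

## Optics arithmetic

The spinning-disk geometry is pure arithmetic, kept exact: maximum frame
rate `(rpm/60)/scan_fraction` (10,000 rpm with a one-third-rotation scan
gives 500 fps); pinhole spacing at the focal plane
`spacing/magnification` (500 µm at 13x gives 38.46 µm); pixel size
`fov/pixels` (1080 µm/1024 px = 1.05 µm; 1106 µm/5310 px = 0.21 µm); axial
stage-displacement correction `n_specimen/n_immersion` (1.33 for air into
water-like tissue); and raw data rate `w·h·bytes·fps·3600` (an 8K sensor at
60 fps yields ~9.9 TB/h). Functions return full precision; rounding is a
display concern (`optics_table()`).

## PSF metrics

Bead profiles are fitted with offset + Gaussian by Levenberg–Marquardt
(`minpack.lm::nls.lm`, moment initialization, tolerance $10^{-12}$);
FWHM $= 2\sqrt{2\ln 2}\,\sigma$ exactly. The offset term is included
because real bead images sit on a background; fits on flat or
non-converging profiles return an explicit failed-fit object rather than
NaN. For 3-D beads the centre is refined as the intensity centroid of the
brightest 10% of a local cube before the X and Z lines are extracted, and
Z coordinates are pre-scaled by the refractive-index correction.
Signal-to-background uses the maximum in a 30 µm square over the mean of
the square minus a central 10 µm circle, and is invariant under intensity
rescaling; depth profiles are compared across modes with the exact
two-sample Wilcoxon rank-sum test (identical-sample degenerate case defined
as $p = 1$).

## The extraction pipeline

Registration estimates per-frame translation by FFT cross-correlation
against a reference (mean image by default) with parabolic sub-pixel
refinement, and corrects by the rounded shift with edge replication;
non-rigid motion is out of scope. Spatial filtering is a separable Gaussian
(sigma in µm, default 0.2) whose kernel is renormalized at image borders so
flat images stay flat and interior mass is conserved — this boundary
behaviour is why the filter is implemented directly rather than with an
FFT-based (circular) convolution. Movies are block-averaged to 6 Hz before
extraction; a trailing partial block is dropped.

ROI extraction is a deliberately simplified constrained nonnegative matrix
factorization, fully specified here rather than a reimplementation of the
published CNMF codebase: the movie is decomposed as $Y \approx AC + bf^T$
with nonnegative footprints $A$, traces $C$ and a rank-1 background.
Components are seeded greedily at maxima of the positive temporal-activity
energy of the mean-subtracted, 3-frame-smoothed movie, each confined to a
small square patch, and refined by 10 hierarchical alternating
least-squares sweeps. A second seeding pass then runs on the residual:
when two correlated boutons sit a few pixels apart, the first component
absorbs their shared signal and only the residual reveals the neighbour.
Phase-2 seeds may not land within the merge distance of an existing centre
(that is unconverged residue, not a bouton) and are accepted only if they
strictly reduce the residual; a short HALS phase follows. Every HALS
update is an exact projected least-squares step, so the recorded residual
norm is non-increasing — a property the tests assert. Seeding stops when
the remaining energy falls to the level expected from pixel noise.

The **patch radius defaults to 4 px**, sized to the bouton footprint
(sigma ≈ 0.7 px at 1.05 µm pixels): larger patches let a component absorb a
highly correlated same-axon neighbour bouton and drag its centre several
pixels off, which measurably hurts recovery. The radius remains an
argument for other footprint scales (e.g. somata).

Events are inferred per component under an AR(1) model whose coefficient is
the lag-1/lag-0 autocovariance ratio: $s_t = \max(0, c_t - g c_{t-1})$,
thresholded at 3 times the frame-noise SD (estimated as
$\mathrm{mad}(\Delta c)/\sqrt{2}$), with a relative floor of 5% of the
trace maximum so that noise-free traces do not count every deconvolution
residue as an event. A transient whose rise straddles a frame boundary
deposits a small residue bin right after the onset bin; a supra-threshold
bin smaller than half its predecessor is folded back into it, while a
comparable-amplitude successor is kept as a genuine second spike. In
degradation studies, event series of matched ROIs are compared as
binarized, 3-frame-smoothed occurrence trains, so a one-frame onset jitter
does not register as decorrelation. Components below an SNR of 4, or with peak amplitude
below 2% of the strongest component, are discarded; components closer than
2 px with temporal correlation above 0.8 are merged. Footprints are
max-normalized at the end, ROI areas are the pixels above 0.5 of the
maximum, and ROIs whose centre lies within 4 µm of the field edge are
flagged for exclusion.

Per-ROI fluorescence is the footprint-weighted movie averaged over the
support; the baseline $F$ is the 8th percentile (linear interpolation
between order statistics) either in a ±15 s sliding window or over the
whole record; $\Delta F/F = (F_{true} - F)/F$.

## Neuropil decontamination

The surround trace is the mean over an annulus within 2 µm of the ROI
support but excluding the support itself — exclusion avoids regressing the
ROI on its own pixels. After dropping time points where the ROI trace
exceeds its mean plus 2 SD (1 SD for two-photon data), the contamination
factor is the slope of an iteratively re-weighted least-squares regression
of $F_{roi}$ on $F_{neuropil}$ with bisquare weights (tuning constant
4.685, the standard 95%-efficiency choice); an intercept is included but
only the slope is used. The field-wide factor $r$ is the median slope
across the field's ROIs — per imaging field, not pooled across fields —
and $F_{true} = F_{roi} - r\,F_{neuropil}$.

## Noise model and degradation studies

Signals are normalized by a single scalar: the variance, across non-vessel
pixels, of each pixel's temporal mean (the default vessel mask takes pixels
below the 5th percentile of temporal mean and is user-overridable, since
the original criterion was visual). Per-pixel distributions are fitted by
maximum-likelihood gamma; $NR$ is the ordinary least-squares slope of
pixel variance on pixel mean over ~100 sampled pixels. Noise injection
adds gamma draws with $k = 2.57$ and per-pixel
$\theta = \sqrt{NR \cdot m / k}$.

Two NR-estimation modes exist because added noise shifts the observed
pixel mean by $k\theta$: regression on the *observed* mean is the
field-faithful default, and regression on ground-truth pre-noise means is
a separate unbiased diagnostic used in the recovery tests.

`degradation_study()` injects noise at a list of NRs, re-extracts, matches
ROIs to the clean reference by centre distance (≤ 3 px, one-to-one), and
reports ROI-count, event-count and event-correlation ratios; ROIs still
detected at NR = 3.71 are flagged robust, and their area/fluorescence/peak
$\Delta F/F$ distributions are compared with all ROIs by the two-sample
Kolmogorov–Smirnov test.

## Correlation maps and multi-plane overlap

For pixel-wise correlation the movie is binned 2×2 in space and 10 frames
in time; a seed correlation map is the Pearson correlation of every binned
pixel with one seed pixel, invariant under positive affine intensity
transforms. Pairwise ROI correlations are ordered by average-linkage
agglomerative clustering on distance 1 − r (linkage unstated in the source
protocol; average linkage chosen as the least shape-biased default), and
summarized by a bin-width-0.02 histogram and the least-squares slope of
correlation against pair distance. Bouton density along an arbor samples
the map along a polyline (bilinear interpolation, one-pixel steps) and
counts local maxima by topographic prominence (default 0.2 correlation
units — peaks are counted relative to their own ridge, so a sloping
baseline does not create or destroy them).

Cross-plane overlap takes ROI areas (footprint > 0.5), computes shared
pixels for every pair on different planes, and normalizes by the *smaller*
ROI's area — the protocol names "50% of the ROI area" without saying which;
the smaller-area convention is conservative (it flags exactly the merges
the larger partner would absorb) and is switchable to the first-ROI
convention. Overlapping pairs with temporal correlation > 0.6 are presumed
to be the same bouton seen twice and excluded; the overlap ratio divides
the remaining overlapping ROIs by all other ROIs.

## Study conditions used in the validation suite

The test suite and the acceptance script run at desk scale: the standard
extraction benchmark is a 256 × 256 px field (1.05 µm pixels), 60 s at
6 Hz, ~20 boutons on 3 arbors, NR 0.5; the degradation benchmark is an
80 × 80 px field with five arbors at 30–60 events/min and a dim-heavy
amplitude spread (12–50 a.u.), NRs {0, 1, 2, 3.71, 5}, medians over 5
injection seeds; noise-law checks use 10,000-frame constant movies and
NR recovery uses 100 pixels × 2,000 frames × 3 seeds. These sizes were
chosen as the smallest at which the measured properties are stable.

## Known limitations

The factorization is a documented simplification: no spatial sparsity
penalty, rank-1 background only, AR(1) events without amplitude
calibration. Boutons closer together than the optical footprint are
extracted as one component by design; the recovery metric therefore counts
a bouton as found when an ROI centre lies within 3 px. Registration is
integer-pixel in its correction step. The bead phantom approximates
defocused background as uniform rather than ray-traced. None of the
quantitative claims about real tissue in the source protocol are
reproduced here — where raw data would be required, properties are
validated on the generator instead.
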