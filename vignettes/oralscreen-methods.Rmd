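---
title: "Methods: dual-modality oral screening analysis"
author: "oralscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-modality oral screening analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralscreen)
```

## The screening problem

Oral squamous cell carcinoma and its precursor lesions are a major health
burden in communities with little access to specialist care. Autofluorescence
imaging (AFI) exploits two photometric signatures of dysplastic mucosa under
~405 nm excitation: endogenous green fluorescence (collagen, FAD) *decreases*
as tissue architecture breaks down and hemoglobin absorption rises, while
porphyrin accumulation adds a *red* emission peak near 635 nm. A paired
white-light image (WLI) gives the reviewing specialist conventional visual
context. `oralscreen` implements the complete analysis stack around such a
device: lesion-highlighting maps and an on-device triage call, color
calibration of the WLI channel, optical and illumination quality control,
and the statistics used to evaluate the screening workflow against a
gold-standard diagnosis — all exercisable end to end on seeded synthetic
phantoms with exact ground truth.

## Autofluorescence analysis

Two per-pixel maps drive everything downstream.

**Green mean-subtraction.** For the green plane $I_G$ the enhanced map is
$f(i,j) = I_G(i,j) - \overline{I_G}$, with the mean taken over the analysis
mask. Negative values mark fluorescence deficit. The map is invariant under
additive exposure offsets, and its in-mask mean is zero by construction
(tested to $10^{-9}$). Out-of-mask pixels are set to 0 so the map renders
neutrally.

**Red/green ratio.** $r(i,j) = I_R(i,j) / (I_G(i,j) + \varepsilon)$ with
$\varepsilon = 10^{-6}$ guarding underflow. The ratio rises inside
dysplastic lesions both because green drops and because porphyrin red rises.
It is pixel-wise rather than region-integrated; both framings exist in the
AFI literature, and the pixel-wise form is what an on-device implementation
can compute in one pass.

**Triage call.** No published threshold exists for this class of device, so
the classifier is deliberately *relative*: a pixel is flagged when its ratio
exceeds `pixel_factor` (default 1.5) times the in-mask **median** ratio, and
the site is called suspicious when flagged pixels reach `area_threshold`
(default 2%) of the mask. The median baseline is robust to the lesion's own
pixels (lesions rarely dominate the field), and a relative rule survives
changes of exposure, gain and illumination level, all of which scale both
channels together. Both defaults are configurable and are package choices,
not published values.

**Analysis mask.** Specular reflections from the hygienic sheath or saliva
saturate the sensor and would corrupt means and medians, so any pixel with
all channels at or above `highlight_cut = 0.98` is excluded. The threshold
is configurable; 0.98 keeps 8-bit code 250+ out while tolerating bright but
informative tissue.

**Features.** For the baseline classifier each AFI frame is reduced to five
mask statistics in fixed order: mean ratio, 95th-percentile ratio (type-7
quantile), flagged fraction at the default thresholds, mean green deficit
(minus the mean of negative mean-subtraction values), and the green
coefficient of variation. The last two give a linear model purchase on
hyperkeratotic lesions that the ratio alone misses.

## Color correction

The AFI emission filter distorts the camera's color rendition, so WLI frames
are corrected through a linear map $\mathbf{XYZ} = A\,\mathbf{RGB}$ fitted on
a 24-patch checker: with measured patch RGB rows $C$ (24×3) and reference
XYZ rows $T$, $A$ solves $\min\lVert C A^{\mathsf T} - T\rVert_F$. The
matrix "inversion" of the normal equations is a QR least-squares solve —
$C$ is tall, so the pseudoinverse is the only consistent reading — and when
$T$ was produced by an exact linear map the fit recovers it to $10^{-8}$
(a property the suite checks against the device's published matrix).
Patch values are measured over the central 50% of each cell with highlight
exclusion.

Two open choices were resolved as follows. *Working space:* by default the
fit and the correction run on pixel values as loaded, because phone pipelines
deliver display-referred values and the device's own matrix was fitted that
way; a `gamma` flag enables the physically linear pathway
(sRGB-linearize → $A$ → XYZ→sRGB matrix → re-encode). With `gamma = FALSE`
and an identity matrix the correction is exactly the identity, which fixes
the semantics unambiguously. *Reference white:* the bundled reference table
assumes D65; the paper trail for any given checker should replace it. The
bundled file is constructed from nominal patch sRGB coordinates and is
labelled synthetic (`colorchecker_xyz_synthetic.csv`) — it is a stand-in
with the right structure, not vendor data. Out-of-gamut corrected pixels are
clipped, never wrapped.

## Optical and illumination quality control

**Asphere sag.** Lens surfaces follow the even-asphere form
$z = \dfrac{c r^2}{1+\sqrt{1-(1+k)c^2r^2}} + \alpha_2 r^4 + \alpha_3 r^6$,
with the conic square root defining a hard aperture limit that the code
reports by name. The intraoral probe prescription ships as a CSV fixture
(10 optical entries, terminated by the smartphone camera surface, which is
metadata rather than a modelled surface — the phone's own optics are not
raytraced here).

**USAF frequencies.** Group $G$, element $E$ bars have spatial frequency
$2^{G+(E-1)/6}$ lp/mm; group 6 element 2 gives 71.8 lp/mm, a 14 µm full
period — the probe's measured cutoff.

**MTF, two routes.** From a measured PSF, the MTF is the modulus of its
normalized Fourier transform; 2-D PSFs are reduced to a radial profile by
binning modulus values at radius multiples of $1/N$ and reporting each bin
at the mean radius of its members (this keeps the profile accurate in the
low-modulation tail, where assigning the bin *center* frequency biases the
comparison against closed forms). From a slanted edge, the estimator follows
standard practice: per-row centroid regression locates the edge (2–15° off
axis recommended; outside that range the result is returned but flagged),
pixel centers are projected onto the edge normal, binned at 4× oversampling
into an ESF, differentiated centrally into an LSF under a Hamming window,
and transformed. The two transfer functions introduced by the analysis
itself — the bin-averaging box and the finite-difference derivative filter —
are divided out (bounded below to avoid noise blow-up). Frequencies are in
cycles/pixel; conversion to lp/mm requires the pixel pitch and system
magnification, which must be supplied explicitly because no universal
scaling factor exists for a probe mounted on an arbitrary phone camera.
On a synthetic Gaussian-blurred edge ($\sigma = 2$ px) the estimate tracks
the closed form $e^{-2\pi^2\sigma^2 f^2}\,|\mathrm{sinc}(f)|$ within 2% RMS
up to 0.4 cycles/pixel, and the PSF and edge routes agree within 3% once
the pixel aperture is accounted for (the PSF route, like the bench
instrument it models, sees no sensor sampling).

**Illumination uniformity.** Uniformity $= 1 - c_v = 1 - \sigma/\bar x$ over
the ROI, with the sample ($N-1$) standard deviation. When a relative
illumination (RI) map of the imaging optics is supplied, the flat-field is
divided by it first so only the *illumination* nonuniformity is scored; a
flat-field exactly explained by the optics scores 1. Because $c_v$ is
scale-free the score is exactly invariant under positive rescaling — any
pre-normalization of the data is mathematically redundant, so none is
applied. The default ROI is the central 80% of the frame (the device's
useful field); the ROI is an explicit argument everywhere.

## Evaluation statistics

Gold-standard diagnoses map to classes by a fixed vocabulary: seven
potentially-malignant/malignant diagnoses (OSCC, lichen planus, homogeneous
and speckled leukoplakia, tobacco pouch keratosis, verrucous leukoplakia,
oral submucous fibrosis) are *suspicious*; normal/variation is *normal*;
benign is excluded from both classes (with a logged count) rather than
silently dropped; unknown labels are an error.

Sensitivity, specificity, PPV and NPV come from the standard confusion
ratios; a zero denominator yields an explicit `NA`, and table-style
presentation rounds half-up to 4 decimals only at report time. ROC curves
sweep thresholds over unique scores (positive iff score ≥ threshold) and the
trapezoidal AUC equals the tie-corrected Mann–Whitney statistic; the suite
verifies this against brute-force pair counting and against an independent
ROC implementation.

Since screening images have no natural orientation, datasets are augmented
with the 8-element dihedral orbit (4 rotations × optional flip), the same
transform applied to WLI, AFI and mask. Cross-validation is stratified and
seeded, and augmentation is applied *after* splitting — equivalently, all
orientations of one original share a fold via the `groups` argument —
because orbit copies on both sides of a split would inflate accuracy. The
deep network used in the field study is out of scope here; its place in the
harness is taken by a deliberately simple linear scorer fit by ridge
(regularized least-squares) regression on the five AFI features, which is
deterministic, dependency-free, and sufficient to exercise the folding,
metric and ROC machinery.

## Synthetic phantoms and what they do (not) show

Every input the package consumes can be generated with known ground truth:

* **Tissue pairs** — uniform mucosa fields with elliptical lesions
  (multiplicative green attenuation 0.55, additive red boost 0.20), a radial
  Gaussian illumination vignette (35% corner falloff) common to both
  channels, additive Gaussian sensor noise (σ = 0.01), and an exact lesion
  mask. With probability 0.05 a suspicious case presents as
  *hyperkeratotic*: green gain ×1.35 and no red boost, reproducing the known
  confound in which keratin *raises* autofluorescence and defeats a
  red/green rule. These contrasts are package choices made once for a
  plausible, testable phantom; no quantitative lesion-contrast statistics
  were available to copy. The hyperkeratosis rate models the confound
  presentation, not the prevalence of keratosis diagnoses in any clinic
  population. WLI rendering is cosmetic (the classifier consumes AFI
  features only), so no test depends on WLI realism.
* **Checkers, edges, flat-fields** — a 4×6 patch checker with returned
  geometry; an analytically antialiased slanted edge (error-function profile
  integrated over a dense subpixel grid) whose true MTF is known in closed
  form; and LED flat-fields as sums of Lambertian-type
  $\cos^m\!\theta \cdot \cos\theta / d^2$ contributions from a
  plane-symmetric layout, returning the exact coefficient of variation of
  the noiseless field as an oracle.

All generators are pure functions of `(params, seed)`; regeneration is
bit-identical. On a 100-case cohort at the default parameters the on-device
classifier recovers ground truth with sensitivity and specificity ≥ 0.9, and
4-fold cross-validation of the linear baseline reaches AUC ≥ 0.95. Those
gates demonstrate *self-consistency of the method with its own generative
model* — lesions defined by decreased green and increased red are found by a
red/green rule. They do not demonstrate clinical performance: real mucosa
has texture, vasculature, motion blur, and specular noise the phantom lacks,
and the study's own network results on clinical images are not reproducible
without those images.

Problem sizes used by the suite (128×128 phantoms, 96×128 edge targets,
100-case cohorts, 4 folds) were chosen as the smallest at which the
estimators' asymptotic behavior is visible; all statistics scale with their
inputs.

## Workflow and provenance

Cases live in a flat-directory JSON store (one record per case, images
alongside). Analysis writes, per site, the four standard renditions —
original AFI, mean-subtraction-enhanced AFI, original WLI, color-corrected
WLI — and a versioned JSON summary report that embeds the fully resolved
configuration. Reports carry no timestamps, so re-analysis with the same
configuration is byte-identical; creation timestamps live on the case
record. Signed green maps exported as images are offset by +0.5 so zero
deficit renders mid-gray. All thresholds, the color matrix, and the sRGB
flag travel in a single configuration object, overridable from YAML, with
unknown keys rejected.

Image I/O is lossless at the source bit depth (8-bit PNG/TIFF, 16-bit
TIFF; the PNG encoder available to R is 8-bit only, so 16-bit data goes to
TIFF). Quantization rounds half away from zero. All internal arithmetic is
on unit-scale floats.

## Known limitations

* The ratio thresholds are heuristics; on real data they would be tuned on
  a labelled calibration set, which the package deliberately does not ship.
* The slanted-edge estimator assumes a single clean edge; curved or
  double edges are not detected as such (the contrast floor and angle flag
  catch the worst cases).
* The prescription loader models surface geometry only; it does not
  raytrace, so system-level MTF predictions from the prescription are out
  of scope.
* Benign lesions — the class the field study excluded — are not generated,
  so the phantom cohort cannot probe the benign-versus-suspicious boundary.
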