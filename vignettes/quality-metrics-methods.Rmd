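---
title: "Quantifying image quality in propagation-based micro-CT of fibrous tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying image quality in propagation-based micro-CT of fibrous tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomoqc)
```

## The problem

Propagation-based (phase-contrast) synchrotron micro-tomography images
soft fibrous tissue — the motivating case is Achilles tendon — by letting
a coherent X-ray wavefront self-interfere over a free-space propagation
distance, so that weakly absorbing structures such as micrometer-scale
collagen fiber bundles become visible against the non-collagenous matrix
between them. Whether a given preparation, optic, and retrieval setting
produces *usable* volumes is a quantitative question: how fine a detail
survives (spatial resolution), how well fibers separate from matrix
statistically (contrast-to-noise), how reliably a threshold can segment
them (segmentation uncertainty), and how sharp phase-enhanced borders
remain (edge gradient). `tomoqc` implements those four metrics together
with the wave-optics stage that produces the inputs (flat/dark
correction, single-distance Paganin phase retrieval) and the morphometry
used to quantify preparation-induced shrinkage (cross-sectional area).

Because real beamline volumes are large and rarely deposited, the package
is exercised end to end on a synthetic phantom generator that reproduces
the statistical structure the metrics assume. Every pipeline stage is a
pure function of its configuration and seed.

## The phantom generator

`phantom_spec()` parameterizes two scene types:

* **Fibers** — bright cylinders of radius `fiber_radius` on a hexagonal
  lattice (densest packing, matching "tightly packed" fiber bundles) with
  center spacing `2 * fiber_radius + fiber_gap`, axes along z, optionally
  crimped (in-phase sinusoidal centerline displacement in x). Voxels are
  exactly `fiber_level` inside and `matrix_level` outside, so the
  undegraded phantom carries its own ground truth: class means are exact,
  and the volume fraction converges to the analytic lattice packing
  fraction $\frac{2\pi r^2}{\sqrt{3}\,a^2}$.
* **Fat cells** — non-overlapping bright spheres with sharp borders,
  radii uniform in `sphere_radius_range`, placed by rejection sampling.

Degradation (`degrade()`) applies, in fixed order, a Gaussian detector
PSF (`psf_sigma`, µm), additive Gaussian noise (`noise_sigma`, gray
units), and a per-slice concentric-ring bias
(`ring_amplitude * sin(r_vox)`), the simplest structured artifact that
defeats naive global thresholding. Blur uses a symmetric (mirror)
boundary operator whose rows *and* columns sum to one, so the mean gray
value is conserved exactly — this keeps edge slices usable in metric
tests.

Default conditions emulate the coarser of the two instrument profiles
(1.63 µm voxels, 15 keV): fibers of 8 µm radius with a 4 µm matrix rim
(so a fiber spans ~10 voxels), gray levels 1.0/0.6, a one-voxel PSF and
noise sd 0.2. The fiber diameter is an assumption — chosen so fibers span
several voxels at the coarse profile — not a measured value; the gray
levels and noise were chosen so the analytic contrast-to-noise ratio
$\Delta/s = 2$ sits in the plausible range for well-prepared tissue. The
generator does **not** emulate tissue mechanics, beam hardening,
fat/matrix partial-volume chemistry, or reconstruction streaks; passing
tests therefore demonstrate correctness of the *metrics and retrieval*,
not fidelity to any particular beamline's artifact spectrum.

## Wave-optics stage

**Fringe rule.** The single-distance regime is anchored at
$z_D = (2p)^2/\lambda$ for pixel size $p$; `first_fringe_distance()`
evaluates it from $\lambda = hc/E$. At 15 keV
($\lambda \approx 0.827$ Å) this gives ≈129 mm for 1.63 µm pixels and
≈5.3 mm for 0.33 µm pixels.

**Forward model.** `fresnel_propagate()` builds the complex transmission
$\exp(-\tfrac{\mu}{2}t - i k \delta t)$ of a projected-thickness map
($\mu = 4\pi\beta/\lambda$) and applies the paraxial transfer function
$H(f) = e^{-i\pi\lambda z |f|^2}$. An aliasing guard rejects distances
beyond $N p^2/\lambda$, where the chirp becomes undersampled. The
propagator is unitary: pure-phase objects conserve flux to numerical
precision.

**Retrieval.** `paganin_retrieve()` applies the homogeneous-object
single-distance filter
$t = -\tfrac{1}{\mu}\ln \mathcal{F}^{-1}\!\left[\frac{\mathcal{F}[I/I_0]}{1 + (z_D\delta/\mu)|q|^2}\right]$
with $|q| = 2\pi|f|$. $\delta$ defaults to
`delta_beta_ratio * beta` with $\beta = 9.3\times10^{-9}$ held fixed
(tabulated soft-tissue attenuation at 15 keV), so retrieval strength is
tuned through the ratio alone; 50:1 is the default, with 10:1 and 100:1
available for the line-profile diagnostic (`ratio_line_profile()`, 200
samples by default). The three-ratio sweep is exposed as a diagnostic,
not an automatic optimizer — ratio selection is a visual judgment on
profiles, which we do not automate. Images are mirror-padded to the next
FFT-friendly size and cropped on return. Flat/dark correction floors the
transmission at $10^{-6}$ of the mean flat level so logarithms stay
finite without materially biasing retrieval; non-positive values *after*
filtering raise an error, since they indicate broken flat-fielding
rather than noise.

The forward–inverse chain is validated as a round trip. The filter's
derivation assumes intensity varying slowly at the first-fringe scale
($\sqrt{\lambda z_D} \approx 3.5$ µm ≈ 2 pixels at the coarse profile),
which a razor-sharp binary line integral violates: the raw map
round-trips at ≈4.5% RMSE, dominated by edge ringing. Applying the
phantom's own detector PSF (one voxel) to the projected map — physically,
no detector records a perfectly sharp projection — restores the validity
regime and the chain recovers thickness to <1% RMSE of maximum;
`make_phase_object(spec, psf_sigma = ...)` exposes that smoothing, with
the raw line integral as default. Round-trip error decreases
monotonically as added noise vanishes, and at vanishing ratio the filter
degenerates to the absorption-only $-\ln(I)/\mu$.

## The four quality metrics

All metrics operate on labeled sub-volumes (`subvolume()`), extracted
along the tendon axis by `extract_subvolumes()` for reproducibility
repeats.

**Spatial resolution** (`estimate_resolution()`). For three z-slices
(first, middle, last), the 1D power spectral densities of all row (x)
and column (y) profiles are averaged. The criterion — the spectrum has
"converged" where signal meets noise — requires three operational
choices the criterion itself does not fix, made here once and exposed as
arguments: the noise floor $L$ is the median PSD over the top 10% of
frequencies; the PSD is smoothed with a 5-bin moving average before the
crossing is located; and the resolution is reported as the *full period*
$1/f^*$ of the lowest frequency at which the smoothed PSD first falls to
$2L$ (the half-period convention would halve all values; the full period
is the default and the convention is recorded with the result). A flat
spectrum — pure noise, nothing above the floor at any scale — saturates
the estimate at the Nyquist period `2 * voxel_size`, which is also the
hard floor of any reported value; a spectrum that never reaches $2L$
raises an error advising a larger sub-volume. The estimate is invariant
to gray offset (DC is excluded) and gain (level-ratio criterion), and
strictly increases along a blur ladder.

**Fiber-to-matrix contrast ratio** (`fmcr()`):
$\mathrm{FMCR} = \frac{\overline{I}_{F} - \overline{I}_{M}}{\sqrt{(\sigma_F^2 + \sigma_M^2)/2}}$
over user-supplied disjoint masks of ≥1000 voxels each (a statistical
floor). The sign is preserved — inverted contrast is a finding, not an
error. On a two-phase phantom with level difference $\Delta$ and noise
sd $s$, FMCR recovers $\Delta/s$ (verified within 5% on megavoxel
masks). Being a ratio of first to second moments it is invariant under
both gray offset and gain. Mask granularity matters — coarser masks that
mix boundary voxels lower the value — so the thresholds used to derive
default masks are recorded in the result.

**Uncertainty of threshold-based segmentation** (`uts()`). The fraction
of voxels that cannot be uniquely assigned to either phase. Otsu's
method is named as the threshold selector, but a fiber-precise *and* a
matrix-precise threshold require two thresholds; the minimal
construction yielding both is a three-class Otsu decomposition, adopted
here: thresholds $t_{low} < t_{high}$ maximize the between-class
variance of the 256-bin histogram (fixed binning over the sub-volume
min–max, for determinism and oracle comparability; ties resolve toward
the smaller thresholds), and
$\mathrm{UTS} = 100\cdot\#\{t_{low} < v \le t_{high}\}/\#v$. A perfectly
bimodal volume (two delta peaks) has no valid three-way split and no
ambiguity: both thresholds collapse to the two-class split and UTS is
exactly 0. An optional Gaussian prefilter (default one voxel for the
coarse profile, none for the fine profile) suppresses noise before
threshold selection; on an already-smooth noiseless field the prefilter
moves the thresholds by only a few bins (~1–2% of the gray range) — a
small residual redistribution of edge-transition voxels, not threshold
instability. The implementation is verified against an exhaustive
two-threshold search on every histogram tested.

**Gradient sharpness at edges** (`gse()`). Per-slice 2D gradient
magnitude by central differences, edge voxels classified by a two-class
Otsu threshold on the pooled gradient-magnitude histogram, and the mean
gradient magnitude over edge voxels returned (gray units per voxel).
Computed on fat-cell sub-volumes because sphere borders are sharp and
unambiguous, whereas fiber–matrix transitions can be gradual and would
inflate variability. The per-slice 2D gradient mirrors the slice-wise
workflow; a 3D gradient is available via `mode = "3d"`. GSE scales
linearly with gray gain, is invariant to offset, and strictly decreases
along a blur ladder. A uniform volume has no edges and errors.

**Reproducibility** (`summarize_metric()`): mean, sample SD (n−1), and
CV = SD/mean over repeated sub-volumes; CV is undefined (an error) at
zero mean.

## Morphometry

`reorient()` aligns the dominant principal axis of the Otsu-thresholded
foreground cloud with +z (Rodrigues rotation, trilinear resampling,
out-of-domain filled with the volume minimum); a largest-to-second
eigenvalue ratio below 1.5 means no dominant axis and is an error.
`cross_section_area()` follows the outline-enhancement procedure: the
central window of stated physical extent (default 500 µm) is split into
non-overlapping blocks (default 100 slices; blocks are anchored at the
window start and remainder slices dropped), each block collapsed by a
per-pixel maximum-intensity projection, binarized by Otsu, holes filled
and the largest connected component kept (these two post-steps make the
area robust to internal fat/matrix voids), and the pixel count converted
to mm². Since the threshold adapts, the area is invariant under affine
gray rescaling; for a z-invariant object every block yields the same
area to the pixel, and the ratio of areas of two cylinders recovers
$(r_2/r_1)^2$ — the computational counterpart of a fresh-versus-embedded
shrinkage comparison. The package reports ratios of its own
measurements only; it does not attempt to reproduce any particular
tissue's shrinkage percentage.

## Session layer and conventions

Volumes are `[y, x, z]` arrays with 1-based indexing (the natural R
convention; z is always the tendon/fiber axis, so `data[, , k]` is a
cross-section). Multi-page TIFF I/O stores 32-bit samples through an
affine export window recorded in a JSON sidecar: one window per
instrument profile, applied identically to every volume of a run and
stored in provenance, so gray values are comparable across volumes of a
run. The 32-bit fixed-point storage bounds round-trip error at
$2^{-32}$ of the window span. Configurations (`run_config()`)
round-trip losslessly through JSON; the two named profiles pin voxel
size (1.63/0.33 µm), energy (15 keV) and prefilter policy, and explicit
fields override them. `run_demo()` runs phantom → degrade → sub-volumes
→ metrics → summaries → area → report as a pure function of the
configuration; reports (CSV rows + JSON summaries + text digest) are
byte-reproducible under a fixed seed. The exported functions are the
interface; there is no shell wrapper.

## Numerical choices and problem sizes

Histograms are always 256 equal-width bins over min–max. FFT work pads
to the next 5-smooth size with mirror boundaries. Blur kernels truncate
at $4\sigma$. Sphere placement aborts after 10,000 rejection attempts,
reporting how many spheres were placed. The test suite runs on volumes
of 64³–160³ voxels and 512² projections — sizes at which every analytic
anchor (packing fraction, sphere volume, $\Delta/s$, disc area,
round-trip RMSE) is already tight — and completes in well under a
minute.

## Known limitations

Tomographic reconstruction itself (filtered backprojection / regridding)
is out of scope: the quality metrics consume reconstructed volumes, and
the optics stage works in projection space. The ring-artifact model is a
radial sinusoid, not a detector-gain stripe model. The resolution
criterion's absolute values depend on the stated floor/smoothing/period
conventions; comparisons across settings (its intended use) are
unaffected. Sub-volume coordinates are user-supplied by plan, not
discovered automatically — deliberate, mirroring manual region selection
in practice.
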