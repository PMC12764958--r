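---
title: "Methods: PORH biomarkers from optoacoustic mesoscopy, and the synthetic chain behind the tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PORH biomarkers from optoacoustic mesoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the scientific model implemented by `porhmeso`, the
choices made where the methodology was genuinely open, and what the
package's synthetic validation does — and does not — establish about real
measurements.

## The measurement and the biomarkers

A post-occlusive reactive hyperemia (PORH) test challenges the skin
microvasculature with an arterial cuff: after a resting baseline the cuff is
inflated above systolic pressure, then released. Optoacoustic mesoscopy
resolves the dermal vascular signal through this challenge as cross-sectional
frames; the mean image intensity of a skin layer over time is the raw
observable. Two cuff timings are built in: `long` (2 min baseline, 5 min
occlusion, 3 min recovery) and `short` (1/3/2 min), sampled at one frame per
second by default (0.5 s supported).

On the baseline-normalized scale the layer response is modeled as a
continuous piecewise curve (`hemodynamic_modulation()`):

* baseline: constant 1;
* occlusion: exponential decay toward the floor $1-\mathrm{MVC}$ with time
  constant $\tau_{occ}$;
* after release: a gamma-variate-shaped rise that attains its maximum
  $1/(1-\mathrm{HR})$ exactly at $\mathrm{TP}$ minutes after release,
  followed by exponential relaxation toward 1 with time constant
  $\tau_{rec}$.

The three parameters are the endothelial-function biomarkers. Estimation
(`compute_biomarkers()`, wrapped by the `porh_fit()` model object) uses the
window definitions: $\mathrm{MVB}$ = mean over the baseline window,
$\mathrm{MVIC}$ = mean over the full occlusion window, $\mathrm{PIV}$ = peak
value at or after release, and
$\mathrm{MVC}=\mathrm{MVB}-\mathrm{MVIC}$,
$\mathrm{HR}=100\,(\mathrm{PIV}-\mathrm{MVB})/\mathrm{PIV}$,
$\mathrm{TP}=t_{\mathrm{PIV}}-t_{\mathrm{release}}$. These identities hold
exactly for every fit, and HR and TP are invariant under positive rescaling
of the profile; both properties are enforced by the test suite.

### Parameter defaults and why

| parameter | default | rationale |
|---|---|---|
| $\tau_{occ}$ | 0.25 min | Under a suprasystolic cuff, inflow stops within seconds and the vascular signal empties over tens of seconds. A short time constant also keeps the occlusion-window mean close to the floor, so the configured MVC is recoverable from the printed window definitions: the residual inflow transient biases recovered MVC low by $\mathrm{MVC}\cdot\tau_{occ}/T_{occ}$ (≈ 5% of MVC for the long protocol), which the recovery tolerances absorb. |
| $\tau_{rec}$ | 1.0 min | Recovery back to baseline over a few minutes, matching the visible relaxation of layer profiles. |
| rise shape $\alpha$ | 9 | Gives a rise width of roughly $\mathrm{TP}/3$ — a sharp hyperemic overshoot as seen in reactive-hyperemia recordings; the rise is monotone up to its peak so the peak location is unambiguous. |
| peak smoothing | 9 samples (9 s) | The raw maximum of a noisy series is biased upward by extreme noise values (order $1.5\sigma$–$2\sigma$, i.e. several percentage points of HR at noise sd 0.02). Peak picking therefore uses a 9 s centered moving average — long enough to suppress the max-noise bias, an order of magnitude shorter than the rise width so the true peak is negligibly flattened. Window means always use the raw profile; `smooth_peak = 0` disables smoothing. |

The occlusion sample taken at the inflation instant still reads 1 by
continuity, so a recovered MVC carries a $\mathrm{MVC}/n_{occ}$ quantization
residue — visible only in noise-free checks.

If TP exceeds the post-release window (plausible for slow responders under
the short protocol), the curve is still rising at the end of the recording;
recovered TP then clips at the window edge while MVC and HR are essentially
unaffected (the gamma-variate is flat near its peak).

## Synthetic cohorts

`cohort_presets()` stores per-layer (DV/SD/RD) means and standard deviations
of MVC, HR and TP for four groups (smokers, matched non-smokers, CVD
patients, matched healthy volunteers); `generate_cohort()` draws per-subject
truths from those distributions — truncated normals via the inverse CDF, so
MVC stays in (0, 1), HR in [0, 1) and TP positive without rejection loops —
and emits noisy normalized profiles (additive white Gaussian noise, default
sd 0.02). Every generator takes an explicit integer seed.

With 10 subjects per cohort the truth mean itself has standard error
$\mathrm{sd}/\sqrt{10}$; recovered cohort means therefore scatter around the
configured mean by design, not estimator error, and recovery checks must be
read with that in mind.

## The synthetic imaging chain

The image-level mode exists so the full analysis path — not just the profile
arithmetic — is exercised against ground truth.

* **Phantoms** (`phantom_spec()` / `generate_phantom()`): a melanin slab
  near the surface (the epidermal reference band) and vessels as cylinders
  along the slow axis at subpapillary (~150–280 µm) and reticular
  (~680–820 µm) depths, radii 25–50 µm.
* **Forward model** (`simulate_raw_scan()`): each spherical source emits the
  classical bipolar N-shaped wave of half-duration $r/c$, band-limited by a
  Gaussian transducer response centered at 50 MHz; contributions are
  restricted to the 60°-aperture acceptance cone with cosine apodization,
  scaled by spherical spreading, and sampled at 500 MS/s
  (≥ 4× the 120 MHz band edge) with speed of sound 1540 m/s. Both values are
  configurable; neither is dictated by the measurement definitions. The
  model is linear in absorption — frame series are therefore synthesized
  exactly as per-layer base sinograms scaled by the hemodynamic curves, plus
  fresh per-frame noise.
* **Reconstruction** (`beamform()`): zero-phase 4th-order Butterworth
  band-pass (forward–backward, so ~48 dB/octave and no phase distortion),
  then sensitivity-weighted delay-and-sum implemented as a precomputed
  sparse operator reused across frames; envelope extraction is the magnitude
  of the analytic signal along depth (FFT Hilbert). The transducer
  sensitivity field is a Gaussian focal beam with the stated 3 mm aperture,
  normalized to unit maximum — the published work references simulated
  sensitivity fields without a formula, so a standard focused-beam model is
  used. Dual-band images reconstruct 10–40 MHz and 40–120 MHz
  independently (red/green composite available via `composite_rgb()`).
* **Motion correction** (`motion_correct()`): the published full algorithm
  is external to this package; implemented here is a self-contained
  surface-tracking corrector — per-A-line first-arrival detection refined to
  the first envelope peak (robust to per-line gain), a median-filtered
  reference surface, and bounded integer shifts.
* **Segmentation** (`detect_surface()`, `flatten()`, `segment_layers()`):
  the surface is the first threshold crossing per column (threshold relative
  to the column maximum, hence scale-invariant), median-smoothed; columns
  are shifted so the surface sits at depth 0. The epidermis/dermis boundary
  is the depth where the laterally averaged intensity falls below 30% of its
  superficial peak, constrained to 60–200 µm with a 100 µm fallback; the
  SD/RD split is a fixed configurable depth (default 200 µm) below that
  boundary. The authors' automatic layer algorithm is unpublished, so these
  are honest, tunable stand-ins — depth-stratified validation therefore uses
  the generator's own layer labels, not anatomical truth.

## Numerical choices and degenerate inputs

Peak ties resolve to the earliest time (a constant profile yields
TP = 0). Sub-voxel vessel diameters use linear interpolation of the
half-maximum crossings (`vessel_fwhm()`), with the background taken as the
median of the profile's outer edges; an absent crossing returns a flagged
`NA` rather than an error. Blood volume thresholds are
median + 3·MAD of the deepest image rows, making the voxel count invariant
to global intensity scaling. All-zero images and surface-free sinograms
refuse processing with diagnostics instead of returning silent nonsense.
Statistical comparisons gate on per-group Shapiro–Wilk at α = 0.05 and use
Welch's unpaired t-test or — because the groups are independent — the
unpaired Wilcoxon rank-sum test, not the (paired) signed-rank variant named
in the originating description of the method; the branch taken is recorded
in the result.

## Problem sizes used in validation

The test suite validates the beamformer against a brute-force delay-and-sum
oracle on grids up to 40 × 40 voxels with 32 scan positions, and point-source
localization on a 64 × 80 grid over 10 random placements. The image-level
depth-lag experiment uses 64 × 100-voxel frames at 1 s intervals over the
full 10-min protocol (601 frames), with the deep layer configured to peak
15 s earlier than the superficial one. Cohort recovery runs use the presets'
10 subjects per group. These sizes were chosen so the whole suite completes
in a few minutes while every stage still runs at meaningful scale.

## Limitations

The forward model omits acoustic attenuation and dispersion, optical fluence
decay with depth, and flow; phantom vessels are straight cylinders, not
capillary loops; melanin screening of strongly pigmented skin is not
modeled. Passing recovery tests therefore demonstrates that the analysis
chain is unbiased and well-calibrated for data matching its own generative
assumptions — it does not certify performance on real scans, where surface
roughness, heterogeneous speed of sound and motion outside the simple jitter
model add error sources the simulation does not emulate.
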