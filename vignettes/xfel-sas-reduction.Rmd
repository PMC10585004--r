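---
title: "Reducing liquid-jet XFEL SAXS data: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing liquid-jet XFEL SAXS data: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(jetsaxs)
```

## The measurement model

A liquid-jet SAXS experiment at a megahertz-pulsed X-ray laser records, for
every pulse, a 2-D detector frame whose expected photon count in a pixel at
momentum transfer $s = 4\pi\sin\theta/\lambda$ is

$$\lambda_{\mathrm{pix}}(t) = \bigl[b(s) + c(t)\,P(s)\bigr]\,
  \epsilon_{\mathrm{pulse}}\,d(t),$$

where $b(s)$ is the buffer + instrument background, $P(s)$ the particle
form factor scaled by the instantaneous protein concentration $c(t)$,
$\epsilon_{\mathrm{pulse}}$ a stochastic per-pulse intensity factor (SASE
lasing is intrinsically noisy, and train-level feedback makes the
train-to-train component dominate), and $d(t)$ a slow multiplicative drift
of beam and jet. The goal of the reduction is the form factor
$P(s)$ with honest uncertainties, which requires (i) removing frames whose
background model is wrong altogether — jet-edge flares and droplet debris —
(ii) averaging enough pulses that Poisson noise becomes manageable, and
(iii) subtracting a buffer measured close enough in time that $b(s)$ and
the multiplicative factors have not drifted away.

The package implements each stage behind an explicit function
(`photonize`, `filter_outliers`, `normalize_pulse_intensity`,
`average_frames`, `azimuthal_integrate`, `build_trace` /
`select_windows` / `buffer_estimate` / `subtract_buffer`, `guinier_fit` /
`ift_pr` / `estimate_dmax` / `chi2_fit`), and `reduce_autosampler_run`
chains them.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| gain | 69 | ADU/photon | single-photon peak position of the detector calibration |
| photon threshold | 0.7 | photons | first-photon acceptance; above it, nearest-integer rounding (the standard photonization convention; the choice only matters in the rare multi-photon tail) |
| distance | 3 | m | gives a visible Guinier range and an s-range of ≈0.06–2.5 nm⁻¹ |
| energy | 9.3 | keV | stable operating point; wavelength is derived as λ = 1.23984/E and validated to 0.5% if both are supplied |
| pulses/train × trains/s | 352 × 10 | — | nominal delivery: 3520 frames/s |
| `min_samples` | 10 | frames | DBSCAN core threshold per memory cell |
| `eps` | adaptive | robust σ | elbow of the sorted (min_samples−1)-NN distance curve per cell (see below) |
| buffer scale clamp | ±5% | — | the most rescaling a matched buffer should ever need; a fit pinned at the clamp is flagged |
| Guinier limit | s·Rg ≤ 1.3 | — | classical qualification range; for compact spheres the fit is essentially bias-free only up to s·Rg ≈ 1.0, which the analysis tests use |
| IFT grid | 101 points on [0, Dmax] | nm | trapezoid quadrature; endpoints pinned to zero |

## What the simulator emulates — and what it does not

`simulate_run` produces ADU frame stacks with: Poisson photon statistics;
a buffer background that is flat plus a weak power-law low-angle term; an
analytic particle signal (solid sphere by default, Rg = 3 nm, forward
signal 0.3 photons/pixel at unit concentration over a 0.5 photons/pixel
buffer); lognormal pulse (CV 10%) and train (CV 10%) intensity factors;
linear drift (1%/min); per-cell bad pixels (0.2%); flare frames (1%) as an
intense streak along a jittering jet axis confined to the inner-module
region; debris frames (1%) with a steep low-angle excess; and, in
autosampler mode, a Gaussian elution plug (σ = 6 s, peaking at 80% of the
injected concentration to reflect dilution along the line). Flare and
debris amplitudes are free phenomenological parameters — the experiment
offers no quantitative description — and the defaults are set so that
artifact frames are genuinely detectable (≥3 robust σ in the occupancy
metric), which is also what makes planted-recall tests meaningful.

Not emulated: jet-explosion hydrodynamics, detector gain switching,
beam-pointing excursions with spatial structure, wavelength jitter and
SASE bandwidth smearing, inter-particle structure factors, radiation
chemistry. Passing tests therefore certify the *reduction logic* under a
realistic noise model, not detector physics.

The scaled-down detector deserves emphasis: 16 modules of 16×16 binned
pixels (4096 active) stand in for a megapixel instrument, with the pixel
pitch enlarged so the same solid angle is covered. Only a few dozen pixels
sit in the Guinier region, so single-run Rg estimates carry 5–10%
statistical errors at the run lengths used in the tests; accuracy is
therefore asserted on repeated runs (ten 40-s reservoir pairs at 2.5×
concentration give a mean Rg within 2% of truth with errors that match the
reported fit uncertainties), while single-run checks are made against the
fit's own, honestly large, standard error.

## Numerical and design choices

**Adaptive DBSCAN radius.** Per memory cell, metrics are standardized by
median/MAD (robust against the very outliers being hunted; IQR and sd are
fallbacks for degenerate columns) and `eps` is set from the sorted
k-distance curve with k = min_samples − 1: the elbow (maximum distance to
the chord), extended to the end of the same regime (all values below twice
the elbow). A fixed quantile (e.g. the 95th percentile of 4-NN distances)
was tried first and rejects 1–2% of perfectly clean frames in the sparse
tail of every run, which both erodes the rejection budget and breaks the
exact-recovery property on planted outliers; the elbow sits just above the
dense bulk and below any genuine density jump. Only noise points are
rejected; all dense clusters are kept; a cell whose frames are all labelled
noise is kept wholesale with a warning (fail-safe), and cells with fewer
than `min_samples` frames are pooled.

**Effective s per bin.** Azimuthal integration assigns pixels to
equispaced half-open s bins by pixel centre (no splitting), which makes
photon totals exactly conserved under rebinning. The profile reports the
mean pixel s of each bin rather than the nominal centre: on a coarse
detector the sparsely filled low-angle bins populate asymmetrically, and
nominal centres bias any fit against the profile (double-digit percent on
Rg in our geometry). Empty bins keep their nominal centre and carry an
explicit flag.

**Error model.** σ(bin) = √(Σ sum)/Σ count — Poisson on summed photons.
After pulse normalization the sums are weighted, and the Poisson formula
is then an approximation good to O(CV²) of the residual weights, which is
negligible once normalization has been applied.

**Buffer windows under drift.** Window selection fits a robust
(iteratively trimmed, one-sided) line to each side of the elution peak and
takes the maximal run of points near that line: a plateau criterion
against a constant baseline would reject every buffer second on a drifting
run — precisely the situation buffer–sample–buffer interpolation exists
for. Both `average` and `interpolate` buffer modes are provided; the
interpolation is per-bin linear in time, evaluated at the sample-window
midpoint, since nothing in the delivery scheme distinguishes the two
readings otherwise.

**Buffer rescaling.** When enabled, the scale is a σ-weighted least-squares
fit of sample on buffer over the top 20% of the s range (where the protein
signal is negligible), clamped to ±5% and recorded in provenance.

**Indirect transform.** p(r) lives on 101 trapezoid nodes with
p(0) = p(Dmax) = 0 eliminated from the unknowns; the smoothness penalty is
the squared second difference on the zero-padded vector; α is chosen at
the maximum-curvature point of a log-log L-curve over a 24-point scan
spanning ten decades (relative to the ratio of the normal-matrix and
penalty traces). Non-negativity, when requested, is imposed by iteratively
pinning negative nodes to zero and re-solving. `estimate_dmax` scans
candidate dimensions and scores each fit by χ² inflated by penalties for
negative mass and a non-vanishing endpoint; the score is L-shaped in Dmax
and the estimate is the first candidate entering the plateau (within 5% of
the minimum). A flat or monotone score raises a `no_knee` flag instead of
fabricating a dimension.

**Guinier auto-range.** The window starts at the first positive bin;
occasional noise-negative bins inside a subtracted profile are skipped
rather than allowed to truncate the window. The range iterates as a fixed
point — fit, recompute the window as {s·Rg ≤ limit}, refit — with cycle
detection; a monotone shrink-and-refit loop was tried first and ratchets
onto runaway Rg values at low signal-to-noise.

**χ² comparator.** Exactly 1/(N−1) Σ[(I_exp − c·I_calc)/σ]² with the
closed-form optimal c = Σ(I_exp I_calc/σ²)/Σ(I_calc²/σ²); N−1, not N−p.
It is invariant under common rescaling of (I_exp, σ) and any rescaling of
I_calc.

**Frames per 1-s window.** The per-window maximum is derived from the
configured pulse structure (pulses/train × trains/s); the package does not
hard-code a count.

**Containers.** Frame stacks persist as RDS (the package's native
container); averages as pairs of 32-bit integer TIFFs (`*_sum.tif`,
`*_count.tif`); profiles as 3-column ASCII `.dat`; geometry as YAML;
reports as JSON.

## Problem sizes used by the tests

Unit tests run on a 16-module 8×8-pixel geometry; the end-to-end
conditions use the default 16×16 geometry with 16 pulses per train: a 60-s
constant-concentration run for filtering, a 60-s autosampler elution run
for form-factor recovery (reduced χ² against ground truth within
[0.7, 1.3]), a 60-s run with 12%/min drift for the interpolation-vs-naive
comparison, and ten 40-s reservoir pairs for repeated Rg recovery. These
sizes give each assertion adequate statistical power at its stated
tolerance.

## Known limitations

* Frame rejection is frame-wise only; there is no in-image flare masking
  or inpainting, so a frame is either kept whole or dropped.
* The Poisson error model ignores residual multiplicative noise when pulse
  normalization is disabled; with train-level CVs of ~10% unnormalized
  averages carry excess variance that χ² will report.
* The elution model is a single Gaussian plug; overlapping peaks,
  column tailing and cross-contamination are out of scope.
* Dmax estimation inherits the usual ill-posedness of the indirect
  transform: on noisy data the plateau criterion has ~10% resolution, and
  the `no_knee` flag should be respected.
* The powder calibration assumes a flat, untilted detector and refines
  only beam centre and distance.
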