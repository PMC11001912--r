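---
title: "Reference-channel Raman processing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-channel Raman processing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reframan)
```

## The instrument concept

`reframan` implements the processing chain of a dual-channel dispersive
Raman spectrometer built around a deliberately *non-stabilized* diode
laser. Instead of stabilizing the laser's temperature and power, the
instrument splits the excitation beam and records, on the same CMOS
sensor and in every exposure, a second spectral band: the Raman spectrum
of a polystyrene chip mounted inside the spectrometer. Everything the
laser does wrong — thermal wavelength drift, abrupt mode hops between
Fabry-Perot cavity modes, power fluctuation — is imprinted identically on
this reference band and can be measured and corrected per acquisition:

1. **Raman-shift calibration.** Prominent polystyrene lines are fitted in
   the reference band; each line's known shift turns its fitted absolute
   wavelength into a vote for the laser wavenumber. The same correction is
   applied to the main channel.
2. **Intensity normalization.** The integrated area of a designated strong
   reference line tracks the delivered laser power during the exact
   exposure; dividing by it cancels power fluctuation.
3. **Anti mode-hop deconvolution.** A hop inside one exposure superimposes
   a shifted copy of the spectrum; the few-spike pixel kernel is estimated
   from the reference band and removed from the main band by
   Richardson-Lucy iteration.
4. **Deblurring.** The spectrometer's line-spread (apparatus) function,
   measured once from a diamond line of known natural width, is
   deconvolved to recover resolution sacrificed to a wide slit.

Two further reference-channel by-products are implemented: SERDS-style
fluorescence separation (the natural wavelength drift plays the role of a
shifted-excitation source) and drift-averaging of static pixel-to-pixel
quantum-efficiency (QE) variation. A PLS quantification layer with
detection limits closes the chain from frames to concentrations.

## The frame simulator

Every stage is testable without hardware because the package ships a
physics-based renderer of the instrument's 16-bit CMOS frames
(`render_frame()`). Its defaults encode the instrument as built: a 785 nm
fingerprint laser and a 675 nm high-frequency laser (200 mW, 0.2 nm
linewidth), a 64 x 2000 sensor with 4 um binned pixels, a quadratic
pixel-to-wavelength map spanning roughly 800-960 nm, an apparatus width
from the 5.4 um slit image convolved with the 4 um pixel aperture, 92%
optical throughput, and a spectral QE falling from 60% at 840 nm to 40%
at 940 nm. The fingerprint configuration covers 400-2300 cm^-1 (a 785 nm
laser cannot reach 2700 cm^-1 inside an 800-960 nm band), the 675 nm
laser covers 2700-4000 cm^-1.

The stochastic ingredients are: exponential-approach thermal drift
`lambda(t) = lambda0 + drift * (1 - exp(-t/tau))`; Bernoulli mode hops of
one cavity free spectral range (default 0.1 nm — typical for these
diodes; within an exposure a hop produces a two-component emission state
with a uniform random exposure split); AR(1) relative power fluctuation;
Poisson shot noise; Gaussian dark+read noise (default 12 counts/pixel at
1 s — not a printed device figure, chosen so that desk-scale
row-compression experiments are dark-noise-dominated at the documented
settings); optional hot pixels; and a static multiplicative per-pixel QE
gain map (relative sd 0.1-0.5%), drawn once per instrument because real
QE variation does not average out over repeated frames. The default
reference-band amplitude puts the SNR of a 1 s reference spectrum
(1001 cm^-1 amplitude over the 1700-2100 cm^-1 RMS) near the ~1250 the
physical instrument reaches.

What the simulator does *not* emulate: diffraction and stray light,
speckle, sensor smear/blooming, cosmic rays, wavelength-dependent
apparatus asymmetry, and any radiative-transfer account of spatially
offset scattering (the out-of-focus fluorescence band amplitude is a free
parameter). Passing tests therefore demonstrate that the algorithms
recover the truth of *this* forward model at realistic noise levels; they
do not certify performance on phenomena outside it.

Reference line positions for polystyrene are the ASTM E1840 consensus
values; the relative intensities and widths shipped with the package are
nominal values for a 785 nm instrument, not certified data.

## Wavenumber calibration

The pixel-to-wavelength map is treated as known (the optics are
monolithic); only the laser wavenumber is re-estimated per acquisition.
Each catalog line is fitted with a pseudo-Voigt plus constant baseline in
a window of +-1 nm around its predicted pixel. The per-peak laser
wavenumber votes `1e7/lambda_fit + shift_known` are aggregated by the
median with one MAD-based rejection pass (> 3 x MAD) — robust to a single
corrupted peak, exact for consistent translations. Fewer than three
usable peaks raises a calibration-degraded error; residual spread above
5 cm^-1 raises an unstable-calibration error. Calibrated spectra live on
a uniform 0.5 cm^-1 grid over 400-4000 cm^-1 (at least ten points per
7 cm^-1 resolution element).

Under the simulator's warm-up drift (0.3 nm, tau = 60 s) the laser is
recovered to well within 1.5 cm^-1 and main-channel peak positions stay
within +-2 cm^-1 of catalog — the tolerances the physical instrument
specifies — with large margin at nominal SNR.

## Intensity normalization

The scale is `baseline_area / area_i`, where the area of the 1001.4 cm^-1
polystyrene line is integrated above a linear baseline anchored on the
*medians* of two flanking bands. One strong line is preferred over the
whole band because it is robust to residual fluorescence; median anchors
are preferred over edge points because a single noisy edge pixel
otherwise dominates the area error. The 785 nm and 675 nm ranges are
normalized independently; no cross-scaling between the two lasers is
attempted when ranges are concatenated.

## Mode-hop kernel estimation and deconvolution

The kernel is estimated by non-negative least squares over integer pixel
offsets (+-7 by default), restricted to columns where the clean reference
carries signal — noise-only columns would otherwise dominate both the fit
and the residual check. The default applies *no* Tikhonov smoothing
across kernel taps: shifted copies of the reference spectrum are nearly
collinear, so any smoothing penalty spreads a genuine two-spike kernel at
almost no residual cost and biases the recovered weights. A
discrepancy-principle smoothing mode (`lambda = "auto"`) remains
available for dense kernels. A residual above 10% of the observed band
energy raises a kernel-unreliable error, which also catches signal-free
input.

One physical caveat motivates the support restriction: a laser jump of
`d lambda` moves a scattered line by `d lambda * (lambda_line /
lambda_laser)^2`, so the pixel kernel is only shift-invariant to first
order across the band. Estimating it where the reference lines live (and
applying it to the overlapping main band) keeps the approximation at the
sub-pixel level.

Both the hop correction and the deblurring stage use Richardson-Lucy
iteration (default 30 iterations, early stop when the relative change per
iteration falls below 1e-5). Richardson-Lucy was chosen over Wiener or
Tikhonov inverses because it preserves non-negativity and conserves flux
— the two constraints that matter for count spectra; both properties are
asserted to 0.1% in the tests for spectra that decay to baseline at the
grid edges.

## Apparatus function and resolution accounting

`estimate_apparatus_function()` deconvolves the known 1.8 cm^-1
Lorentzian natural width of the first-order diamond line out of its
measured profile by regularized Fourier division. The denominator adds a
Wiener-style term proportional to the estimated per-point noise power on
top of a small relative floor (1e-4): without it, frequencies where the
Lorentzian transform has decayed below the noise floor dominate the
division and the recovered width becomes unstable under 1% noise. The
result is clipped to non-negative, renormalized to unit area, and
column-invariance is assumed (a single worst-case apparatus profile, as
the instrument reports a single resolution figure).

Fitted widths use the pseudo-Voigt (Thompson-Cox-Hastings mixing on the
Olivero-Longbothum combined FWHM, accurate to fractions of a percent —
well below the 2% recovery tolerance asserted in the tests). The
ASTM-style resolution estimate removes a known intrinsic width in
quadrature: `resolution = sqrt(measured^2 - intrinsic^2)`; with a
measured 7.4 cm^-1 Voigt width and a 3.35 cm^-1 intrinsic width this
yields 6.6 cm^-1. The 3.35 figure is back-derived from that printed pair,
not a measured constant.

## SERDS separation

On the calibrated shift axis, Raman features are pinned (the calibration
already compensated the drift) while fluorescence — fixed in absolute
wavelength — slides by the per-acquisition excitation offset
`delta_i = nu_i - nu_1`, which the reference channel provides for free.
The separation solves

    min over R >= 0, F of sum_i || S_i - R - F(s - delta_i) ||^2
                          + lambda || D2 F ||^2

by alternating a non-negative update of R with a linear solve for F
(sparse banded systems; linear-interpolation shift operators with edge
clamping so constants map to constants).

Two numerical choices deserve comment, because the objective is nearly
degenerate: adding a smooth term to R and removing it from F changes the
residual only through `F(s - delta_i) - F(s)`, which is tiny for smooth
functions and small offsets.

* **Initialization from differences.** The static R cancels *exactly* in
  between-acquisition differences, so F is first estimated from those
  alone; the alternation then refines near that point instead of wandering
  along the degenerate valley.
* **Smoothing weights by the discrepancy principle.** Both the difference
  solve and the joint solve pick the strongest smoothing whose residual
  stays at the noise level estimated from the data's high-frequency
  content. A fixed effective-degrees-of-freedom target (of order 10) was
  tried first and rejected: it is calibrated against the full-data
  operator, over-smooths the much weaker difference operator, and biases
  polynomial fluorescence into R.

The remaining additive ambiguity is resolved by convention: a separated
solid-state Raman spectrum returns to zero between lines, so the smooth
lower envelope of R (rolling minimum, then spline-smoothed) is
transferred into F, and R is reported non-negative with a zero baseline.
The `fluorescence_penalized` field preserves the raw penalized solve for
diagnostics. A classical two-spectrum difference mode is available for
comparison (`mode = "difference"`). On the package's standard synthetic —
polypropylene lines under a 4th-order polynomial fluorescence at five
times the line amplitude, five acquisitions spanning 4 cm^-1 — the
recovered Raman component correlates with truth above r = 0.99 and peak
areas are recovered within 5%.

## QE drift-averaging

Static pixel-to-pixel QE variation appears, after calibration, as a
high-frequency pattern that *shifts with the laser*: each acquisition
samples the pattern at a different pixel alignment. `drift_average()`
takes the pointwise mean of recalibrated spectra and reports a
high-frequency noise metric (sd of the residual from a Savitzky-Golay
smooth, window 11, order 3, in a peak-free window) before and after. For
independent alignments the metric falls as `sqrt(M)`; with no drift it
does not fall at all, which the function flags.

## Quantification

PLS1 (NIPALS, mean-centered) maps spectra to concentrations. The
component count minimizes the cross-validated RMSE under a
one-standard-error rule, with all replicates of a concentration level
held out together so replicate correlation cannot leak. No SNV or other
preprocessing is applied by default — quantification is meant to be
attributable to the instrument chain's own calibration. Detection limits
use the 3-sigma/10-sigma convention, `LoD = 3 sd(predicted blanks) /
slope`, with the slope from a low-range linear fit of predicted versus
true concentration; the convention is recorded in the result because
LoD/LoQ conventions differ across the field. Mapping acquisitions (SERS
chips) are averaged pointwise over unmasked map points before
quantification.

## Problem sizes and tolerances

The test-suite and acceptance simulations use 64 x 2000-pixel frames,
warm-up sequences of 10-50 frames, 500 replicates for the
row-compression experiment, and Monte-Carlo loops of 12-25 seeds — sizes
at which every stochastic assertion has comfortable margin while the
whole suite runs in well under a minute per module. Key numerical
defaults: Richardson-Lucy 30 iterations / 1e-5 early stop; hop-kernel
support +-7 pixels; SERDS alternation capped at 50 iterations with a
1e-6 relative-objective tolerance (the cap exists because the degenerate
valley admits a slow objective creep that the final baseline convention
renders irrelevant); hot-pixel removal at 8 robust sigmas *and* 30% of
the local value, so single-pixel spikes are removed while resolved lines
of any brightness survive.

## Known limitations

* The mode-hop kernel is treated as column-invariant; the `(lambda_line /
  lambda_laser)^2` magnification makes this exact only locally.
* SERDS identifiability rests on the offsets spanning at least one grid
  step; the zero-baseline convention assigns any genuinely smooth Raman
  background (e.g. amorphous phases) to the fluorescence component.
* The simulator's dark noise level and the SERS/fluorescence amplitudes
  are plausible settings, not measured device constants; conclusions that
  depend on their absolute values (rather than scaling laws) should be
  re-derived for a specific device.
* Detection limits computed on training-set predictions share the usual
  optimism of that practice; the package follows the field's convention
  rather than correcting it.
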