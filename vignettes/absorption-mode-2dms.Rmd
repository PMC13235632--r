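---
title: "Absorption-mode processing of two-dimensional FT-ICR mass spectra"
author: "ftms2d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absorption-mode processing of two-dimensional FT-ICR mass spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftms2d)
```

## The measurement and its model

Two-dimensional FT-ICR mass spectrometry correlates precursor and fragment
ions without isolation. An encoding pulse sequence modulates precursor ion
radii with an incremented delay $t_1$; because collision-free fragmentation
efficiency depends on precursor radius, every fragment's abundance is
modulated along $t_1$ at its precursor's *modulation frequency* — the
precursor's cyclotron frequency minus a fixed encoding offset. One transient
is detected per $t_1$ increment. Fourier transformation along the detection
time $t_2$ (the direct, fragment dimension F2) followed by a second
transformation along $t_1$ (the indirect, precursor dimension F1) yields a
2D map whose horizontal coordinate is fragment frequency (m/z) and whose
vertical coordinate is precursor modulation frequency (m/z).

The synthetic-data generator (`generateDataset2d`) implements exactly this
signal model. Each fragment line contributes

$$ s(t_1, t_2) \;=\; E\,\frac{1 + \cos(2\pi\nu_1 t_1 + b_0 + b_1\nu_1)}{2}\,
   \cos\!\big(2\pi\nu_2 t_2 + a_0 + a_1\nu_2 + a_2\nu_2^2\big)\,
   e^{-t_2/\tau}, $$

with $\nu_1$ the precursor modulation frequency, $\nu_2$ the fragment's
detected cyclotron frequency, and $E$ the product of abundance and
fragmentation efficiency. A linear efficiency-versus-radius law gives the
$(1+\cos)/2$ amplitude factor, which places all encoded signal at the
fundamental modulation frequency; nonlinear laws would add harmonics and are
deliberately out of scope. Unfragmented precursor intensity (one minus the
summed fragment efficiencies, floored at zero) is emitted as a
self-fragment, which populates the autocorrelation line. The $t_1$ signal is
purely real — amplitude modulation without phase cycling — so the F1
transform is a real-to-complex FFT and the F1 spectrum of every column
carries a strong zero-frequency ridge from the constant term of
$(1+\cos)/2$. That ridge is physical, not an artifact of the simulator, and
analysis routines must avoid it (the peak picker works on interior local
maxima; oracle tests search near the expected bin).

White Gaussian noise of standard deviation `noiseSigma` models detector
noise; *scintillation noise*, Gaussian with standard deviation proportional
to the instantaneous signal (`scintFraction`), models the
intensity-dependent noise observed along the indirect dimension. The
generator does not model ion-cloud physics, space charge, harmonics or
radius-dependent isotope-pattern distortion; passing tests therefore
demonstrate the correctness of the processing chain, not instrument realism.

## Phase correction and absorption mode

In absorption mode the displayed spectrum is the phase-corrected real part
of the complex spectrum; lines are narrower and the noise floor lower than
for the modulus. The phase to remove is quadratic in the detected F2
frequency, $\varphi_2(f) = a_0 + a_1 f + a_2 f^2$ (excitation-sweep plus
instrumental delays), and linear in F1, $\varphi_1(f) = b_0 + b_1 f$.
Correction multiplies each spectral point by $e^{-i\varphi(f)}$ with $f$ the
absolute axis frequency in Hz, never the bin index. The two coefficient
sets are independent.

`optimizePhaseF2`/`optimizePhaseF1` estimate the coefficients from resolved
peaks: the complex phase at each peak bin is measured, unwrapped across
peaks ordered by frequency, fitted with the phase model, and refined by
Nelder–Mead on an objective that maximizes summed real-part peak height
minus the integrated absolute negative baseline in ±10-bin neighborhoods
(penalty weight 1). The seeding step makes recovery on clean data
essentially exact; the refinement matters for noisy or partially overlapped
peaks. F1 estimation accepts a list of precursor ion scans and sums them
first — fragment phases evolve identically in $t_1$, so summation improves
the estimate when single scans carry few peaks. At least three peaks are
required for the quadratic fit and two for the linear one.

One convention worth stating: a real nonnegative apodization window
contributes no phase at a line's exact frequency, so on-bin synthetic lines
phased with the generator's own coefficients give purely real peak values
even after windowing. Off the exact center the window's group delay twists
the phase across the line profile; on real data that twist is simply part
of what the optimizer absorbs. For amplitude-modulated (cosine-encoded)
data the intra-line F1 twist cannot be removed by any global linear phase —
it narrows the main lobe and produces the characteristic negative
side-lobes of absorption-mode precursor scans.

## Apodization

The default F2 window is the asymmetric rise-and-fall window
(`kv_asymmetric`): a half-cosine rise from zero reaching 1 at a fraction
$F$ of the transient, then a half-cosine fall to zero. Zeroing the start of
the transient suppresses the baseline oscillation that phase correction
otherwise amplifies. $F = 0.25$ is the default, the value found optimal for
ICR transients. The `kv_asymmetric_sqrt_fall` variant takes the square root
of the falling branch only, keeping more late-transient signal when the
acquisition cuts the decay short; it is the pipeline default. The falling
branch is implemented as the half-cosine mapping of $[NF, N-1]$ onto
argument $[\pi, 2\pi]$; a literal reading of the printed two-branch formula
is discontinuous at $n = NF$ for general $N$ and $F$, so the geometric
intent (rise to the maximum at $F$, fall to zero) is what is implemented,
with the printed form recorded in the source comment. $NF$ rounds to the
nearest integer, ties down. Magnitude-mode processing defaults to the
standard shifted sine bell.

At desk-scale grid sizes an additional choice appears in F1: with only a
few hundred encoding increments, the $1/x$ leakage tails of an unwindowed
(rectangular) F1 transform — dominated by the zero-frequency ridge — exceed
the white-noise floor near peaks. The comparison and scatter tests
therefore apodize F1 with a sine bell in both modes; with thousands of
increments (as in real acquisitions) the unwindowed absorption F1 of the
baseline-corrected scans is the better choice, which is why the pipeline
leaves `apodF1` configurable and defaults it to `none`.

## Zerofilling and digitization

`zerofill(scan, n)` doubles the time-domain length $n$ times. The
frequency-domain point spacing is `axisPointSpacing(dt, nFreqPoints)` =
$(1/2\,dt)/n_\text{freq}$: with the 2 µs $t_1$ increment, 8192 F1 points
give 30.5 Hz and 16384 give 15.3 Hz. Published spacings quoted per
"number of zerofills" are reproduced here through explicit point counts,
because successive-doubling conventions differ between programs. Finer
digitization does not add information but reduces centroid interpolation
error: the acceptance suite reconstructs the two-precursor experiment in
which ions 36 mDa (24 Hz at 15 T) apart are assigned correctly only once
the F1 spacing drops from ~31 Hz to ~15 Hz.

## Autoregressive baseline correction

The first points of each $t_1$ column accumulate phase fastest and are most
corrupted; their errors spread as baseline oscillation across the precursor
ion scan. The signal is a finite sum of exponentially damped sinusoids
$x(n) = \sum_k \alpha_k z_k^n$, $z_k = e^{\gamma_k + i\omega_k}$, so a clean
trailing segment determines the initial points. `fitARBackward` fits
backward linear prediction coefficients ($x(n) = \sum_{k=1}^p c_k x(n+k)$)
by least squares with singular values truncated at $10^{-10}$ of the
largest — Eq-4-style exact-pole models are ill-conditioned under noise —
takes the poles as roots of the prediction polynomial and fits complex
amplitudes. `replaceInitialPoints` rebuilds the first $P$ points from the
parametric model, which is exact on noiseless $p$-pole signals and does not
accumulate recursion error. The default order is twice the number of
spectral peaks above 3× noise (each real damped cosine is a conjugate pole
pair), clipped to $[2, N/4]$; $P$ defaults to the number of phase rotations
of the fastest precursor signal, which is data-set specific and therefore a
config value rather than a derived one.

## Calibration and m/z

Frequency-to-m/z conversion is the two-term ICR law $m/z = c_1/f +
c_2/f^2$; the quadratic term absorbs magnetron/space-charge shifts rather
than modelling them physically. `fitCalibration` is exact with two
calibrants and least-squares beyond; inversion solves the quadratic in $f$
and keeps the root nearest the ideal $c_1/(m/z)$. Physical constants are
CODATA 2018 — with them the package reproduces reference ion masses (e.g.
protonated ergocryptine fragment C32H42N5O5+ at 576.31805) to five
decimals, and the 36 mDa pair at m/z 592.29182/592.25542 differs by 24 Hz
at 15 T. Frequency axes are stored ascending; m/z values are derived for
display (`scanMzValues`), descending as frequency ascends. The F1 axis
holds modulation frequencies; the acquisition's `f1Offset` restores
absolute cyclotron frequency before conversion.

## Out-of-core processing

Both processing passes stream the grid: the row pass apodizes, zerofills,
transforms and (in absorption mode) phases one transient at a time, writing
the two F2 quadrature planes; the column pass reads column blocks sized so
that one iteration's footprint stays within about four rows'/columns' worth
of values, applies optional baseline correction and F1 windowing, performs
the F1 transform, and keeps either the phased real part (absorption) or the
hypercomplex modulus $\sqrt{rr^2 + ri^2 + ir^2 + ii^2}$ (magnitude, which is
invariant under any phase coefficients and therefore skips the phase
multiply entirely). Storage backends are a row-major flat-binary file with
a text sidecar (the documented stand-in for vendor "ser" files), a chunked
HDF5 layout (chunk shape aligned with the row pass), or plain memory for
small grids. Accessors are instrumented: `withMemoryTracking` verifies that
a full pipeline run never materializes more than $4\max(N_1,N_2)$ values in
any processing cycle.

## Analysis

Noise is the mean absolute intensity over an empty segment (user-chosen, or
automatically the lowest-mean window); SNR divides the peak intensity by
it. Resolving power interpolates the half-maximum crossings linearly on the
frequency axis, $R = f/\Delta f_\text{FWHM} = m/\Delta m$. The 2D peak
picker streams three rows at a time, takes 8-neighborhood local maxima
above threshold×noise (ties keep the lower index), and centroids each
dimension independently with a 3-point parabola, falling back to the apex
bin when a neighbor is negative or the parabola degenerate. Output ordering
is deterministic by (precursor m/z, fragment m/z).

## Problem sizes and what the tests show

The test and acceptance suites use grids between 16×64 and 4096×256:
large enough that lines, leakage and digitization behave as in real data,
small enough that the full suite runs in about two minutes on one CPU. On
matched synthetic data with each mode's window the suite verifies per-
dimension FWHM and SNR gains of at least 1.5× for absorption over
magnitude (the theoretical hypercomplex gain is 2), recovery of every
ground-truth precursor–fragment pair within one bin per dimension on a
64×4096 grid, backward-prediction reconstruction of corrupted initial
points to below $10^{-6}$ relative, and a smaller precursor-m/z scatter
across one precursor's fragments in absorption than magnitude mode. These
are statements about the processing chain under the stated signal model;
headline instrument-scale figures (e.g. resolving powers near $2\times
10^5$) require the original data sets and are treated as directional
expectations only.

## Known limitations

* The F1 line shape of amplitude-modulated data retains the intrinsic
  phase twist; no global linear correction can flatten it, and centroid
  accuracy at coarse digitization is limited by the twisted profile.
* Automated phasing assumes resolved, reasonably unwrapped peak phases;
  heavily aliased phase ramps need a better starting point than the
  built-in grid seed.
* The flat-binary dialect and HDF5 layout are self-describing but
  intentionally independent of any vendor format; no proprietary metadata
  is parsed.
* Single-process only; the out-of-core design makes parallelism possible
  but it is not implemented.
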