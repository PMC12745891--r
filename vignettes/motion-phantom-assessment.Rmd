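---
title: "Assessing respiratory-binned 4D-MR and 4D-CT displacement accuracy with a simulated motion phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing respiratory-binned 4D-MR and 4D-CT displacement accuracy with a simulated motion phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motion4d)
```

## The measurement problem

Radiotherapy planning for abdominal tumors needs a reliable estimate of how
far a lesion travels with breathing.  4D-CT, the clinical standard, sorts
cine images into respiratory phases from a surrogate signal; radial
stack-of-stars 4D-MR instead sorts individual radial k-space views into
amplitude bins from a self-navigation signal.  Both pipelines measure
"displacement" as the shift of the lesion between the end-inhale and
end-exhale reconstructions, but they average the underlying motion very
differently, and acquisition parameters (radial views, bin count, slice
thickness, orientation) modulate the artifact burden that the measurement
has to survive.

`motion4d` reproduces this whole measurement chain in software: a
contrast-sphere phantom moving along the superior-inferior (SI) axis
according to a programmable respiratory trace, binned MR and CT
acquisitions of it, the line-profile/FWHM displacement read-out, and the
statistical comparisons used to rank protocols.  Because every stage is
synthetic, each measured number has an analytic oracle, and the mechanistic
claims (streaks grow as spokes-per-bin shrink, amplitude binning truncates
extremes, through-plane motion blurs edges) can be tested rather than
asserted.

## The phantom and its motion

The phantom is a 30 mm sphere at 1.5:1 signal intensity relative to the
surrounding water, oscillating along SI
(`phantom_spec()`).  Drive waveforms are either sinusoids -- 6 and 10 mm
peak-to-peak at 2.4, 4 or 12 s periods, matching the clinical
ITV/breath-hold decision thresholds and the span of observed breathing
rates -- or synthetic patient-like traces in three regularity classes
(`generate_patient_trace()`):

* **regular**: near-sinusoidal `cos^4` breathing with a sharp inhale and a
  broad exhale plateau, 2% period and 3% amplitude jitter;
* **semiregular**: phase-stable breathing whose amplitude drifts gradually
  to about 65% of its starting value;
* **irregular**: strong period/amplitude jitter (18% / 20%, AR(1)
  autocorrelation 0.7) plus at least one transient sharp inhale of about
  3x the typical excursion and one end-exhale pause of 4-6 s.

The jitter magnitudes are chosen so that the three generated classes fall
on the right side of the classifier thresholds below while staying within
the range of clinically reported cycle-to-cycle variability; they are fixed
defaults, not fitting targets.  A peak-to-peak displacement is always the
full excursion (the "displacement" of a 10 mm waveform is 10 mm), the
reading that is consistent with ITV margins and edge-to-edge FWHM
differences.

Phantom programming scales each waveform so that the **mean of the
per-cycle maximum amplitudes** -- peak-to-trough excursion per cycle, not
peak above baseline -- equals the target (`scale_to_mean_amplitude()`).
Scaling to the raw maximum would let a single sharp inhale (sometimes more
than 3x the typical cycle) compress all regular breathing into the bottom
of the amplitude range.

Cycle detection (`detect_cycles()`) uses local extrema with a topographic
prominence threshold of 20% of a robust peak-to-peak reference
(`min(range, 2*sqrt(2)*SD)`; equal to the range for a sinusoid, but not
inflated by amplitude spikes) and a 1 s minimum peak separation -- wide
enough to reject cardiac-scale ripple, narrow enough to resolve 2.4 s
breathing.  Regularity classification (`classify_pattern()`) uses
coefficients of variation of cycle excursion and period: both below 0.10
is regular; either above 0.25, or any single excursion above twice the
median, is irregular; anything between is semiregular.  The thresholds are
exposed as arguments.

## Respiratory binning

`amplitude_bins()` divides a robust amplitude range (1st-99th percentile,
outliers clamped into the edge bins) into `n_bins` equal-width bands;
bin 0 is end-exhale.  Equal width, rather than equal occupancy, mirrors
how a vendor reconstruction defines an "amplitude region", and the robust
range keeps spike cycles from squeezing normal breathing into few bins.
Inhale and exhale samples of equal amplitude share a bin: amplitude
binning ignores hysteresis by construction.

`phase_bins()` assigns each sample its elapsed cycle fraction between
consecutive end-inhale peaks, with bin 0 *centred* on the peak (window
`[-1/(2n), 1/(2n))`).  Centring makes the CT end-inhale phase bin directly
comparable to the MR end-inhale amplitude bin; partial leading/trailing
cycles are extrapolated with the mean period.

For a sinusoid these definitions have closed forms that the tests use as
oracles: with 10 amplitude bins the top bin holds
`(pi - 2 asin(0.8)) / (2 pi) = 0.2048` of the samples with centroid
`0.9324 * (pp/2)`; the end-inhale phase bin of a 10-phase sort has mean
position `sin(pi/10)/(pi/10) = 0.9836 * (pp/2)`.  The occupancy-weighted
mean of the top amplitude bin is what an amplitude-binned reconstruction
effectively images, which is why measured MR displacement is non-decreasing
in the number of bins and sits below both the CT estimate and the
programmed motion.

## The MR forward model

`simulate_mr()` generates stack-of-stars k-space analytically: golden-angle
(111.246 deg) radial spokes in-plane, Cartesian partition encoding
through-plane, partitions looped inside each angular shot at one sample
per TR (4.03 ms).  Each k-space sample is the exact 3D Fourier transform
of the object at that sample's acquisition time: a static water-bath
sphere (80 mm, the signal-producing surround) plus the contrast sphere
displaced by the trace's instantaneous SI position.  Shots are routed to
amplitude bins by the surrogate value at the shot midpoint, and each bin
is reconstructed independently: Kaiser-Bessel convolution gridding (width
4, oversampling 1.5, standard minimum-error shape parameter) with ramp
density compensation in-plane, followed by a Cartesian transform across
partitions.  Complex Gaussian noise is added per k-space sample; the
default level (`noise_sigma = 0.006` of the bath's DC signal) was chosen
to give a background SNR of roughly 30 for the static, fully sampled
phantom.

This analytic-k-space design means the simulator reproduces exactly the
artifact classes the measurement is exposed to, with no inverse crime:

* too few spokes per bin leave azimuthal gaps that alias as streaks, so
  streak level rises with bin count and falls with radial views;
* motion within a bin's amplitude band mixes object positions, blurring
  the sphere edge by the bin's position distribution;
* in **axial** scans the SI motion modulates the *partition* phase, so the
  blur lands through-plane where sampling is coarsest (slice thickness),
  while in **coronal** scans it lands in-plane where the PSF is sharper --
  the mechanism that makes coronal SI edge gradients steeper;
* finite partition coverage gives genuine slice-direction ringing and
  partial-volume behaviour.

At desk scale the default grid is a 128-point matrix over a 300 mm
in-plane field of view (2.34 mm voxels) with thirty 3 mm partitions over a
90 mm slab.  The field of view is reduced from the clinical 450 mm so that
the in-plane voxel stays *finer* than the slice thickness; preserving that
resolution ordering (clinically 1.5 mm in-plane vs 3 mm slices) is what
keeps the axial/coronal comparison mechanistically faithful at reduced
matrix size.  The full 256-point matrix is available through
`acquisition_params()`.

`simulate_ct()` is deliberately simpler, reflecting how a phase-sorted CT
behaves for a rigid phantom: each phase volume is a snapshot rendering at
the occupancy-weighted mean position of that phase bin (2.5 mm slices by
default).  An opt-in mis-sorting mode draws every slice's position
independently from the bin's position distribution, emulating
cine-segment sorting artifacts; it is off by default because its
magnitude is not constrained by any quantitative reference.

## The displacement read-out

`extract_profile()` samples the volume along an SI line through the
programmed rest-centre coordinates -- the identical same-coordinate line
for every bin, deliberately *not* re-centred per bin.  `fwhm_edges()`
locates the sphere edges at the baseline-corrected half-maximum level
`background + (peak - background)/2`, with the background estimated as the
median of the outer 20% of profile samples.  Baseline correction is forced
by the phantom's 1.5:1 contrast: a raw `max/2` level (0.75 of background)
would sit below the water signal and never cross the profile.  Edges are
localised by linear interpolation between the bracketing samples, which is
exact on linear (partial-volume) ramps; with several crossings the pair
bounding the dominant plateau is used, and multiple substantial plateaus
raise an ambiguity error rather than guessing.

`measure_displacement()` differences the superior and inferior edges
between the end-inhale and end-exhale bins and summarises them as the mean
of the absolute shifts.  The combination rule is configurable
(`mean`, `sup`, `inf`, `max`) because a single-number-per-scan convention
is not uniquely determined; the mean is the default as the symmetric
choice.  The measure is symmetric under swapping inhale and exhale.

## Statistics

Parameter sweeps are compared with Welch's heteroscedastic ANOVA
(`welch_anova()`, delegating to `stats::oneway.test`) followed by
Games-Howell pairwise tests (`games_howell()`, Welch-type standard errors
with studentized-range adjustment -- implemented here because no installed
package provides it).  Eta-squared is computed from the *classical*
between/total sums of squares, the convention when an effect size is
reported next to Welch's F, and Cohen's f follows as
`sqrt(eta2/(1-eta2))`; replicate scans are treated as independent
measurements.

Patient-waveform comparisons use a linear mixed-effects model
(`lmm_compare()`, via `lmerTest`): displacement against protocol with a
random intercept per waveform, REML estimation, Wald 95% intervals
(`estimate +/- 1.96 SE`) and Satterthwaite p-values.  The random-effects
structure is intercept-only -- the minimal structure that absorbs the
waveform-specific programmed amplitude -- and is the assumed default
rather than a derived fact; the protocol contrast table also reports a
`waveform_mean` pseudo-protocol (the programmed mean amplitude entered as
data), so the reference protocol's distance from the programmed motion
appears as a fixed effect of its own.  A singular fit falls back to a
per-waveform paired summary with a warning instead of failing.

## In-vivo table arithmetic

`organ_tables()` rebuilds the per-patient organ displacement tables
(box-ROI translations per anatomical direction, Euclidean norms,
per-direction means, CT-minus-MR differences) from the packaged
per-patient fixture.  All table arithmetic uses exact decimal half-up
rounding at one decimal (`round_half_up()`; 4.85 -> 4.9, 4.05 -> 4.1),
which binary-float rounding would not reproduce, and the difference table
is computed from the one-decimal printed means, with which it is exactly
consistent.  Several printed kidney means (and one liver Euclidean) are
*not* reproducible from the printed per-patient values -- the source
tables were evidently computed from unrounded data, and the kidney
per-patient Euclidean values are averages of left/right kidney norms
rather than norms of averaged components.  These cells are surfaced in a
`flags` table rather than silently matched.  `roi_translation()` provides
the measurement-side estimator: normalised cross-correlation of a box ROI
over integer shifts with quadratic sub-voxel peak interpolation.

## Reproducibility and problem sizes

Every stochastic stage (k-space noise, scan-start phase, CT mis-sorting
draws) is seed-controlled, and the experiment runners derive one
deterministic seed per scan from a master seed and the scan's position in
the design, so repeated runs are byte-identical.  Replicate-to-replicate
variability is physical: each repeated scan starts at a seeded random
point of the breathing cycle.

The test-suite problem sizes are the package's own defaults: 128-point
matrix simulations with 600-3000 spokes for the simulator identities and
mechanistic orderings (four replicates per condition), millisecond-sampled
traces for the binning oracles, 2000 replications for the type-I-error
calibration and a 9-waveform x 5-replicate design for the mixed-model
recovery checks.

## What passing tests do and do not show

The synthetic phantom reproduces the *mechanisms* that determine
displacement accuracy -- binning truncation, undersampling streaks,
orientation-dependent blur, partial volume -- under exactly known ground
truth.  It does not emulate vendor reconstruction details (self-navigation
extraction, regularised iterative reconstructions), B0/B1 or fat-saturation
physics, hysteresis loops (the trace is one-dimensional by design),
deformable anatomy, or helical CT geometry.  Agreement of the simulated
protocol rankings with scanner-derived rankings is therefore a mechanistic
consistency check, not a validation on real data; absolute displacement
values from the simulator carry the discretisation of their grids
(roughly a tenth of a voxel for the FWHM read-out) and should be compared
against the analytic oracles, not against scanner measurements.
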