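# motion4d

Simulation and displacement assessment of respiratory-binned 4D-MR and
4D-CT acquisitions of a moving contrast-sphere motion phantom.

## The problem

Radiotherapy planning for abdominal tumors (liver, pancreas, kidneys)
needs the extent of respiratory motion. The clinical standard, 4D-CT,
sorts cine images into respiratory **phase** bins; radial stack-of-stars
4D-MRI sorts individual radial k-space views into **amplitude** bins from
a self-navigation signal. Both report tumor displacement as the shift of
the lesion between end-inhale and end-exhale reconstructions, but they
average motion differently, and acquisition parameters -- number of radial
views, number of respiratory bins, slice thickness, acquisition
orientation -- change the artifact burden the measurement must survive.

`motion4d` reproduces this measurement chain end-to-end in software, for
physicists who want to rank protocols with known ground truth:

* **Waveforms** -- sinusoidal and patient-like surrogate traces
  (regular / semiregular / irregular), mean-of-maxima amplitude scaling,
  cycle detection and regularity classification
  (`generate_sinusoid()`, `generate_patient_trace()`, `classify_pattern()`).
* **Binning** -- amplitude-based (MR-style) and phase-based (CT-style)
  respiratory bins with analytic sinusoid oracles
  (`amplitude_bins()`, `phase_bins()`, `extreme_bins()`).
* **Acquisition simulation** -- golden-angle radial stack-of-stars MR with
  analytic 3D k-space, per-shot bin routing, Kaiser-Bessel regridding
  reconstruction and seeded k-space noise; snapshot phase-sorted CT
  (`simulate_mr()`, `simulate_ct()`, NIfTI I/O via `write_nifti_set()`).
* **Displacement read-out** -- SI line profiles through the sphere centre
  and baseline-corrected FWHM edge shifts between extreme bins
  (`extract_profile()`, `fwhm_edges()`, `measure_displacement()`).
* **Statistics** -- Welch ANOVA + Games-Howell with eta-squared / Cohen's
  f, and a linear mixed-effects protocol comparison with a random
  intercept per waveform (`welch_anova()`, `games_howell()`,
  `lmm_compare()`).
* **In-vivo table arithmetic** -- box-ROI organ translations, Euclidean
  norms, decimal half-up table means and CT-minus-MR difference tables,
  with inconsistent printed cells flagged (`organ_tables()`,
  `roi_translation()`).
* **Experiment harness** -- the one-at-a-time parameter sweep and the
  three-protocol comparison with deterministic per-scan seeding
  (`run_sweep()`, `run_protocol_comparison()`), plus a thin CLI at
  `scripts/motion4d.R`.

The core displacement statistic is the FWHM edge shift: with profile
intensity `I(s)` along the SI axis, edges are the crossings of
`background + (I_max - background)/2`, and

```
displacement = (|sup_in - sup_ex| + |inf_in - inf_ex|) / 2
```

For a sinusoid of peak-to-peak `pp` binned into `n` amplitude bins, the
end-inhale bin images the position band `[pp/2 (1 - 2/n), pp/2]`, so the
measured displacement approaches `pp` from below as `n` grows -- e.g. the
top-bin median position at `n = 10` is `0.949 pp/2`, against
`0.984 pp/2` for a 10-phase CT sort. These closed forms are the oracles
the test suite checks the simulator against.

## Worked example

Simulate the modified coronal 10-bin protocol and the clinical CT on a
10 mm, 4 s sinusoid and measure both:

```r
library(motion4d)

tr <- generate_sinusoid(pp_mm = 10, period_s = 4, duration_s = 60)

mr <- simulate_mr(tr, acquisition_params(n_spokes = 3000, n_bins = 10,
                                         orientation = "coronal", seed = 7))
measure_set_displacement(mr)
#> <displacement_measurement> 9.148 mm (mean of |sup| = 9.092, |inf| = 9.205)

ct <- simulate_ct(tr)
measure_set_displacement(ct)
#> <displacement_measurement> 9.967 mm (mean of |sup| = 9.966, |inf| = 9.969)
```

The MR estimate sits below the CT estimate and both below the programmed
10 mm: amplitude binning truncates the motion extremes (top-bin median
oracle 9.49 mm), while phase-sorted CT snapshots at the end-inhale bin
mean (oracle 9.84 mm); the residual differences are grid discretisation
of the FWHM read-out.

Rebuilding the in-vivo organ tables from the packaged per-patient
fixture:

```r
ot <- organ_tables()
subset(ot$differences, organ == "liver" & direction == "dZ")
#>   organ comparison direction difference_mm
#> 5 liver   CT-AX_MR        dZ           3.4
#> 6 liver  CT-COR_MR        dZ           2.3
nrow(ot$flags)   # printed cells not reproducible from printed inputs
#> [1] 20
```

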