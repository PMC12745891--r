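# Shared fixtures: constructed traces, analytic profiles and synthetic
# measurement tables.  Everything is generated in code at test time.

# concatenated single sinusoid cycles with per-cycle peak-to-peak values
make_piecewise_sine <- function(pp_values, period_s = 4, dt = 0.01) {
  a <- unlist(lapply(pp_values, function(pp) {
    tau <- seq(0, period_s - dt, by = dt)
    (pp / 2) * sin(2 * pi * tau / period_s)
  }))
  respiratory_trace(seq_along(a) * dt - dt, a, label = "piecewise")
}

# rectangular profile with edge samples at the half level (a step sampled
# exactly at the transition)
make_rect_profile <- function(bg = 1, peak = 1.5, edge = 15, pitch = 1.5,
                              extent = 45) {
  s <- seq(-extent, extent, by = pitch)
  I <- ifelse(abs(s) < edge, peak, bg)
  I[abs(abs(s) - edge) < pitch / 100] <- (bg + peak) / 2
  line_profile(s, I)
}

make_trapezoid_profile <- function(bg = 1, peak = 1.5, plateau = 11,
                                   ramp = 4, pitch = 1.5, extent = 45,
                                   center = 0) {
  s <- seq(-extent, extent, by = pitch)
  I <- bg + (peak - bg) *
    pmin(1, pmax(0, (plateau + ramp - abs(s - center)) / ramp))
  line_profile(s, I)
}

make_gauss_profile <- function(bg = 1, amp = 0.5, sigma = 6, pitch = 1.5,
                               extent = 45) {
  s <- seq(-extent, extent, by = pitch)
  line_profile(s, bg + amp * exp(-s^2 / (2 * sigma^2)))
}

# synthetic protocol-comparison table mimicking the published fixed-effect
# magnitudes: offsets 0 / -1.73 / -0.88 mm, waveform SD 1 mm, residual
# 0.5 mm, reference underestimates the programmed mean by 1.32 mm
make_lmm_table <- function(seed, n_waveforms = 9, replicates = 5,
                           offsets = c(MR_coronal_10bin = 0,
                                       MR_axial_5bin = -1.73,
                                       CT = -0.88),
                           waveform_sd = 1, residual_sd = 0.5,
                           mean_gap = 1.32) {
  withr::with_seed(seed, {
    wf <- sprintf("w%02d", seq_len(n_waveforms))
    re <- stats::rnorm(n_waveforms, 0, waveform_sd)
    names(re) <- wf
    tab <- expand.grid(waveform_id = wf, protocol = names(offsets),
                       replicate = seq_len(replicates),
                       stringsAsFactors = FALSE)
    tab$ground_truth_pp <- 10 + re[tab$waveform_id]
    tab$displacement <- tab$ground_truth_pp - mean_gap +
      offsets[tab$protocol] + stats::rnorm(nrow(tab), 0, residual_sd)
    tab
  })
}

# small, fast acquisition for structural simulator tests
tiny_acq <- function(...) {
  args <- utils::modifyList(
    list(n_spokes = 150L, n_bins = 2L, matrix = 32, fov_mm = 200,
         slab_mm = 72, slice_thickness_mm = 6),
    list(...))
  do.call(acquisition_params, args)
}
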