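# Displacement measurement: superior-inferior line intensity profiles
# through the sphere and full-width-at-half-maximum (FWHM) edge shifts
# between respiratory bins.

#' Construct a line profile
#'
#' @param s Positions along the line in mm, strictly increasing, uniformly
#'   spaced, length >= 8.
#' @param I Intensities at those positions.
#' @param axis Profile axis (only `"SI"` supported).
#' @param source_bin Bin id the profile was extracted from (0-based), or
#'   `NA`.
#' @return An object of class `line_profile`.
#' @export
line_profile <- function(s, I, axis = "SI", source_bin = NA_integer_) {
  s <- as.numeric(s)
  I <- as.numeric(I)
  if (length(s) < 8L || length(s) != length(I)) {
    stop("a line profile needs >= 8 (s, I) pairs", call. = FALSE)
  }
  ds <- diff(s)
  if (any(ds <= 0) || max(abs(ds - stats::median(ds))) > 1e-6) {
    stop("`s` must be strictly increasing and uniform", call. = FALSE)
  }
  structure(list(s = s, I = I, axis = axis,
                 source_bin = as.integer(source_bin)),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %s axis, %d samples over [%.1f, %.1f] mm\n",
              x$axis, length(x$s), x$s[1L], x$s[length(x$s)]))
  invisible(x)
}

#' @export
plot.line_profile <- function(x, ...) {
  graphics::plot(x$s, x$I, type = "l", xlab = "position (mm)",
                 ylab = "signal intensity", ...)
  invisible(x)
}

#' Extract the SI line profile through the sphere centre
#'
#' Samples the volume of one respiratory bin along a superior-inferior line
#' through the programmed rest-centre coordinates (the identical
#' same-coordinate line for every bin; the line is deliberately not
#' re-centred per bin).  Off-grid positions are linearly interpolated.
#'
#' @param set A [binned_image_set()].
#' @param bin_id Bin to sample (0-based).
#' @param center_mm Line anchor in volume coordinates (x, y, slice), mm;
#'   defaults to the sphere rest centre recorded in the set's provenance
#'   (origin otherwise).
#' @param half_length_mm Half-extent of the profile, mm.  The outer
#'   portions must reach background (water) for FWHM edge finding.
#' @param pitch_mm Sample spacing; defaults to the native voxel pitch along
#'   SI.
#' @return A [line_profile()].
#' @export
extract_profile <- function(set, bin_id, center_mm = NULL,
                            half_length_mm = 36, pitch_mm = NULL) {
  stopifnot(inherits(set, "binned_image_set"))
  if (bin_id < 0L || bin_id >= set$n_bins) {
    stop("bin_id out of range", call. = FALSE)
  }
  grid <- set$grid
  if (is.null(center_mm)) {
    center_mm <- set$provenance$sphere_center_rest_mm
    if (is.null(center_mm)) center_mm <- c(0, 0, 0)
  }
  ax <- grid_axes(grid)
  si <- si_axis(grid$orientation)
  if (is.null(pitch_mm)) pitch_mm <- grid$voxel_mm[si]
  s <- seq(-half_length_mm, half_length_mm, by = pitch_mm)
  vol <- set$volumes[[bin_id + 1L]]

  lin_w <- function(coords, pos) {
    # linear interpolation weights on an axis: index pair + fraction
    if (pos < coords[1L] || pos > coords[length(coords)]) {
      stop("out of field: profile line leaves the volume", call. = FALSE)
    }
    i <- findInterval(pos, coords)
    i <- min(max(i, 1L), length(coords) - 1L)
    f <- (pos - coords[i]) / (coords[i + 1L] - coords[i])
    list(i = i, f = f)
  }
  if (si == 3L) {          # axial: line runs across slices
    wx <- lin_w(ax$x, center_mm[1L])
    wy <- lin_w(ax$y, center_mm[2L])
    line_v <- (1 - wx$f) * ((1 - wy$f) * vol[wx$i, wy$i, ] +
                            wy$f * vol[wx$i, wy$i + 1L, ]) +
              wx$f * ((1 - wy$f) * vol[wx$i + 1L, wy$i, ] +
                      wy$f * vol[wx$i + 1L, wy$i + 1L, ])
    coords <- ax$z
    anchor <- center_mm[3L]
  } else {                 # coronal: line runs along in-plane row axis
    wx <- lin_w(ax$x, center_mm[1L])
    wz <- lin_w(ax$z, center_mm[3L])
    line_v <- (1 - wx$f) * ((1 - wz$f) * vol[wx$i, , wz$i] +
                            wz$f * vol[wx$i, , wz$i + 1L]) +
              wx$f * ((1 - wz$f) * vol[wx$i + 1L, , wz$i] +
                      wz$f * vol[wx$i + 1L, , wz$i + 1L])
    coords <- ax$y
    anchor <- center_mm[2L]
  }
  pos <- anchor + s
  if (pos[1L] < coords[1L] || pos[length(pos)] > coords[length(coords)]) {
    stop("out of field: profile line leaves the volume", call. = FALSE)
  }
  I <- stats::approx(coords, line_v, xout = pos)$y
  line_profile(s, I, axis = "SI", source_bin = bin_id)
}

#' Locate FWHM edges of a line profile
#'
#' The half-maximum level is baseline-corrected:
#' `background + (peak - background) / 2`, with the background estimated as
#' the median of the outer 20% of samples.  (The phantom background is
#' water, not air, so a raw `max/2` level would sit below background and
#' find no crossings.)  Edge positions are located by linear interpolation
#' between the samples bracketing each crossing; with several crossings the
#' outermost pair enclosing the global peak is used.
#'
#' @param profile A [line_profile()] with a single dominant plateau or peak
#'   above background.
#' @param outer_frac Fraction of samples (split between both ends) used for
#'   the background estimate.
#' @return Named numeric vector `c(inferior, superior)` edge positions in
#'   mm (`inferior < superior`).
#' @export
fwhm_edges <- function(profile, outer_frac = 0.2) {
  stopifnot(inherits(profile, "line_profile"))
  I <- profile$I
  s <- profile$s
  n <- length(I)
  k <- max(2L, floor(n * outer_frac / 2))
  background <- stats::median(c(I[seq_len(k)], I[seq(n - k + 1L, n)]))
  peak_idx <- which.max(I)
  peak <- I[peak_idx]
  if (peak <= background) {
    stop("no edge: profile has no peak above background", call. = FALSE)
  }
  half <- background + (peak - background) / 2
  above <- I > half
  # contiguous runs above the half level; substantial secondary plateaus
  # make the profile ambiguous
  r <- rle(above)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  above_runs <- which(r$values)
  substantial <- above_runs[r$lengths[above_runs] >= 3L]
  if (length(substantial) > 1L) {
    stop("ambiguous profile: multiple disjoint plateaus above half maximum",
         call. = FALSE)
  }
  peak_run <- run_id[peak_idx]
  lo <- which(run_id == peak_run)[1L]
  hi <- which(run_id == peak_run)
  hi <- hi[length(hi)]
  if (lo == 1L || hi == n) {
    stop("no edge: half-maximum crossing lies outside the profile",
         call. = FALSE)
  }
  interp_edge <- function(i0, i1) {
    s[i0] + (half - I[i0]) / (I[i1] - I[i0]) * (s[i1] - s[i0])
  }
  c(inferior = interp_edge(lo - 1L, lo), superior = interp_edge(hi, hi + 1L))
}

#' Measure displacement between inhale and exhale profiles
#'
#' Edge shifts are computed at both sphere edges:
#' `sup_shift = sup_inhale - sup_exhale` and
#' `inf_shift = inf_inhale - inf_exhale`.  The summary displacement
#' defaults to the mean of the absolute shifts; `summary` can select the
#' superior-only, inferior-only or maximum convention instead.  The measure
#' is symmetric: swapping inhale and exhale preserves it.
#'
#' @param inhale,exhale [line_profile()]s from the extreme respiratory
#'   bins.
#' @param summary Combination rule for the two edge shifts.
#' @return An object of class `displacement_measurement` with fields
#'   `sup_shift`, `inf_shift`, `displacement` (mm), `sup_edges`,
#'   `inf_edges` (inhale, exhale positions) and `summary`.
#' @export
measure_displacement <- function(inhale, exhale,
                                 summary = c("mean", "sup", "inf", "max")) {
  summary <- match.arg(summary)
  e_in <- fwhm_edges(inhale)
  e_ex <- fwhm_edges(exhale)
  sup_shift <- e_in[["superior"]] - e_ex[["superior"]]
  inf_shift <- e_in[["inferior"]] - e_ex[["inferior"]]
  displacement <- switch(summary,
    mean = (abs(sup_shift) + abs(inf_shift)) / 2,
    sup = abs(sup_shift), inf = abs(inf_shift),
    max = max(abs(sup_shift), abs(inf_shift)))
  structure(list(sup_shift = sup_shift, inf_shift = inf_shift,
                 displacement = displacement,
                 sup_edges = c(inhale = e_in[["superior"]],
                               exhale = e_ex[["superior"]]),
                 inf_edges = c(inhale = e_in[["inferior"]],
                               exhale = e_ex[["inferior"]]),
                 summary = summary),
            class = "displacement_measurement")
}

#' @export
print.displacement_measurement <- function(x, ...) {
  cat(sprintf(
    "<displacement_measurement> %.3f mm (%s of |sup| = %.3f, |inf| = %.3f)\n",
    x$displacement, x$summary, abs(x$sup_shift), abs(x$inf_shift)))
  invisible(x)
}

#' Measure extreme-bin displacement of a binned image set
#'
#' Convenience wrapper: identifies the end-exhale and end-inhale bins from
#' the set's binning mode (amplitude: first and last bin; phase: trough bin
#' and bin 0), extracts both SI profiles on the identical same-coordinate
#' line, and measures the FWHM edge displacement.
#'
#' @param set A [binned_image_set()].
#' @param summary Passed to [measure_displacement()].
#' @param half_length_mm Passed to [extract_profile()].
#' @return A `displacement_measurement`.
#' @export
measure_set_displacement <- function(set, summary = "mean",
                                     half_length_mm = 36) {
  stopifnot(inherits(set, "binned_image_set"))
  n <- set$n_bins
  if (n < 2L) stop("need at least 2 bins to measure displacement",
                   call. = FALSE)
  if (set$bin_mode == "amplitude") {
    exhale <- 0L
    inhale <- n - 1L
  } else {
    exhale <- as.integer(floor((0.5 + 1 / (2 * n)) * n) %% n)
    inhale <- 0L
  }
  measure_displacement(
    extract_profile(set, inhale, half_length_mm = half_length_mm),
    extract_profile(set, exhale, half_length_mm = half_length_mm),
    summary = summary)
}
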