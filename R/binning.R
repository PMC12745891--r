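# Respiratory binning: amplitude-based (MR-style) and phase-based
# (CT-style) assignment of trace samples to respiratory bins.

#' Construct a bin assignment
#'
#' @param n_bins Number of respiratory bins.
#' @param mode `"amplitude"` or `"phase"`.
#' @param edges Bin boundaries: mm for amplitude mode (length `n_bins + 1`,
#'   strictly increasing); phase fractions in `[0, 1)` for phase mode
#'   (lower edges of the `n_bins` phase windows, bin 0 centred on the
#'   end-inhale peak).
#' @param bin_index Integer vector, one entry per trace sample, values in
#'   `0 .. n_bins - 1`.  Bin 0 is end-exhale (amplitude mode) or the
#'   end-inhale peak window (phase mode).
#' @param trace The [respiratory_trace()] the assignment refers to.
#' @return An object of class `bin_assignment`.
#' @export
bin_assignment <- function(n_bins, mode, edges, bin_index, trace) {
  mode <- match.arg(mode, c("amplitude", "phase"))
  bin_index <- as.integer(bin_index)
  if (any(bin_index < 0L) || any(bin_index >= n_bins)) {
    stop("bin indices must lie in [0, n_bins)", call. = FALSE)
  }
  if (length(bin_index) != length(trace$a)) {
    stop("one bin index per trace sample required", call. = FALSE)
  }
  structure(list(n_bins = as.integer(n_bins), mode = mode, edges = edges,
                 bin_index = bin_index, trace = trace),
            class = "bin_assignment")
}

#' @export
print.bin_assignment <- function(x, ...) {
  occ <- bin_occupancy(x)
  cat(sprintf("<bin_assignment> %s, %d bins, %d samples\n",
              x$mode, x$n_bins, length(x$bin_index)))
  cat("  occupancy:", paste(occ, collapse = " "), "\n")
  invisible(x)
}

#' Per-bin sample counts
#' @param assign A [bin_assignment()].
#' @return Integer vector of length `n_bins`; sums to the sample count.
#' @export
bin_occupancy <- function(assign) {
  stopifnot(inherits(assign, "bin_assignment"))
  tabulate(assign$bin_index + 1L, nbins = assign$n_bins)
}

#' Amplitude-based respiratory binning
#'
#' Samples are sorted into `n_bins` equal-width amplitude bands spanning a
#' robust range of the trace (1st to 99th percentile; outliers are clamped
#' into the edge bins).  Bin 0 collects the lowest amplitudes (end-exhale),
#' bin `n_bins - 1` the highest (end-inhale).  Inhalation and exhalation
#' samples of equal amplitude share a bin: amplitude binning ignores
#' hysteresis, as in self-navigated radial 4D-MR reconstruction.
#'
#' The robust range protects against transient sharp-inhale spikes, which
#' would otherwise compress regular breathing into a few low bins.
#'
#' @param trace A [respiratory_trace()].
#' @param n_bins Number of bins (>= 1).
#' @param probs Quantile pair defining the robust amplitude range.
#' @return A [bin_assignment()] in amplitude mode.
#' @export
amplitude_bins <- function(trace, n_bins, probs = c(0.01, 0.99)) {
  stopifnot(inherits(trace, "respiratory_trace"), n_bins >= 1)
  a <- trace$a
  if (n_bins > 1 && max(a) == min(a)) {
    stop("degenerate trace: constant amplitude cannot be split into bins",
         call. = FALSE)
  }
  if (n_bins == 1) {
    return(bin_assignment(1L, "amplitude", range(a),
                          rep(0L, length(a)), trace))
  }
  rng <- stats::quantile(a, probs, names = FALSE, type = 7)
  if (diff(rng) <= 0) rng <- range(a)
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  idx <- findInterval(a, edges, rightmost.closed = TRUE, all.inside = TRUE) - 1L
  bin_assignment(n_bins, "amplitude", edges, idx, trace)
}

# Phase of every sample: elapsed fraction of the breathing cycle since the
# previous end-inhale peak.  Samples before the first / after the last peak
# are extrapolated with the mean period.
sample_phases <- function(trace, cycles) {
  pk_t <- trace$t[cycles$peak_indices]
  n <- length(trace$t)
  if (length(pk_t) < 1L) stop("no peaks for phase computation", call. = FALSE)
  mean_T <- if (length(pk_t) > 1L) mean(diff(pk_t)) else trace_duration(trace)
  tt <- trace$t
  P <- length(pk_t)
  prev_idx <- findInterval(tt, pk_t)
  phase <- numeric(n)
  mid <- prev_idx >= 1L & prev_idx < P
  if (any(mid)) {
    p0 <- pk_t[prev_idx[mid]]
    p1 <- pk_t[prev_idx[mid] + 1L]
    phase[mid] <- (tt[mid] - p0) / (p1 - p0)
  }
  after <- prev_idx == P
  if (any(after)) phase[after] <- ((tt[after] - pk_t[P]) / mean_T) %% 1
  before <- prev_idx == 0L
  if (any(before)) phase[before] <- (1 - (pk_t[1L] - tt[before]) / mean_T) %% 1
  phase %% 1
}

#' Phase-based respiratory binning
#'
#' Each sample's respiratory phase is its elapsed fraction of the cycle
#' between consecutive end-inhale peaks.  Bin 0 is centred on the peak
#' (phase window `[-1/(2 n), 1/(2 n))`), so the end-inhale bin of a
#' phase-sorted CT is directly comparable to the end-inhale amplitude bin
#' of an MR reconstruction; subsequent bins advance through the cycle.
#'
#' @param trace A [respiratory_trace()].
#' @param n_phases Number of phase bins (>= 1).
#' @return A [bin_assignment()] in phase mode.
#' @export
phase_bins <- function(trace, n_phases) {
  stopifnot(inherits(trace, "respiratory_trace"), n_phases >= 1)
  cycles <- detect_cycles(trace)
  if (length(cycles$peak_indices) == 0L) {
    stop("no breathing cycles detected: cannot phase-sort", call. = FALSE)
  }
  phase <- sample_phases(trace, cycles)
  idx <- floor((phase + 1 / (2 * n_phases)) * n_phases) %% n_phases
  edges <- (seq_len(n_phases) - 1) / n_phases
  bin_assignment(n_phases, "phase", edges, idx, trace)
}

#' Identify the extreme (end-exhale, end-inhale) bins
#'
#' @param assign A [bin_assignment()] with at least 2 bins.
#' @return Integer vector `c(exhale_bin, inhale_bin)` (0-based ids).
#'   Amplitude mode: `(0, n_bins - 1)`.  Phase mode: the bin containing the
#'   trough phase (0.5 for symmetric breathing) and bin 0.
#' @export
extreme_bins <- function(assign) {
  stopifnot(inherits(assign, "bin_assignment"))
  n <- assign$n_bins
  if (n < 2L) stop("extreme bins need at least 2 bins", call. = FALSE)
  if (assign$mode == "amplitude") {
    return(c(exhale = 0L, inhale = n - 1L))
  }
  trough_bin <- as.integer(floor((0.5 + 1 / (2 * n)) * n) %% n)
  c(exhale = trough_bin, inhale = 0L)
}

#' Mean amplitude of the samples in each bin
#'
#' The per-bin centroid position of the surrogate signal, used as the
#' snapshot position for phase-sorted CT simulation and as an analytic
#' oracle for binned-MR edge positions.
#'
#' @param assign A [bin_assignment()].
#' @return Numeric vector of length `n_bins` (mm); `NaN` for empty bins.
#' @export
bin_centroids <- function(assign) {
  stopifnot(inherits(assign, "bin_assignment"))
  vapply(seq_len(assign$n_bins) - 1L, function(b) {
    mean(assign$trace$a[assign$bin_index == b])
  }, numeric(1))
}

#' Serialise a bin assignment to CSV
#'
#' Columns `sample_index, time_s, amp_mm, bin_index` (0-based samples and
#' bins).
#'
#' @param assign A [bin_assignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bins_csv <- function(assign, path) {
  stopifnot(inherits(assign, "bin_assignment"))
  df <- data.frame(sample_index = seq_along(assign$bin_index) - 1L,
                   time_s = assign$trace$t, amp_mm = assign$trace$a,
                   bin_index = assign$bin_index)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
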