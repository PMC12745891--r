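# Respiratory surrogate traces: generation, cycle detection, scaling,
# regularity classification and CSV round-trip.

#' Construct a respiratory trace
#'
#' A respiratory trace is a uniformly sampled surrogate signal: time in
#' seconds and displacement amplitude in mm of the phantom insert along the
#' motion (superior-inferior) axis.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing
#'   and uniformly spaced (within 1e-9 s).
#' @param a Numeric vector of amplitudes in mm, same length as `t`, all
#'   finite.
#' @param label Free-text label.
#' @param category One of `"regular"`, `"semiregular"`, `"irregular"`,
#'   `"sinusoid"`, `"unknown"`.
#' @return An object of class `respiratory_trace` with fields `t`, `a`,
#'   `dt`, `label`, `category`.
#' @export
respiratory_trace <- function(t, a, label = "", category = "unknown") {
  t <- as.numeric(t)
  a <- as.numeric(a)
  if (length(t) != length(a)) {
    stop("`t` and `a` must have the same length", call. = FALSE)
  }
  if (length(t) < 2L) {
    stop("a respiratory trace needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(t)) || !all(is.finite(a))) {
    stop("all times and amplitudes must be finite", call. = FALSE)
  }
  dts <- diff(t)
  if (any(dts <= 0)) {
    stop("`t` must be strictly increasing", call. = FALSE)
  }
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 1e-9) {
    stop("`t` must be uniformly spaced (within 1e-9 s)", call. = FALSE)
  }
  category <- match.arg(category,
    c("unknown", "regular", "semiregular", "irregular", "sinusoid"))
  structure(
    list(t = t, a = a, dt = dt, label = as.character(label)[1L],
         category = category),
    class = "respiratory_trace"
  )
}

#' @export
print.respiratory_trace <- function(x, ...) {
  cat(sprintf(
    "<respiratory_trace> %s\n  %d samples, dt = %.4g s, duration = %.4g s\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    length(x$t), x$dt, x$t[length(x$t)] - x$t[1L]))
  cat(sprintf("  amplitude range [%.3f, %.3f] mm, category: %s\n",
              min(x$a), max(x$a), x$category))
  invisible(x)
}

#' @export
plot.respiratory_trace <- function(x, ...) {
  graphics::plot(x$t, x$a, type = "l", xlab = "time (s)",
                 ylab = "amplitude (mm)",
                 main = if (nzchar(x$label)) x$label else "respiratory trace",
                 ...)
  invisible(x)
}

#' Trace duration in seconds
#' @param trace A [respiratory_trace()].
#' @return Duration from first to last sample plus one sampling interval
#'   (so that looped playback has no duplicated sample).
#' @export
trace_duration <- function(trace) {
  stopifnot(inherits(trace, "respiratory_trace"))
  trace$t[length(trace$t)] - trace$t[1L] + trace$dt
}

#' Evaluate a trace at arbitrary times, looping end-to-start
#'
#' Traces shorter than an acquisition are repeated until the acquisition
#' completes, mirroring how the phantom replays its input waveform.  Values
#' between samples are linearly interpolated.
#'
#' @param trace A [respiratory_trace()].
#' @param times Numeric vector of query times in seconds (>= 0 relative to
#'   trace start).
#' @return Amplitudes in mm at the query times.
#' @export
trace_position <- function(trace, times) {
  stopifnot(inherits(trace, "respiratory_trace"))
  dur <- trace_duration(trace)
  tq <- (times - trace$t[1L]) %% dur
  # wrap interval [t_last, t_last + dt) interpolates back to the first sample
  n <- length(trace$t)
  tt <- c(trace$t - trace$t[1L], dur)
  aa <- c(trace$a, trace$a[1L])
  stats::approx(tt, aa, xout = tq, rule = 2)$y
}

#' Generate a sinusoidal respiratory trace
#'
#' @param pp_mm Peak-to-peak displacement in mm (>= 0).
#' @param period_s Breathing period in seconds (> 0).
#' @param duration_s Trace duration in seconds (>= one period).
#' @param dt Sampling interval in seconds (< period/10).
#' @param phase Phase offset in radians.
#' @return A [respiratory_trace()] with zero mean over whole cycles and
#'   `max(a) - min(a) == pp_mm`.
#' @export
generate_sinusoid <- function(pp_mm, period_s, duration_s, dt = 0.01,
                              phase = 0) {
  if (!is.finite(pp_mm) || pp_mm < 0) {
    stop("`pp_mm` must be a non-negative number", call. = FALSE)
  }
  if (!is.finite(period_s) || period_s <= 0) {
    stop("`period_s` must be positive", call. = FALSE)
  }
  if (!is.finite(dt) || dt <= 0) {
    stop("`dt` must be positive", call. = FALSE)
  }
  if (duration_s < period_s) {
    stop("`duration_s` must cover at least one period", call. = FALSE)
  }
  if (dt >= period_s / 10) {
    stop("`dt` must be smaller than period_s / 10", call. = FALSE)
  }
  t <- seq(0, duration_s - dt, by = dt)
  a <- (pp_mm / 2) * sin(2 * pi * t / period_s + phase)
  respiratory_trace(t, a,
    label = sprintf("sinusoid pp=%g mm T=%g s", pp_mm, period_s),
    category = if (pp_mm > 0) "sinusoid" else "unknown")
}

# Local maxima with topographic prominence and a minimum separation.
# Returns sample indices sorted in time.  Used for end-inhale peaks (on a)
# and end-exhale troughs (on -a).
find_peaks <- function(a, min_prominence, min_separation_samples) {
  n <- length(a)
  if (n < 3L) return(integer(0))
  # candidate local maxima; plateaus contribute their centre sample
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (a[i] > a[i - 1L]) {
      j <- i
      while (j < n && a[j + 1L] == a[j]) j <- j + 1L
      if (j < n && a[j + 1L] < a[j]) {
        cand <- c(cand, as.integer((i + j) %/% 2L))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(cand) == 0L) return(integer(0))
  # topographic prominence: drop to the lowest valley on the way to the
  # nearest higher peak (or trace end) on each side
  prom <- vapply(cand, function(p) {
    h <- a[p]
    side_min <- function(step) {
      k <- p
      lo <- h
      higher <- FALSE
      while (k > 1L && k < n) {
        k <- k + step
        if (a[k] < lo) lo <- a[k]
        if (a[k] > h) {
          higher <- TRUE
          break
        }
      }
      list(lo = lo, higher = higher)
    }
    l <- side_min(-1L)
    r <- side_min(1L)
    # key saddle is the higher of the two valley minima towards the
    # nearest higher ground (or trace boundary) on each side
    h - max(l$lo, r$lo)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) == 0L) return(integer(0))
  # enforce minimum separation, keeping the taller peak
  ord <- keep[order(a[keep], decreasing = TRUE)]
  sel <- logical(length(a))
  chosen <- integer(0)
  for (p in ord) {
    if (!length(chosen) || all(abs(chosen - p) >= min_separation_samples)) {
      chosen <- c(chosen, p)
    }
  }
  sort(chosen)
}

#' Detect breathing cycles in a respiratory trace
#'
#' Peaks (end-inhale) and troughs (end-exhale) are found by local-extremum
#' search with a topographic prominence threshold of 20% of a robust
#' peak-to-peak reference (the smaller of the global range and
#' `2*sqrt(2)*SD`, which equals the range for a sinusoid but is not
#' inflated by transient sharp-inhale spikes) and a minimum separation of
#' 1 s, which rejects cardiac-scale ripple while resolving fast (2.4 s)
#' breathing.  Extrema are then reduced to a strictly alternating
#' peak/trough sequence.
#'
#' @param trace A [respiratory_trace()].
#' @param prominence_frac Prominence threshold as a fraction of the global
#'   peak-to-peak amplitude.
#' @param min_separation_s Minimum time between retained peaks, seconds.
#' @return An object of class `cycle_set` with `peak_indices`,
#'   `trough_indices` (sample indices) and `cycle_pp` (per-cycle
#'   peak-to-trough excursion in mm, one entry per peak).  A constant trace
#'   yields an empty cycle set.
#' @export
detect_cycles <- function(trace, prominence_frac = 0.2,
                          min_separation_s = 1.0) {
  stopifnot(inherits(trace, "respiratory_trace"))
  rng <- max(trace$a) - min(trace$a)
  empty <- structure(list(peak_indices = integer(0),
                          trough_indices = integer(0),
                          cycle_pp = numeric(0)),
                     class = "cycle_set")
  if (rng == 0) return(empty)
  min_sep <- max(1L, round(min_separation_s / trace$dt))
  # robust peak-to-peak reference: 2*sqrt(2)*SD equals the range for a
  # sinusoid but is not inflated by transient sharp-inhale spikes, which
  # would otherwise push the prominence threshold above the half-excursion
  # of boundary cycles
  pp_ref <- min(rng, 2 * sqrt(2) * stats::sd(trace$a))
  prom <- prominence_frac * pp_ref
  peaks <- find_peaks(trace$a, prom, min_sep)
  troughs <- find_peaks(-trace$a, prom, min_sep)
  if (length(peaks) == 0L) return(empty)
  # strictly alternating sequence: among consecutive same-type extrema keep
  # the most extreme one
  ext <- rbind(data.frame(idx = peaks, type = "p"),
               data.frame(idx = troughs, type = "t"))
  ext <- ext[order(ext$idx), ]
  keep <- rep(TRUE, nrow(ext))
  i <- 1L
  while (i < nrow(ext)) {
    j <- i + 1L
    if (ext$type[j] == ext$type[i]) {
      vi <- trace$a[ext$idx[i]]
      vj <- trace$a[ext$idx[j]]
      better_j <- if (ext$type[i] == "p") vj > vi else vj < vi
      if (better_j) keep[i] <- FALSE else keep[j] <- FALSE
      ext <- ext[keep, ]
      keep <- rep(TRUE, nrow(ext))
      # restart comparison at previous element
      i <- max(i - 1L, 1L)
    } else {
      i <- i + 1L
    }
  }
  peaks <- ext$idx[ext$type == "p"]
  troughs <- ext$idx[ext$type == "t"]
  if (length(troughs) == 0L) return(empty)
  # per-cycle excursion: peak minus adjacent trough (following preferred)
  cycle_pp <- vapply(peaks, function(p) {
    nxt <- troughs[troughs > p]
    prv <- troughs[troughs < p]
    tr <- if (length(nxt)) nxt[1L] else prv[length(prv)]
    trace$a[p] - trace$a[tr]
  }, numeric(1))
  structure(list(peak_indices = as.integer(peaks),
                 trough_indices = as.integer(troughs),
                 cycle_pp = cycle_pp),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d peaks, %d troughs\n",
              length(x$peak_indices), length(x$trough_indices)))
  if (length(x$cycle_pp)) {
    cat(sprintf("  cycle peak-to-trough excursion: mean %.3f mm, range [%.3f, %.3f]\n",
                mean(x$cycle_pp), min(x$cycle_pp), max(x$cycle_pp)))
  }
  invisible(x)
}

#' Mean of the per-cycle maximum amplitudes
#'
#' The per-cycle "maximum amplitude" is the peak-to-trough excursion of that
#' cycle.  Averaging these across cycles is robust against transient sharp
#' inhales, which would dominate a max-of-trace scaling (a single 3x spike
#' cycle inflates the mean far less than it would the maximum).
#'
#' @param trace A [respiratory_trace()].
#' @param cycles Optional precomputed [detect_cycles()] result.
#' @return Mean per-cycle excursion in mm.
#' @export
mean_max_amplitude <- function(trace, cycles = NULL) {
  if (is.null(cycles)) cycles <- detect_cycles(trace)
  if (length(cycles$cycle_pp) == 0L) {
    stop("no complete breathing cycles detected", call. = FALSE)
  }
  mean(cycles$cycle_pp)
}

#' Rescale a trace to a target mean-of-maxima amplitude
#'
#' The trace is mean-centred and multiplied by
#' `target_mm / mean_max_amplitude(trace)`, so the rescaled trace has the
#' requested mean per-cycle excursion.  This is the scaling used to program
#' the phantom from patient waveforms: scaling to the raw maximum would
#' compress regular breathing whenever a trace contains sharp-inhale spikes.
#'
#' @param trace A [respiratory_trace()].
#' @param target_mm Target mean per-cycle excursion in mm (> 0).
#' @return A rescaled [respiratory_trace()].
#' @export
scale_to_mean_amplitude <- function(trace, target_mm) {
  stopifnot(inherits(trace, "respiratory_trace"), target_mm > 0)
  mma <- mean_max_amplitude(trace)  # errors if no cycles
  a <- (trace$a - mean(trace$a)) * (target_mm / mma)
  respiratory_trace(trace$t, a, label = trace$label,
                    category = trace$category)
}

#' Classify the regularity of a breathing pattern
#'
#' Operationalises the qualitative regular / semiregular / irregular
#' grouping of clinical surrogate traces with coefficients of variation (CV)
#' of the per-cycle excursion and the cycle period:
#' * regular: CV(excursion) < `regular_cv` and CV(period) < `regular_cv`;
#' * irregular: either CV > `irregular_cv`, or any single cycle excursion
#'   exceeds `spike_factor` times the median (transient sharp inhale);
#' * semiregular otherwise (e.g. phase-stable amplitude drift).
#'
#' @param trace A [respiratory_trace()].
#' @param regular_cv,irregular_cv,spike_factor Classification thresholds.
#' @return One of `"regular"`, `"semiregular"`, `"irregular"`, or
#'   `"unknown"` when fewer than 3 cycles are detected.
#' @export
classify_pattern <- function(trace, regular_cv = 0.10, irregular_cv = 0.25,
                             spike_factor = 2) {
  cycles <- detect_cycles(trace)
  if (length(cycles$peak_indices) < 3L) return("unknown")
  pp <- cycles$cycle_pp
  periods <- diff(trace$t[cycles$peak_indices])
  cv <- function(x) stats::sd(x) / mean(x)
  cv_pp <- cv(pp)
  cv_per <- cv(periods)
  if (any(pp > spike_factor * stats::median(pp)) ||
      cv_pp > irregular_cv || cv_per > irregular_cv) {
    return("irregular")
  }
  if (cv_pp < regular_cv && cv_per < regular_cv) return("regular")
  "semiregular"
}

#' Generate a synthetic patient-like respiratory trace
#'
#' Builds a trace cycle by cycle from a `cos^(2n)` breathing shape (sharp
#' inhale, broad exhale plateau) with per-cycle period jitter and AR(1)
#' amplitude variation.  Category-specific features:
#' * `"regular"`: small period and amplitude jitter;
#' * `"semiregular"`: phase-stable breathing with a gradual linear
#'   amplitude drift to about 65% of the starting excursion;
#' * `"irregular"`: strong period/amplitude jitter plus at least one
#'   transient sharp-inhale spike (about 3x excursion) and one end-exhale
#'   pause of several seconds.
#'
#' The finished trace is rescaled so its mean per-cycle excursion equals
#' `mean_pp_mm` (see [scale_to_mean_amplitude()]).
#'
#' @param category `"regular"`, `"semiregular"` or `"irregular"`.
#' @param duration_s Approximate duration in seconds.
#' @param dt Sampling interval in seconds.
#' @param mean_pp_mm Target mean per-cycle excursion in mm.
#' @param period_s Nominal breathing period in seconds.
#' @param seed Optional integer seed for reproducibility.
#' @return A [respiratory_trace()] with the requested `category`.
#' @export
generate_patient_trace <- function(category = c("regular", "semiregular",
                                                "irregular"),
                                   duration_s = 120, dt = 0.01,
                                   mean_pp_mm = 10, period_s = 4,
                                   seed = NULL) {
  category <- match.arg(category)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  par <- switch(category,
    regular     = list(per_cv = 0.02, amp_cv = 0.03, drift = FALSE,
                       spikes = FALSE, pause = FALSE),
    semiregular = list(per_cv = 0.04, amp_cv = 0.05, drift = TRUE,
                       spikes = FALSE, pause = FALSE),
    irregular   = list(per_cv = 0.18, amp_cv = 0.20, drift = FALSE,
                       spikes = TRUE, pause = TRUE))
  n_cycles <- ceiling(duration_s / period_s) + 2L
  periods <- period_s * pmax(0.4, 1 + stats::rnorm(n_cycles, 0, par$per_cv))
  # AR(1) amplitude factors around 1
  amp <- numeric(n_cycles)
  amp[1L] <- 1
  for (i in seq_len(n_cycles - 1L)) {
    amp[i + 1L] <- 1 + 0.7 * (amp[i] - 1) + stats::rnorm(1, 0, par$amp_cv)
  }
  amp <- pmax(amp, 0.2)
  if (par$drift) amp <- amp * seq(1, 0.65, length.out = n_cycles)
  spike_cycle <- pause_cycle <- 0L
  if (par$spikes) {
    spike_cycle <- sample(3:(n_cycles - 3L), 1L)
    amp[spike_cycle] <- amp[spike_cycle] * stats::runif(1, 2.6, 3.2)
  }
  if (par$pause) {
    pause_cycle <- sample(setdiff(3:(n_cycles - 3L), spike_cycle), 1L)
  }
  shape_n <- 2  # cos^4 breathing shape
  t_all <- numeric(0)
  a_all <- numeric(0)
  t0 <- 0
  for (i in seq_len(n_cycles)) {
    tau <- seq(0, periods[i] - dt, by = dt) / periods[i]
    a_all <- c(a_all, amp[i] * cos(pi * (tau - 0.5))^(2 * shape_n))
    t0 <- t0 + periods[i]
    if (i == pause_cycle) {
      pause_s <- stats::runif(1, 4, 6)
      a_all <- c(a_all, rep(0, round(pause_s / dt)))
      t0 <- t0 + pause_s
    }
  }
  t_all <- seq_along(a_all) * dt - dt
  keep <- t_all <= duration_s + 2 * period_s
  tr <- respiratory_trace(t_all[keep], a_all[keep],
    label = sprintf("synthetic %s trace", category), category = category)
  scale_to_mean_amplitude(tr, mean_pp_mm)
}

#' Read a respiratory trace from a two-column CSV
#'
#' Expects columns `time_s, amp_mm` (header optional, '.' decimal
#' separator).  The sampling interval is inferred from the median spacing;
#' sub-microsecond timing jitter is tolerated and regularised.
#'
#' @param path Path to the CSV file.
#' @param label,category Passed to [respiratory_trace()]; defaults to the
#'   file name and `"unknown"`.
#' @return A [respiratory_trace()].
#' @export
read_trace_csv <- function(path, label = basename(path),
                           category = "unknown") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty trace file: ", path, call. = FALSE)
  parse_row <- function(line) {
    suppressWarnings(as.numeric(strsplit(line, ",")[[1L]][1:2]))
  }
  first <- parse_row(lines[1L])
  start <- if (any(is.na(first))) 2L else 1L
  if (start > length(lines)) {
    stop("no numeric rows in trace file: ", path, call. = FALSE)
  }
  vals <- lapply(seq(start, length(lines)), function(i) {
    v <- parse_row(lines[i])
    if (length(v) < 2L || any(is.na(v))) {
      stop(sprintf("parse error in %s at line %d: non-numeric row", path, i),
           call. = FALSE)
    }
    v
  })
  m <- do.call(rbind, vals)
  t <- m[, 1L]
  a <- m[, 2L]
  dts <- diff(t)
  if (any(dts <= 0)) {
    bad <- which(dts <= 0)[1L] + start  # line number of offending row
    stop(sprintf("parse error in %s at line %d: time not increasing",
                 path, bad), call. = FALSE)
  }
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 1e-6) {
    stop(sprintf("parse error in %s: time spacing varies by more than 1e-6 s",
                 path), call. = FALSE)
  }
  # regularise sub-microsecond jitter so the trace satisfies the uniform
  # sampling invariant
  t <- t[1L] + (seq_along(t) - 1L) * dt
  respiratory_trace(t, a, label = label, category = category)
}

#' Write a respiratory trace to CSV
#'
#' Columns `time_s, amp_mm`, full double precision, so a write/read
#' round-trip reproduces the trace within 1e-9.
#'
#' @param trace A [respiratory_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "respiratory_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,amp_mm", con)
  writeLines(sprintf("%.12g,%.12g", trace$t, trace$a), con)
  invisible(path)
}
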