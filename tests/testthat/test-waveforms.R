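test_that("sinusoid generation hits the programmed excursion and mean", {
  tr <- generate_sinusoid(10, 4, 60, dt = 0.01)
  expect_equal(max(tr$a) - min(tr$a), 10, tolerance = 1e-9)
  expect_lt(abs(mean(tr$a)), 1e-9)

  # time-mean of |a| equals the numeric quadrature of (pp/2)|sin|
  tr2 <- generate_sinusoid(10, 4, 40, dt = 0.001)
  oracle <- stats::integrate(function(t) abs(5 * sin(2 * pi * t / 4)),
                             0, 4)$value / 4
  expect_equal(mean(abs(tr2$a)), oracle, tolerance = 1e-3)

  zero <- generate_sinusoid(0, 4, 12, dt = 0.01)
  expect_true(all(zero$a == 0))

  expect_error(generate_sinusoid(10, -1, 60), "positive")
  expect_error(generate_sinusoid(10, 4, 60, dt = 0), "positive")
  expect_error(generate_sinusoid(10, 4, 2), "one period")
})

test_that("cycle detection counts completed cycles and resists noise", {
  tr <- generate_sinusoid(10, 4, 60)
  cs <- detect_cycles(tr)
  expect_identical(length(cs$peak_indices), 15L)
  expect_equal(cs$cycle_pp, rep(10, 15), tolerance = 1e-3)

  flat <- respiratory_trace(seq(0, 10, 0.01), rep(1, 1001))
  expect_identical(length(detect_cycles(flat)$peak_indices), 0L)

  noisy <- withr::with_seed(42, {
    respiratory_trace(tr$t, tr$a + stats::rnorm(length(tr$a), 0, 0.2))
  })
  expect_identical(length(detect_cycles(noisy)$peak_indices), 15L)

  # peaks and troughs alternate in time
  ext <- sort(c(cs$peak_indices, cs$trough_indices))
  types <- ext %in% cs$peak_indices
  expect_true(all(types[-1] != types[-length(types)]))
})

test_that("mean-of-maxima amplitude averages per-cycle excursions", {
  expect_equal(mean_max_amplitude(generate_sinusoid(10, 4, 60)), 10,
               tolerance = 1e-3)
  mixed <- make_piecewise_sine(c(8, 10, 12))
  expect_equal(mean_max_amplitude(mixed), 10, tolerance = 0.02)

  # a transient 3x spike inflates the mean far less than max-scaling would
  spiky <- make_piecewise_sine(c(10, 10, 30, 10))
  expect_equal(mean_max_amplitude(spiky), 15, tolerance = 0.05)
  expect_gt(max(spiky$a) - min(spiky$a), 29)

  flat <- respiratory_trace(seq(0, 10, 0.01), rep(0, 1001))
  expect_error(mean_max_amplitude(flat), "no complete")
})

test_that("scaling to a target mean amplitude is exact and linear", {
  tr <- generate_sinusoid(10, 4, 60)
  same <- scale_to_mean_amplitude(tr, 10)
  expect_equal(same$a, tr$a, tolerance = 1e-6)

  up <- scale_to_mean_amplitude(generate_sinusoid(4, 4, 60), 10)
  expect_equal(max(up$a) - min(up$a), 10, tolerance = 1e-3)

  mixed <- scale_to_mean_amplitude(make_piecewise_sine(c(8, 10, 12)), 6)
  expect_equal(mean_max_amplitude(mixed), 6, tolerance = 1e-6)

  # property: rescaling any cyclic trace to m yields mean amplitude m
  for (seed in 1:5) {
    cat_i <- c("regular", "semiregular", "irregular")[(seed %% 3) + 1]
    tr_i <- generate_patient_trace(cat_i, duration_s = 80, seed = seed)
    m <- stats::runif(1, 4, 14)
    expect_equal(mean_max_amplitude(scale_to_mean_amplitude(tr_i, m)), m,
                 tolerance = 1e-6)
  }

  expect_error(
    scale_to_mean_amplitude(respiratory_trace(0:10, rep(0, 11)), 5))
})

test_that("pattern classification separates the three regularity classes", {
  for (pp in c(6, 10)) {
    for (T in c(2.4, 4, 12)) {
      expect_identical(classify_pattern(generate_sinusoid(pp, T, 60)),
                       "regular")
    }
  }

  # gradual amplitude drift with stable phase: semiregular by construction
  t <- seq(0, 60, 0.01)
  drift <- (10 + (6 - 10) * t / 60) / 2 * sin(2 * pi * t / 4)
  expect_identical(classify_pattern(respiratory_trace(t, drift)),
                   "semiregular")

  # sharp-inhale spikes plus a pause: irregular by construction
  spiky <- make_piecewise_sine(c(10, 10, 30, 10, 30, 10))
  pause <- respiratory_trace(
    seq_len(length(spiky$a) + 600) * 0.01,
    c(spiky$a[1:1200], rep(0, 600), spiky$a[1201:length(spiky$a)]))
  expect_identical(classify_pattern(pause), "irregular")

  short <- generate_sinusoid(10, 4, 7)
  expect_identical(classify_pattern(short), "unknown")
})

test_that("synthetic patient traces round-trip through the classifier", {
  for (seed in 1:3) {
    for (cat_i in c("regular", "semiregular", "irregular")) {
      tr <- generate_patient_trace(cat_i, duration_s = 120, seed = seed)
      expect_identical(classify_pattern(tr), cat_i)
      expect_equal(mean_max_amplitude(tr), 10, tolerance = 1e-6)
    }
  }
})

test_that("trace CSV round-trips and rejects malformed input", {
  tr <- generate_sinusoid(10, 4, 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path)
  expect_equal(back$t, tr$t, tolerance = 1e-9)
  expect_equal(back$a, tr$a, tolerance = 1e-9)

  # shuffled time column
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,amp_mm", "0.0,1", "0.2,2", "0.1,3"), bad)
  expect_error(read_trace_csv(bad), "line 4")

  nonnum <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,amp_mm", "0.0,1", "oops,2"), nonnum)
  expect_error(read_trace_csv(nonnum), "line 3")

  # sub-microsecond jitter is regularised
  jit <- withr::local_tempfile(fileext = ".csv")
  t <- seq(0, 1, 0.01)
  tj <- t + withr::with_seed(1, stats::runif(length(t), 0, 5e-7))
  writeLines(c("time_s,amp_mm",
               sprintf("%.9f,%.4f", tj, sin(t))), jit)
  got <- read_trace_csv(jit)
  expect_equal(diff(got$t), rep(got$dt, length(t) - 1), tolerance = 1e-12)
})

test_that("looped playback evaluates positions beyond the trace end", {
  tr <- generate_sinusoid(10, 4, 8, dt = 0.01)
  expect_equal(trace_position(tr, c(1, 9, 17)),
               rep(trace_position(tr, 1), 3), tolerance = 1e-9)
})
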