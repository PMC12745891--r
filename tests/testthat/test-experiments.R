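test_that("the sweep design varies one parameter at a time", {
  cond <- sweep_conditions()
  base <- cond[cond$condition == "baseline", ]
  fields <- c("n_spokes", "n_bins", "slice_thickness_mm", "orientation")
  for (i in which(cond$condition != "baseline")) {
    ndiff <- sum(vapply(fields, function(f) {
      !identical(cond[[f]][i], base[[f]])
    }, logical(1)))
    expect_identical(ndiff, 1L)
  }
  # tested values follow the protocol modification table
  expect_setequal(cond$n_spokes, c(3000L, 1500L, 2000L))
  expect_setequal(cond$n_bins, c(5L, 4L, 7L, 10L))
  expect_setequal(cond$slice_thickness_mm, c(3, 1.5, 2))
})

test_that("per-scan seeds are deterministic, distinct and 32-bit safe", {
  seeds <- c()
  for (ci in 1:9) for (wi in 1:3) for (ri in 1:5) {
    seeds <- c(seeds, motion4d:::scan_seed(1, ci, wi, ri))
  }
  expect_identical(anyDuplicated(seeds), 0L)
  expect_true(all(seeds > 0 & seeds < 2^31))
  expect_identical(motion4d:::scan_seed(7, 2, 1, 3),
                   motion4d:::scan_seed(7, 2, 1, 3))
})

test_that("the sweep runner produces one deterministic row per scan", {
  tr <- generate_sinusoid(10, 4, 30)
  cond <- data.frame(condition = c("baseline", "bins_3"),
                     n_spokes = 150L, n_bins = c(2L, 3L),
                     slice_thickness_mm = 6, orientation = "axial")
  tab <- run_sweep(list(sine10 = tr), conditions = cond, replicates = 2,
                   master_seed = 5, acq_base = tiny_acq(), half_length_mm = 30)
  expect_identical(nrow(tab), 4L)
  expect_true(all(is.na(tab$error)))
  expect_true(all(is.finite(tab$displacement)))
  expect_equal(tab$ground_truth_pp, rep(10, 4), tolerance = 1e-3)

  # byte-identical determinism for identical config and seeds
  tab2 <- run_sweep(list(sine10 = tr), conditions = cond, replicates = 2,
                    master_seed = 5, acq_base = tiny_acq(), half_length_mm = 30)
  expect_identical(tab, tab2)

  # a different master seed changes the measurements
  tab3 <- run_sweep(list(sine10 = tr), conditions = cond, replicates = 2,
                    master_seed = 6, acq_base = tiny_acq(), half_length_mm = 30)
  expect_false(identical(tab$displacement, tab3$displacement))
})

test_that("scan failures are recorded per row and the run continues", {
  tr <- generate_sinusoid(10, 4, 30)
  cond <- data.frame(condition = c("bad", "baseline"),
                     n_spokes = c(4L, 150L), n_bins = c(8L, 2L),
                     slice_thickness_mm = 6, orientation = "axial")
  tab <- suppressWarnings(
    run_sweep(list(sine10 = tr), conditions = cond, replicates = 1,
              master_seed = 1, acq_base = tiny_acq(), half_length_mm = 30))
  expect_identical(nrow(tab), 2L)
  expect_true(is.na(tab$displacement[1]))
  expect_match(tab$error[1], "n_spokes")
  expect_true(is.finite(tab$displacement[2]))
})

test_that("protocol comparison covers all protocol x waveform x replicate cells", {
  wfs <- list(a = generate_sinusoid(10, 4, 30),
              b = generate_sinusoid(6, 4, 30))
  res <- run_protocol_comparison(wfs, replicates = 2, master_seed = 3,
                                 acq_base = tiny_acq(n_spokes = 320),
                                 ct_slice_thickness_mm = 5,
                                 half_length_mm = 30)
  expect_identical(nrow(res$table), 3L * 2L * 2L)
  expect_setequal(unique(res$table$protocol),
                  c("MR_axial_5bin", "MR_coronal_10bin", "CT"))
  expect_true(all(table(res$table$protocol) == 4L))
  expect_true(all(is.na(res$table$error)))
  if (!is.null(res$lmm)) {
    expect_s3_class(res$lmm, "lmm_result")
    expect_identical(res$lmm$reference, "MR_coronal_10bin")
  }
})

test_that("experiment configuration round-trips through YAML", {
  cfg <- list(waveform = list(kind = "sinusoid", pp_mm = 6, period_s = 2.4,
                              duration_s = 30),
              replicates = 4, master_seed = 11)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  got <- read_experiment_config(path)
  expect_equal(got$replicates, 4)
  tr <- config_waveform(got$waveform)
  expect_equal(max(tr$a) - min(tr$a), 6, tolerance = 1e-9)
  expect_equal(trace_duration(tr), 30, tolerance = 0.02)

  pt <- config_waveform(list(kind = "patient", category = "irregular",
                             duration_s = 60, seed = 2))
  expect_identical(pt$category, "irregular")
})
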