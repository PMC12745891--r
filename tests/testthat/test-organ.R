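test_that("decimal half-up rounding matches hand-rounded table values", {
  expect_identical(round_half_up(4.85), 4.9)
  expect_identical(round_half_up(4.05), 4.1)
  expect_identical(round_half_up(-4.05), -4.1)
  expect_identical(round_half_up(2.34), 2.3)
})

test_that("Euclidean displacement reproduces printed per-patient cells", {
  expect_identical(euclidean_displacement(4.1, 9.2, 7.0), 12.3)
  expect_identical(euclidean_displacement(7.7, 9.0, 9.7), 15.3)
  expect_identical(euclidean_displacement(0, 0, 0), 0)

  # rotation invariance of the component vector
  v <- c(3.2, -1.4, 7.7)
  th <- 0.7
  rot <- c(cos(th) * v[1] - sin(th) * v[2],
           sin(th) * v[1] + cos(th) * v[2], v[3])
  expect_identical(euclidean_displacement(v[1], v[2], v[3]),
                   euclidean_displacement(rot[1], rot[2], rot[3]))
  # monotone in each |component|
  expect_gt(euclidean_displacement(5, 9.2, 7.0),
            euclidean_displacement(4.1, 9.2, 7.0))
})

test_that("direction means reproduce printed table means", {
  expect_identical(direction_means(c(4.1, 1.1)), 2.6)
  expect_identical(direction_means(c(5.5, 1.0, 4.4)), 3.6)
  expect_identical(direction_means(7.3), 7.3)
  expect_error(direction_means(numeric(0)), "non-empty")
})

test_that("modality differences match the printed comparison table", {
  means <- load_organ_means()
  diffs <- modality_difference_table(means)
  cell <- function(org, cmp, dir) {
    diffs$difference_mm[diffs$organ == org & diffs$comparison == cmp &
                          diffs$direction == dir]
  }
  expect_identical(cell("liver", "CT-AX_MR", "dZ"), 3.4)
  expect_identical(cell("liver", "CT-COR_MR", "dX"), -1.8)
  expect_identical(cell("liver", "CT-AX_MR", "euclidean"), 0.7)
  expect_identical(cell("kidney_mean", "CT-COR_MR", "dZ"), -2.7)
  expect_identical(cell("kidney_mean", "CT-AX_MR", "euclidean"), -1.5)

  # any modality minus itself is zero
  self <- means
  self$mean_mm[self$modality == "CT"] <-
    self$mean_mm[self$modality == "AX_MR"]
  d2 <- modality_difference_table(self)
  expect_true(all(d2$difference_mm[d2$comparison == "CT-AX_MR"] == 0))

  expect_error(modality_difference_table(means[means$modality != "CT", ]),
               "missing modality")
})

test_that("table reconstruction flags known inconsistent printed cells", {
  ot <- organ_tables()
  # every printed difference-table cell is reproduced from printed means
  expect_identical(nrow(ot$differences), 16L)
  # arithmetically consistent cells are not flagged
  expect_false("liver/AX_MR/patient 1" %in%
                 ot$flags$cell[ot$flags$table == "per_patient_euclidean"])
  # the printed liver CT patient-1 Euclidean (17.4) disagrees with its
  # components, and the kidney per-patient Euclideans are averages of the
  # left/right kidneys rather than norms of averaged components
  flagged <- ot$flags$cell[ot$flags$table == "per_patient_euclidean"]
  expect_true("liver/CT/patient 1" %in% flagged)
  # printed kidney mean cells known to disagree with per-patient values
  mean_flags <- ot$flags$cell[ot$flags$table == "direction_mean"]
  expect_true("kidney_mean/AX_MR/euclidean" %in% mean_flags)
  expect_true("kidney_mean/COR_MR/euclidean" %in% mean_flags)
  # consistent means (e.g. liver AX dX = 2.6) are not flagged
  expect_false("liver/AX_MR/dX" %in% mean_flags)
})

test_that("box-ROI translation recovers constructed shifts", {
  spec <- phantom_spec()
  grid <- image_grid(64, 160, 32, 2.5, "axial")
  exhale <- render_phantom(0, spec, grid)
  roi <- list(lo = c(23, 23, 7), hi = c(42, 42, 26))

  expect_equal(roi_translation(exhale, exhale, roi,
                               voxel_mm = grid$voxel_mm),
               c(0, 0, 0), tolerance = 1e-9)

  # shift of exactly 2 slices (5 mm) is recovered exactly
  inh2 <- render_phantom(5, spec, grid)
  tr2 <- roi_translation(inh2, exhale, roi, voxel_mm = grid$voxel_mm)
  expect_equal(tr2[3], 5, tolerance = 1e-6)
  expect_equal(tr2[1:2], c(0, 0), tolerance = 1e-6)

  # sub-voxel shift of 7.5 mm = 3 slices exactly; 6.2 mm needs the
  # quadratic peak interpolation
  inh3 <- render_phantom(6.2, spec, grid)
  tr3 <- roi_translation(inh3, exhale, roi, voxel_mm = grid$voxel_mm)
  expect_equal(tr3[3], 6.2, tolerance = 0.25)

  flat <- array(1, dim(exhale))
  expect_error(roi_translation(flat, flat, roi), "degenerate ROI")
  expect_error(roi_translation(exhale, exhale,
                               list(lo = c(0, 1, 1), hi = c(10, 10, 10))),
               "outside")
})
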