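test_that("FWHM edges are exact on rectangles and trapezoids", {
  rect <- make_rect_profile(edge = 15)
  e <- fwhm_edges(rect)
  expect_equal(unname(e), c(-15, 15), tolerance = 1e-9)

  # linear interpolation is exact on linear ramps: edges at ramp midpoints
  trap <- make_trapezoid_profile(plateau = 11, ramp = 4)
  e <- fwhm_edges(trap)
  expect_equal(unname(e), c(-13, 13), tolerance = 1e-9)
})

test_that("FWHM of a Gaussian bump matches the closed form", {
  g <- make_gauss_profile(sigma = 6, pitch = 1.5)
  e <- fwhm_edges(g)
  fwhm_oracle <- 2 * 6 * sqrt(2 * log(2))
  expect_equal(e[["superior"]] - e[["inferior"]], fwhm_oracle,
               tolerance = 0.05)
  expect_equal(e[["superior"]], -e[["inferior"]], tolerance = 0.05)
})

test_that("degenerate profiles raise informative errors", {
  s <- seq(-30, 30, 1.5)
  expect_error(fwhm_edges(line_profile(s, rep(1, length(s)))), "no edge")
  # two disjoint plateaus
  I <- 1 + 0.5 * (abs(s - 15) < 5) + 0.4 * (abs(s + 15) < 5)
  expect_error(fwhm_edges(line_profile(s, I)), "ambiguous")
  # peak running off the profile end
  I2 <- 1 + 0.5 * (s > 20)
  expect_error(fwhm_edges(line_profile(s, I2)), "no edge")
})

test_that("displacement measurement is a symmetric shift detector", {
  base <- make_trapezoid_profile()
  expect_equal(measure_displacement(base, base)$displacement, 0)

  shifted <- make_trapezoid_profile(center = 7)
  m <- measure_displacement(shifted, base)
  expect_equal(m$sup_shift, 7, tolerance = 1e-6)
  expect_equal(m$inf_shift, 7, tolerance = 1e-6)
  expect_equal(m$displacement, 7, tolerance = 1e-6)

  # swap symmetry is exact
  expect_identical(measure_displacement(base, shifted)$displacement,
                   m$displacement)

  # sub-sample shifts that are not multiples of the pitch resolve exactly
  # on ramped profiles (linear interpolation is exact on linear ramps)
  for (d in c(0.37, 1.91, 3.55)) {
    m <- measure_displacement(make_trapezoid_profile(center = d), base)
    expect_lt(abs(m$displacement - d), 0.01)
  }

  # summary conventions
  asym_in <- make_trapezoid_profile(center = 4)
  m2 <- measure_displacement(asym_in, base, summary = "max")
  expect_equal(m2$displacement, max(abs(m2$sup_shift), abs(m2$inf_shift)))
})

test_that("profile extraction samples the same-coordinate SI line", {
  spec <- phantom_spec()
  grid <- image_grid(64, 200, 24, 3, "axial")
  vol <- render_phantom(0, spec, grid)
  set <- binned_image_set(list(vol, vol), grid, "CT", "phase",
                          provenance = list(sphere_center_rest_mm = c(0, 0, 0)))
  p <- extract_profile(set, 0, half_length_mm = 30)
  e <- fwhm_edges(p)
  expect_equal(e[["superior"]] - e[["inferior"]], 30, tolerance = 1.5)

  # flat volume gives a flat profile
  uni <- binned_image_set(list(array(1, dim(vol))), grid, "CT", "phase")
  pf <- extract_profile(uni, 0, half_length_mm = 30)
  expect_true(all(abs(pf$I - 1) < 1e-12))

  # shifting the volume shifts the profile (cross-correlation check)
  vol5 <- render_phantom(6, spec, grid)
  set5 <- binned_image_set(list(vol5), grid, "CT", "phase")
  p5 <- extract_profile(set5, 0, half_length_mm = 30)
  cc <- vapply(-10:10, function(k) {
    n <- length(p$I)
    idx <- seq_len(n - abs(k))
    if (k >= 0) stats::cor(p5$I[idx + k], p$I[idx])
    else stats::cor(p5$I[idx], p$I[idx - k])
  }, numeric(1))
  pitch <- p$s[2] - p$s[1]
  expect_equal((-10:10)[which.max(cc)] * pitch, 6, tolerance = pitch)

  expect_error(extract_profile(set, 0, half_length_mm = 500),
               "out of field")
  expect_error(extract_profile(set, 5), "out of range")
})

test_that("translation equivariance: rigid shifts cancel in displacement", {
  spec <- phantom_spec()
  grid <- image_grid(64, 200, 24, 3, "axial")
  inhale <- render_phantom(4, spec, grid)
  exhale <- render_phantom(-4, spec, grid)
  set <- binned_image_set(list(exhale, inhale), grid, "CT", "phase")
  m0 <- measure_displacement(extract_profile(set, 1, half_length_mm = 30),
                             extract_profile(set, 0, half_length_mm = 30))
  spec2 <- phantom_spec(sphere_center_rest_mm = c(0, 0, 2.2))
  set2 <- binned_image_set(
    list(render_phantom(-4, spec2, grid), render_phantom(4, spec2, grid)),
    grid, "CT", "phase",
    provenance = list(sphere_center_rest_mm = c(0, 0, 2.2)))
  m1 <- measure_displacement(extract_profile(set2, 1, half_length_mm = 30),
                             extract_profile(set2, 0, half_length_mm = 30))
  expect_equal(m1$displacement, m0$displacement, tolerance = 0.05)
})
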