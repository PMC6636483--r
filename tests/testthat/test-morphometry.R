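test_that("flat parallel boundaries give exact 200 um at every point", {
  p <- flat_profile(200)
  th <- mean_thickness(p)
  expect_equal(th$thickness_points, rep(200, 20), tolerance = 1e-9)
  expect_equal(th$thickness_mean, 200, tolerance = 1e-9)
  expect_equal(th$n_fallback, 0)
})

test_that("perpendicular thickness on a curved section matches the offset", {
  # generator geometry: tidemark is the 180-um normal offset of the base
  # parabola, so perpendicular rays must read 180 um despite the slope
  p <- withr::with_seed(2, synth_profile(config = mf_config(),
                                         thickness_um = 180, rms_um = 0))
  th <- mean_thickness(p)
  expect_lt(abs(th$thickness_mean - 180), 1)
  expect_true(all(abs(th$thickness_points - 180) < 1.5))
})

test_that("thickness converges from 20 to 2000 points on smooth profiles", {
  p <- withr::with_seed(3, synth_profile(config = mf_config(),
                                         thickness_um = 220, rms_um = 0))
  t20 <- mean_thickness(p, 20)$thickness_mean
  t2000 <- mean_thickness(p, 2000)$thickness_mean
  expect_lt(abs(t20 - t2000) / t2000, 0.02)
})

test_that("cartilage area: rectangle and wedge closed forms", {
  rect <- cartilage_profile(
    surface = data.frame(x = c(0, 7000), y = c(200, 200)),
    tidemark = data.frame(x = c(0, 7000), y = c(0, 0)),
    roi = c(0, 7000))
  expect_equal(cartilage_area(rect), 1400000)

  wedge <- cartilage_profile(
    surface = data.frame(x = c(0, 7000), y = c(1e-9, 200)),
    tidemark = data.frame(x = c(0, 7000), y = c(0, 0)),
    roi = c(0, 7000))
  expect_equal(cartilage_area(wedge), 700000, tolerance = 1e-6)
})

test_that("trapezoidal area agrees with a shoelace polygon oracle", {
  set.seed(14)
  cfg <- mf_config()
  for (i in 1:20) {
    p <- synth_profile(preset = default_presets()$control, config = cfg)
    a <- cartilage_area(p)
    # independent oracle: shoelace formula on the closed boundary polygon
    sel_s <- p$surface$x >= p$roi[1] & p$surface$x <= p$roi[2]
    sel_t <- p$tidemark$x >= p$roi[1] & p$tidemark$x <= p$roi[2]
    px <- c(p$surface$x[sel_s], rev(p$tidemark$x[sel_t]))
    py <- c(p$surface$y[sel_s], rev(p$tidemark$y[sel_t]))
    n <- length(px)
    shoelace <- abs(sum(px * py[c(2:n, 1)] - px[c(2:n, 1)] * py)) / 2
    expect_lt(abs(a - shoelace) / shoelace, 0.001)
  }
})

test_that("boundary crossings inside the window raise a geometry error", {
  bad <- cartilage_profile(
    surface = data.frame(x = c(0, 3000, 7000), y = c(200, 100, 200)),
    tidemark = data.frame(x = c(0, 3000, 7000), y = c(0, 0, 0)),
    roi = c(0, 7000))
  bad$tidemark$y <- c(0, 150, 0)  # crosses the dipped surface
  expect_error(cartilage_area(bad), class = "cartmorph_geometry_error")
})

test_that("idealized fit recovers quadratic flanks to 1e-6 relative", {
  p <- withr::with_seed(4, synth_profile(config = mf_config(),
                                         thickness_um = 200, rms_um = 0))
  fit <- fit_idealized_surface(p, degree = 2)
  truth <- p$truth$base_coef
  expect_lt(max(abs((fit$coef - truth) / pmax(abs(truth), 1e-12))), 1e-6)
})

test_that("constant flanks give a constant idealized surface", {
  p <- flat_profile(200)
  fit <- fit_idealized_surface(p)
  expect_equal(unname(fit$sampled$y), rep(200, nrow(fit$sampled)),
               tolerance = 1e-9)
})

test_that("with a lesioned roi the fit still tracks the clean base curve", {
  p <- withr::with_seed(5, synth_profile(
    config = mf_config(), thickness_um = 200, rms_um = 7,
    lesions = data.frame(depth = "erosion_third", extent = 0.5)))
  fit <- fit_idealized_surface(p)
  xs <- p$surface$x[p$surface$x >= p$roi[1] & p$surface$x <= p$roi[2]]
  base <- p$truth$base_coef[1] + p$truth$base_coef[2] * xs +
    p$truth$base_coef[3] * xs^2
  expect_lt(max(abs(fit$predict(xs) - base)), 2)
})

test_that("missing flanks raise a fit error with guidance", {
  p <- flat_profile(200)
  p$flanks <- NULL
  expect_error(fit_idealized_surface(p), regexp = "flank",
               class = "cartmorph_fit_error")
})

test_that("RMS roughness: zero, constant offset, and sinusoid A/sqrt(2)", {
  flat <- flat_profile(200, spacing = 2)
  expect_equal(rms_roughness(flat)$rms, 0, tolerance = 1e-9)

  # constant offset d below the idealized surface -> rms = |d|
  # (offset strictly inside the roi so the flank fit stays clean)
  off <- flat_profile(200, spacing = 2)
  inner <- off$surface$x > off$roi[1] & off$surface$x < off$roi[2]
  off$surface$y[inner] <- off$surface$y[inner] - 12
  expect_equal(rms_roughness(off)$rms, 12, tolerance = 1e-3)

  sine <- sin_profile(A = 10, wavelength = 500, spacing = 1)
  rr <- rms_roughness(sine)
  expect_lt(abs(rr$rms - 10 / sqrt(2)) / (10 / sqrt(2)), 0.005)
  expect_equal(rr$n_digitized, sum(sine$surface$x >= sine$roi[1] &
                                     sine$surface$x <= sine$roi[2]))
})

test_that("empty roi raises an error", {
  p <- flat_profile(200)
  p$roi <- c(20000, 27000)
  expect_error(rms_roughness(p), class = "cartmorph_geometry_error")
})

test_that("normalized roughness is the x1000 thickness-scaled ratio", {
  expect_equal(normalized_roughness(5.39, 242.82), 1000 * 5.39 / 242.82)
  expect_equal(round(normalized_roughness(5.39, 242.82), 1), 22.2)
  expect_equal(normalized_roughness(0, 150), 0)
  expect_equal(normalized_roughness(150, 150), 1000)
  expect_equal(normalized_roughness(5, 250, scale = 1), 0.02)
  expect_error(normalized_roughness(5, 0), class = "cartmorph_domain_error")
})

test_that("uniform geometric scaling: thickness/rms linear, area quadratic,
           normalized roughness invariant", {
  p <- withr::with_seed(6, synth_profile(config = mf_config(),
                                         thickness_um = 200, rms_um = 6))
  m1 <- measure_profile(p)
  m2 <- measure_profile(transform_profile(p, s = 2))
  expect_equal(m2$thickness_um / m1$thickness_um, 2, tolerance = 1e-3)
  expect_equal(m2$rms_um / m1$rms_um, 2, tolerance = 1e-3)
  expect_equal(m2$area_um2 / m1$area_um2, 4, tolerance = 1e-3)
  expect_equal(m2$normalized_roughness, m1$normalized_roughness,
               tolerance = 1e-3)
})

test_that("rigid motion of the whole section changes results < 0.5%", {
  p <- withr::with_seed(8, synth_profile(config = mf_config(),
                                         thickness_um = 200, rms_um = 6))
  m1 <- measure_profile(p)
  shifted <- transform_profile(p, dx = 1234, dy = -567)
  m2 <- measure_profile(shifted)
  expect_equal(m2$thickness_um, m1$thickness_um, tolerance = 1e-6)
  expect_equal(m2$rms_um, m1$rms_um, tolerance = 1e-6)

  rot <- transform_profile(p, theta = 0.5 * pi / 180)
  m3 <- measure_profile(rot)
  expect_lt(abs(m3$thickness_um - m1$thickness_um) / m1$thickness_um, 0.005)
  expect_lt(abs(m3$area_um2 - m1$area_um2) / m1$area_um2, 0.005)
  expect_lt(abs(m3$rms_um - m1$rms_um) / max(m1$rms_um, 1), 0.005)
})

test_that("measured roughness increases strictly with injected fibrillation", {
  cfg <- mf_config()
  levels <- c(1, 3, 5, 7, 9)
  means <- withr::with_seed(9, vapply(levels, function(r) {
    mean(vapply(1:20, function(i) {
      p <- synth_profile(config = cfg, thickness_um = 250, rms_um = r)
      rms_roughness(p)$rms
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(cor(levels, means, method = "spearman"), 1)
  expect_true(all(diff(means) > 0))
})
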