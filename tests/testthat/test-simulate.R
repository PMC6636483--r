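test_that("study structure: 33 animals, 11 per arm, 4 compartments each", {
  study <- simulate_study(desc_config(), seed = 1)
  expect_equal(nrow(study$animals), 33)
  expect_true(all(table(study$animals$group) == 11))
  expect_equal(nrow(study$sections), 132)
  counts <- table(study$sections$animal_id)
  expect_true(all(counts == 4))
})

test_that("group sizes are conserved under block randomization for any seed", {
  for (s in c(2, 17, 991, 123456)) {
    study <- simulate_study(desc_config(n_per_group = 5), seed = s)
    expect_true(all(table(study$animals$group) == 5))
  }
})

test_that("identical (config, seed) reproduces byte-identical datasets", {
  cfg <- mf_config(n_per_group = 3)
  s1 <- simulate_study(cfg, seed = 42)
  s2 <- simulate_study(cfg, seed = 42)
  expect_identical(s1$animals, s2$animals)
  expect_identical(s1$sections, s2$sections)
  s3 <- simulate_study(cfg, seed = 43)
  expect_false(identical(s1$sections$true_thickness_um,
                         s3$sections$true_thickness_um))
})

test_that("profiles carry exact truth: realized roi RMS and mean separation", {
  cfg <- mf_config()
  study <- simulate_cohort(default_presets()$control, n = 6, config = cfg,
                           seed = 5)
  profs <- Filter(Negate(is.null), study$sections$profile)
  for (p in profs) {
    xs <- p$surface$x
    in_roi <- xs >= p$roi[1] & xs <= p$roi[2]
    base <- p$truth$base_coef[1] + p$truth$base_coef[2] * xs +
      p$truth$base_coef[3] * xs^2
    realized_rms <- sqrt(mean((p$surface$y - base)[in_roi]^2))
    expect_equal(realized_rms, p$truth$rms_um, tolerance = 1e-8)
    expect_true(all(diff(p$surface$x) > 0))
    expect_true(all(diff(p$surface$x) <= 5 + 1e-9))  # digitization spacing
  }
})

test_that("smooth lesion-free profile measures at its true geometry", {
  p <- withr::with_seed(1, synth_profile(config = mf_config(),
                                         thickness_um = 200, rms_um = 0))
  m <- measure_profile(p)
  expect_lt(abs(m$thickness_um - 200), 1)
  expect_lt(m$rms_um, 0.5)
})

test_that("injected fibrillation RMS is recovered within 10% over 50 profiles", {
  cfg <- mf_config()
  est <- withr::with_seed(7, vapply(1:50, function(i) {
    p <- synth_profile(config = cfg, thickness_um = 250, rms_um = 5)
    rms_roughness(p)$rms
  }, numeric(1)))
  expect_lt(abs(mean(est) - 5) / 5, 0.10)
})

test_that("a full-depth lesion over half the surface scores 9 or 11", {
  lesions <- data.frame(depth = "full_depth", extent = 0.6)
  expect_identical(score_structure(lesions), 9L)
  lesions2 <- data.frame(depth = "full_depth_calcified", extent = 0.5)
  expect_identical(score_structure(lesions2), 11L)
})

test_that("serum panel honours the assay range and degenerate sds", {
  hp <- healthy_preset()  # zero serum sds
  vals <- withr::with_seed(1, synth_serum(hp))
  expect_equal(unname(vals), unname(hp$serum_means), tolerance = 1e-12)

  high <- hp
  high$serum_means[] <- c(500, 500, 500)
  expect_warning(v <- withr::with_seed(1, synth_serum(high)),
                 class = "cartmorph_clip_warning")
  expect_true(all(v == 100))

  study <- simulate_study(desc_config(), seed = 2)
  expect_true(all(study$animals$comp >= 1.56 & study$animals$comp <= 100))
})

test_that("a 2-SD COMP separation is detected by ANOVA in most simulations", {
  sep2 <- function(label, mu) {
    p <- healthy_preset()
    p$group_label <- label
    p$serum_means[] <- c(mu, 18, 40)
    p$serum_sds[] <- c(8, 5, 10)
    p
  }
  presets <- list(control = sep2("control", 52), channa = sep2("channa", 36))
  hits <- withr::with_seed(99, vapply(1:200, function(i) {
    vals <- lapply(presets, function(p)
      vapply(1:11, function(j) suppressWarnings(synth_serum(p))[["comp"]],
             numeric(1)))
    df <- data.frame(y = unlist(vals),
                     g = rep(names(presets), each = 11))
    anova(aov(y ~ g, data = df))[["Pr(>F)"]][1] < 0.05
  }, logical(1)))
  expect_gte(mean(hits), 0.80)
})

test_that("invalid preset probabilities raise a configuration error", {
  expect_error(
    group_preset("x", 200, 10, 20, 2, 400,
                 structure_mean = c(MF = 1, LF = 1, MT = 1, LT = 1),
                 density_mean = c(MF = 1, LF = 1, MT = 1, LT = 1),
                 cluster_mean = c(MF = 1, LF = 1, MT = 1, LT = 1),
                 macro_probs = list(MF = c(0.5, 0.5, 0.5, 0.5),
                                    LF = c(1, 0, 0, 0), MT = c(1, 0, 0, 0),
                                    LT = c(1, 0, 0, 0)),
                 serum_means = c(comp = 1, cox2 = 1, pge2 = 1),
                 serum_sds = c(comp = 0, cox2 = 0, pge2 = 0)),
    regexp = "macro_probs\\$MF", class = "cartmorph_config_error")
})

test_that("preset probability vectors are proper distributions", {
  for (p in default_presets()) {
    for (comp in c("MF", "LF", "MT", "LT")) {
      expect_equal(sum(p$structure_dist[[comp]]), 1, tolerance = 1e-9)
      expect_equal(sum(p$density_dist[[comp]]), 1, tolerance = 1e-9)
      expect_equal(sum(p$macro_probs[[comp]]), 1, tolerance = 1e-9)
      expect_length(p$macro_probs[[comp]], 4)
    }
    expect_gt(p$thickness_mean, 0)
    expect_gte(p$fibrillation_rms, 0)
  }
})

test_that("preset expected scores match their calibration targets exactly", {
  # E[structure] + E[density] + E[clusters] per compartment sums to the
  # preset's compartment mean; totals are 15.73 / 17.55 / 28.27.
  targets <- c(channa = 15.73, glucosamine = 17.55, control = 28.27)
  for (g in names(targets)) {
    p <- default_presets()[[g]]
    total <- 0
    for (comp in c("MF", "LF", "MT", "LT")) {
      es <- sum(0:11 * p$structure_dist[[comp]])
      ed <- sum(0:4 * p$density_dist[[comp]])
      lam <- p$cluster_lambda[[comp]]
      ec <- sum(dpois(0:300, lam) *
                  c(0, 1, 1, 1, 2, 2, 2, 2, rep(3, 293)))
      expect_equal(es, p$structure_mean[[comp]], tolerance = 1e-9)
      expect_equal(ed, p$density_mean[[comp]], tolerance = 1e-9)
      expect_equal(ec, p$cluster_mean[[comp]], tolerance = 1e-6)
      total <- total + es + ed + ec
    }
    expect_equal(total, targets[[g]], tolerance = 1e-5)
  }
})
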