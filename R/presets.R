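#' Construct a group preset for the synthetic-study generator
#'
#' A group preset is the ground truth for one experimental arm of a
#' simulated ACLT osteoarthritis study.  It fixes the between-animal
#' distribution of cartilage thickness and normalized surface roughness
#' on the medial femoral condyle, per-compartment distributions for the
#' modified OARSI components (structure, chondrocyte density, cluster
#' formation), per-compartment India-ink grade probabilities, and serum
#' analyte levels.  Downstream measurement and scoring stages are
#' validated by recovering these values from the generated data.
#'
#' Roughness is parameterized through the thickness-normalized ratio
#' (RMS roughness / thickness, reported x1000): each animal draws a
#' ratio and its true RMS roughness is `ratio * thickness / 1000`.  The
#' group-level `fibrillation_rms` (mean RMS deviation in micrometres) is
#' derived from the two means and stored for reference.
#'
#' Structure scores are drawn per compartment from a probability vector
#' over the 12 rubric rows (a joint law over erosion depth category and
#' surface extent); by default a binomial(11, mean/11) profile with the
#' requested expected score.  Density patterns use binomial(4, mean/4)
#' over the five categories, and cluster counts are Poisson with the
#' rate solved so the expected cluster score equals the requested value.
#'
#' @param group_label One of `"channa"`, `"glucosamine"`, `"control"`
#'   (or any label for custom arms).
#' @param thickness_mean,thickness_sd Between-animal mean and sd of true
#'   cartilage thickness, micrometres.
#' @param norm_roughness_mean,norm_roughness_sd Between-animal mean and
#'   sd of the true normalized roughness ratio (dimensionless x1000).
#' @param area_window_um Width (micrometres) of the centered evaluation
#'   window used for the cartilage-area endpoint (see the methods
#'   vignette for why this is narrower than the full region of
#'   interest).
#' @param structure_mean,density_mean,cluster_mean Named numeric vectors
#'   (names `MF`, `LF`, `MT`, `LT`) of expected per-compartment scores
#'   on the structure (0-11), density (0-4) and cluster (0-3) scales.
#' @param macro_probs Named list of four probability vectors, each of
#'   length 4, giving per-compartment probabilities of India-ink grades
#'   1-4.
#' @param serum_means,serum_sds Named numeric vectors (`comp`, `cox2`,
#'   `pge2`) of serum analyte means and sds in ng/ml.
#' @param extra_lesion_rate Expected number of secondary (milder)
#'   lesions added per compartment beyond the primary lesion, to
#'   exercise the most-severe-lesion scoring rule.
#'
#' @return An object of class `cart_preset`.
#' @seealso [default_presets()], [healthy_preset()], [simulate_study()]
#' @export
group_preset <- function(group_label,
                         thickness_mean, thickness_sd,
                         norm_roughness_mean, norm_roughness_sd,
                         area_window_um,
                         structure_mean, density_mean, cluster_mean,
                         macro_probs,
                         serum_means, serum_sds,
                         extra_lesion_rate = 0.7) {
  comps <- compartment_levels()
  check_comp_named <- function(x, what) {
    if (!all(comps %in% names(x))) {
      cm_abort(paste0("`", what, "` must be named with all of ",
                      paste(comps, collapse = ", ")), "cartmorph_config_error")
    }
    x[comps]
  }
  structure_mean <- check_comp_named(structure_mean, "structure_mean")
  density_mean <- check_comp_named(density_mean, "density_mean")
  cluster_mean <- check_comp_named(cluster_mean, "cluster_mean")
  macro_probs <- check_comp_named(macro_probs, "macro_probs")

  if (thickness_mean <= 0) {
    cm_abort("`thickness_mean` must be positive", "cartmorph_config_error")
  }
  if (norm_roughness_mean < 0) {
    cm_abort("`norm_roughness_mean` must be non-negative", "cartmorph_config_error")
  }
  if (any(structure_mean < 0 | structure_mean > 11)) {
    cm_abort("`structure_mean` values must lie in [0, 11]", "cartmorph_config_error")
  }
  if (any(density_mean < 0 | density_mean > 4)) {
    cm_abort("`density_mean` values must lie in [0, 4]", "cartmorph_config_error")
  }
  if (any(cluster_mean < 0 | cluster_mean >= 3)) {
    cm_abort("`cluster_mean` values must lie in [0, 3)", "cartmorph_config_error")
  }
  for (comp in comps) {
    p <- macro_probs[[comp]]
    if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      cm_abort(paste0("`macro_probs$", comp,
                      "` must be 4 non-negative probabilities summing to 1"),
               "cartmorph_config_error")
    }
  }
  ana <- serum_analytes()
  if (!all(ana %in% names(serum_means)) || !all(ana %in% names(serum_sds))) {
    cm_abort("`serum_means` and `serum_sds` must be named comp, cox2, pge2",
             "cartmorph_config_error")
  }

  structure_dist <- lapply(structure_mean, function(m) dbinom(0:11, 11, m / 11))
  density_dist <- lapply(density_mean, function(m) dbinom(0:4, 4, m / 4))
  cluster_lambda <- vapply(cluster_mean, solve_cluster_lambda, numeric(1))

  structure(list(
    group_label = group_label,
    thickness_mean = thickness_mean,
    thickness_sd = thickness_sd,
    norm_roughness_mean = norm_roughness_mean,
    norm_roughness_sd = norm_roughness_sd,
    fibrillation_rms = norm_roughness_mean * thickness_mean / 1000,
    area_window_um = area_window_um,
    structure_mean = structure_mean,
    structure_dist = structure_dist,
    density_mean = density_mean,
    density_dist = density_dist,
    cluster_mean = cluster_mean,
    cluster_lambda = cluster_lambda,
    macro_probs = macro_probs,
    serum_means = serum_means[ana],
    serum_sds = serum_sds[ana],
    extra_lesion_rate = extra_lesion_rate
  ), class = "cart_preset")
}

# Expected cluster score for a Poisson(lambda) cluster count under the
# rubric bands 0 / 1-3 / 4-7 / >=8.
expected_cluster_score <- function(lambda) {
  if (lambda <= 0) return(0)
  p13 <- sum(dpois(1:3, lambda))
  p47 <- sum(dpois(4:7, lambda))
  p8 <- 1 - sum(dpois(0:7, lambda))
  p13 + 2 * p47 + 3 * p8
}

solve_cluster_lambda <- function(target) {
  if (target <= 0) return(0)
  if (target >= 3) {
    cm_abort("expected cluster score must be below 3", "cartmorph_config_error")
  }
  uniroot(function(l) expected_cluster_score(l) - target,
          lower = 1e-9, upper = 200, tol = 1e-10)$root
}

#' Default group presets calibrated to a three-arm rabbit ACLT study
#'
#' Returns presets for the Channa striatus, glucosamine sulphate and
#' untreated control arms of an eleven-animal-per-group ACLT study.
#' Between-animal spreads are derived from reported standard errors
#' (`sd = SEM * sqrt(11)`); per-compartment OARSI component means are
#' split 55/30/15 between structure, density and clusters; India-ink
#' grade probabilities are calibrated so per-compartment and total
#' medians match the reference severity pattern.  See the methods
#' vignette for the full calibration rationale.
#'
#' @return Named list of three [group_preset()] objects
#'   (`channa`, `glucosamine`, `control`).
#' @export
default_presets <- function() {
  split3 <- function(total) {
    c(structure = 0.55 * total, density = 0.30 * total, cluster = 0.15 * total)
  }
  comp_means <- list(
    channa      = c(MF = 4.36, LF = 5.00, MT = 2.55, LT = 3.82),  # total 15.73
    glucosamine = c(MF = 3.64, LF = 6.00, MT = 3.60, LT = 4.31),  # total 17.55
    control     = c(MF = 7.27, LF = 7.73, MT = 5.82, LT = 7.45)   # total 28.27
  )
  components <- lapply(comp_means, function(m) {
    s <- vapply(m, split3, numeric(3))
    list(structure = s["structure", ], density = s["density", ],
         cluster = s["cluster", ])
  })

  macro <- list(
    channa = list(LF = c(0.90, 0.07, 0.02, 0.01), MF = c(0.82, 0.12, 0.04, 0.02),
                  LT = c(0.90, 0.07, 0.02, 0.01), MT = c(0.82, 0.12, 0.04, 0.02)),
    glucosamine = list(LF = c(0.10, 0.35, 0.38, 0.17), MF = c(0.15, 0.55, 0.22, 0.08),
                       LT = c(0.15, 0.55, 0.22, 0.08), MT = c(0.15, 0.55, 0.22, 0.08)),
    control = list(LF = c(0.05, 0.30, 0.45, 0.20), MF = c(0.05, 0.30, 0.45, 0.20),
                   LT = c(0.10, 0.55, 0.28, 0.07), MT = c(0.10, 0.55, 0.28, 0.07))
  )

  sqrt11 <- sqrt(11)
  list(
    channa = group_preset(
      "channa",
      thickness_mean = 242.82, thickness_sd = 12.79 * sqrt11,
      norm_roughness_mean = 22.18, norm_roughness_sd = 2.35 * sqrt11,
      area_window_um = 97722.27 / 242.82,
      structure_mean = components$channa$structure,
      density_mean = components$channa$density,
      cluster_mean = components$channa$cluster,
      macro_probs = macro$channa,
      serum_means = c(comp = 36, cox2 = 18, pge2 = 40),
      serum_sds = c(comp = 8, cox2 = 5, pge2 = 10)
    ),
    glucosamine = group_preset(
      "glucosamine",
      thickness_mean = 211.73, thickness_sd = 10.60 * sqrt11,
      norm_roughness_mean = 33.82, norm_roughness_sd = 2.17 * sqrt11,
      area_window_um = 79368.91 / 211.73,
      structure_mean = components$glucosamine$structure,
      density_mean = components$glucosamine$density,
      cluster_mean = components$glucosamine$cluster,
      macro_probs = macro$glucosamine,
      serum_means = c(comp = 38, cox2 = 18, pge2 = 40),
      serum_sds = c(comp = 8, cox2 = 5, pge2 = 10)
    ),
    control = group_preset(
      "control",
      thickness_mean = 155.73, thickness_sd = 19.50 * sqrt11,
      norm_roughness_mean = 45.10, norm_roughness_sd = 4.17 * sqrt11,
      area_window_um = 57895.82 / 155.73,
      structure_mean = components$control$structure,
      density_mean = components$control$density,
      cluster_mean = components$control$cluster,
      macro_probs = macro$control,
      serum_means = c(comp = 52, cox2 = 18, pge2 = 40),
      serum_sds = c(comp = 8, cox2 = 5, pge2 = 10)
    )
  )
}

#' Preset for a healthy (lesion-free) arm
#'
#' All lesion, density, cluster and fibrillation parameters are zero and
#' every compartment is India-ink grade 1, so the scored OARSI total is
#' 0 and the macroscopic total is 4 (grades floor at 1) for every
#' animal.  Useful as a negative control in recovery tests.
#'
#' @param thickness_mean,thickness_sd True thickness distribution, um.
#' @return A [group_preset()] object.
#' @export
healthy_preset <- function(thickness_mean = 250, thickness_sd = 0) {
  zero4 <- setNames(rep(0, 4), compartment_levels())
  intact <- lapply(setNames(compartment_levels(), compartment_levels()),
                   function(.) c(1, 0, 0, 0))
  group_preset(
    "healthy",
    thickness_mean = thickness_mean, thickness_sd = thickness_sd,
    norm_roughness_mean = 0, norm_roughness_sd = 0,
    area_window_um = 7000,
    structure_mean = zero4, density_mean = zero4, cluster_mean = zero4,
    macro_probs = intact,
    serum_means = c(comp = 20, cox2 = 15, pge2 = 30),
    serum_sds = c(comp = 0, cox2 = 0, pge2 = 0),
    extra_lesion_rate = 0
  )
}

#' Study configuration for simulation and the end-to-end pipeline
#'
#' Bundles the group presets with the geometric, scoring and statistical
#' settings shared by all pipeline stages.
#'
#' @param presets Named list of [group_preset()] objects, one per arm.
#' @param n_per_group Animals per arm (default 11, a three-arm study of
#'   33 animals).
#' @param roi_um Length of the weight-bearing region of interest over
#'   which thickness, area and roughness are evaluated (micrometres).
#' @param flank_um Length of the normal-cartilage flank on each side of
#'   the region of interest, used to fit the idealized surface.
#' @param spacing_um Digitization spacing of profile polylines.
#' @param arc_radius_um Apex radius of curvature of the condylar base
#'   curve.
#' @param edge_taper_um Width of the cosine taper that fades the
#'   fibrillation field to zero at the region-of-interest edges.
#' @param pixel_size_um Pixel size used when rendering section rasters.
#' @param profile_compartments Compartments for which full boundary
#'   profiles are generated (descriptors are always generated for all
#'   four).  Quantitative histomorphometry uses the medial femoral
#'   condyle, so `"MF"` alone is sufficient for measurement studies.
#' @param n_thickness_points Number of perpendicular thickness
#'   measurements per section.
#' @param fit_degree Polynomial degree of the idealized-surface fit.
#' @param alpha Significance level for all gates and flags.
#' @param adjust Pairwise adjustment method for the ordinal pipeline
#'   (`"bonferroni"` or any method accepted by [stats::p.adjust()]).
#' @param normalized_scale Reporting multiplier for normalized roughness
#'   (1000 reports the dimensionless ratio x1000).
#'
#' @return An object of class `cart_config`.
#' @export
study_config <- function(presets = default_presets(),
                         n_per_group = 11,
                         roi_um = 7000,
                         flank_um = 1500,
                         spacing_um = 4,
                         arc_radius_um = 15000,
                         edge_taper_um = 250,
                         pixel_size_um = 2,
                         profile_compartments = compartment_levels(),
                         n_thickness_points = 20,
                         fit_degree = 2,
                         alpha = 0.05,
                         adjust = "bonferroni",
                         normalized_scale = 1000) {
  if (!length(presets) || !all(vapply(presets, inherits, logical(1), "cart_preset"))) {
    cm_abort("`presets` must be a named list of `cart_preset` objects",
             "cartmorph_config_error")
  }
  if (is.null(names(presets)) || any(names(presets) == "")) {
    cm_abort("`presets` must be named by group", "cartmorph_config_error")
  }
  if (roi_um <= 0 || flank_um <= 0 || spacing_um <= 0 || spacing_um > 5) {
    cm_abort("geometry settings invalid: need roi_um, flank_um > 0 and 0 < spacing_um <= 5",
             "cartmorph_config_error")
  }
  bad <- setdiff(profile_compartments, compartment_levels())
  if (length(bad)) {
    cm_abort(paste0("unknown compartments: ", paste(bad, collapse = ", ")),
             "cartmorph_config_error")
  }
  structure(list(
    presets = presets,
    n_per_group = as.integer(n_per_group),
    roi_um = roi_um,
    flank_um = flank_um,
    spacing_um = spacing_um,
    arc_radius_um = arc_radius_um,
    edge_taper_um = edge_taper_um,
    pixel_size_um = pixel_size_um,
    profile_compartments = profile_compartments,
    n_thickness_points = as.integer(n_thickness_points),
    fit_degree = as.integer(fit_degree),
    alpha = alpha,
    adjust = adjust,
    normalized_scale = normalized_scale
  ), class = "cart_config")
}

#' @export
print.cart_preset <- function(x, ...) {
  cat("<cart_preset> ", x$group_label, "\n", sep = "")
  cat(sprintf("  thickness      %.2f um (sd %.2f)\n", x$thickness_mean, x$thickness_sd))
  cat(sprintf("  norm roughness %.2f x1000 (sd %.2f); RMS ~%.2f um\n",
              x$norm_roughness_mean, x$norm_roughness_sd, x$fibrillation_rms))
  cat(sprintf("  OARSI compartment means: %s\n",
              paste(sprintf("%s %.2f", names(x$structure_mean),
                            x$structure_mean + x$density_mean + x$cluster_mean),
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.cart_config <- function(x, ...) {
  cat("<cart_config>\n")
  cat("  groups:", paste(names(x$presets), collapse = ", "), "\n")
  cat(sprintf("  n per group %d; roi %g um; flanks %g um; spacing %g um\n",
              x$n_per_group, x$roi_um, x$flank_um, x$spacing_um))
  cat(sprintf("  profiles for: %s\n", paste(x$profile_compartments, collapse = ", ")))
  invisible(x)
}
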