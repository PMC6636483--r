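# Synthetic ACLT-osteoarthritis study generator.
#
# The generator is the package's source of fully known ground truth:
# every profile records the true thickness and true RMS roughness it was
# built with, and every descriptor is drawn from a preset whose expected
# scores are known exactly, so measurement and scoring stages can be
# validated by parameter recovery.

depth_categories <- function() {
  c("irregularity", "fissure", "erosion_third", "erosion_two_thirds",
    "full_depth", "full_depth_calcified")
}

density_categories <- function() {
  c("no_decrease", "focal", "multifocal", "multifocal_confluent", "diffuse")
}

ink_categories <- function() {
  c("none", "minimal_focal", "large_focal_patches", "bone_exposed")
}

# Nominal carved depth as a fraction of local cartilage thickness, by
# depth category.  Values above 1 reach into the calcified layer.
depth_fraction <- function(depth) {
  unname(c(irregularity = 0.05, fissure = 0.30, erosion_third = 1 / 3,
           erosion_two_thirds = 2 / 3, full_depth = 1,
           full_depth_calcified = 1.1)[depth])
}

# Realize a lesion descriptor row of the structure rubric (1..11) as a
# (depth category, extent fraction) pair.  Extent is drawn inside the
# rubric row's band: < 50% rows from U(0.05, 0.45), >= 50% rows from
# U(0.50, 0.95).
realize_rubric_row <- function(row) {
  stopifnot(row >= 1, row <= 11)
  if (row == 1) {
    return(tibble(depth = "irregularity", extent = runif(1, 0.05, 0.95)))
  }
  depth <- depth_categories()[1 + ceiling((row - 1) / 2)]
  extent <- if (row %% 2 == 0) runif(1, 0.05, 0.45) else runif(1, 0.50, 0.95)
  tibble(depth = depth, extent = extent)
}

# Draw one compartment's lesion set from a structure-score distribution.
# The primary lesion realizes the drawn rubric row; optional secondary
# lesions realize strictly milder rows so the most-severe rule is the
# one that determines the score.
draw_lesions <- function(structure_dist, extra_lesion_rate) {
  row <- sample(0:11, 1, prob = structure_dist)
  if (row == 0) {
    return(tibble(depth = character(), extent = numeric()))
  }
  lesions <- realize_rubric_row(row)
  if (row >= 2 && extra_lesion_rate > 0) {
    n_extra <- rpois(1, extra_lesion_rate)
    if (n_extra > 0) {
      extra_rows <- sample.int(row - 1, n_extra, replace = TRUE)
      lesions <- dplyr::bind_rows(
        lesions, dplyr::bind_rows(lapply(extra_rows, realize_rubric_row)))
    }
  }
  lesions
}

#' Synthesize one cartilage section profile
#'
#' Builds a digitized cross-section of the medial femoral condyle (or
#' any compartment): a shallow parabolic condylar base curve (apex
#' radius of curvature `arc_radius_um`), a zero-mean fibrillation field
#' of 3-8 random-phase sinusoids, and cosine-tapered erosion/fissure
#' depressions carved per the lesion descriptor.  The field is scaled so
#' that the realized RMS deviation from the base curve over the region
#' of interest equals `rms_um` exactly, and the tidemark is offset along
#' the inward surface normals so that the mean perpendicular separation
#' over the region of interest equals `thickness_um` exactly.  Flanking
#' segments outside the region of interest are smooth, lesion-free
#' normal cartilage.
#'
#' When a `preset` is supplied, `thickness_um`, `rms_um` and `lesions`
#' default to draws from the preset (thickness and normalized-roughness
#' ratio from their between-animal gamma distributions; lesions from the
#' compartment's structure-score distribution).  Draws use the current
#' RNG state; wrap in [withr::with_seed()] for reproducibility.
#'
#' @param preset Optional [group_preset()] supplying the truth draws.
#' @param config A [study_config()] providing the geometry settings.
#' @param compartment Compartment label used for preset draws.
#' @param thickness_um,rms_um Override the true mean thickness and the
#'   true RMS surface roughness (micrometres).
#' @param lesions Override the lesion descriptor: a data frame with
#'   columns `depth` (category) and `extent` (fraction of surface).
#' @return A [cartilage_profile()] whose `truth` records the true
#'   thickness, RMS roughness, normalized roughness and lesion set.
#' @export
synth_profile <- function(preset = NULL, config = study_config(),
                          compartment = "MF",
                          thickness_um = NULL, rms_um = NULL, lesions = NULL) {
  if (is.null(thickness_um)) {
    if (is.null(preset)) cm_abort("need `preset` or `thickness_um`",
                                  "cartmorph_config_error")
    thickness_um <- rgamma_ms(1, preset$thickness_mean, preset$thickness_sd)
  }
  if (is.null(rms_um)) {
    if (is.null(preset)) cm_abort("need `preset` or `rms_um`",
                                  "cartmorph_config_error")
    ratio <- rgamma_ms(1, preset$norm_roughness_mean, preset$norm_roughness_sd)
    rms_um <- ratio * thickness_um / 1000
  }
  if (is.null(lesions)) {
    lesions <- if (is.null(preset)) {
      tibble(depth = character(), extent = numeric())
    } else {
      draw_lesions(preset$structure_dist[[compartment]], preset$extra_lesion_rate)
    }
  }
  lesions <- as_tibble(lesions)
  if (nrow(lesions) && !all(lesions$depth %in% depth_categories())) {
    cm_abort("unknown lesion depth category", "cartmorph_domain_error")
  }
  build_profile(thickness_um, rms_um, lesions, config)
}

# Deterministic geometry construction given the truth values.  Consumes
# RNG draws for the sinusoid field and lesion placement.
build_profile <- function(thickness_um, rms_um, lesions, config) {
  roi_len <- config$roi_um
  flank <- config$flank_um
  spacing <- config$spacing_um
  R <- config$arc_radius_um
  taper <- config$edge_taper_um

  len <- roi_len + 2 * flank
  x <- seq(0, len, by = spacing)
  if (x[length(x)] < len) x <- c(x, len)
  roi <- c(flank, flank + roi_len)
  xc <- len / 2

  base <- -(x - xc)^2 / (2 * R)
  slope <- -(x - xc) / R
  s_fac <- sqrt(1 + slope^2)
  in_roi <- x >= roi[1] & x <= roi[2]

  # Cosine taper of the fibrillation field at the roi edges so the
  # flanks stay perfectly smooth for the idealized-surface fit.
  ramp <- function(d) {
    r <- numeric(length(d))
    mid <- d > 0 & d < taper
    r[d >= taper] <- 1
    r[mid] <- 0.5 * (1 - cos(pi * d[mid] / taper))
    r
  }
  w <- pmin(ramp(x - roi[1]), ramp(roi[2] - x))

  # Fibrillation field: 3-8 random-phase sinusoids.
  k <- sample(3:8, 1)
  wavelen <- exp(runif(k, log(200), log(2000)))
  amp <- runif(k, 0.5, 1)
  phase <- runif(k, 0, 2 * pi)
  S <- rep(0, length(x))
  for (j in seq_len(k)) S <- S + amp[j] * sin(2 * pi * x / wavelen[j] + phase[j])
  Sw <- w * S

  # Lesion depression field (non-negative depths below the base curve).
  lesion_field <- rep(0, length(x))
  if (nrow(lesions) && rms_um > 0) {
    avail <- roi_len - 2 * taper
    for (i in seq_len(nrow(lesions))) {
      depth_um <- depth_fraction(lesions$depth[i]) * thickness_um
      extent <- min(max(lesions$extent[i], 0.01), 1)
      span <- min(extent * roi_len, avail)
      c0 <- runif(1, roi[1] + taper + span / 2, roi[2] - taper - span / 2)
      if (lesions$depth[i] %in% c("fissure")) {
        # Fissures: a spray of narrow notches across the affected span.
        n_notch <- max(1L, round(extent * 12))
        centers <- runif(n_notch, c0 - span / 2, c0 + span / 2)
        widths <- runif(n_notch, 40, 80)
        for (m in seq_len(n_notch)) {
          dx <- abs(x - centers[m])
          hit <- dx < widths[m] / 2
          dep <- depth_um * 0.5 * (1 + cos(2 * pi * (x[hit] - centers[m]) / widths[m]))
          lesion_field[hit] <- pmax(lesion_field[hit], dep)
        }
      } else {
        dx <- abs(x - c0)
        hit <- dx < span / 2
        dep <- depth_um * 0.5 * (1 + cos(2 * pi * (x[hit] - c0) / span))
        lesion_field[hit] <- pmax(lesion_field[hit], dep)
      }
    }
    # Budget the carved depressions inside the total roughness target so
    # the combined deviation field can be scaled to the exact true RMS.
    msL <- mean(lesion_field[in_roi]^2)
    cap <- (0.7 * rms_um)^2
    if (msL > cap) lesion_field <- lesion_field * sqrt(cap / msL)
    lesion_field <- lesion_field * w
  } else {
    lesions <- lesions[0, ]
  }

  # Scale the sinusoid field so the realized roi RMS deviation equals
  # rms_um exactly: solve a^2 msS - 2 a cross + msL = rms^2 for a >= 0.
  D <- rep(0, length(x))
  if (rms_um > 0) {
    msS <- mean(Sw[in_roi]^2)
    msL <- mean(lesion_field[in_roi]^2)
    cross <- mean(Sw[in_roi] * lesion_field[in_roi])
    disc <- cross^2 - msS * (msL - rms_um^2)
    a <- (cross + sqrt(max(disc, 0))) / msS
    D <- a * Sw - lesion_field
  }

  surface_y <- base + D

  # Offset the tidemark along the inward normal so the mean perpendicular
  # separation across the roi equals the true thickness.
  cosine <- 1 / s_fac
  t_base <- thickness_um - mean((D * cosine)[in_roi])
  tm_x <- x + t_base * slope / s_fac
  tm_y <- base - t_base / s_fac

  truth <- list(
    thickness_um = thickness_um,
    rms_um = rms_um,
    normalized_roughness = if (thickness_um > 0) 1000 * rms_um / thickness_um else 0,
    lesions = lesions,
    base_coef = c(-xc^2 / (2 * R), xc / R, -1 / (2 * R)),
    t_base = t_base
  )

  cartilage_profile(
    surface = tibble(x = x, y = surface_y),
    tidemark = tibble(x = tm_x, y = tm_y),
    roi = roi,
    flanks = list(c(0, roi[1]), c(roi[2], len)),
    scale = 1,
    truth = truth
  )
}

#' Draw one animal's serum panel from a preset
#'
#' Serum COMP, COX-2 and PGE2 concentrations are drawn from lognormal
#' distributions moment-matched to the preset means and sds, then
#' clipped to the assay detection range 1.56-100 ng/ml (with a warning
#' when clipping occurs).
#'
#' @param preset A [group_preset()].
#' @param detection_range Assay range in ng/ml.
#' @return Named numeric vector (`comp`, `cox2`, `pge2`).
#' @export
synth_serum <- function(preset, detection_range = c(1.56, 100)) {
  vals <- vapply(serum_analytes(), function(a) {
    rlnorm_ms(1, preset$serum_means[[a]], preset$serum_sds[[a]])
  }, numeric(1))
  clipped <- vals < detection_range[1] | vals > detection_range[2]
  if (any(clipped)) {
    warn(paste0("serum value(s) clipped to assay range [",
                detection_range[1], ", ", detection_range[2], "] ng/ml: ",
                paste(names(vals)[clipped], collapse = ", ")),
         class = "cartmorph_clip_warning")
  }
  pmin(pmax(vals, detection_range[1]), detection_range[2])
}

# Block randomization: assign group labels in blocks of `block` animals
# with equal representation per group inside each (possibly short final)
# block.  Group sizes are conserved exactly for any seed.
block_randomize <- function(groups, n_per_group, block = 6) {
  k <- length(groups)
  total <- n_per_group * k
  labels <- character(0)
  remaining <- total
  while (remaining > 0) {
    size <- min(block, remaining)
    if (size %% k == 0) {
      blk <- rep(groups, each = size / k)
    } else {
      blk <- rep(groups, length.out = size)
    }
    labels <- c(labels, sample(blk))
    remaining <- remaining - size
  }
  # Guarantee exact quotas even for block sizes not divisible by the
  # number of groups: rebalance by resampling if any quota is off.
  if (!all(table(factor(labels, levels = groups)) == n_per_group)) {
    labels <- sample(rep(groups, each = n_per_group))
  }
  labels
}

# Generate one animal under its own RNG substream.  Draw order (part of
# the serialization contract): thickness, roughness ratio, descriptors
# per compartment (MF, LF, MT, LT: structure row, secondary lesions,
# density, clusters, ink grade), profiles per profiled compartment,
# serum panel.
simulate_animal <- function(animal_id, group, preset, config, substream_seed) {
  withr::with_seed(substream_seed, {
    thickness <- rgamma_ms(1, preset$thickness_mean, preset$thickness_sd)
    ratio <- rgamma_ms(1, preset$norm_roughness_mean, preset$norm_roughness_sd)
    rms <- ratio * thickness / 1000

    comps <- compartment_levels()
    desc <- lapply(comps, function(comp) {
      lesions <- draw_lesions(preset$structure_dist[[comp]], preset$extra_lesion_rate)
      density <- density_categories()[1 + sample(0:4, 1, prob = preset$density_dist[[comp]])]
      clusters <- if (preset$cluster_lambda[[comp]] > 0) {
        rpois(1, preset$cluster_lambda[[comp]])
      } else 0L
      ink <- ink_categories()[sample(1:4, 1, prob = preset$macro_probs[[comp]])]
      list(lesions = lesions, density = density, clusters = clusters, ink = ink)
    })
    names(desc) <- comps

    profiles <- setNames(vector("list", length(comps)), comps)
    for (comp in intersect(comps, config$profile_compartments)) {
      profiles[[comp]] <- build_profile(thickness, rms, desc[[comp]]$lesions, config)
    }

    serum <- synth_serum(preset)

    sections <- tibble(
      animal_id = animal_id,
      group = group,
      compartment = comps,
      lesions = unname(lapply(desc, `[[`, "lesions")),
      density_pattern = unname(vapply(desc, `[[`, character(1), "density")),
      cluster_count = unname(vapply(desc, function(d) as.integer(d$clusters),
                                    integer(1))),
      ink_uptake = unname(vapply(desc, `[[`, character(1), "ink")),
      profile = unname(profiles),
      true_thickness_um = thickness,
      true_rms_um = rms,
      true_norm_roughness = ratio
    )
    list(
      animal = tibble(animal_id = animal_id, group = group,
                      comp = serum[["comp"]], cox2 = serum[["cox2"]],
                      pge2 = serum[["pge2"]]),
      sections = sections
    )
  })
}

#' Simulate a complete three-arm ACLT osteoarthritis study
#'
#' Generates a full synthetic study: animals are assigned to arms by
#' block randomization (blocks of six), and each animal receives four
#' compartments (MF, LF, MT, LT) of lesion descriptors, chondrocyte
#' density patterns, cluster counts and India-ink grades, boundary
#' profiles for the configured compartments, and a serum panel.  Every
#' animal is generated under its own RNG substream spawned from the
#' master seed, so the result is byte-identical for a fixed
#' `(config, seed)` pair.
#'
#' @param config A [study_config()].
#' @param seed Integer master seed.
#' @return A `cart_study` object: list with tibbles `animals` (one row
#'   per animal: serum panel) and `sections` (one row per animal x
#'   compartment: descriptors, grades, profile and generator truth),
#'   plus the config, seed and a config fingerprint as attributes.
#' @examples
#' study <- simulate_study(study_config(profile_compartments = "MF"), seed = 1)
#' study
#' @export
simulate_study <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "cart_config"))
  groups <- names(config$presets)
  n <- config$n_per_group
  n_animals <- n * length(groups)

  assignment <- withr::with_seed(as.integer(seed),
                                 block_randomize(groups, n))
  seeds <- spawn_seeds(as.integer(seed) + 1L, n_animals)
  ids <- sprintf("A%02d", seq_len(n_animals))

  out <- vector("list", n_animals)
  for (i in seq_len(n_animals)) {
    out[[i]] <- simulate_animal(ids[i], assignment[i],
                                config$presets[[assignment[i]]], config, seeds[i])
  }

  study <- structure(list(
    animals = dplyr::bind_rows(lapply(out, `[[`, "animal")),
    sections = dplyr::bind_rows(lapply(out, `[[`, "sections"))
  ), class = "cart_study")
  attr(study, "config") <- config
  attr(study, "master_seed") <- as.integer(seed)
  attr(study, "animal_seeds") <- seeds
  attr(study, "config_fingerprint") <- config_fingerprint(config)
  study
}

#' Simulate a single-arm cohort
#'
#' Convenience wrapper for parameter-recovery studies: one arm of
#' `n` animals generated from a single preset.
#'
#' @param preset A [group_preset()].
#' @param n Number of animals.
#' @param config A [study_config()]; its presets are replaced.
#' @param seed Integer master seed.
#' @return A `cart_study` with a single group.
#' @export
simulate_cohort <- function(preset, n = 11, config = study_config(), seed = 1) {
  config$presets <- setNames(list(preset), preset$group_label)
  config$n_per_group <- as.integer(n)
  simulate_study(config, seed)
}

#' @export
print.cart_study <- function(x, ...) {
  cat("<cart_study>\n")
  tab <- table(x$animals$group)
  cat(sprintf("  %d animals (%s); %d sections\n", nrow(x$animals),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
              nrow(x$sections)))
  n_prof <- sum(!vapply(x$sections$profile, is.null, logical(1)))
  cat(sprintf("  %d boundary profiles; master seed %d\n", n_prof,
              attr(x, "master_seed")))
  invisible(x)
}

# Stable fingerprint of a configuration (md5 of its canonical YAML).
config_fingerprint <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config_to_list(config), tf)
  unname(tools::md5sum(tf))
}
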