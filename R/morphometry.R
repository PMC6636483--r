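# Quantitative histology assessment: scale calibration, idealized
# surface fitting, 20-point perpendicular thickness, cartilage area and
# RMS surface roughness.

#' Fit the idealized smooth surface of a cartilage section
#'
#' The idealized surface is the reference against which surface
#' roughness is measured: a low-order polynomial least-squares fit to
#' the articular-surface points of the *flanking* normal cartilage only
#' (outside the region of degeneration), evaluated across the region of
#' interest.
#'
#' @param profile A [cartilage_profile()] with non-empty flanks.
#' @param degree Polynomial degree (default 2: a quadratic captures the
#'   condylar curvature without following lesions).
#' @return An object of class `idealized_surface` with elements `coef`
#'   (polynomial coefficients, ascending powers), `degree`, and
#'   `sampled` (tibble of the fit evaluated at the roi surface
#'   abscissae).
#' @export
fit_idealized_surface <- function(profile, degree = 2) {
  flanks <- profile$flanks
  if (is.null(flanks) || length(flanks) != 2) {
    cm_abort(paste("profile has no flank intervals: provide `flanks` or fit a",
                   "degree-0 (constant) reference explicitly"),
             "cartmorph_fit_error")
  }
  xs <- profile$surface$x
  ys <- profile$surface$y
  in_flank <- (xs >= flanks[[1]][1] & xs <= flanks[[1]][2]) |
    (xs >= flanks[[2]][1] & xs <= flanks[[2]][2])
  n_left <- sum(xs >= flanks[[1]][1] & xs <= flanks[[1]][2])
  n_right <- sum(xs >= flanks[[2]][1] & xs <= flanks[[2]][2])
  if (n_left < 10 || n_right < 10) {
    cm_abort(sprintf(
      "each flank needs >= 10 surface points (found %d left, %d right)",
      n_left, n_right), "cartmorph_fit_error")
  }
  # Center x for numerical conditioning of the raw-polynomial fit.
  x0 <- mean(range(xs))
  fit <- lm(y ~ poly(x, degree, raw = TRUE),
            data = data.frame(x = xs[in_flank] - x0, y = ys[in_flank]))
  coef_centered <- coef(fit)
  coef_centered[is.na(coef_centered)] <- 0

  eval_centered <- function(x) {
    xx <- x - x0
    out <- rep(coef_centered[1], length(x))
    for (p in seq_len(degree)) out <- out + coef_centered[p + 1] * xx^p
    out
  }
  deriv_centered <- function(x) {
    xx <- x - x0
    out <- rep(0, length(x))
    for (p in seq_len(degree)) out <- out + p * coef_centered[p + 1] * xx^(p - 1)
    out
  }

  in_roi <- xs >= profile$roi[1] & xs <= profile$roi[2]
  structure(list(
    coef = uncenter_poly(coef_centered, x0),
    coef_centered = coef_centered,
    center = x0,
    degree = degree,
    predict = eval_centered,
    derivative = deriv_centered,
    sampled = tibble(x = xs[in_roi], y = eval_centered(xs[in_roi]))
  ), class = "idealized_surface")
}

# Expand coefficients of sum b_p (x - x0)^p into ascending powers of x.
uncenter_poly <- function(b, x0) {
  degree <- length(b) - 1
  out <- numeric(degree + 1)
  for (p in 0:degree) {
    for (q in 0:p) {
      out[q + 1] <- out[q + 1] + b[p + 1] * choose(p, q) * (-x0)^(p - q)
    }
  }
  names(out) <- paste0("x^", 0:degree)
  out
}

#' @export
print.idealized_surface <- function(x, ...) {
  cat("<idealized_surface> degree", x$degree, "\n")
  cat("  coef:", signif(x$coef, 6), "\n")
  invisible(x)
}

#' Mean cartilage thickness from perpendicular measurements
#'
#' Thickness from the articular surface to the tidemark is the mean of
#' `n_points` measurements made perpendicularly to the surface at
#' equally spaced abscissae across the region of interest.  The
#' perpendicular direction is the local normal of the *idealized*
#' (smooth) surface, so the measurement is not dominated by fibrillation
#' noise; each ray is cast from the real surface to its nearest
#' intersection with the tidemark polyline.  If a ray fails to intersect
#' the tidemark (edge geometry), that point falls back to the vertical
#' surface-tidemark distance and the fallback is counted.
#'
#' @param profile A [cartilage_profile()].
#' @param n_points Number of measurement points (default 20).
#' @param idealized Optional precomputed [fit_idealized_surface()] fit.
#' @return List with `thickness_mean` (um), `thickness_points` (the
#'   `n_points` ray lengths), and `n_fallback`.
#' @export
mean_thickness <- function(profile, n_points = 20, idealized = NULL) {
  if (n_points < 2) cm_abort("`n_points` must be >= 2", "cartmorph_domain_error")
  if (is.null(idealized)) idealized <- fit_idealized_surface(profile)
  roi <- profile$roi
  # Midpoint placement: points at the centres of n equal roi bins.
  xq <- roi[1] + (seq_len(n_points) - 0.5) * diff(roi) / n_points
  y_surf <- approx(profile$surface$x, profile$surface$y, xout = xq)$y
  slope <- idealized$derivative(xq)
  s_fac <- sqrt(1 + slope^2)
  # Inward (downward) unit normal of the idealized surface.
  dir_x <- slope / s_fac
  dir_y <- -1 / s_fac

  tm <- profile$tidemark
  lengths <- numeric(n_points)
  fallback <- logical(n_points)
  for (j in seq_len(n_points)) {
    hit <- ray_polyline_intersection(xq[j], y_surf[j], dir_x[j], dir_y[j],
                                     tm$x, tm$y)
    if (is.na(hit)) {
      fallback[j] <- TRUE
      lengths[j] <- y_surf[j] - approx(tm$x, tm$y, xout = xq[j], rule = 2)$y
    } else {
      lengths[j] <- hit
    }
  }
  if (any(fallback)) {
    inform(sprintf("mean_thickness: vertical-distance fallback at %d of %d points",
                   sum(fallback), n_points),
           class = "cartmorph_fallback")
  }
  list(thickness_mean = mean(lengths), thickness_points = lengths,
       n_fallback = sum(fallback))
}

# Distance from (px, py) along unit direction (dx, dy) to the nearest
# intersection with the polyline (xs, ys); NA when the ray misses.
ray_polyline_intersection <- function(px, py, dx, dy, xs, ys) {
  # Restrict to segments within a lateral window for speed.
  keep <- which(xs >= px - 1000 & xs <= px + 1000)
  if (length(keep) < 2) keep <- seq_along(xs)
  i1 <- keep[-length(keep)]
  x1 <- xs[i1]; y1 <- ys[i1]
  x2 <- xs[i1 + 1]; y2 <- ys[i1 + 1]
  ex <- x2 - x1; ey <- y2 - y1
  denom <- dx * ey - dy * ex
  ok <- abs(denom) > 1e-12
  t <- (ex * (py - y1) - ey * (px - x1)) / denom
  u <- (dx * (py - y1) - dy * (px - x1)) / denom
  valid <- ok & t > 0 & u >= 0 & u <= 1
  if (!any(valid)) return(NA_real_)
  min(t[valid])
}

#' Cartilage area by boundary integration
#'
#' Area of the region bounded by the articular surface, the tidemark and
#' the two vertical edges of the evaluation window, computed by
#' trapezoidal integration of the vertical surface-tidemark separation
#' over the window.  The default window is the full region of interest;
#' group presets carry a narrower centered evaluation window for the
#' area endpoint (see the methods vignette).
#'
#' @param profile A [cartilage_profile()].
#' @param window Numeric length-2 evaluation window (um); default the
#'   profile's roi.  A single number is interpreted as a width centered
#'   in the roi.
#' @return Area in um^2.
#' @export
cartilage_area <- function(profile, window = NULL) {
  roi <- profile$roi
  if (is.null(window)) {
    window <- roi
  } else if (length(window) == 1) {
    mid <- mean(roi)
    window <- mid + c(-0.5, 0.5) * window
  }
  xs <- profile$surface$x
  sel <- xs >= window[1] & xs <= window[2]
  if (sum(sel) < 2) cm_abort("evaluation window contains < 2 surface points",
                             "cartmorph_geometry_error")
  x <- xs[sel]
  y_s <- profile$surface$y[sel]
  y_t <- approx(profile$tidemark$x, profile$tidemark$y, xout = x, rule = 2)$y
  h <- y_s - y_t
  if (any(h < 0)) {
    cm_abort("surface crosses below tidemark inside the evaluation window",
             "cartmorph_geometry_error")
  }
  trapz(x, h)
}

#' RMS surface roughness
#'
#' Root-mean-square deviation of the digitized articular surface from
#' the idealized smooth surface over the region of interest:
#' `sqrt(mean((y_idealized - y_real)^2))` over all N digitized roi
#' surface points.
#'
#' @param profile A [cartilage_profile()].
#' @param idealized Optional precomputed [fit_idealized_surface()] fit.
#' @return List with `rms` (um) and `n_digitized` (N).
#' @export
rms_roughness <- function(profile, idealized = NULL) {
  if (is.null(idealized)) idealized <- fit_idealized_surface(profile)
  xs <- profile$surface$x
  in_roi <- xs >= profile$roi[1] & xs <= profile$roi[2]
  n <- sum(in_roi)
  if (n == 0) cm_abort("no digitized surface points inside the roi",
                       "cartmorph_geometry_error")
  dev <- idealized$predict(xs[in_roi]) - profile$surface$y[in_roi]
  list(rms = sqrt(mean(dev^2)), n_digitized = n)
}

#' Normalized cartilage roughness
#'
#' Surface roughness depends on cartilage thickness, so the RMS
#' roughness is normalized by the mean thickness.  The dimensionless
#' ratio is reported multiplied by `scale` (default 1000), which puts
#' typical osteoarthritic cartilage in the range ~20-50.
#'
#' @param rms RMS surface roughness, um.
#' @param thickness_mean Mean cartilage thickness, um.
#' @param scale Reporting multiplier (set 1 for the bare ratio).
#' @return Normalized roughness (dimensionless x `scale`).
#' @export
normalized_roughness <- function(rms, thickness_mean, scale = 1000) {
  if (any(thickness_mean <= 0)) {
    cm_abort("`thickness_mean` must be positive", "cartmorph_domain_error")
  }
  scale * rms / thickness_mean
}

#' Full morphometric measurement of one section
#'
#' Runs the quantitative histology pipeline on a profile: idealized
#' surface fit from the flanks, 20-point perpendicular thickness,
#' cartilage area and (normalized) RMS surface roughness.
#'
#' @param profile A [cartilage_profile()].
#' @param n_points Thickness measurement points.
#' @param degree Idealized-surface polynomial degree.
#' @param area_window Evaluation window for the area endpoint (width in
#'   um or an explicit interval); default the full roi.
#' @param normalized_scale Reporting multiplier for normalized
#'   roughness.
#' @return One-row tibble: `thickness_um`, `area_um2`, `rms_um`,
#'   `normalized_roughness`, `n_digitized`, `n_fallback`, plus a
#'   `thickness_points` list column.
#' @export
measure_profile <- function(profile, n_points = 20, degree = 2,
                            area_window = NULL, normalized_scale = 1000) {
  ideal <- fit_idealized_surface(profile, degree = degree)
  th <- mean_thickness(profile, n_points = n_points, idealized = ideal)
  rr <- rms_roughness(profile, idealized = ideal)
  area <- cartilage_area(profile, window = area_window)
  tibble(
    thickness_um = th$thickness_mean,
    area_um2 = area,
    rms_um = rr$rms,
    normalized_roughness = normalized_roughness(rr$rms, th$thickness_mean,
                                                scale = normalized_scale),
    n_digitized = rr$n_digitized,
    n_fallback = th$n_fallback,
    thickness_points = list(th$thickness_points)
  )
}

#' Measure every profiled section of a study
#'
#' Applies [measure_profile()] to each section of the requested
#' compartment(s) that carries a boundary profile.  The area evaluation
#' window defaults to each group's preset `area_window_um`.
#'
#' @param study A `cart_study` from [simulate_study()].
#' @param compartments Compartments to measure (default `"MF"`, the
#'   compartment used for quantitative assessment).
#' @param area_windows Named numeric vector of window widths by group;
#'   defaults to the preset values, or the full roi for groups without
#'   a preset.
#' @return Tibble with one row per measured section: ids, group, the
#'   measured endpoints and the generator truth columns.
#' @export
measure_study <- function(study, compartments = "MF", area_windows = NULL) {
  stopifnot(inherits(study, "cart_study"))
  config <- attr(study, "config")
  if (is.null(area_windows)) {
    area_windows <- vapply(config$presets, function(p) {
      p$area_window_um %||% config$roi_um
    }, numeric(1))
  }
  sec <- dplyr::filter(study$sections,
                       .data$compartment %in% compartments,
                       !vapply(.data$profile, is.null, logical(1)))
  res <- purrr::pmap_dfr(
    list(sec$profile, sec$group),
    function(profile, group) {
      w <- area_windows[[group]] %||% NULL
      measure_profile(profile,
                      n_points = config$n_thickness_points,
                      degree = config$fit_degree,
                      area_window = w,
                      normalized_scale = config$normalized_scale)
    }
  )
  dplyr::bind_cols(
    sec[c("animal_id", "group", "compartment",
          "true_thickness_um", "true_rms_um", "true_norm_roughness")],
    res
  )
}
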