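#' Cartilage cross-section profile
#'
#' A `cartilage_profile` holds the two digitized boundary polylines of a
#' stained cartilage section in physical (micrometre) coordinates: the
#' articular surface and the tidemark.  `x` increases along the section,
#' `y` increases toward the joint space, so the surface lies above the
#' tidemark everywhere.  The region of interest (`roi`) is the 7-mm
#' weight-bearing window over which thickness, area and roughness are
#' evaluated; the `flanks` are the stretches of normal cartilage outside
#' it from which the idealized smooth surface is fitted.
#'
#' @param surface,tidemark Data frames with numeric columns `x`, `y`
#'   (micrometres), strictly increasing in `x`.
#' @param roi Numeric length-2: start and end of the region of interest.
#' @param flanks List of two length-2 numeric intervals (left, right)
#'   of normal cartilage outside the roi.
#' @param scale Micrometres per pixel of the source image (1 when the
#'   coordinates are already physical).
#' @param truth Optional list of generator ground truth (true thickness,
#'   true RMS roughness, lesion inventory) carried for recovery tests.
#'
#' @return An object of class `cartilage_profile`.
#' @export
cartilage_profile <- function(surface, tidemark, roi, flanks = NULL,
                              scale = 1, truth = NULL) {
  surface <- as_tibble(surface)[c("x", "y")]
  tidemark <- as_tibble(tidemark)[c("x", "y")]
  prof <- structure(list(
    surface = surface, tidemark = tidemark,
    roi = as.numeric(roi), flanks = flanks,
    scale = scale, truth = truth
  ), class = "cartilage_profile")
  validate_profile(prof)
  prof
}

#' Validate a cartilage profile
#'
#' Checks monotone-x polylines, roi width (7000 um within 1 um by
#' default study geometry is not enforced here; any positive width is
#' allowed for custom geometries), and that the surface lies above the
#' tidemark at shared abscissae.
#'
#' @param profile A [cartilage_profile()].
#' @param check_order Also check surface-above-tidemark (default TRUE).
#' @return The profile, invisibly; aborts with a validation error
#'   otherwise.
#' @export
validate_profile <- function(profile, check_order = TRUE) {
  for (nm in c("surface", "tidemark")) {
    pl <- profile[[nm]]
    if (!is.data.frame(pl) || !all(c("x", "y") %in% names(pl)) || nrow(pl) < 2) {
      cm_abort(paste0("polyline `", nm, "` must have columns x, y and >= 2 points"),
               "cartmorph_validation_error")
    }
    if (any(!is.finite(pl$x)) || any(!is.finite(pl$y))) {
      cm_abort(paste0("polyline `", nm, "` contains non-finite coordinates"),
               "cartmorph_validation_error")
    }
    if (any(diff(pl$x) <= 0)) {
      cm_abort(paste0("polyline `", nm, "` must be strictly increasing in x"),
               "cartmorph_validation_error")
    }
  }
  if (length(profile$roi) != 2 || diff(profile$roi) <= 0) {
    cm_abort("`roi` must be an increasing (start, end) pair", "cartmorph_validation_error")
  }
  if (check_order) {
    xs <- profile$surface$x
    lo <- max(min(profile$tidemark$x), min(xs))
    hi <- min(max(profile$tidemark$x), max(xs))
    sel <- xs >= lo & xs <= hi
    tm <- approx(profile$tidemark$x, profile$tidemark$y, xout = xs[sel])$y
    if (any(profile$surface$y[sel] <= tm)) {
      cm_abort("surface must lie above the tidemark at every shared x",
               "cartmorph_validation_error")
    }
  }
  invisible(profile)
}

#' @export
print.cartilage_profile <- function(x, ...) {
  cat("<cartilage_profile>\n")
  cat(sprintf("  surface: %d pts, x %.0f..%.0f um; tidemark: %d pts\n",
              nrow(x$surface), min(x$surface$x), max(x$surface$x),
              nrow(x$tidemark)))
  cat(sprintf("  roi: [%.0f, %.0f] um (width %.0f)\n",
              x$roi[1], x$roi[2], diff(x$roi)))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: thickness %.1f um, rms %.2f um, %d lesion(s)\n",
                x$truth$thickness_um, x$truth$rms_um,
                if (is.null(x$truth$lesions)) 0L else nrow(x$truth$lesions)))
  }
  invisible(x)
}

#' @describeIn cartilage_profile Long-format tibble of both boundaries
#'   (columns `boundary`, `x`, `y`).
#' @param x A `cartilage_profile`.
#' @param ... Unused.
#' @export
as_tibble.cartilage_profile <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$surface, boundary = "surface"),
    dplyr::mutate(x$tidemark, boundary = "tidemark")
  )[c("boundary", "x", "y")]
}

#' @export
autoplot.cartilage_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$boundary)) +
    ggplot2::annotate("rect", xmin = object$roi[1], xmax = object$roi[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "Cartilage section boundaries",
                  subtitle = "shaded band: 7-mm evaluation region") +
    ggplot2::theme_minimal()
}
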