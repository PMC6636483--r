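# Raster rendering of sections and the segmentation round trip.  The
# segmentation handles only this synthetic raster dialect (a single
# tissue band on a bright background), not general histology images.

#' Render a cartilage section as a grayscale raster
#'
#' Produces a numeric intensity matrix (rows = image rows top-to-bottom,
#' values in `[0, 1]`): the cartilage band between surface and tidemark
#' is filled with tissue intensity (~0.55), the background is bright
#' (~0.95), and Gaussian pixel noise is added.  Optionally a dark 1-mm
#' calibration ruler bar is drawn below the tissue for scale-calibration
#' testing.
#'
#' @param profile A [cartilage_profile()].
#' @param pixel_size_um Pixel size, um/px.
#' @param ruler Draw the calibration ruler bar (default FALSE; images
#'   fed to [extract_boundaries()] must not contain one).
#' @param ruler_um Physical length of the ruler bar.
#' @param noise_sd Gaussian intensity noise sd.
#' @return Intensity matrix with attributes `pixel_size_um`, `x0_um`,
#'   `y_top_um` mapping pixels back to section coordinates.
#' @export
render_section_image <- function(profile, pixel_size_um = 2, ruler = FALSE,
                                 ruler_um = 1000, noise_sd = 0.03) {
  if (pixel_size_um <= 0) cm_abort("`pixel_size_um` must be positive",
                                   "cartmorph_domain_error")
  surf <- profile$surface
  tide <- profile$tidemark
  band_min <- min(surf$y - approx(tide$x, tide$y, xout = surf$x, rule = 2)$y)
  if (band_min / pixel_size_um < 3) {
    cm_abort(sprintf(
      "pixel size %.3g um/px too coarse: band would be %.1f px (< 3 px) thick",
      pixel_size_um, band_min / pixel_size_um), "cartmorph_resolution_error")
  }

  x0 <- min(surf$x)
  x1 <- max(surf$x)
  margin <- 30 * pixel_size_um
  y_top <- max(surf$y) + margin
  y_bot <- min(tide$y) - margin - if (ruler) 20 * pixel_size_um else 0

  ncol_px <- ceiling((x1 - x0) / pixel_size_um)
  nrow_px <- ceiling((y_top - y_bot) / pixel_size_um)
  img <- matrix(0.95, nrow = nrow_px, ncol = ncol_px)

  xc <- x0 + (seq_len(ncol_px) - 0.5) * pixel_size_um
  ys <- approx(surf$x, surf$y, xout = xc, rule = 2)$y
  yt <- approx(tide$x, tide$y, xout = xc, rule = 2)$y
  # Row index grows downward from y_top.
  row_of <- function(y) (y_top - y) / pixel_size_um + 0.5
  for (j in seq_len(ncol_px)) {
    r1 <- max(1L, ceiling(row_of(ys[j])))
    r2 <- min(nrow_px, floor(row_of(yt[j])))
    if (r2 >= r1) img[r1:r2, j] <- 0.55
  }

  if (ruler) {
    bar_px <- round(ruler_um / pixel_size_um)
    r0 <- nrow_px - 8L
    c0 <- 20L
    if (c0 + bar_px - 1 <= ncol_px && r0 + 4 <= nrow_px) {
      img[r0:(r0 + 4L), c0:(c0 + bar_px - 1L)] <- 0.05
    } else {
      cm_abort("image too small for the requested ruler bar",
               "cartmorph_resolution_error")
    }
  }

  img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow = nrow_px)
  img <- pmin(pmax(img, 0), 1)
  attr(img, "pixel_size_um") <- pixel_size_um
  attr(img, "x0_um") <- x0
  attr(img, "y_top_um") <- y_top
  img
}

#' Calibrate the image scale from a rendered ruler bar
#'
#' Finds the longest dark horizontal pixel run in the image (the ruler
#' bar) and returns `known_length_um` divided by its length in pixels.
#'
#' @param image Grayscale intensity matrix in `[0, 1]`.
#' @param known_length_um Physical length of the ruler bar (default
#'   1 mm).
#' @param dark_threshold Intensity below which a pixel counts as ruler
#'   ink (the tissue band is brighter than this).
#' @return Scale in um/px.
#' @export
calibrate_scale <- function(image, known_length_um = 1000, dark_threshold = 0.3) {
  dark <- image < dark_threshold
  best <- 0L
  for (i in seq_len(nrow(image))) {
    r <- rle(dark[i, ])
    runs <- r$lengths[r$values]
    if (length(runs)) best <- max(best, max(runs))
  }
  if (best < 5) {
    cm_abort("no ruler bar found: no dark horizontal run of >= 5 px",
             "cartmorph_calibration_error")
  }
  known_length_um / best
}

#' Extract boundary polylines from a section raster
#'
#' Segments the single contiguous tissue band (intensity below
#' `threshold` on a bright background), takes its upper contour as the
#' articular surface and its lower contour as the tidemark, and converts
#' both to micrometre coordinates via `scale`.  Columns are sampled at
#' the pixel pitch, so the digitization spacing equals `scale`.
#'
#' @param image Grayscale intensity matrix in `[0, 1]` (optionally with
#'   the coordinate attributes written by [render_section_image()]).
#' @param scale um/px; defaults to the image's `pixel_size_um`
#'   attribute.
#' @param threshold Tissue intensity threshold.
#' @param roi_um Width of the centered region of interest assigned to
#'   the extracted profile (default 7000).
#' @return A [cartilage_profile()] in micrometre coordinates.
#' @export
extract_boundaries <- function(image, scale = NULL, threshold = 0.75,
                               roi_um = 7000) {
  scale <- scale %||% attr(image, "pixel_size_um")
  if (is.null(scale)) cm_abort("`scale` (um/px) required", "cartmorph_domain_error")
  mask <- image < threshold
  if (!any(mask)) {
    cm_abort("segmentation found 0 tissue bands", "cartmorph_segmentation_error")
  }
  labels <- EBImage::bwlabel(mask)
  n_comp <- max(labels)
  if (n_comp != 1) {
    cm_abort(sprintf("segmentation found %d connected components, expected 1",
                     n_comp), "cartmorph_segmentation_error")
  }

  x0 <- attr(image, "x0_um") %||% 0
  y_top <- attr(image, "y_top_um") %||% (nrow(image) * scale)

  cols <- which(apply(mask, 2, any))
  top <- apply(mask[, cols, drop = FALSE], 2, function(col) which(col)[1])
  bot <- apply(mask[, cols, drop = FALSE], 2, function(col) {
    w <- which(col)
    w[length(w)]
  })
  x_um <- x0 + (cols - 0.5) * scale
  surf_y <- y_top - (top - 0.5) * scale
  tide_y <- y_top - (bot + 0.5) * scale

  extent <- range(x_um)
  mid <- mean(extent)
  roi <- mid + c(-0.5, 0.5) * min(roi_um, diff(extent))
  flanks <- list(c(extent[1], roi[1]), c(roi[2], extent[2]))

  cartilage_profile(
    surface = tibble(x = x_um, y = surf_y),
    tidemark = tibble(x = x_um, y = tide_y),
    roi = roi, flanks = flanks, scale = scale
  )
}
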