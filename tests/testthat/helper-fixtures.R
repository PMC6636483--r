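# Fixtures built in code: small profiles and configs shared across tests.

# Flat slab profile: surface at `thickness`, tidemark at 0, flat flanks.
flat_profile <- function(thickness = 200, roi_len = 7000, flank = 1500,
                         spacing = 5) {
  len <- roi_len + 2 * flank
  x <- seq(0, len, by = spacing)
  cartilage_profile(
    surface = tibble::tibble(x = x, y = rep(thickness, length(x))),
    tidemark = tibble::tibble(x = x, y = rep(0, length(x))),
    roi = c(flank, flank + roi_len),
    flanks = list(c(0, flank), c(flank + roi_len, len))
  )
}

# Flat slab with a sinusoidal surface deviation confined to the roi.
sin_profile <- function(A = 10, wavelength = 500, thickness = 200,
                        roi_len = 7000, flank = 1500, spacing = 2) {
  len <- roi_len + 2 * flank
  x <- seq(0, len, by = spacing)
  roi <- c(flank, flank + roi_len)
  dev <- ifelse(x >= roi[1] & x <= roi[2],
                A * sin(2 * pi * (x - roi[1]) / wavelength), 0)
  cartilage_profile(
    surface = tibble::tibble(x = x, y = thickness + dev),
    tidemark = tibble::tibble(x = x, y = rep(0, length(x))),
    roi = roi,
    flanks = list(c(0, flank), c(roi[2], len))
  )
}

# Configs used throughout: profiles only for the medial femoral condyle
# (the compartment used for quantitative assessment), or none at all
# (descriptor/grade-only studies).
mf_config <- function(...) study_config(profile_compartments = "MF", ...)
desc_config <- function(...) study_config(profile_compartments = character(0), ...)

# Geometric transform of a whole profile (scaling s, rotation theta in
# radians, translation (dx, dy)); used by the equivariance tests.
transform_profile <- function(profile, s = 1, theta = 0, dx = 0, dy = 0) {
  rot <- function(df) {
    x <- s * (cos(theta) * df$x - sin(theta) * df$y) + dx
    y <- s * (sin(theta) * df$x + cos(theta) * df$y) + dy
    tibble::tibble(x = x, y = y)
  }
  tr_x <- function(v) s * cos(theta) * v + dx  # approximate for small theta
  cartilage_profile(
    surface = rot(profile$surface),
    tidemark = rot(profile$tidemark),
    roi = tr_x(profile$roi),
    flanks = lapply(profile$flanks, tr_x),
    scale = profile$scale,
    truth = profile$truth
  )
}

# Brute-force Mann-Whitney U (pairwise enumeration) and the exact
# permutation p value by full enumeration of group labelings.
brute_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

enum_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  u_obs <- brute_u(x, y)
  idx <- utils::combn(length(pooled), m)
  us <- apply(idx, 2, function(i) brute_u(pooled[i], pooled[-i]))
  mu <- m * (length(y)) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
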