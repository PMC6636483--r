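# Internal helpers shared across modules.

# Standard error of the mean.
sem <- function(x) stats::sd(x) / sqrt(length(x))

# Interquartile range with linear-interpolation (type 7) quantiles, the
# convention used for the median (IQR) summaries.
iqr7 <- function(x) {
  q <- stats::quantile(x, probs = c(0.25, 0.75), type = 7, names = FALSE)
  q[2] - q[1]
}

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Draw from a gamma distribution parameterized by mean and sd.  Used for
# strictly positive biological quantities (thickness, roughness ratios)
# where a normal with a large coefficient of variation would put mass
# below zero.
rgamma_ms <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  rgamma(n, shape = shape, scale = sd^2 / mean)
}

# Draw from a lognormal matched to a target mean and sd on the natural
# scale (moment matching).
rlnorm_ms <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  sigma2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# Spawn `n` independent substream seeds from a master seed.  The spawn
# order (one draw block, in animal order) is part of the serialization
# contract: the same master seed always yields the same substreams.
spawn_seeds <- function(master_seed, n) {
  withr::with_seed(as.integer(master_seed), sample.int(.Machine$integer.max - 1L, n))
}

# Abort with a classed condition so callers/tests can match on class.
cm_abort <- function(message, class) {
  abort(message, class = c(class, "cartmorph_error"))
}

compartment_levels <- function() c("MF", "LF", "MT", "LT")

group_levels <- function() c("channa", "glucosamine", "control")

serum_analytes <- function() c("comp", "cox2", "pge2")
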