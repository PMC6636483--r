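#' Convert a human daily dose to an animal dose by body surface area
#'
#' Body-surface-area scaling: the human dose per kilogram is multiplied
#' by a species conversion factor.  With the rabbit factor 3.6, a
#' 1000 mg/day dose for a 70 kg human converts to 51.4 mg/kg.
#'
#' @param human_total_mg Total human daily dose, mg/day.
#' @param human_mass_kg Reference human body mass, kg.
#' @param species_factor Dimensionless body-surface-area factor for the
#'   target species (3.6 for rabbit).
#' @return Dose in mg/kg, rounded to one decimal place.
#' @examples
#' convert_human_dose(1000, 70, 3.6)  # 51.4 mg/kg
#' @export
convert_human_dose <- function(human_total_mg, human_mass_kg, species_factor = 3.6) {
  if (any(human_total_mg <= 0) || any(human_mass_kg <= 0) ||
      any(species_factor <= 0)) {
    cm_abort("all dose-conversion inputs must be positive",
             "cartmorph_domain_error")
  }
  round(human_total_mg / human_mass_kg * species_factor, 1)
}

#' Sample size for comparing two means
#'
#' Standard normal-approximation sample size per group for a two-sided
#' two-sample comparison of means.
#'
#' @param delta Difference in means to detect.
#' @param sd Common standard deviation.
#' @param alpha Two-sided type-I error rate.
#' @param power Desired power.
#' @return Animals per group (rounded up).
#' @export
sample_size_two_means <- function(delta, sd, alpha = 0.05, power = 0.90) {
  if (delta <= 0 || sd <= 0) {
    cm_abort("`delta` and `sd` must be positive", "cartmorph_domain_error")
  }
  ceiling(2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 * (sd / delta)^2)
}
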