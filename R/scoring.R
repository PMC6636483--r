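# Semiquantitative scoring: modified OARSI histology rubric (structure
# 0-11, chondrocyte density 0-4, cluster formation 0-3) and the
# four-grade India-ink macroscopic scale.

#' The structure rubric (scores 0-11)
#'
#' The 12-row mapping from lesion depth category and surface extent to
#' the structure score, encoded once as data.  Extent ties at exactly
#' 50% classify as the `>= 50%` band.
#'
#' @return Tibble with columns `score`, `depth`, `extent_band` and
#'   `description`.
#' @export
oarsi_structure_table <- function() {
  tibble::tribble(
    ~score, ~depth,                  ~extent_band, ~description,
    0L,  "none",                  "any",   "normal",
    1L,  "irregularity",          "any",   "surface irregularities",
    2L,  "fissure",               "<50%",  "fissures in < 50% surface",
    3L,  "fissure",               ">=50%", "fissures in >= 50% surface",
    4L,  "erosion_third",         "<50%",  "erosion 1/3 hyaline cartilage < 50% surface",
    5L,  "erosion_third",         ">=50%", "erosion 1/3 hyaline cartilage >= 50% surface",
    6L,  "erosion_two_thirds",    "<50%",  "erosion 2/3 hyaline cartilage < 50% surface",
    7L,  "erosion_two_thirds",    ">=50%", "erosion 2/3 hyaline cartilage >= 50% surface",
    8L,  "full_depth",            "<50%",  "full depth erosion 2/3 hyaline cartilage < 50% surface",
    9L,  "full_depth",            ">=50%", "full depth erosion 2/3 hyaline cartilage >= 50% surface",
    10L, "full_depth_calcified",  "<50%",  "full depth erosion to the subchondral bone < 50%",
    11L, "full_depth_calcified",  ">=50%", "full depth erosion to the subchondral bone >= 50%"
  )
}

# Score a single (depth, extent) lesion.
score_one_lesion <- function(depth, extent) {
  if (depth == "none") return(0L)
  if (depth == "irregularity") return(1L)
  base <- switch(depth,
    fissure = 2L,
    erosion_third = 4L,
    erosion_two_thirds = 6L,
    full_depth = 8L,
    full_depth_calcified = 10L,
    cm_abort(paste0("unknown lesion depth category: ", depth),
             "cartmorph_domain_error")
  )
  base + as.integer(extent >= 0.5)
}

#' Structure score of a lesion set (0-11)
#'
#' Each lesion is mapped to its rubric row by depth category and surface
#' extent (`< 50%` vs `>= 50%`, ties at exactly 50% counting as
#' `>= 50%`).  The compartment's score is the score of the most severe
#' lesion; an empty lesion set scores 0 (normal).
#'
#' @param lesions Data frame with columns `depth` and `extent`
#'   (fraction of surface in `[0, 1]`).
#' @return Integer score 0-11.
#' @export
score_structure <- function(lesions) {
  lesions <- as.data.frame(lesions)
  if (!nrow(lesions)) return(0L)
  if (!all(c("depth", "extent") %in% names(lesions))) {
    cm_abort("`lesions` needs columns `depth` and `extent`",
             "cartmorph_domain_error")
  }
  if (any(lesions$extent < 0 | lesions$extent > 1)) {
    cm_abort("lesion `extent` must lie in [0, 1]", "cartmorph_domain_error")
  }
  max(vapply(seq_len(nrow(lesions)), function(i) {
    score_one_lesion(lesions$depth[i], lesions$extent[i])
  }, integer(1)))
}

#' Chondrocyte density score (0-4)
#'
#' Direct ordinal lookup: no decrease 0, focal decrease 1, multifocal
#' decrease 2, multifocal confluent decrease 3, diffuse decrease 4.
#'
#' @param pattern Density category (character, vectorized).
#' @return Integer score(s) 0-4.
#' @export
score_density <- function(pattern) {
  idx <- match(pattern, density_categories())
  if (any(is.na(idx))) {
    cm_abort(paste0("unknown density pattern: ",
                    paste(unique(pattern[is.na(idx)]), collapse = ", ")),
             "cartmorph_domain_error")
  }
  as.integer(idx - 1L)
}

#' Cluster formation score (0-3)
#'
#' 0 for no clusters, 1 for 1-3 clusters, 2 for at least 4 but fewer
#' than 8, and 3 for 8 or more.
#'
#' @param count Non-negative integer cluster count (vectorized).
#' @return Integer score(s) 0-3.
#' @export
score_clusters <- function(count) {
  if (any(count < 0)) cm_abort("cluster count must be non-negative",
                               "cartmorph_domain_error")
  ifelse(count == 0, 0L, ifelse(count <= 3, 1L, ifelse(count <= 7, 2L, 3L)))
}

#' India-ink macroscopic grade (1-4)
#'
#' Grade 1: intact surface, no ink retention.  Grade 2: minimal focal
#' ink uptake (minimal fibrillation).  Grade 3: large focal dark patches
#' of ink uptake (overt fibrillation).  Grade 4: loss of cartilage with
#' exposure of the bone (erosion).
#'
#' @param obs Ink-uptake category (character, vectorized): `"none"`,
#'   `"minimal_focal"`, `"large_focal_patches"`, `"bone_exposed"`.
#' @return Integer grade(s) 1-4.
#' @export
grade_macroscopic <- function(obs) {
  idx <- match(obs, ink_categories())
  if (any(is.na(idx))) {
    cm_abort(paste0("unknown ink-uptake category: ",
                    paste(unique(obs[is.na(idx)]), collapse = ", ")),
             "cartmorph_domain_error")
  }
  as.integer(idx)
}

#' Aggregate compartment scores to joint totals
#'
#' Sums the OARSI compartment totals (structure + density + clusters,
#' 0-18 each) over the four compartments to the histology total (0-72),
#' and the macroscopic grades to the macroscopic total (4-16).
#'
#' @param scores Data frame with one row per compartment and columns
#'   `compartment`, `structure`, `density`, `clusters`, `macro_grade`.
#' @return One-row tibble: `histology_total`, `macro_total`.
#' @export
aggregate_joint <- function(scores) {
  scores <- as.data.frame(scores)
  missing <- setdiff(compartment_levels(), scores$compartment)
  if (length(missing)) {
    cm_abort(paste0("missing compartment(s): ", paste(missing, collapse = ", ")),
             "cartmorph_aggregation_error")
  }
  dup <- scores$compartment[duplicated(scores$compartment)]
  if (length(dup)) {
    cm_abort(paste0("duplicated compartment(s): ", paste(unique(dup), collapse = ", ")),
             "cartmorph_aggregation_error")
  }
  tibble(
    histology_total = sum(scores$structure + scores$density + scores$clusters),
    macro_total = sum(scores$macro_grade)
  )
}

#' Score every section of a study
#'
#' Applies the OARSI rubric and the macroscopic grading to each
#' animal x compartment record of a simulated (or imported) study.
#'
#' @param study A `cart_study`, or a sections tibble with columns
#'   `animal_id`, `group`, `compartment`, `lesions` (list of lesion
#'   data frames), `density_pattern`, `cluster_count`, `ink_uptake`.
#' @return List of two tibbles: `sections` (per-compartment `structure`,
#'   `density`, `clusters`, `compartment_total`, `macro_grade`) and
#'   `animals` (per-animal `histology_total`, `macro_total`).
#' @export
score_study <- function(study) {
  sections <- if (inherits(study, "cart_study")) study$sections else study
  scored <- dplyr::mutate(
    sections[c("animal_id", "group", "compartment")],
    structure = vapply(sections$lesions, score_structure, integer(1)),
    density = score_density(sections$density_pattern),
    clusters = score_clusters(sections$cluster_count),
    macro_grade = grade_macroscopic(sections$ink_uptake)
  )
  scored$compartment_total <- scored$structure + scored$density + scored$clusters
  animals <- scored |>
    dplyr::group_by(.data$animal_id, .data$group) |>
    dplyr::group_modify(~ aggregate_joint(.x)) |>
    dplyr::ungroup()
  list(sections = scored, animals = animals)
}
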