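# I/O layer: YAML configuration, CSV tables (RFC-4180 via readr), JSON
# profile geometry and stats reports, and the end-to-end pipeline.
#
# Column dictionaries (units):
#   animals.csv     animal_id, group, compartment, density_pattern,
#                   cluster_count, ink_uptake, lesions_json,
#                   true_thickness_um (um), true_rms_um (um),
#                   true_norm_roughness (dimensionless x1000),
#                   comp_ng_ml, cox2_ng_ml, pge2_ng_ml (ng/ml)
#   morphometry.csv animal_id, compartment, group, thickness_um (um),
#                   area_um2 (um^2), rms_um (um), normalized_roughness
#                   (dimensionless x1000), n_digitized, n_fallback
#   scores.csv      animal_id, group, compartment, structure, density,
#                   clusters, compartment_total, macro_grade (+ per-
#                   animal totals in animal_totals.csv)

preset_to_list <- function(p) {
  list(
    group_label = p$group_label,
    thickness_mean = p$thickness_mean, thickness_sd = p$thickness_sd,
    norm_roughness_mean = p$norm_roughness_mean,
    norm_roughness_sd = p$norm_roughness_sd,
    area_window_um = p$area_window_um,
    structure_mean = as.list(p$structure_mean),
    density_mean = as.list(p$density_mean),
    cluster_mean = as.list(p$cluster_mean),
    macro_probs = lapply(p$macro_probs, as.numeric),
    serum_means = as.list(p$serum_means),
    serum_sds = as.list(p$serum_sds),
    extra_lesion_rate = p$extra_lesion_rate
  )
}

preset_from_list <- function(l) {
  needed <- c("group_label", "thickness_mean", "thickness_sd",
              "norm_roughness_mean", "norm_roughness_sd", "area_window_um",
              "structure_mean", "density_mean", "cluster_mean", "macro_probs",
              "serum_means", "serum_sds", "extra_lesion_rate")
  unknown <- setdiff(names(l), needed)
  if (length(unknown)) {
    cm_abort(paste0("unknown preset field(s): ", paste(unknown, collapse = ", ")),
             "cartmorph_config_error")
  }
  missing <- setdiff(needed, names(l))
  if (length(missing)) {
    cm_abort(paste0("missing preset field(s): ", paste(missing, collapse = ", ")),
             "cartmorph_config_error")
  }
  group_preset(
    l$group_label,
    thickness_mean = l$thickness_mean, thickness_sd = l$thickness_sd,
    norm_roughness_mean = l$norm_roughness_mean,
    norm_roughness_sd = l$norm_roughness_sd,
    area_window_um = l$area_window_um,
    structure_mean = unlist(l$structure_mean),
    density_mean = unlist(l$density_mean),
    cluster_mean = unlist(l$cluster_mean),
    macro_probs = lapply(l$macro_probs, unlist),
    serum_means = unlist(l$serum_means),
    serum_sds = unlist(l$serum_sds),
    extra_lesion_rate = l$extra_lesion_rate
  )
}

config_to_list <- function(config) {
  list(
    presets = lapply(config$presets, preset_to_list),
    n_per_group = config$n_per_group,
    roi_um = config$roi_um, flank_um = config$flank_um,
    spacing_um = config$spacing_um, arc_radius_um = config$arc_radius_um,
    edge_taper_um = config$edge_taper_um,
    pixel_size_um = config$pixel_size_um,
    profile_compartments = config$profile_compartments,
    n_thickness_points = config$n_thickness_points,
    fit_degree = config$fit_degree,
    alpha = config$alpha, adjust = config$adjust,
    normalized_scale = config$normalized_scale
  )
}

config_from_list <- function(l) {
  allowed <- c("presets", "n_per_group", "roi_um", "flank_um", "spacing_um",
               "arc_radius_um", "edge_taper_um", "pixel_size_um",
               "profile_compartments", "n_thickness_points", "fit_degree",
               "alpha", "adjust", "normalized_scale")
  unknown <- setdiff(names(l), allowed)
  if (length(unknown)) {
    cm_abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")),
             "cartmorph_config_error")
  }
  l$presets <- lapply(l$presets, preset_from_list)
  do.call(study_config, l)
}

#' Read / write a study configuration as YAML
#'
#' The YAML round trip is lossless; unknown keys are rejected with a
#' configuration error naming the field.
#'
#' @param config A [study_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config`
#'   returns a `cart_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cart_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) cm_abort(paste0("config file not found: ", path),
                                   "cartmorph_validation_error")
  config_from_list(yaml::read_yaml(path))
}

lesions_to_json <- function(lesions) {
  vapply(lesions, function(l) {
    as.character(jsonlite::toJSON(as.data.frame(l), digits = NA))
  }, character(1))
}

lesions_from_json <- function(txt) {
  lapply(txt, function(s) {
    df <- jsonlite::fromJSON(s)
    if (!length(df)) tibble(depth = character(), extent = numeric())
    else as_tibble(df)
  })
}

#' Write / read a simulated study directory
#'
#' Writes `animals.csv` (one row per animal x compartment: descriptors,
#' grades, generator truth and serum panel), `profiles/*.json` (boundary
#' polylines in micrometres plus truth), `truth.json` (per-animal
#' generator truth), `config.yaml` and `run.log`.
#'
#' @param study A `cart_study`.
#' @param dir Output directory (created if needed).
#' @param write_profiles Write the per-section geometry JSON files.
#' @return `write_study` returns `dir` invisibly; `read_study` returns
#'   the reconstructed `cart_study`.
#' @export
write_study <- function(study, dir, write_profiles = TRUE) {
  stopifnot(inherits(study, "cart_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- study$sections |>
    dplyr::mutate(lesions_json = lesions_to_json(.data$lesions)) |>
    dplyr::select(-"lesions", -"profile") |>
    dplyr::left_join(
      dplyr::rename(study$animals, comp_ng_ml = "comp", cox2_ng_ml = "cox2",
                    pge2_ng_ml = "pge2"),
      by = c("animal_id", "group"))
  readr::write_csv(tab, file.path(dir, "animals.csv"))

  if (write_profiles) {
    pdir <- file.path(dir, "profiles")
    dir.create(pdir, showWarnings = FALSE)
    for (i in seq_len(nrow(study$sections))) {
      prof <- study$sections$profile[[i]]
      if (is.null(prof)) next
      write_profile_json(prof, file.path(
        pdir, paste0(study$sections$animal_id[i], "_",
                     study$sections$compartment[i], ".json")))
    }
  }

  truth <- study$sections |>
    dplyr::distinct(.data$animal_id, .data$group, .data$true_thickness_um,
                    .data$true_rms_um, .data$true_norm_roughness)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  write_config(attr(study, "config"), file.path(dir, "config.yaml"))
  log_line(dir, sprintf("simulate: %d animals, seed %d, config %s",
                        nrow(study$animals), attr(study, "master_seed"),
                        attr(study, "config_fingerprint")))
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  path <- file.path(dir, "animals.csv")
  if (!file.exists(path)) cm_abort(paste0("missing file: ", path),
                                   "cartmorph_validation_error")
  tab <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("animal_id", "group", "compartment", "density_pattern",
                "cluster_count", "ink_uptake", "lesions_json",
                "true_thickness_um", "true_rms_um", "true_norm_roughness",
                "comp_ng_ml", "cox2_ng_ml", "pge2_ng_ml")
  check_columns(tab, required, "animals.csv")
  if (!nrow(tab)) cm_abort("animals.csv is empty", "cartmorph_validation_error")

  config <- read_config(file.path(dir, "config.yaml"))
  pdir <- file.path(dir, "profiles")
  sections <- tab |>
    dplyr::mutate(lesions = lesions_from_json(.data$lesions_json)) |>
    dplyr::select(-"lesions_json", -"comp_ng_ml", -"cox2_ng_ml", -"pge2_ng_ml")
  sections$profile <- purrr::map2(sections$animal_id, sections$compartment,
    function(id, comp) {
      f <- file.path(pdir, paste0(id, "_", comp, ".json"))
      if (file.exists(f)) read_profile_json(f) else NULL
    })
  sections <- sections[c("animal_id", "group", "compartment", "lesions",
                         "density_pattern", "cluster_count", "ink_uptake",
                         "profile", "true_thickness_um", "true_rms_um",
                         "true_norm_roughness")]
  animals <- tab |>
    dplyr::distinct(.data$animal_id, .data$group, .data$comp_ng_ml,
                    .data$cox2_ng_ml, .data$pge2_ng_ml) |>
    dplyr::rename(comp = "comp_ng_ml", cox2 = "cox2_ng_ml", pge2 = "pge2_ng_ml")
  study <- structure(list(animals = animals, sections = as_tibble(sections)),
                     class = "cart_study")
  attr(study, "config") <- config
  attr(study, "config_fingerprint") <- config_fingerprint(config)
  study
}

#' Write / read one profile as JSON
#'
#' @param profile A [cartilage_profile()].
#' @param path JSON file path.
#' @return `write_profile_json` returns `path` invisibly;
#'   `read_profile_json` a validated profile.
#' @export
write_profile_json <- function(profile, path) {
  truth <- profile$truth
  if (!is.null(truth)) truth$lesions <- as.data.frame(truth$lesions)
  jsonlite::write_json(list(
    surface = as.data.frame(profile$surface),
    tidemark = as.data.frame(profile$tidemark),
    roi = profile$roi, flanks = profile$flanks, scale = profile$scale,
    truth = truth
  ), path, dataframe = "columns", digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  l <- tryCatch(jsonlite::fromJSON(path),
                error = function(e) cm_abort(
                  paste0("corrupt profile file ", path, ": ", conditionMessage(e)),
                  "cartmorph_validation_error"))
  for (f in c("surface", "tidemark", "roi", "flanks")) {
    if (is.null(l[[f]])) cm_abort(paste0("profile file ", path,
                                         " missing field `", f, "`"),
                                  "cartmorph_validation_error")
  }
  truth <- l$truth
  if (!is.null(truth) && !is.null(truth$lesions)) {
    truth$lesions <- as_tibble(as.data.frame(truth$lesions))
  }
  tryCatch(
    cartilage_profile(as.data.frame(l$surface), as.data.frame(l$tidemark),
                      roi = l$roi, flanks = l$flanks,
                      scale = l$scale %||% 1, truth = truth),
    cartmorph_validation_error = function(e) cm_abort(
      paste0("invalid profile in ", path, ": ", conditionMessage(e)),
      "cartmorph_validation_error"))
}

check_columns <- function(tab, required, what) {
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    cm_abort(paste0(what, " missing required column(s): ",
                    paste(missing, collapse = ", ")),
             "cartmorph_schema_error")
  }
  invisible(tab)
}

#' Write / read the morphometry and score tables
#'
#' @param measurements A [measure_study()] tibble.
#' @param scores A [score_study()] result.
#' @param path,dir File path / directory.
#' @return The written path(s) invisibly; readers return tibbles.
#' @export
write_morphometry <- function(measurements, path) {
  out <- dplyr::select(measurements, -dplyr::any_of("thickness_points"))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_morphometry
#' @export
read_morphometry <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(tab, c("animal_id", "group", "thickness_um", "area_um2",
                       "rms_um", "normalized_roughness", "n_digitized"),
                "morphometry.csv")
  tab
}

#' @rdname write_morphometry
#' @export
write_scores <- function(scores, dir) {
  readr::write_csv(scores$sections, file.path(dir, "scores.csv"))
  readr::write_csv(scores$animals, file.path(dir, "animal_totals.csv"))
  invisible(dir)
}

#' @rdname write_morphometry
#' @export
read_scores <- function(dir) {
  sections <- readr::read_csv(file.path(dir, "scores.csv"), show_col_types = FALSE)
  check_columns(sections, c("animal_id", "group", "compartment", "structure",
                            "density", "clusters", "compartment_total",
                            "macro_grade"), "scores.csv")
  animals <- readr::read_csv(file.path(dir, "animal_totals.csv"),
                             show_col_types = FALSE)
  check_columns(animals, c("animal_id", "group", "histology_total",
                           "macro_total"), "animal_totals.csv")
  list(sections = sections, animals = animals)
}

#' Serialize a stats report to JSON
#'
#' @param report A `cart_report` from [analyze_study()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(report, path) {
  out <- lapply(unclass(report), function(cmp) {
    list(
      endpoint = cmp$endpoint, scale = cmp$scale,
      omnibus = as.data.frame(cmp$omnibus),
      posthoc = cmp$posthoc,
      pairwise = as.data.frame(cmp$pairwise),
      summaries = as.data.frame(cmp$summaries),
      normality = if (!is.null(cmp$plan$normality)) as.data.frame(cmp$plan$normality),
      levene_p = cmp$plan$levene_p
    )
  })
  jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

log_line <- function(dir, msg) {
  cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "INFO", msg, "\n",
      file = file.path(dir, "run.log"), append = TRUE)
}

#' Run the full simulate-measure-score-analyze pipeline
#'
#' Executes all stages in order into `out_dir`: simulation
#' (`animals.csv`, `profiles/`, `truth.json`), morphometry
#' (`morphometry.csv`), scoring (`scores.csv`, `animal_totals.csv`),
#' statistics (`report/stats.json`, `report/report.md`), and a run
#' manifest (`manifest.json`) recording the configuration fingerprint,
#' seed, package version and md5 hash of every output.  Re-running with
#' identical `(config, seed)` reproduces identical tables and stats.
#'
#' @param config A [study_config()].
#' @param seed Integer master seed.
#' @param out_dir Writable output directory.
#' @param write_profiles Write per-section geometry JSON (on by
#'   default; disable for large simulation sweeps).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = study_config(), seed = 1, out_dir,
                         write_profiles = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  manifest_stages <- list()
  tick <- function(stage) {
    manifest_stages[[stage]] <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  }
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      cm_abort(paste0("pipeline failed at stage `", name, "`: ",
                      conditionMessage(e)), "cartmorph_pipeline_error")
    })
  }

  study <- run_stage("simulate", simulate_study(config, seed))
  run_stage("write_study", write_study(study, out_dir,
                                       write_profiles = write_profiles))
  tick("simulate")

  measurements <- run_stage("measure", measure_study(study))
  write_morphometry(measurements, file.path(out_dir, "morphometry.csv"))
  log_line(out_dir, sprintf("measure: %d sections, %d thickness fallbacks",
                            nrow(measurements), sum(measurements$n_fallback)))
  tick("measure")

  scores <- run_stage("score", score_study(study))
  write_scores(scores, out_dir)
  log_line(out_dir, sprintf("score: %d sections", nrow(scores$sections)))
  tick("score")

  report <- run_stage("analyze", analyze_study(
    study, measurements = measurements, scores = scores,
    alpha = config$alpha, adjust = config$adjust))
  rdir <- file.path(out_dir, "report")
  dir.create(rdir, showWarnings = FALSE)
  write_stats_json(report, file.path(rdir, "stats.json"))
  writeLines(render_report_md(report), file.path(rdir, "report.md"))
  log_line(out_dir, sprintf("analyze: %d endpoints", length(report)))
  tick("analyze")

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$|run\\.log$", files)]
  hashes <- tools::md5sum(files)
  manifest <- list(
    package = "cartmorph",
    version = as.character(utils::packageVersion("cartmorph")),
    seed = as.integer(seed),
    config_fingerprint = attr(study, "config_fingerprint"),
    stages = manifest_stages,
    files = as.list(setNames(unname(hashes),
                             sub(paste0("^", out_dir, "/?"), "", files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Markdown tables in the two reporting conventions: median (IQR) for the
# macroscopic grades, mean +/- SEM for histology totals and morphometry.
render_report_md <- function(report) {
  eps <- attr(report, "endpoints")
  fmt_row <- function(...) paste0("| ", paste(..., sep = " | "), " |")
  lines <- c("# Study report", "")

  if ("macro_total" %in% names(report)) {
    s <- report$macro_total$summaries
    lines <- c(lines, "## Macroscopic grading (median (IQR))", "",
               fmt_row("Group", "total score"),
               fmt_row("---", "---"),
               sprintf("| %s | %.2f (%.1f) |", s$group, s$median, s$iqr), "")
  }
  cont <- intersect(c("histology_total", "thickness_um", "area_um2",
                      "normalized_roughness", "comp_ng_ml", "cox2_ng_ml",
                      "pge2_ng_ml"), names(report))
  if (length(cont)) {
    lines <- c(lines, "## Group summaries", "",
               fmt_row("Endpoint", "Group", "summary", "omnibus p"),
               fmt_row("---", "---", "---", "---"))
    for (ep in cont) {
      s <- report[[ep]]$summaries
      p <- report[[ep]]$omnibus$p_value
      txt <- if ("mean" %in% names(s)) {
        sprintf("%.2f ± %.2f (mean ± SEM)", s$mean, s$sem)
      } else {
        sprintf("%.2f (IQR %.2f)", s$median, s$iqr)
      }
      lines <- c(lines, sprintf("| %s | %s | %s | %.3g |", ep, s$group, txt, p))
    }
    lines <- c(lines, "")
  }
  sig <- tidy(report) |> dplyr::filter(.data$significant)
  lines <- c(lines, "## Significant pairwise comparisons", "",
             if (nrow(sig)) sprintf("- %s: %s vs %s (adjusted p = %s)",
                                    sig$endpoint, sig$group1, sig$group2,
                                    ifelse(is.na(sig$p_adj), "n/a (Dunnett's C)",
                                           signif(sig$p_adj, 3)))
             else "- none")
  lines
}
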