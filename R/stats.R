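# Group-comparison pipeline: Shapiro-Wilk normality, Levene-gated
# choice between Tukey HSD and Dunnett's C after one-way ANOVA for
# continuous endpoints, and Kruskal-Wallis with Bonferroni-adjusted
# pairwise Mann-Whitney tests for ordinal/non-normal endpoints.

# Split an endpoint data frame into a named list of group value vectors.
endpoint_groups <- function(data, value, group) {
  v <- data[[value]]
  g <- data[[group]]
  if (is.null(v) || is.null(g)) {
    cm_abort(sprintf("columns `%s` and `%s` must exist", value, group),
             "cartmorph_validation_error")
  }
  keep <- is.finite(v) & !is.na(g)
  split(v[keep], factor(g[keep]))
}

check_group_sizes <- function(groups) {
  n <- vapply(groups, length, integer(1))
  if (length(groups) < 2 || any(n < 2)) {
    cm_abort(paste0("need >= 2 groups with n >= 2 each (got ",
                    paste(sprintf("%s n=%d", names(groups), n), collapse = ", "),
                    ")"), "cartmorph_insufficient_data")
  }
  invisible(n)
}

#' Group summaries in the reporting conventions
#'
#' Continuous endpoints are summarized as mean and standard error of the
#' mean (`sd/sqrt(n)`); ordinal endpoints as median and interquartile
#' range with linear-interpolation quantiles.
#'
#' @param data Data frame with one row per animal.
#' @param value,group Column names (strings) of the endpoint values and
#'   the group labels.
#' @param scale `"continuous"` or `"ordinal"`.
#' @return Tibble with one row per group: `n` and either `mean`, `sem`
#'   or `median`, `iqr`, `q1`, `q3`.
#' @export
summarize_groups <- function(data, value, group, scale = c("continuous", "ordinal")) {
  scale <- match.arg(scale)
  groups <- endpoint_groups(data, value, group)
  if (scale == "continuous") {
    purrr::imap_dfr(groups, function(v, nm) {
      tibble(group = nm, n = length(v), mean = mean(v), sem = sem(v))
    })
  } else {
    purrr::imap_dfr(groups, function(v, nm) {
      q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      tibble(group = nm, n = length(v), median = q[2], iqr = q[3] - q[1],
             q1 = q[1], q3 = q[3])
    })
  }
}

#' Choose the test pipeline for an endpoint
#'
#' Continuous endpoints that pass Shapiro-Wilk normality in every group
#' are analysed by one-way ANOVA, with Tukey's HSD when Levene's test
#' (mean-centered) does not reject variance homogeneity and Dunnett's C
#' when it does.  Ordinal or non-normal endpoints go to Kruskal-Wallis
#' with pairwise Mann-Whitney tests and adjusted p values.
#'
#' @inheritParams summarize_groups
#' @param scale `"auto"` treats numeric endpoints with more than ~10
#'   distinct values as continuous; `"continuous"` and `"ordinal"`
#'   force the choice.
#' @param alpha Gate level for the normality and homogeneity tests.
#' @return List of class `cart_plan`: `omnibus` (`"anova"` or
#'   `"kruskal"`), `posthoc` (`"tukey"`, `"dunnett_c"` or
#'   `"mann_whitney"`), per-group Shapiro results and the Levene p
#'   value (when computed).
#' @export
choose_pipeline <- function(data, value, group,
                            scale = c("auto", "continuous", "ordinal"),
                            alpha = 0.05) {
  scale <- match.arg(scale)
  groups <- endpoint_groups(data, value, group)
  check_group_sizes(groups)
  if (scale == "auto") {
    distinct <- length(unique(unlist(groups)))
    scale <- if (distinct > 10) "continuous" else "ordinal"
  }

  normality <- NULL
  levene_p <- NA_real_
  if (scale == "continuous") {
    normality <- purrr::imap_dfr(groups, function(v, nm) {
      p <- if (length(unique(v)) < 3) 0 else shapiro.test(v)$p.value
      tibble(group = nm, n = length(v), shapiro_p = p)
    })
    all_normal <- all(normality$shapiro_p > alpha)
    if (all_normal) {
      levene_p <- levene_p_value(groups)
      posthoc <- if (levene_p > alpha) "tukey" else "dunnett_c"
      plan <- list(omnibus = "anova", posthoc = posthoc)
    } else {
      plan <- list(omnibus = "kruskal", posthoc = "mann_whitney")
    }
  } else {
    plan <- list(omnibus = "kruskal", posthoc = "mann_whitney")
  }
  structure(c(plan, list(scale = scale, normality = normality,
                         levene_p = levene_p, alpha = alpha)),
            class = "cart_plan")
}

# Levene's test p value (mean-centered, as in mainstream statistics
# packages' one-way homogeneity gate).
levene_p_value <- function(groups) {
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), lengths(groups)))
  )
  res <- car::leveneTest(y ~ g, data = df, center = mean)
  res[["Pr(>F)"]][1]
}

pairwise_index <- function(groups) {
  utils::combn(names(groups), 2, simplify = FALSE)
}

#' One-way ANOVA with Tukey's HSD post hoc
#'
#' @inheritParams summarize_groups
#' @param alpha Significance level for the pairwise flags.
#' @param plan Optional precomputed [choose_pipeline()] result (used to
#'   carry the normality/Levene diagnostics into the report).
#' @return A `cart_comparison` object.
#' @export
anova_tukey <- function(data, value, group, alpha = 0.05, plan = NULL) {
  groups <- endpoint_groups(data, value, group)
  check_group_sizes(groups)
  check_not_degenerate(groups)
  df <- data.frame(y = unlist(groups, use.names = FALSE),
                   g = factor(rep(names(groups), lengths(groups))))
  fit <- aov(y ~ g, data = df)
  an <- anova(fit)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairwise <- purrr::map2_dfr(pairs, seq_along(pairs), function(pr, i) {
    tibble(group1 = pr[2], group2 = pr[1],
           estimate = -tk[i, "diff"],
           p_raw = NA_real_, p_adj = tk[i, "p adj"],
           critical_difference = NA_real_,
           significant = tk[i, "p adj"] < alpha)
  })
  new_comparison(
    endpoint = value, scale = "continuous",
    omnibus = tibble(method = "One-way ANOVA",
                     statistic = an[["F value"]][1],
                     df1 = an[["Df"]][1], df2 = an[["Df"]][2],
                     p_value = an[["Pr(>F)"]][1]),
    posthoc = "Tukey HSD",
    pairwise = pairwise,
    summaries = summarize_groups(data, value, group, "continuous"),
    plan = plan, alpha = alpha
  )
}

#' One-way ANOVA with Dunnett's C post hoc
#'
#' Dunnett's C is the unequal-variance pairwise procedure used when
#' Levene's test rejects variance homogeneity.  For each pair the
#' critical difference is `q * sqrt((s_i^2/n_i + s_j^2/n_j)/2)`, where
#' `q` is the mean of the studentized-range quantiles
#' `q_{alpha}(k, n_i - 1)` and `q_{alpha}(k, n_j - 1)`.  The procedure
#' yields significance decisions, not p values; pairwise `p_adj` is
#' reported as `NA` and `critical_difference` is filled in.
#'
#' @inheritParams anova_tukey
#' @return A `cart_comparison` object.
#' @export
anova_dunnett_c <- function(data, value, group, alpha = 0.05, plan = NULL) {
  groups <- endpoint_groups(data, value, group)
  check_group_sizes(groups)
  check_not_degenerate(groups)
  df <- data.frame(y = unlist(groups, use.names = FALSE),
                   g = factor(rep(names(groups), lengths(groups))))
  an <- anova(aov(y ~ g, data = df))
  k <- length(groups)
  pairwise <- purrr::map_dfr(pairwise_index(groups), function(pr) {
    vi <- groups[[pr[1]]]; vj <- groups[[pr[2]]]
    se <- sqrt((var(vi) / length(vi) + var(vj) / length(vj)) / 2)
    q <- mean(c(qtukey(1 - alpha, k, length(vi) - 1),
                qtukey(1 - alpha, k, length(vj) - 1)))
    cd <- q * se
    est <- mean(vi) - mean(vj)
    tibble(group1 = pr[1], group2 = pr[2], estimate = est,
           p_raw = NA_real_, p_adj = NA_real_,
           critical_difference = cd, significant = abs(est) > cd)
  })
  new_comparison(
    endpoint = value, scale = "continuous",
    omnibus = tibble(method = "One-way ANOVA",
                     statistic = an[["F value"]][1],
                     df1 = an[["Df"]][1], df2 = an[["Df"]][2],
                     p_value = an[["Pr(>F)"]][1]),
    posthoc = "Dunnett's C",
    pairwise = pairwise,
    summaries = summarize_groups(data, value, group, "continuous"),
    plan = plan, alpha = alpha
  )
}

#' Kruskal-Wallis with pairwise Mann-Whitney tests
#'
#' Kruskal-Wallis omnibus test (tie-corrected) followed by a
#' Mann-Whitney (Wilcoxon rank-sum) test for each group pair, exact
#' when samples are small and tie-free and a continuity-corrected
#' normal approximation otherwise, with p values adjusted for the
#' number of pairs (Bonferroni by default).
#'
#' @inheritParams anova_tukey
#' @param adjust Adjustment method passed to [stats::p.adjust()].
#' @return A `cart_comparison` object.
#' @export
kruskal_pairwise <- function(data, value, group, alpha = 0.05,
                             adjust = "bonferroni", plan = NULL) {
  groups <- endpoint_groups(data, value, group)
  check_group_sizes(groups)
  check_not_degenerate(groups)
  kw <- kruskal.test(unname(groups))
  prs <- pairwise_index(groups)
  raw <- vapply(prs, function(pr) {
    suppressWarnings(
      wilcox.test(groups[[pr[1]]], groups[[pr[2]]], correct = TRUE)$p.value)
  }, numeric(1))
  adj <- stats::p.adjust(raw, method = adjust)
  pairwise <- purrr::map_dfr(seq_along(prs), function(i) {
    pr <- prs[[i]]
    tibble(group1 = pr[1], group2 = pr[2],
           estimate = median(groups[[pr[1]]]) - median(groups[[pr[2]]]),
           p_raw = raw[i], p_adj = adj[i],
           critical_difference = NA_real_,
           significant = adj[i] < alpha)
  })
  new_comparison(
    endpoint = value, scale = "ordinal",
    omnibus = tibble(method = "Kruskal-Wallis",
                     statistic = unname(kw$statistic),
                     df1 = unname(kw$parameter), df2 = NA_real_,
                     p_value = kw$p.value),
    posthoc = paste0("Mann-Whitney (", adjust, ")"),
    pairwise = pairwise,
    summaries = summarize_groups(data, value, group, "ordinal"),
    plan = plan, alpha = alpha
  )
}

check_not_degenerate <- function(groups) {
  if (length(unique(unlist(groups))) < 2) {
    cm_abort("degenerate endpoint: all values identical across all groups",
             "cartmorph_degenerate_data")
  }
  invisible(TRUE)
}

#' Compare groups on one endpoint with the gated pipeline
#'
#' Runs [choose_pipeline()] and dispatches to [anova_tukey()],
#' [anova_dunnett_c()] or [kruskal_pairwise()] accordingly.
#'
#' @inheritParams choose_pipeline
#' @param adjust Pairwise adjustment for the ordinal branch.
#' @return A `cart_comparison` object with the omnibus test, all
#'   pairwise comparisons, group summaries and the gate diagnostics.
#' @examples
#' df <- data.frame(y = rnorm(33, rep(c(0, 0, 1), each = 11)),
#'                  g = rep(c("a", "b", "c"), each = 11))
#' cmp <- compare_groups(df, "y", "g", scale = "continuous")
#' tidy(cmp)
#' glance(cmp)
#' @export
compare_groups <- function(data, value, group,
                           scale = c("auto", "continuous", "ordinal"),
                           alpha = 0.05, adjust = "bonferroni") {
  plan <- choose_pipeline(data, value, group, scale = scale, alpha = alpha)
  if (plan$omnibus == "anova" && plan$posthoc == "tukey") {
    anova_tukey(data, value, group, alpha = alpha, plan = plan)
  } else if (plan$omnibus == "anova") {
    anova_dunnett_c(data, value, group, alpha = alpha, plan = plan)
  } else {
    kruskal_pairwise(data, value, group, alpha = alpha, adjust = adjust,
                     plan = plan)
  }
}

new_comparison <- function(endpoint, scale, omnibus, posthoc, pairwise,
                           summaries, plan, alpha) {
  structure(list(
    endpoint = endpoint, scale = scale, omnibus = omnibus, posthoc = posthoc,
    pairwise = pairwise, summaries = summaries, plan = plan, alpha = alpha
  ), class = "cart_comparison")
}

#' @export
print.cart_comparison <- function(x, ...) {
  cat("<cart_comparison> ", x$endpoint, " (", x$scale, ")\n", sep = "")
  cat(sprintf("  %s: statistic %.3f, p = %.4g; post hoc: %s\n",
              x$omnibus$method, x$omnibus$statistic, x$omnibus$p_value,
              x$posthoc))
  print(x$pairwise)
  invisible(x)
}

#' @describeIn compare_groups Pairwise comparison table (one row per
#'   group pair).
#' @param x A `cart_comparison`.
#' @param ... Unused.
#' @export
tidy.cart_comparison <- function(x, ...) {
  dplyr::mutate(x$pairwise, endpoint = x$endpoint, .before = 1)
}

#' @describeIn compare_groups One-row omnibus summary.
#' @export
glance.cart_comparison <- function(x, ...) {
  tibble(
    endpoint = x$endpoint, scale = x$scale,
    method = x$omnibus$method, statistic = x$omnibus$statistic,
    df1 = x$omnibus$df1, df2 = x$omnibus$df2, p_value = x$omnibus$p_value,
    posthoc = x$posthoc,
    levene_p = if (!is.null(x$plan)) x$plan$levene_p else NA_real_,
    n_significant = sum(x$pairwise$significant)
  )
}

#' @export
autoplot.cart_comparison <- function(object, data = NULL, ...) {
  if (is.null(data)) {
    cm_abort("supply the endpoint data frame via `data`", "cartmorph_domain_error")
  }
  ggplot2::ggplot(data, ggplot2::aes(x = .data$group, y = .data[[object$endpoint]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6) +
    ggplot2::labs(title = object$endpoint,
                  subtitle = sprintf("%s, p = %.3g; post hoc %s",
                                     object$omnibus$method,
                                     object$omnibus$p_value, object$posthoc)) +
    ggplot2::theme_minimal()
}

#' Analyse all endpoints of a simulated study
#'
#' Builds the per-animal endpoint table (morphometry on the medial
#' femoral condyle, OARSI histology total, macroscopic total, serum
#' panel) and runs the gated comparison pipeline on each endpoint:
#' continuous endpoints through the ANOVA gate, ordinal totals through
#' Kruskal-Wallis.  The histology total is treated as continuous
#' (interval-scaled sum of 12 components), the macroscopic total as
#' ordinal.
#'
#' @param study A `cart_study`.
#' @param measurements Optional precomputed [measure_study()] table.
#' @param scores Optional precomputed [score_study()] result.
#' @param alpha Significance level.
#' @param adjust Pairwise adjustment for ordinal endpoints.
#' @return A `cart_report`: named list of `cart_comparison` objects with
#'   `tidy()`/`glance()` methods, plus the endpoint data as an
#'   attribute.
#' @export
analyze_study <- function(study, measurements = NULL, scores = NULL,
                          alpha = 0.05, adjust = "bonferroni") {
  stopifnot(inherits(study, "cart_study"))
  if (is.null(measurements)) measurements <- measure_study(study)
  if (is.null(scores)) scores <- score_study(study)

  endpoints <- scores$animals |>
    dplyr::left_join(measurements[c("animal_id", "thickness_um", "area_um2",
                                    "rms_um", "normalized_roughness")],
                     by = "animal_id") |>
    dplyr::left_join(study$animals[c("animal_id", "comp", "cox2", "pge2")],
                     by = "animal_id") |>
    dplyr::rename(comp_ng_ml = "comp", cox2_ng_ml = "cox2", pge2_ng_ml = "pge2")

  endpoint_scales <- c(
    thickness_um = "continuous", area_um2 = "continuous",
    normalized_roughness = "continuous", histology_total = "continuous",
    macro_total = "ordinal", comp_ng_ml = "continuous",
    cox2_ng_ml = "continuous", pge2_ng_ml = "continuous")
  endpoint_scales <- endpoint_scales[names(endpoint_scales) %in% names(endpoints)]
  comparisons <- purrr::imap(endpoint_scales, function(sc, ep) {
    compare_groups(endpoints, ep, "group", scale = sc, alpha = alpha,
                   adjust = adjust)
  })
  structure(comparisons, class = "cart_report", endpoints = endpoints)
}

#' @export
print.cart_report <- function(x, ...) {
  cat("<cart_report> ", length(x), " endpoints\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @describeIn analyze_study All pairwise comparisons across endpoints.
#' @param x A `cart_report`.
#' @param ... Unused.
#' @export
tidy.cart_report <- function(x, ...) {
  purrr::map_dfr(unclass(x), tidy)
}

#' @describeIn analyze_study One row per endpoint: omnibus results.
#' @export
glance.cart_report <- function(x, ...) {
  purrr::map_dfr(unclass(x), glance)
}
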