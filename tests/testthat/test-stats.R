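make_groups <- function(means, sds = rep(1, length(means)), n = 11, seed = 1) {
  withr::with_seed(seed, data.frame(
    y = unlist(purrr::map2(means, sds, ~ rnorm(n, .x, .y))),
    g = rep(paste0("g", seq_along(means)), each = n)
  ))
}

test_that("pipeline choice: homoscedastic normal -> ANOVA + Tukey", {
  df <- make_groups(c(0, 0, 0), seed = 2)
  plan <- choose_pipeline(df, "y", "g", scale = "continuous")
  expect_equal(plan$omnibus, "anova")
  expect_equal(plan$posthoc, "tukey")
  expect_true(all(plan$normality$shapiro_p > 0.05))
})

test_that("pipeline choice: a 25-fold variance group -> Dunnett's C", {
  df <- make_groups(c(0, 0, 0), sds = c(1, 1, 5), seed = 3)
  plan <- choose_pipeline(df, "y", "g", scale = "continuous")
  expect_equal(plan$omnibus, "anova")
  expect_equal(plan$posthoc, "dunnett_c")
  expect_lt(plan$levene_p, 0.05)
})

test_that("pipeline choice: ordinal data -> Kruskal-Wallis + Mann-Whitney", {
  df <- data.frame(y = rep(c(1, 2, 3, 2), 6), g = rep(c("a", "b", "c"), 8))
  plan <- choose_pipeline(df, "y", "g", scale = "ordinal")
  expect_equal(plan$omnibus, "kruskal")
  expect_equal(plan$posthoc, "mann_whitney")
  expect_error(choose_pipeline(data.frame(y = 1:3, g = c("a", "b", "c")),
                               "y", "g"),
               class = "cartmorph_insufficient_data")
})

test_that("identical groups: F near 0 and no pair significant", {
  df <- make_groups(c(0, 0, 0), seed = 4)
  res <- anova_tukey(df, "y", "g")
  expect_lt(res$omnibus$p_value, 1 + 1e-9)
  expect_false(any(res$pairwise$significant))
  expect_equal(nrow(res$pairwise), 3)  # all three group pairs
})

test_that("a 10-SD shift flags every pair involving the shifted group", {
  df <- make_groups(c(0, 0, 10), seed = 5)
  res <- compare_groups(df, "y", "g", scale = "continuous")
  flagged <- res$pairwise$significant[res$pairwise$group1 == "g3" |
                                        res$pairwise$group2 == "g3"]
  expect_true(all(flagged))
})

test_that("Tukey and Dunnett's C agree on strongly separated groups", {
  df <- make_groups(c(0, 5, 10), seed = 6)
  tk <- anova_tukey(df, "y", "g")
  dc <- anova_dunnett_c(df, "y", "g")
  expect_identical(tk$pairwise$significant, dc$pairwise$significant)
  expect_true(all(is.na(dc$pairwise$p_adj)))  # decision-only procedure
  expect_true(all(dc$pairwise$critical_difference > 0))
})

test_that("degenerate all-tied data raise an error", {
  df <- data.frame(y = rep(1, 12), g = rep(c("a", "b", "c"), each = 4))
  expect_error(kruskal_pairwise(df, "y", "g"),
               class = "cartmorph_degenerate_data")
  expect_error(anova_tukey(df, "y", "g"), class = "cartmorph_degenerate_data")
})

test_that("Bonferroni-adjusted pairwise p values are min(1, 3p)", {
  df <- make_groups(c(0, 1, 2), seed = 7)
  res <- kruskal_pairwise(df, "y", "g")
  expect_equal(res$pairwise$p_adj, pmin(1, 3 * res$pairwise$p_raw))
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw))
  expect_identical(res$pairwise$significant, res$pairwise$p_adj < 0.05)
})

test_that("exact Mann-Whitney matches full enumeration on n <= 8", {
  set.seed(8)
  for (rep in 1:10) {
    m <- sample(4:8, 1); n <- sample(4:8, 1)
    x <- round(rnorm(m), 2); y <- round(rnorm(n, 0.5), 2)
    while (anyDuplicated(c(x, y))) y <- round(rnorm(n, 0.5), 2)
    w <- wilcox.test(x, y, exact = TRUE)
    expect_equal(unname(w$statistic), brute_u(x, y))
    expect_equal(w$p.value, enum_wilcox_p(x, y), tolerance = 1e-10)
  }
})

test_that("permuting group labels permutes but never alters pairwise results", {
  df <- make_groups(c(0, 1, 3), seed = 9)
  res1 <- compare_groups(df, "y", "g", scale = "continuous")
  relab <- c(g1 = "g2", g2 = "g3", g3 = "g1")
  df2 <- transform(df, g = unname(relab[g]))
  res2 <- compare_groups(df2, "y", "g", scale = "continuous")
  key <- function(r) {
    pw <- r$pairwise
    pair <- purrr::map2_chr(pw$group1, pw$group2,
                            ~ paste(sort(c(.x, .y)), collapse = "-"))
    setNames(pw$p_adj, pair)
  }
  k1 <- key(res1)
  pair_map <- function(p) paste(sort(unname(relab[strsplit(p, "-")[[1]]])),
                                collapse = "-")
  expect_equal(unname(k1), unname(key(res2)[vapply(names(k1), pair_map,
                                                   character(1))]),
               tolerance = 1e-12)
})

test_that("positive rescaling of a continuous endpoint leaves p unchanged", {
  df <- make_groups(c(0, 1, 2), seed = 10)
  r1 <- compare_groups(df, "y", "g", scale = "continuous")
  df2 <- transform(df, y = 37.5 * y)
  r2 <- compare_groups(df2, "y", "g", scale = "continuous")
  expect_equal(r1$omnibus$p_value, r2$omnibus$p_value, tolerance = 1e-9)
  expect_equal(r1$pairwise$p_adj, r2$pairwise$p_adj, tolerance = 1e-9)
})

test_that("summaries use mean/SEM and interpolated median/IQR conventions", {
  df <- data.frame(y = c(1, 2, 3, 4), g = rep("a", 4))
  s <- summarize_groups(df, "y", "g", "ordinal")
  expect_equal(s$median, 2.5)
  expect_equal(s$iqr, 1.5)

  const <- data.frame(y = rep(7, 5), g = "a")
  expect_equal(summarize_groups(const, "y", "g", "continuous")$sem, 0)

  v <- rnorm(11)
  v <- (v - mean(v)) / sd(v) * 5.86 + 20  # exact sd 5.86, n = 11
  d <- data.frame(y = v, g = "a")
  expect_equal(round(summarize_groups(d, "y", "g", "continuous")$sem, 2), 1.77)
})

test_that("tidy/glance return the report tables", {
  df <- make_groups(c(0, 0, 2), seed = 11)
  cmp <- compare_groups(df, "y", "g", scale = "continuous")
  td <- tidy(cmp)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("endpoint", "group1", "group2", "p_adj", "significant")
                  %in% names(td)))
  gl <- glance(cmp)
  expect_equal(nrow(gl), 1)
  expect_true(gl$method %in% c("One-way ANOVA", "Kruskal-Wallis"))
})

test_that("analyze_study covers the endpoint panel with sensible choices", {
  study <- simulate_study(mf_config(n_per_group = 6), seed = 12)
  rep <- analyze_study(study)
  expect_gte(length(rep), 6)
  gl <- glance(rep)
  expect_true(all(c("thickness_um", "normalized_roughness", "histology_total",
                    "macro_total", "comp_ng_ml") %in% gl$endpoint))
  expect_equal(gl$method[gl$endpoint == "macro_total"], "Kruskal-Wallis")
  td <- tidy(rep)
  expect_equal(nrow(td), 3 * length(rep))  # three pairs per endpoint
})
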