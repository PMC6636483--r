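test_that("the full 12-row structure rubric scores row-exactly", {
  tab <- oarsi_structure_table()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    if (row$depth == "none") {
      expect_identical(score_structure(data.frame(depth = character(),
                                                  extent = numeric())), 0L)
      next
    }
    extents <- switch(row$extent_band,
                      "any" = c(0.1, 0.8),
                      "<50%" = c(0.05, 0.49),
                      ">=50%" = c(0.50, 0.95))  # tie at 50% is >= 50%
    for (e in extents) {
      expect_identical(
        score_structure(data.frame(depth = row$depth, extent = e)),
        row$score,
        label = sprintf("depth %s extent %.2f", row$depth, e))
    }
  }
})

test_that("structure score uses the most-severe-lesion rule (brute force)", {
  set.seed(11)
  depths <- setdiff(oarsi_structure_table()$depth, "none")
  for (rep in 1:50) {
    n <- sample(1:5, 1)
    lesions <- data.frame(depth = sample(depths, n, replace = TRUE),
                          extent = runif(n))
    singles <- vapply(seq_len(n), function(i) score_structure(lesions[i, ]),
                      integer(1))
    expect_identical(score_structure(lesions), max(singles))
  }
})

test_that("deepening a lesion or crossing 50% extent never lowers the score", {
  depths <- c("irregularity", "fissure", "erosion_third", "erosion_two_thirds",
              "full_depth", "full_depth_calcified")
  for (i in seq_along(depths)) {
    low <- score_structure(data.frame(depth = depths[i], extent = 0.3))
    high <- score_structure(data.frame(depth = depths[i], extent = 0.6))
    expect_gte(high, low)
    if (i > 1) {
      prev <- score_structure(data.frame(depth = depths[i - 1], extent = 0.3))
      expect_gte(low, prev)
    }
  }
})

test_that("density, cluster and macroscopic lookups match their scales", {
  expect_identical(score_density("no_decrease"), 0L)
  expect_identical(score_density("multifocal_confluent"), 3L)
  expect_identical(score_density("diffuse"), 4L)
  expect_error(score_density("sparse"), class = "cartmorph_domain_error")

  expect_identical(score_clusters(0), 0L)
  expect_identical(score_clusters(c(1, 3)), c(1L, 1L))
  expect_identical(score_clusters(5), 2L)
  expect_identical(score_clusters(c(7, 8, 40)), c(2L, 3L, 3L))
  expect_error(score_clusters(-1), class = "cartmorph_domain_error")

  expect_identical(grade_macroscopic("none"), 1L)
  expect_identical(grade_macroscopic("minimal_focal"), 2L)
  expect_identical(grade_macroscopic("large_focal_patches"), 3L)
  expect_identical(grade_macroscopic("bone_exposed"), 4L)
  expect_error(grade_macroscopic("pristine"), class = "cartmorph_domain_error")
})

test_that("all scores stay within their declared scales under fuzzing", {
  set.seed(21)
  depths <- setdiff(oarsi_structure_table()$depth, "none")
  for (rep in 1:200) {
    n <- sample(0:6, 1)
    lesions <- data.frame(depth = sample(depths, n, replace = TRUE),
                          extent = runif(n))
    s <- score_structure(lesions)
    expect_true(s >= 0 && s <= 11)
  }
  expect_true(all(score_clusters(0:100) %in% 0:3))
  expect_true(all(score_density(density_patterns <- c(
    "no_decrease", "focal", "multifocal", "multifocal_confluent", "diffuse"
  )) %in% 0:4))
})

test_that("joint aggregation sums the four compartments and flags gaps", {
  scores <- data.frame(
    compartment = c("MF", "LF", "MT", "LT"),
    structure = c(4, 4, 3, 4), density = c(2, 3, 2, 2),
    clusters = c(1, 1, 1, 1), macro_grade = c(1, 1, 1, 1)
  )
  agg <- aggregate_joint(scores)
  expect_equal(agg$histology_total, sum(7, 8, 6, 7))  # 28
  expect_equal(agg$macro_total, 4)

  expect_error(aggregate_joint(scores[-2, ]),
               regexp = "LF", class = "cartmorph_aggregation_error")
  expect_error(aggregate_joint(rbind(scores, scores[1, ])),
               class = "cartmorph_aggregation_error")
})

test_that("a lesion-free arm scores 0 histology and 4 macroscopic everywhere", {
  study <- simulate_cohort(healthy_preset(), n = 6, config = desc_config(),
                           seed = 3)
  sc <- score_study(study)
  expect_true(all(sc$animals$histology_total == 0))
  expect_true(all(sc$animals$macro_total == 4))
  expect_true(all(sc$sections$structure == 0))
})
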