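# Synthetic alpha/beta tables with known cluster structure.
two_cluster_alpha <- function(n = 20L, centers = c(0.40, 0.90), eps = 0.02,
                              seed = 3L) {
  set.seed(seed)
  data.frame(
    alpha = c(centers[1] + runif(n, -eps, eps),
              centers[2] + runif(n, -eps, eps)),
    beta = c(runif(n, 0.45, 0.55), runif(n, 0.70, 1.10))
  )
}

test_that("step one separates low-alpha laps and places alpha1 between clusters", {
  ab <- two_cluster_alpha()
  model <- fit_two_step(ab, seed = 1)
  expect_gt(model$alpha1, 0.45)
  expect_lt(model$alpha1, 0.85)
  labels <- predict(model, ab)
  expect_true(all(labels[ab$alpha < 0.5] == "CatA"))
  expect_true(all(labels[ab$alpha > 0.8] != "CatA"))
})

test_that("step two recovers three beta clusters in order", {
  set.seed(5)
  n <- 15L
  ab <- data.frame(
    alpha = c(runif(n, 0.38, 0.44), runif(3 * n, 0.70, 0.95)),
    beta = c(runif(n, 1.0, 1.1),
             0.50 + runif(n, -0.03, 0.03),
             0.77 + runif(n, -0.03, 0.03),
             1.07 + runif(n, -0.03, 0.03))
  )
  model <- fit_two_step(ab, seed = 2)
  expect_gt(model$beta1, 0.53)
  expect_lt(model$beta1, 0.74)
  expect_gt(model$beta2, 0.80)
  expect_lt(model$beta2, 1.04)
  expect_true(model$beta1 < model$beta2)
  labels <- as.character(predict(model, ab))
  expect_equal(labels[(n + 1):(2 * n)], rep("CatB", n))
  expect_equal(labels[(2 * n + 1):(3 * n)], rep("CatC", n))
  expect_equal(labels[(3 * n + 1):(4 * n)], rep("CatD", n))
})

test_that("degenerate clustering input is rejected", {
  expect_error(fit_two_step(data.frame(alpha = rep(0.5, 8), beta = 1:8 / 8)),
               "degenerate clustering input")
  expect_error(fit_two_step(data.frame(alpha = c(0.4, 0.9), beta = c(0.5, 0.9))),
               "degenerate clustering input")
  # too few distinct beta values outside the low-alpha cluster
  ab <- data.frame(alpha = c(0.4, 0.41, 0.9, 0.91, 0.92),
                   beta = c(0.5, 0.5, 0.8, 0.8, 0.8))
  expect_error(fit_two_step(ab), "degenerate clustering input")
  expect_error(fit_two_step(data.frame(alpha = c(0.4, NA, 0.9, 0.8, 0.7),
                                       beta = rep(0.5, 5))),
               "degenerate clustering input")
})

test_that("classify_fixed follows the boundary inequalities exactly", {
  th <- reference_thresholds()
  lab <- function(a, b) as.character(classify_fixed(data.frame(alpha = a, beta = b), th))
  expect_equal(lab(0.58, 1.0), "CatA")   # alpha == alpha1 -> CatA
  expect_equal(lab(0.59, 0.62), "CatB")  # beta < beta1
  expect_equal(lab(0.59, 0.63), "CatC")  # beta == beta1 -> CatC
  expect_equal(lab(0.59, 0.90), "CatC")
  expect_equal(lab(0.59, 0.91), "CatD")  # beta == beta2 -> CatD
  expect_error(classify_fixed(data.frame(alpha = NaN, beta = 1)),
               "unclassifiable lap")
  expect_error(classify_fixed(data.frame(alpha = 0.5, beta = 1),
                              thresholds = c(alpha1 = 0.5, beta1 = 0.9, beta2 = 0.6)),
               "invalid thresholds")
})

test_that("published thresholds classify the four mean constructions correctly", {
  labels <- vapply(CATEGORY_LEVELS, function(cat) {
    as.character(classify_fixed(mean_params(cat)))
  }, character(1))
  expect_equal(unname(labels), CATEGORY_LEVELS)
})

test_that("categories map onto strategies A->S1, B->S2, C/D->S3", {
  expect_equal(as.character(category_to_strategy("CatA")), "S1")
  expect_equal(as.character(category_to_strategy(c("CatB", "CatC", "CatD"))),
               c("S2", "S3", "S3"))
  # not invertible for S3: both four-beat subcategories collapse
  expect_equal(category_to_strategy("CatC"), category_to_strategy("CatD"))
  expect_error(category_to_strategy("CatE"), "unknown category")
})

test_that("fitting is deterministic in the seed and invariant to input order", {
  ab <- profile_cohort(10L, seed = 4)
  m1 <- fit_two_step(ab, seed = 7)
  m2 <- fit_two_step(ab, seed = 7)
  expect_equal(m1$alpha1, m2$alpha1)
  expect_equal(c(m1$beta1, m1$beta2), c(m2$beta1, m2$beta2))

  perm <- sample(nrow(ab))
  m3 <- fit_two_step(ab[perm, ], seed = 7)
  expect_equal(m3$alpha1, m1$alpha1, tolerance = 1e-12)
  expect_equal(m3$beta1, m1$beta1, tolerance = 1e-12)
  expect_equal(as.character(predict(m3, ab)), as.character(predict(m1, ab)))
})

test_that("the fitted model is exactly its thresholds", {
  ab <- profile_cohort(12L, seed = 9)
  model <- fit_two_step(ab, seed = 1)
  expect_equal(
    as.character(predict(model, ab)),
    as.character(classify_fixed(ab, thresholds = c(alpha1 = model$alpha1,
                                                   beta1 = model$beta1,
                                                   beta2 = model$beta2)))
  )
  expect_gt(model$alpha1, 0)
  expect_lt(model$beta1, model$beta2)
  expect_equal(sum(model$fit_metadata$counts), nrow(ab))
})

test_that("alternative clusterings agree on separable data but cannot split four groups", {
  set.seed(6)
  n <- 12L
  ab <- data.frame(
    alpha = c(runif(n, 0.30, 0.40), runif(2 * n, 0.75, 0.95)),
    beta = c(runif(n, 0.95, 1.10), runif(n, 0.45, 0.55), runif(n, 0.95, 1.10))
  )
  truth <- rep(c("S1", "S2", "S3"), each = n)
  two_step <- category_to_strategy(predict(fit_two_step(ab, seed = 1), ab))
  k3 <- fit_alternative(ab, "single_k3_on_plane", seed = 1)
  k2k2 <- fit_alternative(ab, "two_successive_k2", seed = 1)
  expect_equal(as.character(two_step), truth)
  expect_equal(as.character(k3$labels), truth)
  expect_equal(as.character(k2k2$labels), truth)

  # two beta subclusters inside the four-beat strategy: only the two-step
  # classifier (k = 3 on beta) resolves them into distinct categories
  ab4 <- data.frame(
    alpha = c(runif(n, 0.30, 0.40), runif(3 * n, 0.75, 0.95)),
    beta = c(runif(n, 0.95, 1.10), runif(n, 0.45, 0.55),
             0.77 + runif(n, -0.02, 0.02), 1.07 + runif(n, -0.02, 0.02))
  )
  cats <- predict(fit_two_step(ab4, seed = 1), ab4)
  expect_equal(length(unique(as.character(cats))), 4L)
  alt <- fit_alternative(ab4, "two_successive_k2", seed = 1)
  expect_lte(length(unique(as.character(alt$labels))), 3L)

  expect_error(fit_alternative(ab4[1, ], "single_k3_on_plane"),
               "degenerate clustering input")
})
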