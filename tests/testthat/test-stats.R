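test_that("the Shapiro screen reports per group and flags degenerate samples", {
  rep_norm <- qnorm(ppoints(10))
  bimodal <- c(-5.1, -5, -4.9, -4.95, -5.05, 4.9, 5, 5.1, 4.95, 5.05)
  out <- shapiro_screen(list(A = rep_norm, B = rep(3, 10), C = bimodal,
                             D = c(1, 2)))
  expect_gt(out$p[out$group == "A"], 0.05)
  expect_true(is.na(out$p[out$group == "B"]))
  expect_identical(out$note[out$group == "B"], "constant")
  expect_lt(out$p[out$group == "C"], 0.05)
  expect_identical(out$note[out$group == "D"], "n < 3")
})

test_that("Kruskal-Wallis reproduces the hand-ranked example and its invariances", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  kw <- kruskal_wallis(g)
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$p, pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(kw$df, 2, tolerance = 0)
  same <- list(a = rep(2, 4), b = rep(2, 4), c = rep(2, 4))
  kw0 <- kruskal_wallis(same)
  expect_identical(kw0$H, 0)
  expect_identical(kw0$p, 1)
  # permuting which values carry which label leaves H unchanged
  perm <- list(a = c(7, 8, 9), b = c(1, 2, 3), c = c(4, 5, 6))
  expect_equal(kruskal_wallis(perm)$H, kw$H, tolerance = 1e-12)
})

test_that("Dunn-Holm agrees with an independently coded oracle on random fixtures", {
  set.seed(11)
  for (rep in 1:20) {
    g <- list(BV = round(rnorm(10, 0, 2), 1 + rep %% 2),
              UV = round(rnorm(10, 0.5, 2), 1 + rep %% 2),
              HS = round(rnorm(10, 1, 2), 1 + rep %% 2))
    dn <- dunn_holm(g)
    raw <- oracle_dunn(g)
    expect_equal(dn$p_raw, unname(raw[dn$comparison]), tolerance = 1e-10)
    expect_equal(dn$p_adj, unname(oracle_holm(dn$p_raw)), tolerance = 1e-10)
    # Holm never decreases a raw p and never reverses an ordering
    expect_true(all(dn$p_adj >= dn$p_raw - 1e-15))
    for (i in 1:3) for (j in 1:3)
      if (dn$p_raw[i] < dn$p_raw[j])
        expect_lte(dn$p_adj[i], dn$p_adj[j])
  }
})

test_that("Dunn-Holm degenerate and contract cases", {
  same <- list(BV = rep(1, 5), UV = rep(1, 5), HS = rep(1, 5))
  expect_identical(dunn_holm(same)$p_adj, rep(1, 3))
  g <- list(BV = 1:5, UV = 2:6, HS = 3:7)
  expect_error(dunn_holm(g, kw_p = 0.4), "exceeds alpha")
})

test_that("Kruskal-Wallis agrees with the rank-formula oracle on random fixtures", {
  set.seed(21)
  for (rep in 1:20) {
    g <- list(a = round(rnorm(8), 1), b = round(rnorm(9), 1),
              c = round(rnorm(10), 1))
    expect_equal(kruskal_wallis(g)$H, oracle_kw(g), tolerance = 1e-10)
  }
})

test_that("validity categories follow the published thresholds", {
  expect_identical(categorize(0.0005, "discriminant"), "excellent")
  expect_identical(categorize(0.001, "discriminant"), "excellent")
  expect_identical(categorize(0.005, "discriminant"), "good")
  expect_identical(categorize(0.03, "discriminant"), "moderate")
  expect_identical(categorize(0.07, "discriminant"), "fair")
  expect_identical(categorize(0.1, "discriminant"), "poor")
  expect_identical(categorize(0.85, "convergent"), "excellent")
  expect_identical(categorize(0.61, "convergent"), "good")
  expect_identical(categorize(-0.5, "convergent"), "moderate")
  expect_identical(categorize(0.3, "convergent"), "fair")
  expect_identical(categorize(0.2, "convergent"), "poor")
  expect_error(categorize(1.4, "discriminant"), "out of")
  expect_error(categorize(1.4, "convergent"), "out of")
})

test_that("relevance synthesis applies the three-condition rule", {
  grid <- data.frame(task = "comfortable",
                     parameter = c("Walking_speed", "GaitSD", "MoS_ML"),
                     kw_p = c(0.03, 0.03, 0.5),
                     status = "ok", strict = FALSE,
                     stringsAsFactors = FALSE)
  corr <- data.frame(task = "comfortable",
                     parameter = c("Walking_speed", "GaitSD", "MoS_ML"),
                     group = "BV", r = c(0.7, 0.5, 0.9), n = 10,
                     stringsAsFactors = FALSE)
  app <- data.frame(parameter = c("Walking_speed", "GaitSD", "MoS_ML"),
                    applicability = c("excellent", "poor", "excellent"),
                    stringsAsFactors = FALSE)
  rel <- synthesize_relevance(grid, corr, app)
  expect_identical(rel$tier[rel$parameter == "Walking_speed"], "relevant")
  expect_identical(rel$tier[rel$parameter == "GaitSD"], "interesting")
  expect_identical(rel$tier[rel$parameter == "MoS_ML"], "not-relevant")
  expect_error(synthesize_relevance(grid, corr, app[1:2, ]),
               "applicability")
})

test_that("median and quartiles reproduce the clinical cohort's printed values", {
  bv_fga <- c(19, 21, 20, 21, 20, 18, 24, 26, 15, 22)
  uv_fga <- c(14, 30, 22, 28, 29, 27, 28, 28, 26, 27)
  hs_fga <- c(29, 30, 28, 30, 30, 30, 29, 29, 29, 27)
  expect_equal(unname(median_iqr(bv_fga)), c(20.5, 19.25, 21.75),
               tolerance = 1e-12)
  expect_equal(unname(median_iqr(uv_fga)[c("median", "q1")]), c(27.5, 26.25),
               tolerance = 1e-12)
  expect_equal(unname(median_iqr(hs_fga)["median"]), 29, tolerance = 1e-12)
  bv_dhi <- c(48, 46, 12, 34, 20, 74, 2, 40, 48)
  expect_equal(unname(median_iqr(bv_dhi)), c(40, 20, 48), tolerance = 1e-12)
  expect_equal(unname(median_iqr(5)), c(5, 5, 5))
  expect_true(all(is.na(median_iqr(numeric()))))
})

test_that("the power simulation is calibrated under the null and saturates", {
  null_p <- simulate_kw_power(c(1, 1, 1), c(0.2, 0.2, 0.2), c(10, 10, 10),
                              n_sim = 3000, seed = 3)
  expect_gt(null_p$power, 0.03)
  expect_lt(null_p$power, 0.07)
  sat <- simulate_kw_power(c(0, 2, 4), c(0.2, 0.2, 0.2), c(10, 10, 10),
                           n_sim = 1000, seed = 4)
  expect_gte(sat$power, 0.999)
  expect_error(simulate_kw_power(c(1, 1, 1), c(0, 0.1, 0.1), c(5, 5, 5)),
               "positive")
})
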