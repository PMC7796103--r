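test_that("weighted R2 matches the direct weighted-correlation formula", {
  f <- weighted_linear_fit(c(1, 2, 3), c(1, 3, 2), c(1, 1, 1))
  expect_equal(f$r2, 0.25)
  expect_equal(f$r2, wr2_oracle(c(1, 2, 3), c(1, 3, 2), c(1, 1, 1)))

  set.seed(51)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n); w <- runif(n, 1, 100)
    f <- weighted_linear_fit(x, y, w)
    expect_equal(f$r2, wr2_oracle(x, y, w), tolerance = 1e-12)
    # cross-check slope/intercept/R2 against lm with weights
    lmfit <- lm(y ~ x, weights = w)
    expect_equal(f$slope, unname(coef(lmfit)[2]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(coef(lmfit)[1]), tolerance = 1e-10)
    expect_equal(f$r2, summary(lmfit)$r.squared, tolerance = 1e-10)
  }
})

test_that("collinear data gives a perfect, degenerate fit", {
  x <- c(1, 2, 4, 7)
  f <- weighted_linear_fit(x, 2 * x + 1, c(3, 1, 2, 5))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1)
  expect_equal(r2_confidence(f), c(1, 1))
})

test_that("R2 is invariant to affine rescaling, weight scaling, and x/y swap", {
  set.seed(52)
  x <- rnorm(8); y <- x + rnorm(8); w <- runif(8, 10, 500)
  r <- weighted_linear_fit(x, y, w)$r2
  expect_equal(weighted_linear_fit(3 * x - 7, y, w)$r2, r, tolerance = 1e-12)
  expect_equal(weighted_linear_fit(x, -0.5 * y + 2, w)$r2, r, tolerance = 1e-12)
  expect_equal(weighted_linear_fit(x, y, 10 * w)$r2, r, tolerance = 1e-12)
  expect_equal(weighted_linear_fit(y, x, w)$r2, r, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  expect_error(weighted_linear_fit(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1)),
               "zero weighted variance")
  expect_error(weighted_linear_fit(c(1, 2), c(1, 2), c(1, 1)), "at least 3")
  expect_error(weighted_linear_fit(c(1, NA, 3), c(1, 2, 3), c(1, 1, 1)),
               "missing")
  expect_error(weighted_linear_fit(c(1, 2, 3), c(1, 2, 3), c(1, -1, 1)),
               "positive")
})

test_that("bootstrap CI is seed-stable and brackets the estimate on real data", {
  ici <- ici_rmst_rows()
  f <- weighted_linear_fit(ici$rmst6_pfs, ici$rmst6_os, ici$n)
  ci1 <- r2_confidence(f, method = "bootstrap", n_boot = 500, seed = 1)
  ci2 <- r2_confidence(f, method = "bootstrap", n_boot = 500, seed = 1)
  expect_identical(ci1, ci2)
  expect_true(ci1[1] <= f$r2 && f$r2 <= ci1[2])
  small <- weighted_linear_fit(1:3, c(1, 3, 2), rep(1, 3))
  expect_error(r2_confidence(small, method = "bootstrap"), "at least 4")
})

test_that("interaction coefficients are exact on noise-free constructions", {
  x <- rep(1:5, 2)
  g <- rep(c("A", "B"), each = 5)
  w <- rep(1, 10)
  same <- suppressWarnings(interaction_test(x, 2 * x + 1, w, g))
  expect_equal(same$interaction_coef, 0, tolerance = 1e-12)
  y <- ifelse(g == "B", 3 * x + 1, 2 * x + 1)
  diff1 <- suppressWarnings(interaction_test(x, y, w, g))
  expect_equal(diff1$interaction_coef, 1, tolerance = 1e-12)
  expect_error(interaction_test(x, y, w, rep("A", 10)), "2 groups")
  expect_error(interaction_test(x[1:4], y[1:4], w[1:4], c("A", "A", "A", "B")),
               "at least 2 arms")
})

test_that("the interaction test keeps its nominal size under the null", {
  set.seed(53)
  p <- replicate(400, {
    x <- rnorm(20); g <- rep(c("A", "B"), each = 10)
    y <- 1 + 0.8 * x + rnorm(20)
    interaction_test(x, y, runif(20, 50, 300), g)$interaction_p
  })
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("printed-table surrogacy fits reproduce the published R2 pattern", {
  ici <- ici_rmst_rows()
  f6 <- weighted_linear_fit(ici$rmst6_pfs, ici$rmst6_os, ici$n)
  expect_equal(round(f6$r2, 2), 0.80)
  f12 <- weighted_linear_fit(ici$rmst12_pfs, ici$rmst12_os, ici$n)
  expect_equal(round(f12$r2, 2), 0.80)

  arms <- ici_arm_table()
  suite <- surrogacy_suite(arms)
  q1 <- suite$fits[["q1.ICI"]]
  expect_equal(q1$n_arms, 7L)
  expect_setequal(
    attr(q1, "arm_ids"),
    c("pembrolizumab", "camrelizumab", "nivolumab",
      "nivolumab-ipilimumab-cabozantinib", "nivolumab-cabozantinib",
      "atezolizumab-bevacizumab"))
  expect_lt(abs(q1$r2 - 0.89), 0.011)
})

test_that("strata without enough usable arms are skipped with a reason", {
  arms <- data.frame(arm_id = letters[1:6],
                     drug_class = rep(c("ICI", "MKI"), each = 3),
                     n = rep(100, 6),
                     q3_pfs = c(NA, NA, NA, 1, 2, 3),
                     q3_os = c(NA, NA, NA, 2, 4, 5))
  suite <- surrogacy_suite(arms, pairs = list(q3 = c("q3_pfs", "q3_os")))
  expect_null(suite$fits[["q3.ICI"]])
  log <- suite$log
  expect_false(log$fitted[log$pair == "q3" & log$stratum == "ICI"])
  expect_match(log$reason[log$pair == "q3" & log$stratum == "ICI"],
               "fewer than 3")
  expect_true(log$fitted[log$pair == "q3" & log$stratum == "MKI"])
})

test_that("ORR surrogacy behaves like a weighted regression of rates", {
  arms <- data.frame(arm_id = letters[1:5], drug_class = "ICI",
                     n = c(100, 200, 150, 80, 120),
                     orr_pct = c(10, 20, 30, 40, 50),
                     os_rate_end_fu_pct = c(25, 35, 45, 55, 65))
  f <- orr_surrogacy(arms)
  expect_equal(f$r2, 1)
  expect_equal(f$slope, 1)

  set.seed(54)
  r2s <- replicate(300, {
    a <- data.frame(arm_id = letters[1:10], drug_class = "ICI", n = 100,
                    orr_pct = runif(10, 5, 50),
                    os_rate_end_fu_pct = runif(10, 20, 80))
    f <- orr_surrogacy(a)
    expect_equal(sign(f$slope),
                 sign(sum((a$orr_pct - mean(a$orr_pct)) *
                            (a$os_rate_end_fu_pct -
                               mean(a$os_rate_end_fu_pct)))))
    f$r2
  })
  # null small-sample bias of R2 is ~ 1/(n_arms - 1)
  expect_equal(mean(r2s), 1 / 9, tolerance = 0.04)
})
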