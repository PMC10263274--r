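test_that("odds ratio and Woolf interval reproduce the hand-derived case", {
  res <- odds_ratio_ci(10, 5, 20, 40)
  expect_equal(res$or, 4.0, tolerance = 1e-12)
  expect_equal(res$lower, exp(log(4) - qnorm(0.975) * sqrt(0.375)),
               tolerance = 1e-12)
  expect_equal(res$lower, 1.204, tolerance = 1e-3)
  expect_equal(res$upper, 13.285, tolerance = 1e-3)
  expect_false(res$corrected)
})

test_that("the unit table is symmetric about 1 on the log scale", {
  res <- odds_ratio_ci(1, 1, 1, 1)
  expect_equal(res$or, 1)
  expect_equal(log(res$upper), -log(res$lower), tolerance = 1e-12)
})

test_that("Haldane-Anscombe correction applies to all cells when any is zero", {
  res <- odds_ratio_ci(0, 5, 20, 40)
  expect_true(res$corrected)
  expect_equal(res$or, (0.5 * 40.5) / (5.5 * 20.5), tolerance = 1e-12)
})

test_that("chi-squared reproduces the hand case and its known properties", {
  res <- chi_squared_2x2(10, 5, 20, 40)
  expect_equal(res$statistic, 5.556, tolerance = 1e-3)
  expect_lt(abs(res$p_value - 0.018), 5e-4)
  # independence: ad = bc -> statistic 0, p 1
  ind <- chi_squared_2x2(10, 20, 30, 60)
  expect_equal(ind$statistic, 0)
  expect_equal(ind$p_value, 1)
  # scaling all cells by 10 scales the statistic by 10
  expect_equal(chi_squared_2x2(100, 50, 200, 400)$statistic,
               10 * res$statistic, tolerance = 1e-9)
  expect_error(chi_squared_2x2(0, 0, 20, 40), "marginal")
})

test_that("both 2x2 statistics agree with direct recomputation on all small tables", {
  tables <- expand.grid(a = 0:12, b = 0:12, c = 0:12, d = 0:12)
  tables <- tables[rowSums(tables) <= 12 & rowSums(tables) > 0, ]
  z <- qnorm(0.975)
  for (i in seq_len(nrow(tables))) {
    t4 <- as.numeric(tables[i, ])
    a <- t4[1]; b <- t4[2]; cc <- t4[3]; d <- t4[4]
    # odds ratio oracle: direct formula with the stated correction rule
    if (any(t4 == 0)) {
      a2 <- a + 0.5; b2 <- b + 0.5; c2 <- cc + 0.5; d2 <- d + 0.5
    } else {
      a2 <- a; b2 <- b; c2 <- cc; d2 <- d
    }
    or_exp <- (a2 * d2) / (b2 * c2)
    se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
    got <- odds_ratio_ci(a, b, cc, d)
    expect_equal(got$or, or_exp, tolerance = 1e-12)
    expect_equal(got$lower, exp(log(or_exp) - z * se), tolerance = 1e-12)
    expect_equal(got$upper, exp(log(or_exp) + z * se), tolerance = 1e-12)
    # chi-squared oracle
    marg <- c(a + b, cc + d, a + cc, b + d)
    if (all(marg > 0)) {
      n <- sum(t4)
      stat_exp <- n * (a * d - b * cc)^2 / prod(marg)
      got2 <- chi_squared_2x2(a, b, cc, d)
      expect_equal(got2$statistic, stat_exp, tolerance = 1e-12)
      expect_equal(got2$p_value, pchisq(stat_exp, 1, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  }
})

test_that("chi-squared matches the stock uncorrected test on a nontrivial table", {
  ours <- chi_squared_2x2(13, 44, 25, 29)
  ref <- chisq.test(matrix(c(13, 44, 25, 29), 2, byrow = TRUE),
                    correct = FALSE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("odds-ratio exchange symmetries hold", {
  set.seed(3)
  for (i in 1:20) {
    t4 <- sample(1:50, 4, replace = TRUE)
    or0 <- odds_ratio_ci(t4[1], t4[2], t4[3], t4[4])$or
    # swap both rows and both columns -> invariant
    expect_equal(odds_ratio_ci(t4[4], t4[3], t4[2], t4[1])$or, or0,
                 tolerance = 1e-12)
    # swap one row -> reciprocal
    expect_equal(odds_ratio_ci(t4[3], t4[4], t4[1], t4[2])$or, 1 / or0,
                 tolerance = 1e-12)
  }
})

test_that("group tests handle null, equal-mean and separated-group limits", {
  df <- data.frame(v = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  res <- group_tests(df, "v", "g")
  expect_equal(res$t_test$statistic, 0)
  expect_equal(res$t_test$p_value, 1)

  df3 <- data.frame(v = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  expect_equal(group_tests(df3, "v", "g")$anova$statistic, 0)

  set.seed(1)
  dfs <- data.frame(v = c(0, 0, 0, 1, 1, 1) + rnorm(6, 0, 1e-9),
                    g = rep(c("a", "b"), each = 3))
  expect_lt(group_tests(dfs, "v", "g")$t_test$p_value, 1e-6)

  expect_error(group_tests(data.frame(v = 1:3, g = c("a", "a", "a")),
                           "v", "g"), "2 groups")
})

test_that("percent density change: constant groups, identity, and delta-vs-bootstrap SE", {
  res <- percent_density_change(c(730, 730, 730), c(1000, 1000, 1000))
  expect_equal(res$percent_decrease, 27.0)
  expect_equal(res$se, 0)

  expect_equal(percent_density_change(c(5, 6), c(5, 6))$percent_decrease, 0)
  expect_error(percent_density_change(1, 0), "zero")

  ad <- c(600, 750, 840); ctl <- c(950, 1000, 1050)
  res2 <- percent_density_change(ad, ctl)
  expect_equal(res2$percent_decrease, 27.0, tolerance = 1e-9)
  # bootstrap oracle for the SE of the ratio estimator
  set.seed(17)
  boot <- replicate(1e4, {
    100 * (mean(sample(ctl, 3, TRUE)) - mean(sample(ad, 3, TRUE))) /
      mean(sample(ctl, 3, TRUE))
  })
  expect_equal(res2$se, sd(boot), tolerance = 0.35)
})

test_that("the mixed model reduces to least squares in the noiseless limit", {
  layer_eff <- c(0, 50, 120, 80, 150, 60)
  grid <- expand.grid(donor_id = c("d1", "d2"), layer = 1:6,
                      at8_status = c("AT8-", "AT8+"), repn = 1:3)
  grid$hud_volume <- 1000 + 300 * (grid$at8_status == "AT8+") +
    layer_eff[grid$layer]
  fit <- fit_lmm(grid, "hud_volume")
  est <- tidy(fit)
  expect_equal(est$estimate[est$term == "at8AT8+"], 300, tolerance = 1e-6)
  expect_equal(est$estimate[est$term == "layer5"], 150, tolerance = 1e-6)
  g <- glance(fit)
  expect_equal(g$n_obs, nrow(grid))
  expect_equal(g$n_donors, 2)
})

test_that("the mixed model contracts: single donor and single status fail", {
  df <- data.frame(donor_id = "d1", at8_status = rep(c("AT8-", "AT8+"), 5),
                   layer = 1, hud_volume = rnorm(10, 1000))
  expect_error(fit_lmm(df, "hud_volume"), "single donor")
  df2 <- data.frame(donor_id = rep(c("d1", "d2"), 5), at8_status = "AT8+",
                    layer = 1, hud_volume = rnorm(10, 1000))
  expect_error(fit_lmm(df2, "hud_volume"), "statuses")
})

test_that("a permuted response decouples the AT8 effect", {
  set.seed(23)
  n <- 600
  df <- data.frame(donor_id = sample(paste0("d", 1:6), n, TRUE),
                   at8_status = sample(c("AT8-", "AT8+"), n, TRUE),
                   layer = sample(1:6, n, TRUE))
  df$hud_volume <- 1500 + rnorm(n, 0, 400)
  sig <- replicate(25, {
    df$at8_status <- sample(df$at8_status)
    est <- tidy(fit_lmm(df, "hud_volume"))
    est$p_value[est$term == "at8AT8+"] < 0.05
  })
  expect_gte(mean(!sig), 0.9)
})
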