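#' Odds ratio with Woolf confidence interval
#'
#' For a 2x2 table of counts with rows ghost / non-ghost and columns
#' layers-of-interest / other layers, the cross-product odds ratio is
#' `OR = (a d) / (b c)` with the Woolf (log-normal) interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is zero
#' the Haldane-Anscombe correction adds 0.5 to all four cells before
#' estimation.
#'
#' @param a,b,c,d Nonnegative counts. `a`,`b` = first row, `c`,`d` = second.
#' @param conf_level Confidence level in (0, 1). Default 0.95.
#' @return Tibble with `or`, `lower`, `upper`, `conf_level`, `corrected`.
#' @examples
#' odds_ratio_ci(10, 5, 20, 40)
#' @export
odds_ratio_ci <- function(a, b, c, d, conf_level = 0.95) {
  check_2x2(a, b, c, d)
  if (!(conf_level > 0 && conf_level < 1)) {
    stop("conf_level must lie in (0, 1)", call. = FALSE)
  }
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  if ((a == 0 && b == 0) || (c == 0 && d == 0) ||
        (a == 0 && c == 0) || (b == 0 && d == 0)) {
    stop("a zero row or column remains after correction; ",
         "odds ratio undefined", call. = FALSE)
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(or = or,
                 lower = exp(log(or) - z * se),
                 upper = exp(log(or) + z * se),
                 conf_level = conf_level,
                 corrected = corrected)
}

check_2x2 <- function(a, b, c, d) {
  v <- c(a, b, c, d)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("2x2 cells must be finite nonnegative counts", call. = FALSE)
  }
  if (sum(v) <= 0) stop("2x2 table is empty", call. = FALSE)
  invisible(v)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' The Pearson statistic without continuity correction,
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, against chi-squared with one
#' degree of freedom.
#'
#' @inheritParams odds_ratio_ci
#' @return Tibble with `statistic`, `p_value`, `df`.
#' @examples
#' chi_squared_2x2(10, 5, 20, 40)
#' @export
chi_squared_2x2 <- function(a, b, c, d) {
  check_2x2(a, b, c, d)
  n <- a + b + c + d
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) {
    stop("zero marginal total; chi-squared undefined", call. = FALSE)
  }
  stat <- n * (a * d - b * c)^2 / prod(marg)
  tibble::tibble(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 df = 1L)
}

#' Group comparisons: t-test and one-way ANOVA
#'
#' With exactly two groups, a two-tailed two-sample Student t-test (Welch by
#' request); with any number of groups, a one-way fixed-effects ANOVA. When
#' every group has zero within-group variance and all means are equal the F
#' statistic is defined as 0 with p = 1. Pairwise two-sample t-tests across
#' all group pairs accompany the ANOVA.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the response and grouping
#'   variable.
#' @param var_equal Use the pooled-variance Student test (default `TRUE`).
#' @param alpha Significance threshold reported alongside. Default 0.05.
#' @return List with `anova` (tibble: statistic, df, p_value), `t_test`
#'   (tibble, two-group case only), `pairwise` (tibble of group pairs) and
#'   `alpha`.
#' @export
group_tests <- function(data, value, group, var_equal = TRUE, alpha = 0.05) {
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L)) stop("need at least 2 values per group",
                               call. = FALSE)

  safe_t <- function(x, y) {
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) {
        return(tibble::tibble(statistic = 0, p_value = 1,
                              estimate = mean(x) - mean(y)))
      }
      # degenerate separation: infinite t
      return(tibble::tibble(statistic = sign(mean(x) - mean(y)) * Inf,
                            p_value = 0, estimate = mean(x) - mean(y)))
    }
    tt <- stats::t.test(x, y, var.equal = var_equal, alternative = "two.sided")
    tibble::tibble(statistic = unname(tt$statistic),
                   p_value = tt$p.value,
                   estimate = mean(x) - mean(y))
  }

  lv <- levels(g)
  if (all(tapply(v, g, stats::var) == 0)) {
    means <- tapply(v, g, mean)
    if (isTRUE(all.equal(max(means), min(means)))) {
      anova_tbl <- tibble::tibble(statistic = 0,
                                  df1 = nlevels(g) - 1L,
                                  df2 = length(v) - nlevels(g),
                                  p_value = 1)
    } else {
      anova_tbl <- tibble::tibble(statistic = Inf,
                                  df1 = nlevels(g) - 1L,
                                  df2 = length(v) - nlevels(g),
                                  p_value = 0)
    }
  } else {
    fit <- stats::aov(v ~ g)
    sm <- summary(fit)[[1]]
    anova_tbl <- tibble::tibble(statistic = sm[["F value"]][1],
                                df1 = sm[["Df"]][1],
                                df2 = sm[["Df"]][2],
                                p_value = sm[["Pr(>F)"]][1])
  }

  pairs <- utils::combn(lv, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(p) {
    res <- safe_t(v[g == p[1]], v[g == p[2]])
    dplyr::mutate(res, group1 = p[1], group2 = p[2], .before = 1)
  })

  out <- list(anova = anova_tbl, pairwise = pairwise, alpha = alpha)
  if (nlevels(g) == 2L) {
    out$t_test <- safe_t(v[g == lv[1]], v[g == lv[2]])
  }
  out
}

#' Percent decrease in density with propagated standard error
#'
#' `decrease = 100 (mean_control - mean_case) / mean_control`, with the
#' standard error obtained by first-order (delta-method) propagation of the
#' two group standard errors through the ratio:
#' `var = (100 / mc)^2 var(ma) + (100 ma / mc^2)^2 var(mc)` where
#' `var(m) = s^2 / n` is the squared standard error of each group mean.
#'
#' @param case_densities Densities in the affected group (e.g. AD subjects).
#' @param control_densities Densities in the control group.
#' @return Tibble with `percent_decrease`, `se`, `t_statistic`, `p_value`
#'   (two-tailed Student t-test on the raw densities where both groups have
#'   at least two values).
#' @export
percent_density_change <- function(case_densities, control_densities) {
  ma <- mean(case_densities)
  mc <- mean(control_densities)
  if (mc == 0) stop("control mean density is zero", call. = FALSE)
  dec <- 100 * (mc - ma) / mc
  var_ma <- if (length(case_densities) > 1) {
    stats::var(case_densities) / length(case_densities)
  } else 0
  var_mc <- if (length(control_densities) > 1) {
    stats::var(control_densities) / length(control_densities)
  } else 0
  se <- sqrt((100 / mc)^2 * var_ma + (100 * ma / mc^2)^2 * var_mc)
  tt <- if (length(case_densities) > 1 && length(control_densities) > 1 &&
              (stats::var(case_densities) > 0 ||
                 stats::var(control_densities) > 0)) {
    res <- stats::t.test(case_densities, control_densities, var.equal = TRUE)
    c(unname(res$statistic), res$p.value)
  } else {
    c(NA_real_, NA_real_)
  }
  tibble::tibble(percent_decrease = dec, se = se,
                 t_statistic = tt[1], p_value = tt[2])
}

#' Linear mixed-effects model of cell size
#'
#' Fits `size ~ at8_status + layer + (1 | donor)` by restricted maximum
#' likelihood: tangle status (AT8+/AT8-) and cortical layer (treatment
#' coding, layer 1 reference) as fixed effects and a per-donor random
#' intercept. The response is the HuD-stained soma volume or the
#' DAPI-stained nucleus volume in um^3.
#'
#' @param rows Tibble with columns `donor_id`, `at8_status`
#'   (`"AT8+"`/`"AT8-"`), `layer` (1-6) and the response column.
#' @param response `"hud_volume"` or `"dapi_volume"` (any numeric column).
#' @return A `ts_lmm_fit`; see [tidy.ts_lmm_fit()] and
#'   [glance.ts_lmm_fit()].
#' @export
fit_lmm <- function(rows, response = "hud_volume") {
  rows <- tibble::as_tibble(rows)
  need <- c("donor_id", "at8_status", "layer", response)
  if (!all(need %in% names(rows))) {
    stop("rows need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (length(unique(rows$donor_id)) < 2L) {
    stop("a single donor cannot support a donor random effect; ",
         "fit a fixed-effects linear model instead", call. = FALSE)
  }
  if (length(unique(rows$at8_status)) < 2L) {
    stop("both AT8 statuses must be present", call. = FALSE)
  }
  if (any(!rows$layer %in% 1:6)) stop("layer must be 1-6", call. = FALSE)
  df <- data.frame(
    y = rows[[response]],
    at8 = factor(rows$at8_status, levels = c("AT8-", "AT8+")),
    layer = factor(rows$layer, levels = 1:6),
    donor = factor(rows$donor_id))
  fit <- lmerTest::lmer(y ~ at8 + layer + (1 | donor), data = df, REML = TRUE,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore",
                          calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fit = fit, response = response,
                 donor_sd = vc$sdcor[vc$grp == "donor"],
                 residual_sd = vc$sdcor[vc$grp == "Residual"],
                 method = "REML"),
            class = "ts_lmm_fit")
}

#' @export
print.ts_lmm_fit <- function(x, ...) {
  cat(sprintf("<ts_lmm_fit> %s ~ AT8 status + layer + (1 | donor), %s\n",
              x$response, x$method))
  cat(sprintf("  donor sd %.1f, residual sd %.1f um^3\n",
              x$donor_sd, x$residual_sd))
  est <- tidy(x)
  at8 <- est[est$term == "at8AT8+", ]
  if (nrow(at8)) {
    cat(sprintf("  AT8+ effect: %.1f um^3 (se %.1f, p = %.3g)\n",
                at8$estimate, at8$std_error, at8$p_value))
  }
  invisible(x)
}

#' Tidy the fixed effects of a cell-size mixed model
#'
#' @param x A `ts_lmm_fit`.
#' @param conf_level Confidence level for the Wald intervals.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `df`, `statistic`,
#'   `p_value`, `conf_low`, `conf_high`.
#' @export
tidy.ts_lmm_fit <- function(x, conf_level = 0.95, ...) {
  co <- as.data.frame(summary(x$fit)$coefficients)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(term = rownames(co),
                 estimate = co[["Estimate"]],
                 std_error = co[["Std. Error"]],
                 df = co[["df"]],
                 statistic = co[["t value"]],
                 p_value = co[["Pr(>|t|)"]],
                 conf_low = co[["Estimate"]] - z * co[["Std. Error"]],
                 conf_high = co[["Estimate"]] + z * co[["Std. Error"]])
}

#' Variance components and fit summary of a cell-size mixed model
#'
#' @param x A `ts_lmm_fit`.
#' @param ... Unused.
#' @return One-row tibble with `donor_sd`, `residual_sd`, `n_obs`,
#'   `n_donors`, `method`, `REMLcrit`.
#' @export
glance.ts_lmm_fit <- function(x, ...) {
  tibble::tibble(donor_sd = x$donor_sd,
                 residual_sd = x$residual_sd,
                 n_obs = stats::nobs(x$fit),
                 n_donors = lme4::ngrps(x$fit)[["donor"]],
                 method = x$method,
                 REMLcrit = lme4::REMLcrit(x$fit))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
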