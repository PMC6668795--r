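#' Kruskal-Wallis H test across procedure groups
#'
#' Thin wrapper around [stats::kruskal.test()] that accepts a list of
#' value vectors (one per group) and returns the tie-corrected H statistic
#' and its chi-square p value with `k - 1` degrees of freedom.
#'
#' @param groups Named or unnamed list of numeric vectors, each non-empty,
#'   at least two groups.
#' @return A list with `h`, `p_value`, `df`, `n_groups`.
#' @export
kruskal_wallis <- function(groups) {
  .check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  list(h = unname(kt$statistic), p_value = unname(kt$p.value),
       df = unname(kt$parameter), n_groups = length(groups))
}

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("Need a list of at least two groups")
  }
  if (any(lengths(groups) == 0)) abort("Every group must be non-empty")
  invisible(groups)
}

#' Dunn's pairwise post-hoc test with Bonferroni correction
#'
#' For every pair of groups the z statistic is the difference of mean ranks
#' (ranks taken over the pooled sample, midranks for ties) divided by its
#' standard error with the tie-corrected variance
#' `(N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/n_i + 1/n_j)`. Two-sided raw
#' p values are Bonferroni-adjusted by the number of pairs `k(k-1)/2` and
#' capped at 1.
#'
#' @param groups List of numeric vectors as in [kruskal_wallis()]; names
#'   are used as group labels.
#' @param alpha Significance level for the adjusted p values, default 0.05.
#' @return A list with the omnibus `h` and `p_value`, `n_pairs`,
#'   `n_significant`, and `pairwise`: a tibble `group_a`, `group_b`, `z`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
dunn_pairwise <- function(groups, alpha = 0.05) {
  .check_groups(groups)
  k <- length(groups)
  labels <- names(groups) %||% as.character(seq_len(k))
  values <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  N <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, g, mean)
  n_i <- lengths(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term

  pairs <- utils::combn(k, 2)
  pw <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(c) {
    i <- pairs[1, c]; j <- pairs[2, c]
    se <- sqrt(var_base * (1 / n_i[i] + 1 / n_i[j]))
    z <- unname((mean_ranks[[i]] - mean_ranks[[j]]) / se)
    tibble::tibble(group_a = labels[i], group_b = labels[j], z = z,
                   p_raw = 2 * pnorm(-abs(z)))
  }))
  n_pairs <- ncol(pairs)
  pw$p_adj <- pmin(1, pw$p_raw * n_pairs)
  pw$significant <- pw$p_adj < alpha
  kw <- kruskal_wallis(groups)
  list(h = kw$h, p_value = kw$p_value, n_pairs = n_pairs,
       n_significant = sum(pw$significant), alpha = alpha, pairwise = pw)
}

#' Ordinary least-squares fit reporting the slope and its 95% CI
#'
#' The conversion-factor regressions of the package all go through this
#' single fit: ordinary least squares of `y` on `x`, 95% confidence
#' interval of the slope from the t distribution with `n - 2` residual
#' degrees of freedom (`n - 1` when forced through the origin), and R2 as
#' the share of explained variance. A through-origin mode is provided
#' because conversion-factor usage `dose = CF x DAP_BW` implicitly assumes
#' a zero intercept; the default fits an intercept and reports only the
#' slope as the conversion factor.
#'
#' Dose-area-product distributions are strongly right-skewed and dose
#' residuals grow with DAP, so the classical homoscedastic slope CI can be
#' severely anti-conservative on dose data. `robust = TRUE` switches the CI
#' to heteroscedasticity-consistent sandwich standard errors (HC4, which
#' keeps near-nominal coverage under the high-leverage points such skewed
#' regressors produce); the slope estimate itself is unchanged.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, `x` not constant.
#' @param through_origin Force the intercept to zero.
#' @param robust Use HC4 sandwich standard errors for the slope CI.
#' @return A list: `slope`, `intercept` (`NA` for through-origin),
#'   `r_squared`, `slope_ci_low`, `slope_ci_high`, `n`, `through_origin`,
#'   `robust`.
#' @export
fit_linear <- function(x, y, through_origin = FALSE, robust = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Need at least 3 complete observations")
  if (max(x) - min(x) < .Machine$double.eps * max(1, abs(max(x)))) {
    abort("x is constant; slope undefined")
  }
  fit <- if (through_origin) lm(y ~ x + 0) else lm(y ~ x)
  # noiseless inputs (e.g. ground-truth recovery checks) fit exactly;
  # summary()'s "essentially perfect fit" caution is expected there
  muffle_perfect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  sm <- muffle_perfect(summary(fit))
  if (robust) {
    se <- muffle_perfect(sqrt(sandwich::vcovHC(fit, type = "HC4")["x", "x"]))
    df <- n - if (through_origin) 1 else 2
    tq <- stats::qt(0.975, df)
    b <- unname(coef(fit)[["x"]])
    ci <- matrix(c(b - tq * se, b + tq * se), nrow = 1)
  } else {
    ci <- muffle_perfect(suppressMessages(confint(fit, "x", level = 0.95)))
  }
  r2 <- if (through_origin) {
    # share of variance about the mean explained, comparable across modes
    1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  } else sm$r.squared
  list(
    slope = unname(coef(fit)[["x"]]),
    intercept = if (through_origin) NA_real_ else unname(coef(fit)[[1]]),
    r_squared = r2,
    slope_ci_low = ci[1, 1],
    slope_ci_high = ci[1, 2],
    n = n,
    through_origin = through_origin,
    robust = robust
  )
}

#' Bootstrap dispersion of the median: CI95/med
#'
#' Width of the bootstrap-percentile 95% confidence interval of the median,
#' expressed as a percentage of the sample median. Used to compare how
#' tightly the candidate DRL parameters (DAP, DAP/BW, DAP/(BWxFT)) are
#' determined from the same cohort: a narrower CI95/med means fewer
#' procedures suffice for a stable DRL.
#'
#' @param values Numeric vector, `n >= 8`, median nonzero.
#' @param replicates Bootstrap replicates, default 2000.
#' @param seed Integer seed; resampling is fully determined by it.
#' @return A list: `ci95_over_median` (percent), `median`, `ci_low`,
#'   `ci_high`, `n`, `replicates`, `seed`.
#' @export
ci95_over_median <- function(values, replicates = 2000, seed = 1) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 8) abort("Need at least 8 values for a bootstrap CI of the median")
  med <- median(values)
  if (med == 0) abort("Median is zero; CI95/med undefined")
  boot_medians <- withr::with_seed(seed, {
    vapply(seq_len(replicates),
           function(i) median(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  ci <- quantile(boot_medians, c(0.025, 0.975), names = FALSE)
  list(ci95_over_median = (ci[2] - ci[1]) / med * 100,
       median = med, ci_low = ci[1], ci_high = ci[2],
       n = n, replicates = replicates, seed = seed)
}
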