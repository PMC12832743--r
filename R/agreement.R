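#' Bland-Altman analysis of paired measurements
#'
#' Computes the mean difference (bias) and 95% limits of agreement between
#' two methods measured on the same eyes. Differences are `a - b`
#' (method A minus method B), the SD of the differences uses the n-1
#' denominator, and the limits are `bias +/- 1.96 * sd_diff` (no
#' small-sample t correction).
#'
#' @param a,b Numeric vectors of paired measurements (same length, n >= 2,
#'   all finite).
#' @return An object of class `agreement_result` with fields `n`,
#'   `mean_a`, `sd_a`, `mean_b`, `sd_b`, `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`.
#' @examples
#' bland_altman(c(4, 6), c(3, 5))   # constant offset: bias 1, LoA [1, 1]
#' @export
bland_altman <- function(a, b) {
  check_pairs(a, b, n_min = 2L)
  d <- a - b
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(
    list(n = length(a),
         mean_a = mean(a), sd_a = stats::sd(a),
         mean_b = mean(b), sd_b = stats::sd(b),
         bias = bias, sd_diff = sd_diff,
         loa_low = bias - 1.96 * sd_diff,
         loa_high = bias + 1.96 * sd_diff),
    class = "agreement_result"
  )
}

check_pairs <- function(a, b, n_min) {
  if (length(a) != length(b))
    stop("'a' and 'b' must have the same length")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("paired values must all be finite")
  if (length(a) < n_min)
    stop("at least ", n_min, " pairs are required")
  invisible(TRUE)
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Agreement (n = %d): bias %.4g, 95%% LoA [%.4g, %.4g]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  if (!is.null(x$pearson_r))
    cat(sprintf("  OLS a = %.4g b + %.4g (R^2 %.4g); r %.4g [%.4g, %.4g]\n",
                x$slope, x$intercept, x$r_squared, x$pearson_r,
                x$r_ci_low, x$r_ci_high))
  invisible(x)
}

#' Simple OLS and Pearson correlation with Fisher-z confidence interval
#'
#' Fits the ordinary least-squares regression of method A on method B
#' (`a = slope * b + intercept`) and computes Pearson's r with a
#' `100 * (1 - alpha)%` confidence interval via Fisher's z
#' transformation, `tanh(atanh(r) +/- z / sqrt(n - 3))`. A perfect
#' correlation (`|r| = 1`) yields the degenerate interval `[r, r]`.
#'
#' @inheritParams bland_altman
#' @param alpha Two-sided error rate (default 0.05).
#' @return An `agreement_result` with fields `n`, `slope`, `intercept`,
#'   `r_squared`, `pearson_r`, `r_ci_low`, `r_ci_high`.
#' @export
ols_and_pearson <- function(a, b, alpha = 0.05) {
  check_pairs(a, b, n_min = 4L)
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("zero variance in one of the coordinates")
  fit <- stats::lm(a ~ b)
  r <- stats::cor(a, b)
  n <- length(a)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((a - mean(a))^2)
  if (abs(r) >= 1 - 1e-12) {
    ci <- c(r, r)
  } else {
    z <- atanh(r)
    half <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
    ci <- tanh(c(z - half, z + half))
  }
  structure(
    list(n = n,
         slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2,
         pearson_r = r, r_ci_low = ci[1L], r_ci_high = ci[2L]),
    class = "agreement_result"
  )
}

#' Proportional-bias regression
#'
#' Regresses the paired differences `d = a - b` on the within-pair means
#' `m = (a + b)/2` and tests the slope against zero with a two-sided
#' t-test on n - 2 degrees of freedom. A zero residual variance is
#' resolved exactly: a zero slope gives `t = 0, p = 1`; a non-zero slope
#' with zero residuals gives `p = 0`.
#'
#' @inheritParams bland_altman
#' @return A list with `beta` (slope), `se`, `t`, `p_value`, `intercept`,
#'   `n`.
#' @export
proportional_bias <- function(a, b) {
  check_pairs(a, b, n_min = 4L)
  m <- (a + b) / 2
  d <- a - b
  if (stats::var(m) == 0)
    stop("zero variance in the within-pair means")
  n <- length(a)
  # differences identical up to floating-point rounding: slope exactly 0
  if (stats::sd(d) <= 8 * .Machine$double.eps * max(abs(d), 1)) {
    return(list(beta = 0, se = 0, t = 0, p_value = 1,
                intercept = mean(d), n = n))
  }
  fit <- stats::lm(d ~ m)
  beta <- unname(stats::coef(fit)[2L])
  rss <- sum(stats::residuals(fit)^2)
  se <- sqrt(rss / (n - 2) / sum((m - mean(m))^2))
  if (se == 0) {
    tval <- if (abs(beta) < 1e-15) 0 else sign(beta) * Inf
    p <- if (abs(beta) < 1e-15) 1 else 0
  } else {
    tval <- beta / se
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(beta = beta, se = se, t = tval, p_value = p,
       intercept = unname(stats::coef(fit)[1L]), n = n)
}

#' Shapiro-Wilk normality p-value
#'
#' Thin contract around the Shapiro-Wilk test: returns the p-value for a
#' sample of 3 to 5000 observations. A zero-variance sample returns `NA`
#' with a warning. By reporting convention, `p > 0.05` labels a metric
#' distribution "approximately normal".
#'
#' @param values Numeric vector, `3 <= n <= 5000`.
#' @return The p-value, or `NA` for a degenerate (constant) sample.
#' @export
normality_pvalue <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires between 3 and 5000 observations")
  if (stats::var(values) == 0) {
    warning("constant sample: normality p-value undefined")
    return(NA_real_)
  }
  stats::shapiro.test(values)$p.value
}

#' Paired method comparison for one PLR metric
#'
#' Assembles the eye-matched pairs of session-averaged values for one
#' metric from a long per-eye metrics table and runs the full agreement
#' battery: Bland-Altman bias and limits of agreement, OLS regression of
#' modality A on modality B, Pearson r with Fisher-z CI, and the
#' proportional-bias regression of differences on within-pair means.
#' Differences are `modality_a - modality_b`.
#'
#' @param metrics_table Data frame with columns `eye_id`, `modality`, and
#'   the metric columns `init_mm, end_mm, delta, lat_s, acv_mm_s,
#'   adv_mm_s` (one session-averaged row per eye and modality). If an
#'   `acquisition` column is present (as written by [run_study()]), only
#'   the session-averaged rows (`acquisition == "avg"`) are used.
#' @param metric_name One of `"init", "end", "delta", "lat", "acv",
#'   "adv"`.
#' @param modality_a,modality_b Labels of the two modalities in the table
#'   (defaults `"auto_upa"` and `"ipa"`).
#' @param alpha Two-sided error rate for the Fisher-z CI.
#' @return A one-row data frame with the metric name, n, per-modality
#'   means and SDs, bias, limits of agreement, regression and correlation
#'   fields, and the proportional-bias slope and p-value.
#' @export
compare_modalities <- function(metrics_table, metric_name,
                               modality_a = "auto_upa",
                               modality_b = "ipa", alpha = 0.05) {
  col <- metric_column(metric_name)
  if ("acquisition" %in% names(metrics_table))
    metrics_table <- metrics_table[metrics_table$acquisition == "avg", ]
  ta <- metrics_table[metrics_table$modality == modality_a, ]
  tb <- metrics_table[metrics_table$modality == modality_b, ]
  only_a <- setdiff(ta$eye_id, tb$eye_id)
  only_b <- setdiff(tb$eye_id, ta$eye_id)
  if (length(only_a) || length(only_b))
    stop("unmatched eyes: ",
         paste(unique(c(only_a, only_b)), collapse = ", "))
  if (anyDuplicated(ta$eye_id) || anyDuplicated(tb$eye_id))
    stop("expected one session-averaged row per eye and modality")
  ord <- match(ta$eye_id, tb$eye_id)
  a <- ta[[col]]
  b <- tb[[col]][ord]
  drop <- !is.finite(a) | !is.finite(b)
  if (any(drop)) {
    warning(sum(drop), " eye(s) dropped for metric '", metric_name,
            "' (undefined value)")
    a <- a[!drop]; b <- b[!drop]
  }
  ba <- bland_altman(a, b)
  ols <- ols_and_pearson(a, b, alpha = alpha)
  pb <- proportional_bias(a, b)
  data.frame(
    metric = metric_name, n = ba$n,
    mean_a = ba$mean_a, sd_a = ba$sd_a,
    mean_b = ba$mean_b, sd_b = ba$sd_b,
    bias = ba$bias, sd_diff = ba$sd_diff,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    slope = ols$slope, intercept = ols$intercept,
    r_squared = ols$r_squared, pearson_r = ols$pearson_r,
    r_ci_low = ols$r_ci_low, r_ci_high = ols$r_ci_high,
    prop_bias_slope = pb$beta, prop_bias_p = pb$p_value
  )
}

metric_column <- function(metric_name) {
  cols <- c(init = "init_mm", end = "end_mm", delta = "delta",
            lat = "lat_s", acv = "acv_mm_s", adv = "adv_mm_s")
  if (metric_name %in% names(cols)) return(unname(cols[metric_name]))
  if (metric_name %in% cols) return(metric_name)
  stop("unknown metric '", metric_name, "'")
}
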