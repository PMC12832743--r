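test_that("Bland-Altman bias and limits follow the paired-difference definitions", {
  r0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$bias, 0)
  expect_equal(c(r0$loa_low, r0$loa_high), c(0, 0))
  r1 <- bland_altman(c(4, 6), c(3, 5))      # constant offset
  expect_equal(r1$bias, 1)
  expect_equal(r1$sd_diff, 0)
  expect_equal(c(r1$loa_low, r1$loa_high), c(1, 1))
  expect_error(bland_altman(1, 1), "at least 2")
  expect_error(bland_altman(c(1, NA), c(1, 2)), "finite")
})

test_that("bias always equals the difference of the per-modality means", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    a <- rnorm(n, 4, 0.6); b <- rnorm(n, 4, 0.6)
    r <- bland_altman(a, b)
    expect_equal(r$bias, r$mean_a - r$mean_b, tolerance = 1e-12)
    expect_true(r$loa_low <= r$bias && r$bias <= r$loa_high)
  }
})

test_that("OLS and Pearson handle exact linear relationships", {
  b <- 1:5
  r <- ols_and_pearson(2 * b + 1, b)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)
  expect_equal(r$pearson_r, 1)
  expect_equal(c(r$r_ci_low, r$r_ci_high), c(1, 1))  # degenerate CI
  expect_equal(ols_and_pearson(-b, b)$pearson_r, -1)
  expect_error(ols_and_pearson(rep(1, 5), b), "zero variance")
})

test_that("Fisher-z interval matches direct evaluation of the transform", {
  # frozen oracle: hand-evaluated atanh/tanh expressions for these points
  r <- ols_and_pearson(c(1, 2, 3, 5), c(1, 2, 3, 4))
  expect_equal(r$pearson_r, 0.982707629823991, tolerance = 1e-12)
  expect_equal(r$r_ci_low, 0.389332187170518, tolerance = 1e-12)
  expect_equal(r$r_ci_high, 0.999653943027958, tolerance = 1e-12)
  expect_equal(r$slope, 1.3, tolerance = 1e-12)
  expect_equal(r$intercept, -0.5, tolerance = 1e-12)
  expect_equal(r$r_squared, r$pearson_r^2, tolerance = 1e-9)
})

test_that("squared Pearson r equals OLS R-squared for simple regression", {
  set.seed(5)
  for (i in 1:20) {
    b <- rnorm(10); a <- 0.5 * b + rnorm(10, 0, 0.4)
    r <- ols_and_pearson(a, b)
    expect_equal(r$r_squared, r$pearson_r^2, tolerance = 1e-9)
  }
})

test_that("proportional-bias regression resolves degenerate and exact cases", {
  # constant offset: slope exactly 0, p = 1
  pb <- proportional_bias(c(2, 3, 4, 5) + 0.4, c(2, 3, 4, 5))
  expect_equal(pb$beta, 0)
  expect_equal(pb$p_value, 1)
  # difference proportional to the mean (tiny jitter): p below 1e-6
  b <- c(2, 3, 4, 5, 6)
  a <- 1.2 * b + c(1, -1, 1, -1, 1) * 1e-9
  expect_lt(proportional_bias(a, b)$p_value, 1e-6)
  expect_error(proportional_bias(c(1, 2, 3, 4), rep(2, 4) - c(1, 2, 3, 4)),
               "zero variance")
})

test_that("proportional-bias slope matches the normal-equations oracle", {
  set.seed(40)
  a <- rnorm(40, 4, 0.5); b <- rnorm(40, 4, 0.5)
  pb <- proportional_bias(a, b)
  # explicit normal equations for d ~ 1 + m
  m <- (a + b) / 2; d <- a - b
  X <- cbind(1, m)
  beta_hat <- solve(t(X) %*% X, t(X) %*% d)
  expect_equal(pb$beta, unname(beta_hat[2L, 1L]), tolerance = 1e-10)
  expect_equal(pb$intercept, unname(beta_hat[1L, 1L]), tolerance = 1e-10)
})

test_that("normality screening behaves under the null, the alternative and degeneracy", {
  expect_error(normality_pvalue(c(1, 2)), "between 3 and 5000")
  expect_warning(p <- normality_pvalue(rep(2, 10)), "constant")
  expect_true(is.na(p))
  set.seed(123)
  null_p <- replicate(100, normality_pvalue(rnorm(40)))
  expect_gte(mean(null_p > 0.05), 0.9)
  alt_p <- replicate(100, normality_pvalue(rexp(200)))
  expect_gte(mean(alt_p < 0.05), 0.9)
})

test_that("modality comparison matches eyes, injects and recovers offsets, and rejects bad tables", {
  set.seed(9)
  n <- 10
  tmpl <- data.frame(eye_id = sprintf("E%02d", 1:n),
                     init_mm = rnorm(n, 4, 0.5))
  tmpl$end_mm <- tmpl$init_mm * 0.75
  tmpl$delta <- (tmpl$init_mm - tmpl$end_mm) / tmpl$init_mm
  tmpl$lat_s <- rnorm(n, 0.28, 0.02)
  tmpl$acv_mm_s <- rnorm(n, 1.4, 0.2)
  tmpl$adv_mm_s <- rnorm(n, 0.8, 0.1)
  ta <- cbind(data.frame(modality = "auto_upa"), tmpl)
  tb <- cbind(data.frame(modality = "ipa"), tmpl)
  ta$lat_s <- ta$lat_s + 0.12                    # injected latency offset
  tab <- rbind(ta, tb)
  row <- compare_modalities(tab, "lat")
  expect_equal(row$bias, 0.12, tolerance = 1e-12)
  expect_equal(row$n, n)
  # zero-offset metrics have zero bias and perfect correlation
  expect_equal(compare_modalities(tab, "init")$bias, 0)
  expect_equal(compare_modalities(tab, "init")$pearson_r, 1)
  # unmatched eyes are reported by id
  expect_error(compare_modalities(tab[-1L, ], "init"), "E01")
  # undefined values are dropped with a warning
  tab2 <- tab; tab2$lat_s[1L] <- NA
  expect_warning(row2 <- compare_modalities(tab2, "lat"), "dropped")
  expect_equal(row2$n, n - 1L)
  # a single pair cannot be compared
  one <- tab[tab$eye_id == "E01", ]
  expect_error(compare_modalities(one, "init"), "at least")
})
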