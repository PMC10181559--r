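test_that("difference factor and percentage bias conventions", {
  expect_equal(df_percent(50, 50), 0)
  expect_equal(p_bias(50, 50), 0)
  expect_equal(round(df_percent(81.44, 81.23), 2), 0.26)
  expect_equal(round(df_percent(24.39, 33.37), 2), 36.82)
  expect_equal(round(p_bias(47.94, 52.21), 1), -8.2)
  expect_equal(round(p_bias(48, 55.72), 1), -13.9)
  expect_error(df_percent(0, 10), "nonzero")
  expect_error(p_bias(10, 0), "nonzero")
})

test_that("rmse matches a brute-force elementwise loop", {
  expect_equal(rmse(c(3, 3), c(3, 3)), 0)
  expect_equal(rmse(c(1, 0), c(0, 1)), 1)
  set.seed(20)
  x <- rnorm(40); y <- rnorm(40)
  acc <- 0
  for (i in seq_along(x)) acc <- acc + (x[i] - y[i])^2   # oracle loop
  expect_equal(rmse(x, y), sqrt(acc / 40))
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("Bland-Altman identities hold and labels mirror", {
  same <- bland_altman(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$bias, 0)
  expect_equal(same$loa_high - same$loa_low, 0)

  ba <- bland_altman(c(1, 1), c(2, 0))       # diffs -1, +1
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2))

  set.seed(21)
  x <- rnorm(30, 100, 10); y <- x + rnorm(30, 2, 3)
  f <- bland_altman(x, y); r <- bland_altman(y, x)
  expect_equal(f$loa_low, f$bias - 1.96 * f$sd_diff)
  expect_equal(f$loa_high, f$bias + 1.96 * f$sd_diff)
  expect_lte(f$loa_low, f$bias); expect_lte(f$bias, f$loa_high)
  expect_equal(r$bias, -f$bias)
  expect_equal(r$loa_low, -f$loa_high)
  expect_error(bland_altman(1, 1), ">= 2")
})

test_that("about 95% of Gaussian differences fall inside the LoA", {
  set.seed(22)
  x <- rnorm(10000); y <- x + rnorm(10000, 0.5, 1)
  ba <- bland_altman(x, y)
  inside <- mean(ba$pair_diffs >= ba$loa_low & ba$pair_diffs <= ba$loa_high)
  expect_lte(abs(inside - 0.95), 0.01)
})

test_that("regression recovers exact lines and closed-form OLS", {
  x <- c(1, 2, 3, 4, 5)
  exact <- linreg_r2(x, 2 * x + 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r2, 1)
  expect_equal(linreg_r2(x, rep(4, 5))$r2, 0)

  set.seed(23)
  xr <- rnorm(50); yr <- 1.5 * xr + rnorm(50)
  fit <- linreg_r2(xr, yr)
  # oracle: normal equations
  slope <- sum((xr - mean(xr)) * (yr - mean(yr))) / sum((xr - mean(xr))^2)
  intercept <- mean(yr) - slope * mean(xr)
  expect_equal(fit$slope, slope)
  expect_equal(fit$intercept, intercept)
  r2 <- 1 - sum((yr - intercept - slope * xr)^2) / sum((yr - mean(yr))^2)
  expect_equal(fit$r2, r2)
  expect_error(linreg_r2(rep(1, 5), rnorm(5)), "variance")
})

test_that("paired comparison gates on Shapiro-Wilk normality", {
  x <- c(3, 4, 5, 6)
  expect_true(paired_compare(x, x)$degenerate)

  set.seed(24)
  picks <- vapply(1:1000, function(i) {
    d <- rnorm(30)
    paired_compare(d + 5, rep(5, 30))$test_used
  }, character(1))
  expect_lte(abs(mean(picks == "paired_t") - 0.95), 0.025)

  set.seed(25)
  heavy <- vapply(1:300, function(i) {
    d <- rcauchy(30)
    paired_compare(d, rep(0, 30))$test_used
  }, character(1))
  expect_gt(mean(heavy == "wilcoxon"), 0.5)
})

test_that("Levene gate flags variance heterogeneity at about its level", {
  g <- rep(c("a", "b"), each = 30)
  same <- variance_gate(rep(rnorm(30), 2), g)
  expect_true(same$homogeneous)

  set.seed(26)
  het <- vapply(1:50, function(i)
    variance_gate(c(rnorm(30, 0, 1), rnorm(30, 0, 10)), g)$homogeneous,
    logical(1))
  expect_lte(sum(het), 1)

  hom_rate <- vapply(1:300, function(i)
    variance_gate(c(rnorm(30), rnorm(30)), g)$homogeneous, logical(1))
  expect_lte(abs(mean(hom_rate) - 0.95), 0.04)

  # median-centered variant is the Brown-Forsythe form
  bf <- variance_gate(c(rnorm(30), rnorm(30, 0, 3)), g, center = "median")
  expect_true(is.finite(bf$statistic))
  expect_error(variance_gate(rnorm(4), rep("a", 4)), "2 groups")
})

test_that("SRH reduces to Kruskal-Wallis when one factor is constant", {
  set.seed(27)
  v <- rnorm(45)
  a <- gl(3, 15)
  srh <- scheirer_ray_hare(v, a, rep("only", 45))
  kw <- kruskal.test(v, a)
  expect_equal(unname(srh$H["A"]), unname(kw$statistic), tolerance = 1e-9)
  expect_equal(unname(srh$p_values["A"]), kw$p.value, tolerance = 1e-9)
  # with ties
  vt <- round(v, 0)
  expect_equal(unname(scheirer_ray_hare(vt, a, rep("x", 45))$H["A"]),
               unname(kruskal.test(vt, a)$statistic), tolerance = 1e-9)
})

test_that("SRH handles degenerate and two-factor layouts", {
  a <- gl(2, 8); b <- rep(gl(2, 4), 2)
  expect_equal(unname(scheirer_ray_hare(rep(3, 16), a, b)$H),
               c(0, 0, 0))
  expect_error(scheirer_ray_hare(rnorm(4), rep("a", 4), rep("b", 4)),
               "levels")
  set.seed(28)
  v <- rnorm(36)
  res <- scheirer_ray_hare(v, gl(3, 12), rep(gl(4, 3), 3))
  expect_equal(unname(res$df), c(2, 3, 6))
  expect_true(all(res$H >= 0))
  expect_true(all(res$p_values >= 0 & res$p_values <= 1))
})

test_that("SRH type-I error for the A effect is near nominal", {
  set.seed(29)
  v <- rnorm(36)
  a <- gl(3, 12); b <- rep(gl(4, 3), 3)
  rej <- vapply(1:2000, function(i) {
    r <- scheirer_ray_hare(sample(v), a, b)
    r$p_values["A"] < 0.05
  }, logical(1))
  expect_lte(abs(mean(rej) - 0.05), 0.02)
})

test_that("Dunn's test agrees with the direct two-group z formula", {
  set.seed(30)
  v <- c(rnorm(12), rnorm(15, 1))
  g <- rep(c("a", "b"), c(12, 15))
  dunn <- posthoc_dunn(v, g, adjust = "none")
  # oracle: direct z on joint ranks with tie correction
  r <- rank(v); n <- length(v)
  ties <- table(r)
  z <- (mean(r[g == "a"]) - mean(r[g == "b"])) /
    sqrt((n * (n + 1) / 12 - sum(ties^3 - ties) / (12 * (n - 1))) *
           (1 / 12 + 1 / 15))
  expect_equal(dunn$z["a", "b"], z, ignore_attr = TRUE)
  expect_equal(dunn$p["a", "b"], 2 * pnorm(-abs(z)), ignore_attr = TRUE)

  flat <- posthoc_dunn(rep(c(1, 2, 3), 3), gl(3, 3))
  expect_true(all(flat$p[upper.tri(flat$p)] > 0.99))

  set.seed(31)
  v3 <- c(rnorm(30), rnorm(30), rnorm(30, 5))
  g3 <- gl(3, 30, labels = c("a", "b", "shift"))
  d3 <- posthoc_dunn(v3, g3)        # Holm by default
  expect_lt(d3$p["a", "shift"], 0.001)
  expect_lt(d3$p["b", "shift"], 0.001)
})

test_that("agreement report on an exact cohort is all-zero error", {
  coh <- synthetic_cohort(n_subjects = 12, bias = 0, noise_sd = 0)
  coh$ppg_value <- coh$ecg_value
  rep_ <- build_agreement_report(coh)
  tab <- agreement_table(rep_)
  expect_equal(tab$df_pct, rep(0, nrow(tab)))
  expect_equal(tab$p_bias, rep(0, nrow(tab)))
  expect_equal(tab$rmse, rep(0, nrow(tab)))
  expect_equal(tab$r2, rep(1, nrow(tab)))
})

test_that("agreement report recovers a known device bias", {
  coh <- synthetic_cohort(n_subjects = 30, bias = 4, noise_sd = 1,
                          seed = 33)
  rep_ <- build_agreement_report(coh)
  for (cl in rep_$cells) {
    ci <- cl$bland_altman$bias +
      c(-1, 1) * 3 * cl$bland_altman$sd_diff / sqrt(cl$n)
    expect_true(ci[1] <= 4 && 4 <= ci[2],
                info = sprintf("%s/%s bias CI", cl$scenario, cl$indicator))
  }
  expect_false(is.null(rep_$omnibus))
})

test_that("single-indicator cohorts restrict the report structurally", {
  coh <- synthetic_cohort(indicators = "HR")
  rep_ <- build_agreement_report(coh)
  expect_true(all(vapply(rep_$cells, function(cl) cl$indicator == "HR",
                         logical(1))))
  expect_null(rep_$omnibus)   # needs >= 2 indicator levels
  expect_error(build_agreement_report(rbind(coh, coh[1, ])), "one row")
})
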