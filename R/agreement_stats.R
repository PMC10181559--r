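#' Difference factor between device means
#'
#' `DF% = 100 * |ecg_mean - ppg_mean| / ecg_mean`: the relative absolute
#' difference between the reference (ECG) and test (PPG) cohort means,
#' normalized by the reference mean.
#'
#' @param ecg_mean,ppg_mean cohort means of the indicator per device.
#' @return difference factor in percent (vectorized).
#' @export
df_percent <- function(ecg_mean, ppg_mean) {
  if (any(ecg_mean == 0)) stop("`ecg_mean` must be nonzero")
  100 * abs(ecg_mean - ppg_mean) / ecg_mean
}

#' Percentage bias between device means
#'
#' `P bias = 100 * (ecg_mean - ppg_mean) / ppg_mean`: signed relative
#' difference normalized by the test-device (PPG) mean. Negative values
#' mean the PPG overestimates the reference.
#'
#' @param ecg_mean,ppg_mean cohort means of the indicator per device.
#' @return percentage bias (vectorized).
#' @export
p_bias <- function(ecg_mean, ppg_mean) {
  if (any(ppg_mean == 0)) stop("`ppg_mean` must be nonzero")
  100 * (ecg_mean - ppg_mean) / ppg_mean
}

#' Root mean square error of paired values
#'
#' @param x,y paired numeric vectors (e.g. ECG- and PPG-derived values).
#' @return `sqrt(mean((x - y)^2))`.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y) || !length(x))
    stop("`x` and `y` must be non-empty and of equal length")
  sqrt(mean((x - y)^2))
}

#' Bland-Altman agreement analysis
#'
#' Computes the bias (mean of pairwise differences `x - y`) and the
#' 95% limits of agreement `bias +/- 1.96 * sd(diffs)` (SD with `N - 1`).
#'
#' @param x,y paired numeric vectors; >= 2 pairs.
#' @return an object of class `bland_altman`: `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `pair_means`, `pair_diffs`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 2L) stop("need >= 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s,
                 pair_means = (x + y) / 2, pair_diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.3f, 95%% LoA [%.3f, %.3f] (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, length(x$pair_diffs)))
  invisible(x)
}

#' Ordinary least squares of test-device on reference values
#'
#' Fits `ppg ~ ecg` by OLS and reports slope, intercept and the
#' coefficient of determination `R^2 = 1 - SSres/SStot`.
#'
#' @param x reference (ECG) values; must have nonzero variance.
#' @param y test (PPG) values.
#' @return list with `slope`, `intercept`, `r2`.
#' @export
linreg_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 pairs of equal length")
  if (stats::var(x) == 0) stop("`x` has zero variance; regression degenerate")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]), r2 = r2)
}

#' Normality-gated paired comparison
#'
#' Shapiro-Wilk on the paired differences decides the test: `p > alpha`
#' selects the paired t-test, otherwise the Wilcoxon signed-rank test
#' (zero differences dropped; exact p for fewer than 25 nonzero
#' differences, normal approximation with continuity correction
#' otherwise). All-zero differences yield a degenerate result with no
#' test.
#'
#' @param x,y paired numeric vectors; >= 3 pairs.
#' @param alpha normality gate level, default 0.05.
#' @return list with `normality_p`, `test_used` (`"paired_t"`,
#'   `"wilcoxon"` or `"none"`), `statistic`, `p_value`, `degenerate`.
#' @export
paired_compare <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 pairs of equal length")
  d <- x - y
  if (all(d == 0))
    return(list(normality_p = NA_real_, test_used = "none",
                statistic = NA_real_, p_value = NA_real_,
                degenerate = TRUE))
  sw_p <- if (stats::sd(d) == 0) NA_real_ else stats::shapiro.test(d)$p.value
  if (!is.na(sw_p) && sw_p > alpha) {
    tt <- stats::t.test(x, y, paired = TRUE)
    list(normality_p = sw_p, test_used = "paired_t",
         statistic = unname(tt$statistic), p_value = tt$p.value,
         degenerate = FALSE)
  } else {
    n_nonzero <- sum(d != 0)
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = n_nonzero < 25,
                         correct = TRUE))
    list(normality_p = sw_p, test_used = "wilcoxon",
         statistic = unname(wt$statistic), p_value = wt$p.value,
         degenerate = FALSE)
  }
}

#' Levene's test for homogeneity of variance
#'
#' Classical Levene statistic: one-way ANOVA F on the absolute deviations
#' of each value from its group center (mean by default; the
#' median-centered Brown-Forsythe variant via `center = "median"`).
#' Homogeneity is declared when `p > alpha`.
#'
#' @param values numeric vector.
#' @param groups grouping factor (>= 2 groups, each >= 2 values).
#' @param center `"mean"` (default) or `"median"`.
#' @param alpha gate level, default 0.05.
#' @return list with `statistic`, `levene_p`, `homogeneous`, `df`.
#' @export
variance_gate <- function(values, groups, center = c("mean", "median"),
                          alpha = 0.05) {
  center <- match.arg(center)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need >= 2 groups")
  groups <- droplevels(groups)
  if (any(tabulate(groups) < 2L)) stop("each group needs >= 2 values")
  cfun <- if (center == "mean") mean else stats::median
  z <- abs(values - stats::ave(values, groups, FUN = cfun))
  k <- nlevels(groups)
  n <- length(z)
  zbar <- mean(z)
  zg <- tapply(z, groups, mean)
  ng <- tabulate(groups)
  ssb <- sum(ng * (zg - zbar)^2)
  ssw <- sum((z - stats::ave(z, groups, FUN = mean))^2)
  if (ssw == 0 && ssb == 0) {        # all deviations identical
    f <- 0; p <- 1
  } else {
    f <- (ssb / (k - 1)) / (ssw / (n - k))
    p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  }
  list(statistic = f, levene_p = p, homogeneous = p > alpha,
       df = c(k - 1, n - k))
}

# Tie-correction divisor for rank statistics: 1 - sum(t^3 - t)/(n^3 - n).
tie_divisor <- function(r) {
  n <- length(r)
  t <- table(r)
  1 - sum(t^3 - t) / (n^3 - n)
}

#' Scheirer-Ray-Hare rank-based two-way ANOVA
#'
#' Nonparametric analogue of the two-way fixed-effects ANOVA with
#' interaction: all values are jointly ranked (midranks for ties), the
#' classical sum-of-squares decomposition is applied to the ranks, and
#' each effect's statistic `H = SS_effect / MS_total`
#' (`MS_total = SS_total / (n - 1)`) is referred to a chi-square
#' distribution with the effect's degrees of freedom. Computing
#' `MS_total` from the midrank sum of squares applies the standard tie
#' correction `1 - sum(t^3 - t)/(n^3 - n)` implicitly (the midrank
#' `SS_total` equals the untied value times that divisor). When one
#' factor has a single level the other factor's `H` equals the
#' Kruskal-Wallis statistic, ties included.
#'
#' @param values numeric response.
#' @param factor_a,factor_b crossed factors; >= 2 levels each (a
#'   single-level factor is tolerated only so far as its own effect is
#'   dropped — both single-level is an error).
#' @return list with components `H` (named vector: A, B, interaction),
#'   `df`, `p_values`, and the rank `ss` decomposition.
#' @export
scheirer_ray_hare <- function(values, factor_a, factor_b) {
  a <- droplevels(as.factor(factor_a))
  b <- droplevels(as.factor(factor_b))
  n <- length(values)
  if (length(a) != n || length(b) != n)
    stop("`values`, `factor_a`, `factor_b` must have equal length")
  if (nlevels(a) < 2L && nlevels(b) < 2L)
    stop("at least one factor must have >= 2 levels")
  r <- rank(values)
  grand <- mean(r)
  ss_total <- sum((r - grand)^2)
  ms_total <- ss_total / (n - 1)
  grp_ss <- function(f) {
    m <- tapply(r, f, mean)
    cnt <- tabulate(f)
    sum(cnt * (m[levels(f)] - grand)^2)
  }
  ss_a <- if (nlevels(a) >= 2L) grp_ss(a) else 0
  ss_b <- if (nlevels(b) >= 2L) grp_ss(b) else 0
  cells <- interaction(a, b, drop = TRUE)
  ss_cells <- grp_ss(cells)
  ss_ab <- max(0, ss_cells - ss_a - ss_b)
  D <- tie_divisor(r)
  if (ms_total == 0) {
    H <- c(A = 0, B = 0, interaction = 0)
  } else {
    # midrank SS_total already carries the tie correction:
    # SS_total = D * (n^3 - n) / 12
    H <- c(A = ss_a, B = ss_b, interaction = ss_ab) / ms_total
  }
  df <- c(A = nlevels(a) - 1L, B = nlevels(b) - 1L,
          interaction = (nlevels(a) - 1L) * (nlevels(b) - 1L))
  p <- ifelse(df > 0,
              stats::pchisq(H, pmax(df, 1L), lower.tail = FALSE),
              NA_real_)
  names(p) <- names(df)
  list(H = H, df = df, p_values = p,
       ss = c(A = ss_a, B = ss_b, interaction = ss_ab, total = ss_total),
       tie_correction = D)
}

#' Dunn's post hoc pairwise rank comparisons
#'
#' Pairwise z statistics on the joint midranks with tie correction:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t) / (12 (N - 1))`. Two-sided p-values with
#' optional Holm adjustment (default).
#'
#' @param values numeric vector.
#' @param groups grouping factor (>= 2 groups).
#' @param adjust `"holm"` (default) or `"none"`.
#' @return list with `z` and `p` (symmetric matrices, `NA` diagonal) and
#'   `mean_ranks`.
#' @export
posthoc_dunn <- function(values, groups, adjust = c("holm", "none")) {
  adjust <- match.arg(adjust)
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  n <- length(values)
  r <- rank(values)
  rb <- tapply(r, g, mean)
  cnt <- tabulate(g)
  names(cnt) <- levels(g)
  ties <- table(r)
  Tcorr <- sum(ties^3 - ties) / (12 * (n - 1))
  k <- nlevels(g)
  z <- matrix(NA_real_, k, k, dimnames = list(levels(g), levels(g)))
  p <- z
  pairs <- utils::combn(k, 2L)
  praw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    se <- sqrt((n * (n + 1) / 12 - Tcorr) *
                 (1 / cnt[i1] + 1 / cnt[i2]))
    zij <- (rb[i1] - rb[i2]) / se
    z[i1, i2] <- z[i2, i1] <- zij
    praw[j] <- 2 * stats::pnorm(-abs(zij))
  }
  padj <- if (adjust == "holm") stats::p.adjust(praw, "holm") else praw
  padj <- pmin(padj, 1)
  for (j in seq_len(ncol(pairs))) {
    p[pairs[1L, j], pairs[2L, j]] <- padj[j]
    p[pairs[2L, j], pairs[1L, j]] <- padj[j]
  }
  list(z = z, p = p, mean_ranks = rb)
}

#' Full device-agreement workflow on a paired cohort
#'
#' Reproduces the cohort-level agreement analysis for paired
#' (ECG-derived, PPG-derived) indicator values across scenarios:
#' per-cell descriptive rows (means, SDs, difference, RMSE, P bias, DF%),
#' normality-gated paired tests and Bland-Altman / regression per cell,
#' then — on the per-subject relative differences
#' `100 (ecg - ppg) / ecg` — a Levene gate per indicator deciding
#' between parametric two-way ANOVA (with Tukey post hoc) and the
#' Scheirer-Ray-Hare test (with Dunn post hoc) for the scenario and
#' indicator effects and their interaction.
#'
#' @param cohort data frame with columns `subject_id`, `scenario`,
#'   `indicator`, `ecg_value`, `ppg_value`; one row per
#'   subject x scenario x indicator.
#' @param alpha gate level for normality/homogeneity decisions.
#' @return an object of class `agreement_report`.
#' @export
build_agreement_report <- function(cohort, alpha = 0.05) {
  need <- c("subject_id", "scenario", "indicator", "ecg_value", "ppg_value")
  if (!all(need %in% names(cohort)))
    stop("cohort must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(cohort$ecg_value)) || any(!is.finite(cohort$ppg_value)))
    stop("ecg/ppg values must be finite")
  key <- interaction(cohort$subject_id, cohort$scenario, cohort$indicator)
  if (anyDuplicated(key))
    stop("cohort must have one row per subject x scenario x indicator")
  cohort$scenario <- as.factor(cohort$scenario)
  cohort$indicator <- as.factor(cohort$indicator)

  warnings <- character(0)
  cells <- list()
  for (sc in levels(cohort$scenario)) {
    for (ind in levels(cohort$indicator)) {
      sub <- cohort[cohort$scenario == sc & cohort$indicator == ind, ]
      if (!nrow(sub)) next
      e <- sub$ecg_value; p <- sub$ppg_value
      row <- list(scenario = sc, indicator = ind, n = nrow(sub),
                  ecg_mean = mean(e), ecg_sd = stats::sd(e),
                  ppg_mean = mean(p), ppg_sd = stats::sd(p),
                  diff_mean = mean(e - p), diff_sd = stats::sd(e - p),
                  rmse = rmse(e, p),
                  p_bias = if (mean(p) != 0) p_bias(mean(e), mean(p)) else NA_real_,
                  df_pct = if (mean(e) != 0) df_percent(mean(e), mean(p)) else NA_real_)
      row$paired_test <- if (nrow(sub) >= 3L) {
        tryCatch(paired_compare(e, p, alpha = alpha), error = function(err) {
          warnings <<- c(warnings, sprintf("%s/%s paired test skipped: %s",
                                           sc, ind, conditionMessage(err)))
          NULL
        })
      } else NULL
      row$bland_altman <- if (nrow(sub) >= 2L) bland_altman(e, p) else NULL
      row$regression <- if (nrow(sub) >= 3L && stats::var(e) > 0) {
        tryCatch(linreg_r2(e, p), error = function(err) {
          warnings <<- c(warnings, sprintf("%s/%s regression skipped: %s",
                                           sc, ind, conditionMessage(err)))
          NULL
        })
      } else NULL
      cells[[paste(sc, ind, sep = ".")]] <- row
    }
  }

  # cross-cell analysis on the per-subject relative differences
  rel <- cohort[cohort$ecg_value != 0, ]
  rel$rel_diff <- 100 * (rel$ecg_value - rel$ppg_value) / rel$ecg_value
  gates <- list()
  omnibus <- NULL
  posthoc <- NULL
  if (nlevels(droplevels(rel$scenario)) >= 2L &&
      nlevels(droplevels(rel$indicator)) >= 2L) {
    for (ind in levels(droplevels(rel$indicator))) {
      sub <- rel[rel$indicator == ind, ]
      gates[[ind]] <- tryCatch(
        variance_gate(sub$rel_diff, sub$scenario, alpha = alpha),
        error = function(err) {
          warnings <<- c(warnings,
                         sprintf("Levene gate skipped for %s: %s", ind,
                                 conditionMessage(err)))
          NULL
        })
    }
    homo <- vapply(gates, function(g) isTRUE(g$homogeneous), logical(1))
    all_homogeneous <- length(homo) > 0 && all(homo)
    if (all_homogeneous) {
      fit <- stats::aov(rel_diff ~ scenario * indicator, data = rel)
      omnibus <- list(method = "two_way_anova",
                      table = summary(fit)[[1L]])
      posthoc <- list(method = "tukey", result = stats::TukeyHSD(fit))
    } else {
      srh <- scheirer_ray_hare(rel$rel_diff, rel$scenario, rel$indicator)
      omnibus <- list(method = "scheirer_ray_hare", result = srh)
      posthoc <- list(
        method = "dunn",
        scenario = posthoc_dunn(rel$rel_diff, rel$scenario),
        indicator = posthoc_dunn(rel$rel_diff, rel$indicator))
    }
    attr(omnibus, "all_homogeneous") <- all_homogeneous
  }

  structure(list(cells = cells, variance_gates = gates, omnibus = omnibus,
                 posthoc = posthoc, warnings = warnings, alpha = alpha),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d scenario x indicator cells\n",
              length(x$cells)))
  tab <- agreement_table(x)
  print(tab, digits = 4)
  if (!is.null(x$omnibus))
    cat("omnibus method:", x$omnibus$method, "\n")
  if (length(x$warnings))
    cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Flatten an agreement report into a descriptive table
#'
#' One row per scenario x indicator cell, mirroring the column order of
#' the study's descriptive tables (ECG mean/SD, PPG mean/SD, difference
#' mean/SD, RMSE, P bias, DF%).
#'
#' @param report an `agreement_report`.
#' @return a `data.frame`.
#' @export
agreement_table <- function(report) {
  stopifnot(inherits(report, "agreement_report"))
  rows <- lapply(report$cells, function(cl)
    data.frame(scenario = cl$scenario, indicator = cl$indicator, n = cl$n,
               ecg_mean = cl$ecg_mean, ecg_sd = cl$ecg_sd,
               ppg_mean = cl$ppg_mean, ppg_sd = cl$ppg_sd,
               diff_mean = cl$diff_mean, diff_sd = cl$diff_sd,
               rmse = cl$rmse, p_bias = cl$p_bias, df_pct = cl$df_pct,
               r2 = if (is.null(cl$regression)) NA_real_ else cl$regression$r2,
               test_used = if (is.null(cl$paired_test)) NA_character_ else
                 cl$paired_test$test_used,
               test_p = if (is.null(cl$paired_test)) NA_real_ else
                 cl$paired_test$p_value))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
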