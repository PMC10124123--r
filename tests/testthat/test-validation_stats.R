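# validation statistics: CFU arithmetic, log conversion, differences,
# regression, t-test, ANOVA, consistency checking

test_that("CFU back-calculation matches the one-line oracle", {
  p <- plate_count("s1", -5, 0.1, 100)
  expect_equal(cfu_per_ml(p)$cfu_per_ml, 100 / (0.1 * 1e-5))
  expect_equal(cfu_per_ml(p)$cfu_per_ml, 1e8)
  p2 <- plate_count("s2", -6, 1, 50)
  expect_equal(cfu_per_ml(p2)$cfu_per_ml, 5e7)
  z <- cfu_per_ml(plate_count("s3", -4, 0.1, 0))
  expect_equal(z$cfu_per_ml, 0)
  expect_equal(z$flag, "below_detection")
  expect_equal(cfu_per_ml(plate_count("s4", -5, 0.1, 300))$flag,
               "above_countable")
})

test_that("select_countable keeps the countable level with tie-breaks", {
  mk <- function(expo, cols) do.call(rbind, lapply(seq_along(expo),
    function(i) plate_count("s", expo[i], 0.1, cols[i])))
  # means {1200, 130, 11}: only 130 in 25-250
  pl <- mk(c(-4, -4, -5, -5, -6, -6), c(1150, 1250, 120, 140, 10, 12))
  sel <- select_countable(pl)
  expect_true(all(sel$dilution_exponent == -5))
  expect_identical(attr(sel, "selection_flag"), "")
  # both in range: higher-count (less dilute) level wins
  pl2 <- mk(c(-4, -5), c(200, 30))
  expect_true(all(select_countable(pl2)$dilution_exponent == -4))
  # all zero: least dilute level, flagged
  pl3 <- mk(c(-4, -5, -6), c(0, 0, 0))
  sel3 <- select_countable(pl3)
  expect_true(all(sel3$dilution_exponent == -4))
  expect_identical(attr(sel3, "selection_flag"), "no_countable_level")
})

test_that("log10 conversion flags non-positive input", {
  expect_equal(log10_concentration(1e8), 8)
  expect_equal(log10_concentration(3.55e8), log10(3.55) + 8)
  expect_warning(v <- log10_concentration(0))
  expect_true(is.na(v))
})

test_that("method difference reproduces published rows at 2 decimals", {
  # replicate lists constructed to carry the printed means exactly
  mk <- function(m) c(m - 0.01, m + 0.01)
  d1 <- method_difference(mk(9.65), mk(9.71))
  expect_equal(d1$difference, -0.06)
  d2 <- method_difference(mk(7.17), mk(7.67))
  expect_equal(d2$difference, -0.50)
  expect_equal(method_difference(mk(8), mk(8))$difference, 0)
})

test_that("percent difference is symmetric with mean denominator", {
  expect_equal(percent_difference(100, 100), 0)
  expect_equal(percent_difference(90, 110), 20)
  expect_equal(percent_difference(110, 90), percent_difference(90, 110))
  expect_error(percent_difference(-1, 5))
})

test_that("titration regression matches a normal-equations oracle", {
  expect_equal(titration_regression(1:5, 2 * (1:5))$r_squared, 1)
  expect_equal(titration_regression(1:5, 2 * (1:5))$slope, 2)
  expect_equal(titration_regression(1:5, rep(3, 5))$r_squared, 0)
  set.seed(4)
  x <- c(0.1, 0.25, 0.5, 0.75, 1, 0.1, 0.5, 1)
  y <- 3e8 * x + rnorm(8, 0, 2e7)
  fit <- titration_regression(x, y)
  # independent normal-equations solve
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  expect_equal(fit$r_squared, r2, tolerance = 1e-10)
  expect_error(titration_regression(c(1, 1, 1), c(1, 2, 3)),
               class = "mixcount_degenerate_design")
  expect_error(titration_regression(c(1, 2), c(1, 2)),
               class = "mixcount_domain_error")
})

test_that("Welch t-test agrees with the hand-computed statistic", {
  a <- c(9.61, 9.68, 9.66, 9.63)
  b <- c(9.91, 9.75, 9.82, 9.88, 9.79)
  tt <- two_sample_t(a, b)
  # hand computation of Welch t and df
  se2 <- var(a) / length(a) + var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((var(a) / length(a))^2 / (length(a) - 1) +
                   (var(b) / length(b))^2 / (length(b) - 1))
  expect_equal(tt$statistic, tstat, tolerance = 1e-6)
  expect_equal(tt$df, df, tolerance = 1e-6)
  expect_equal(tt$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-6)
  # identical samples -> p = 1; huge separation -> p ~ 0
  expect_equal(two_sample_t(a, a)$p_value, 1)
  expect_lt(two_sample_t(rnorm(5, 0, 1e-4), rnorm(5, 100, 1e-4))$p_value,
            1e-6)
})

test_that("method ANOVA matches a manual sums-of-squares decomposition", {
  a <- c(9.65, 9.65, 9.80)  # manual means per trial
  b <- c(9.71, 9.74, 9.77)  # cytometry means per trial
  an <- method_anova(a, b)
  grand <- mean(c(a, b))
  ssb <- 3 * (mean(a) - grand)^2 + 3 * (mean(b) - grand)^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  f <- ssb / (ssw / 4)
  expect_equal(an$F, f, tolerance = 1e-9)
  expect_equal(an$df1, 1L)
  expect_equal(an$df2, 4L)  # 2(T-1) for T = 3 trials
  expect_equal(an$p_value, pf(f, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # cross-check against lm on the same layout
  y <- c(a, b); g <- factor(rep(c("m", "c"), each = 3))
  expect_equal(an$p_value, anova(lm(y ~ g))$`Pr(>F)`[1], tolerance = 1e-12)
  # identical method means -> F = 0, p = 1
  expect_equal(method_anova(a, a)$F, 0)
  expect_equal(method_anova(a, a)$p_value, 1)
  expect_error(method_anova(9.5, 9.6),
               class = "mixcount_insufficient_replication")
  # blocked replicate-level variant runs and agrees qualitatively
  man <- matrix(c(a, a + 0.02), 3)
  cyt <- matrix(c(b, b - 0.01), 3)
  ab <- method_anova(man, cyt, blocked = TRUE)
  expect_true(ab$p_value > 0 && ab$p_value <= 1)
})

test_that("consistency checker flags exactly the inconsistent rows", {
  tabs <- reference_comparison_tables()
  for (nm in c("titration", "ratio_mixture", "fermentation"))
    expect_true(all(check_table_consistency(tabs[[nm]])$consistent),
                info = nm)
  cm <- check_table_consistency(tabs$constant_mixture)
  expect_equal(sum(!cm$consistent), 5L)
  bad <- cm[!cm$consistent, c("experiment", "organism", "trial")]
  expect_true(all(paste(bad$experiment, bad$organism, bad$trial) %in%
                    c("yeast_constant bacteria 2", "yeast_constant yeast 3",
                      "bacteria_constant bacteria 3",
                      "bacteria_constant yeast 1",
                      "bacteria_constant yeast 3")))
})

test_that("plate simulation plus back-calculation recovers the truth", {
  ests <- vapply(1:500, function(s) {
    pl <- simulate_plate_counts(1e8, -5, 0.1, 3, seed = s)
    mean(cfu_per_ml(pl)$cfu_per_ml)
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 1e8), 3 * se)
})
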