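# The statistical comparison layer: CFU back-calculation, log-scale
# conversion, difference tables, percent difference, titration regression,
# Welch t-tests and the method-comparison ANOVA.

#' Plate-count record
#'
#' @param sample_id sample label.
#' @param dilution_exponent integer <= 0 (e.g. -5 for a 10^-5 dilution).
#' @param plated_volume_ml plated volume, mL (> 0).
#' @param colonies colony count (integer >= 0).
#' @param medium `"APDA"` (yeast) or `"MRS"` (bacteria).
#' @return One-row data.frame of class `plate_count`.
#' @export
plate_count <- function(sample_id, dilution_exponent, plated_volume_ml,
                        colonies, medium = c("MRS", "APDA")) {
  medium <- match.arg(medium)
  stopifnot(dilution_exponent <= 0,
            dilution_exponent == round(dilution_exponent),
            plated_volume_ml > 0, colonies >= 0, colonies == round(colonies))
  structure(data.frame(sample_id = sample_id,
                       dilution_exponent = as.integer(dilution_exponent),
                       plated_volume_ml = plated_volume_ml,
                       colonies = as.integer(colonies), medium = medium,
                       stringsAsFactors = FALSE),
            class = c("plate_count", "data.frame"))
}

# artifact-convention countable ranges per medium (configurable everywhere)
default_countable_range <- function(medium) {
  if (identical(medium, "APDA")) c(8, 80) else c(25, 250)
}

#' Back-calculate CFU/mL from a plate
#'
#' `CFU/mL = colonies / (plated_volume * 10^dilution_exponent)`.  Plates
#' whose colony count falls outside the countable range are flagged (column
#' `flag`), not rejected; zero-colony plates are flagged `below_detection`.
#'
#' @param plates data.frame with `colonies`, `dilution_exponent`,
#'   `plated_volume_ml` and optionally `medium`.
#' @param countable_range length-2 numeric, or `NULL` for the per-medium
#'   default (25-250 for MRS, 8-80 for APDA spread plates).
#' @return `plates` with `cfu_per_ml` and `flag` columns added.
#' @export
cfu_per_ml <- function(plates, countable_range = NULL) {
  stopifnot(is.data.frame(plates),
            all(c("colonies", "dilution_exponent", "plated_volume_ml") %in%
                  names(plates)))
  out <- as.data.frame(plates)
  out$cfu_per_ml <- out$colonies /
    (out$plated_volume_ml * 10^out$dilution_exponent)
  rng <- function(i) countable_range %||%
    default_countable_range(out$medium[i] %||% "MRS")
  out$flag <- vapply(seq_len(nrow(out)), function(i) {
    r <- rng(i)
    if (out$colonies[i] == 0) "below_detection"
    else if (out$colonies[i] < r[1]) "below_countable"
    else if (out$colonies[i] > r[2]) "above_countable"
    else ""
  }, character(1))
  out
}

#' Select the most countable dilution level
#'
#' Keeps the dilution level whose mean colony count falls inside the
#' countable range; when several qualify the higher-count (less dilute)
#' level wins.  If no level is countable, the level closest to the range is
#' returned, flagged `"no_countable_level"`.
#'
#' @inheritParams cfu_per_ml
#' @return The subset of `plates` at the selected level, with attribute
#'   `selection_flag` (`""` or `"no_countable_level"`).
#' @export
select_countable <- function(plates, countable_range = NULL) {
  stopifnot(is.data.frame(plates), nrow(plates) >= 1)
  rng <- countable_range %||%
    default_countable_range(plates$medium[1] %||% "MRS")
  levels_ <- sort(unique(plates$dilution_exponent))
  means <- vapply(levels_, function(e)
    mean(plates$colonies[plates$dilution_exponent == e]), numeric(1))
  inrange <- means >= rng[1] & means <= rng[2]
  flag <- ""
  if (any(inrange)) {
    cand <- levels_[inrange]
    pick <- cand[which.max(means[match(cand, levels_)])]
  } else {
    dist <- pmax(rng[1] - means, means - rng[2], 0)
    cand <- levels_[dist == min(dist)]
    cm <- means[match(cand, levels_)]
    cand <- cand[cm == max(cm)]
    pick <- max(cand)  # remaining tie (e.g. all zero): least dilute level
    flag <- "no_countable_level"
  }
  out <- plates[plates$dilution_exponent == pick, , drop = FALSE]
  attr(out, "selection_flag") <- flag
  out
}

#' Base-10 log of a concentration
#'
#' @param conc concentration(s), per mL.  Non-positive values yield `NA`
#'   with a warning (absent, flagged).
#' @return `log10(conc)`.
#' @export
log10_concentration <- function(conc) {
  bad <- !is.na(conc) & conc <= 0
  if (any(bad)) warning("non-positive concentration(s); log10 undefined")
  out <- ifelse(bad, NA_real_, log10(conc))
  out
}

#' Per-method log means and their difference
#'
#' `difference = mean(manual) - mean(cytometry)`, reported at two decimals
#' alongside each method's mean and sd.  The difference is always
#' recomputed from the means, never trusted from input.
#'
#' @param manual_logs,cyto_logs replicate log10 concentrations (non-empty).
#' @return List with `manual_mean`, `manual_sd`, `cyto_mean`, `cyto_sd`,
#'   `difference` (2 dp) and `difference_raw`.
#' @export
method_difference <- function(manual_logs, cyto_logs) {
  stopifnot(length(manual_logs) >= 1, length(cyto_logs) >= 1)
  m <- mean(manual_logs); cy <- mean(cyto_logs)
  list(manual_mean = m, manual_sd = sd(manual_logs),
       cyto_mean = cy, cyto_sd = sd(cyto_logs),
       difference = round(m - cy, 2), difference_raw = m - cy)
}

#' Symmetric percent difference
#'
#' `100 * |a - b| / mean(a, b)`; order-invariant.
#'
#' @param a,b positive concentrations.
#' @return Percent difference.
#' @export
percent_difference <- function(a, b) {
  stopifnot(a > 0, b > 0)
  100 * abs(a - b) / mean(c(a, b))
}

#' Titration linearity regression
#'
#' Ordinary least squares of measured concentration on dilution fraction;
#' `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param dilution_fractions,concentrations paired numeric vectors, >= 3
#'   points with >= 2 distinct x (a constant x is a degenerate design
#'   error).
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
titration_regression <- function(dilution_fractions, concentrations) {
  x <- dilution_fractions; y <- concentrations
  stopifnot(length(x) == length(y))
  if (length(x) < 3)
    stop_mixcount("need at least 3 points", class = "mixcount_domain_error")
  if (length(unique(x)) < 2)
    stop_mixcount("constant dilution fraction: degenerate design",
                  class = "mixcount_degenerate_design")
  fit <- lm(y ~ x)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 0)
}

#' Two-sample t-test p-value
#'
#' Welch (unequal variance) by default; pooled optional.  Two-sided.
#'
#' @param a,b samples (each n >= 2).
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
two_sample_t <- function(a, b, var_equal = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b))
    return(list(statistic = 0, df = length(a) + length(b) - 2, p_value = 1))
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Method-comparison one-way ANOVA
#'
#' One-way ANOVA with counting method as the factor and per-trial means as
#' replicates: for T trials the F statistic has (1, 2(T-1)) degrees of
#' freedom.  This is the simplest model consistent with comparing the
#' average results of each experiment between methods.  A replicate-level
#' two-way layout with a trial block is available via `blocked = TRUE`
#' (then supply matrices with one row per trial and one column per
#' replicate).
#'
#' @param manual_means,cyto_means per-trial mean log10 concentrations
#'   (length T >= 2), or matrices of replicate values when
#'   `blocked = TRUE`.
#' @param blocked use the replicate-level two-way (method + trial block)
#'   model.
#' @return List with `F`, `df1`, `df2`, `p_value`.
#' @export
method_anova <- function(manual_means, cyto_means, blocked = FALSE) {
  if (blocked) {
    stopifnot(is.matrix(manual_means), is.matrix(cyto_means),
              nrow(manual_means) == nrow(cyto_means))
    y <- c(as.vector(manual_means), as.vector(cyto_means))
    method <- factor(rep(c("manual", "cyto"),
                         c(length(manual_means), length(cyto_means))))
    trial <- factor(c(rep(seq_len(nrow(manual_means)),
                          ncol(manual_means)),
                      rep(seq_len(nrow(cyto_means)), ncol(cyto_means))))
    fit <- stats::aov(y ~ trial + method)
    tab <- summary(fit)[[1]]
    i <- trimws(rownames(tab)) == "method"
    return(list(F = tab$`F value`[i], df1 = tab$Df[i],
                df2 = tab$Df[trimws(rownames(tab)) == "Residuals"],
                p_value = tab$`Pr(>F)`[i]))
  }
  a <- manual_means; b <- cyto_means
  if (length(a) < 2 || length(b) < 2)
    stop_mixcount("insufficient replication: need >= 2 trials per method",
                  class = "mixcount_insufficient_replication")
  y <- c(a, b)
  g <- rep(1:2, c(length(a), length(b)))
  grand <- mean(y)
  ssb <- length(a) * (mean(a) - grand)^2 + length(b) * (mean(b) - grand)^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  df1 <- 1L
  df2 <- length(y) - 2L
  if (ssw == 0 && ssb == 0)
    return(list(F = 0, df1 = df1, df2 = df2, p_value = 1))
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df1 = df1, df2 = df2,
       p_value = pf(f, df1, df2, lower.tail = FALSE))
}

#' Build a method-comparison row
#'
#' @param experiment experiment label.
#' @param trial trial number.
#' @param manual_logs,cyto_logs replicate log10 concentrations.
#' @return One-row data.frame with means, sds and the recomputed
#'   difference.
#' @export
method_comparison <- function(experiment, trial, manual_logs, cyto_logs) {
  d <- method_difference(manual_logs, cyto_logs)
  data.frame(experiment = experiment, trial = as.integer(trial),
             manual_mean = d$manual_mean, manual_sd = d$manual_sd,
             cyto_mean = d$cyto_mean, cyto_sd = d$cyto_sd,
             difference = d$difference, n_manual = length(manual_logs),
             n_cyto = length(cyto_logs), stringsAsFactors = FALSE)
}

#' Check a printed comparison table for internal consistency
#'
#' Flags rows whose printed `difference` does not equal the difference of
#' the printed per-method means at two decimals (tolerance 0.005 to absorb
#' the final rounding).
#'
#' @param table data.frame with `manual_mean`, `cyto_mean`, `difference`.
#' @return `table` with a logical `consistent` column added.
#' @export
check_table_consistency <- function(table) {
  stopifnot(all(c("manual_mean", "cyto_mean", "difference") %in%
                  names(table)))
  recomputed <- round(table$manual_mean - table$cyto_mean, 2)
  table$consistent <- abs(recomputed - table$difference) <= 0.005
  table
}
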