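#' Published reference method-comparison tables
#'
#' The log-scale method-comparison results reported for the validating wet-
#' lab study: per trial, the manual plate-count mean +/- sd
#' (log10 CFU/mL), the image-cytometry mean +/- sd (log10 cells/mL), the
#' printed difference (manual - cytometry) and the ANOVA p-value per
#' experiment block.  These printed numbers serve as inputs for the
#' table-arithmetic checks; [check_table_consistency()] identifies the rows
#' of the constant-plus-titration block whose printed difference does not
#' match the printed means (typographical inconsistencies in the source).
#'
#' @return Named list of data.frames: `titration`, `constant_mixture`,
#'   `ratio_mixture`, `fermentation`.  Columns: `experiment`, `organism`,
#'   `trial`, `manual_mean`, `manual_sd`, `cyto_mean`, `cyto_sd`,
#'   `difference`, `p_value` (repeated within a block).
#' @export
reference_comparison_tables <- function() {
  row <- function(experiment, organism, trial, mm, ms, cm, cs, d, p) {
    data.frame(experiment = experiment, organism = organism, trial = trial,
               manual_mean = mm, manual_sd = ms, cyto_mean = cm,
               cyto_sd = cs, difference = d, p_value = p,
               stringsAsFactors = FALSE)
  }
  titration <- rbind(
    row("titration", "bacteria", 1, 9.65, 0.04, 9.71, 0.25, -0.06, 0.49),
    row("titration", "bacteria", 2, 9.65, 0.06, 9.74, 0.26, -0.09, 0.49),
    row("titration", "bacteria", 3, 9.80, 0.04, 9.77, 0.19, 0.03, 0.49),
    row("titration", "yeast", 1, 7.66, 0.07, 7.54, 0.17, 0.12, 0.85),
    row("titration", "yeast", 2, 7.32, 0.12, 7.31, 0.08, 0.01, 0.85),
    row("titration", "yeast", 3, 7.53, 0.08, 7.58, 0.08, -0.05, 0.85)
  )
  constant_mixture <- rbind(
    row("yeast_constant", "bacteria", 1, 9.68, 0.04, 9.85, 0.07, -0.17, 0.58),
    row("yeast_constant", "bacteria", 2, 9.89, 0.07, 9.72, 0.04, 0.32, 0.58),
    row("yeast_constant", "bacteria", 3, 9.79, 0.07, 9.63, 0.08, 0.16, 0.58),
    row("yeast_constant", "yeast", 1, 7.66, 0.07, 7.73, 0.08, -0.07, 0.50),
    row("yeast_constant", "yeast", 2, 7.57, 0.13, 7.71, 0.07, -0.14, 0.50),
    row("yeast_constant", "yeast", 3, 7.50, 0.05, 7.49, 0.13, 0.07, 0.50),
    row("bacteria_constant", "bacteria", 1, 9.69, 0.03, 9.78, 0.03, -0.09, 0.96),
    row("bacteria_constant", "bacteria", 2, 9.49, 0.11, 9.65, 0.03, -0.16, 0.96),
    row("bacteria_constant", "bacteria", 3, 9.76, 0.07, 9.49, 0.05, 0.26, 0.96),
    row("bacteria_constant", "yeast", 1, 7.66, 0.07, 7.87, 0.05, -0.11, 0.46),
    row("bacteria_constant", "yeast", 2, 7.62, 0.11, 7.62, 0.14, 0.00, 0.46),
    row("bacteria_constant", "yeast", 3, 7.47, 0.05, 7.54, 0.06, -0.10, 0.46)
  )
  ratio_mixture <- rbind(
    row("ratio_mixture", "bacteria", 1, 9.32, 0.06, 9.68, 0.07, -0.36, 0.18),
    row("ratio_mixture", "bacteria", 2, 9.60, 0.12, 9.76, 0.14, -0.16, 0.18),
    row("ratio_mixture", "bacteria", 3, 9.68, 0.08, 9.65, 0.14, 0.03, 0.18),
    row("ratio_mixture", "yeast", 1, 7.17, 0.06, 7.67, 0.10, -0.50, 0.08),
    row("ratio_mixture", "yeast", 2, 7.33, 0.12, 7.74, 0.08, -0.41, 0.08),
    row("ratio_mixture", "yeast", 3, 7.54, 0.15, 7.51, 0.11, 0.03, 0.08)
  )
  fermentation <- rbind(
    row("fermentation", "bacteria", 1, 8.51, 0.25, 8.51, 0.22, 0.00, 0.81),
    row("fermentation", "bacteria", 2, 8.38, 0.12, 8.40, 0.12, -0.02, 0.81),
    row("fermentation", "bacteria", 3, 8.40, 0.12, 8.42, 0.17, -0.02, 0.81),
    row("fermentation", "yeast", 1, 6.72, 0.47, 6.43, 0.43, 0.29, 0.73),
    row("fermentation", "yeast", 2, 6.98, 0.40, 7.20, 0.41, -0.22, 0.73),
    row("fermentation", "yeast", 3, 6.64, 0.26, 6.99, 0.21, -0.35, 0.73)
  )
  list(titration = titration, constant_mixture = constant_mixture,
       ratio_mixture = ratio_mixture, fermentation = fermentation)
}
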