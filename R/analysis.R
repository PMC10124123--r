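# High-level analyses: run simulated samples through the counting pipeline
# and summarise titration linearity.

#' Count one simulated sample
#'
#' Runs the detection pipeline on the sample's `"total"`-channel frames.
#' In `"mono"` mode a single profile produces one [count_result()]; in
#' `"mixed"` mode the two size-exclusion profiles produce yeast and
#' bacteria results via [dual_count()].
#'
#' @param sample one element of a [simulate_experiment()] /
#'   [simulate_fermentation()] sample list.
#' @param mode `"mono"` or `"mixed"`.
#' @param profile the profile for `"mono"` mode.
#' @param population population label for `"mono"` mode.
#' @param yeast_profile,bacteria_profile profiles for `"mixed"` mode.
#' @param extra_dilution upstream dilution to undo (e.g. 10 for 1:10
#'   fermentation sampling); read from the sample descriptor when present.
#' @param spillover also compute the between-gate spillover diagnostic
#'   (mixed mode; costs one extra detection pass).
#' @param min_contrast see [count_population()].
#' @return Named list of [count_result()]s (`total` population name as
#'   given in mono mode; `yeast`/`bacteria` in mixed mode).
#' @export
count_sample <- function(sample, mode = c("mixed", "mono"), profile = NULL,
                         population = "total",
                         yeast_profile = builtin_profile("mixed_yeast"),
                         bacteria_profile = builtin_profile("mixed_bacteria"),
                         extra_dilution = NULL, spillover = FALSE,
                         min_contrast = 0.08) {
  mode <- match.arg(mode)
  chamber <- sample$truths[[1]]$chamber
  staining <- sample$truths[[1]]$staining
  dil <- extra_dilution %||% sample$descriptor$extra_dilution %||% 1
  frames <- sample$frames[["total"]]
  if (is.null(frames))
    stop_mixcount("sample '%s' has no 'total' channel frames",
                  sample$descriptor$sample_id, class = "mixcount_config_error")
  if (mode == "mono") {
    stopifnot(inherits(profile, "counting_profile"))
    cp <- count_population(frames, profile, min_contrast)
    conc <- counts_to_concentration(cp$raw_count, cp$fields_used, chamber,
                                    staining, dil)
    res <- count_result(population, cp$raw_count, cp$fields_used, conc)
    # viability from the dead channel when the plan has one
    if (!is.null(sample$frames[["dead"]]) && population == "total") {
      cd <- count_population(sample$frames[["dead"]], profile, min_contrast)
      res$viability <- suppressWarnings(viability(cp$raw_count, cd$raw_count))
    }
    setNames(list(res), population)
  } else {
    dc <- dual_count(frames, yeast_profile, bacteria_profile, chamber,
                     staining, dil, spillover = spillover,
                     min_contrast = min_contrast)
    out <- list(yeast = dc$yeast, bacteria = dc$bacteria)
    attr(out, "spillover") <- dc$spillover
    out
  }
}

#' Titration linearity of a simulated design
#'
#' Counts every sample and regresses the measured concentration of the
#' requested population on the design level (dilution fraction).
#'
#' @param samples a [simulate_experiment()] sample list.
#' @param population which population's concentration to regress.
#' @param mode,profile,yeast_profile,bacteria_profile see [count_sample()].
#' @param min_contrast see [count_population()].
#' @return List with `results` (per-sample data.frame: sample_id, level,
#'   concentration, true concentration) and `regression`
#'   ([titration_regression()] output).
#' @export
titration_linearity <- function(samples, population = c("bacteria", "yeast",
                                                        "total"),
                                mode = c("mixed", "mono"), profile = NULL,
                                yeast_profile = builtin_profile("mixed_yeast"),
                                bacteria_profile =
                                  builtin_profile("mixed_bacteria"),
                                min_contrast = 0.08) {
  population <- match.arg(population)
  mode <- match.arg(mode)
  rows <- lapply(samples, function(s) {
    res <- count_sample(s, mode, profile, population, yeast_profile,
                        bacteria_profile, min_contrast = min_contrast)
    r <- res[[population]]
    data.frame(sample_id = s$descriptor$sample_id,
               level = s$descriptor$level,
               concentration = r$concentration,
               true_conc = switch(population,
                 yeast = s$descriptor$conc_yeast,
                 bacteria = s$descriptor$conc_bacteria,
                 total = s$descriptor$conc_yeast + s$descriptor$conc_bacteria),
               raw_count = r$raw_count, stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  reg <- titration_regression(results$level, results$concentration)
  list(results = results, regression = reg)
}
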