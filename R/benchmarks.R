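# End-to-end simulation benchmarks mirroring the validating study's
# titration and mixed-culture designs.  Field areas are desk-scaled so that
# per-field object counts land in the practical counting range (hundreds to
# ~1000 objects) while runtime stays modest; per-field densities -- the
# quantity that drives overlap and declustering -- follow directly from the
# stated concentrations and chamber depth and are not scaled.  Samples are
# simulated, counted and discarded one at a time so memory stays flat even
# for multi-megapixel yeast fields.

stream_design <- function(levels, replicates, conc_at_level, chamber,
                          staining, seed, count_one, design_name,
                          optics = optics_config(), render_roles = "total") {
  rows <- list()
  counter <- 0L
  for (li in seq_along(levels)) {
    for (rep_i in seq_len(replicates)) {
      counter <- counter + 1L
      conc <- conc_at_level(levels[li])
      s <- simulate_sample(
        sprintf("%s_l%02d_r%02d", design_name, li, rep_i),
        conc[["yeast"]], conc[["bacteria"]], chamber, staining,
        optics, 0.01, 0.05, 0, 0, seed, counter,
        descriptor_extra = list(design = design_name, level = levels[li],
                                replicate = rep_i),
        render_roles = render_roles)
      rows[[counter]] <- count_one(s)
    }
  }
  do.call(rbind, rows)
}

#' Monoculture titration benchmark
#'
#' Simulates a monoculture titration (bacteria: 1e9 cells/mL stock, SYTO BC
#' staining, dilution fractions 0.1/0.25/0.5/0.75/1, n = 6 per fraction;
#' yeast: 1e7 cells/mL stock, AO/PI staining, fractions
#' 0.1/0.3/0.5/0.7/0.9/1, n = 4), four fields per sample in the SD025
#' chamber, runs the full detection + enumeration pipeline with the
#' matching monoculture profile, and regresses measured concentration on
#' dilution fraction.
#'
#' @param organism `"bacteria"` or `"yeast"`.
#' @param seed base seed.
#' @param field_area_um2 imaged area per field; defaults chosen per
#'   organism for count range and runtime (1e5 for bacteria, 2e6 for
#'   yeast).
#' @return List with `results` (per-sample concentrations) and `regression`
#'   (slope, intercept, `r_squared`).
#' @export
benchmark_titration <- function(organism = c("bacteria", "yeast"), seed = 1,
                                field_area_um2 = NULL) {
  organism <- match.arg(organism)
  if (organism == "bacteria") {
    chamber <- builtin_chamber("SD025", field_area_um2 %||% 1e5)
    staining <- builtin_staining("bacteria_sytobc")
    profile <- builtin_profile("bacteria_sytobc")
    levels <- c(0.1, 0.25, 0.5, 0.75, 1); reps <- 6
    conc_at <- function(f) c(yeast = 0, bacteria = 1e9 * f)
  } else {
    chamber <- builtin_chamber("SD025", field_area_um2 %||% 2e6)
    staining <- builtin_staining("yeast_aopi")
    profile <- builtin_profile("yeast_aopi_fl1")
    levels <- c(0.1, 0.3, 0.5, 0.7, 0.9, 1); reps <- 4
    conc_at <- function(f) c(yeast = 1e7 * f, bacteria = 0)
  }
  count_one <- function(s) {
    res <- count_sample(s, "mono", profile = profile)$total
    data.frame(sample_id = s$descriptor$sample_id,
               level = s$descriptor$level,
               concentration = res$concentration,
               raw_count = res$raw_count, stringsAsFactors = FALSE)
  }
  results <- stream_design(levels, reps, conc_at, chamber, staining, seed,
                           count_one, paste0("titration_", organism))
  list(results = results,
       regression = titration_regression(results$level,
                                         results$concentration))
}

#' Mixed-culture constant-plus-titration benchmark
#'
#' Yeast held constant at 1e7 cells/mL while bacteria are titrated from a
#' 1e9 cells/mL stock over fractions 0.001/0.01/0.1/0.2/0.5/1 (n = 6), all
#' rendered into a single green channel and counted by the mixed-mode
#' size-exclusion profiles (yeast 6.0-50.0 um, bacteria 0.5-5.0 um).
#'
#' @param seed base seed.
#' @param field_area_um2 imaged area per field (default 1e5).
#' @return List with `results` (per-sample yeast and bacteria
#'   concentrations), `bacteria_regression` (bacteria concentration on
#'   bacteria fraction) and `yeast_regression` (constant-organism trend).
#' @export
benchmark_mixed_titration <- function(seed = 1, field_area_um2 = 1e5) {
  chamber <- builtin_chamber("SD025", field_area_um2)
  staining <- builtin_staining("mixed_ao_sytobc")
  count_one <- function(s) {
    res <- count_sample(s, "mixed")
    data.frame(sample_id = s$descriptor$sample_id,
               level = s$descriptor$level,
               conc_yeast = res$yeast$concentration,
               conc_bacteria = res$bacteria$concentration,
               stringsAsFactors = FALSE)
  }
  results <- stream_design(
    c(0.001, 0.01, 0.1, 0.2, 0.5, 1), 6,
    function(f) c(yeast = 1e7, bacteria = 1e9 * f),
    chamber, staining, seed, count_one, "mixed_titration")
  list(results = results,
       bacteria_regression = titration_regression(results$level,
                                                  results$conc_bacteria),
       yeast_regression = titration_regression(results$level,
                                               results$conc_yeast))
}
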