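# Converts detected objects into per-population counts, concentrations
# (cells/mL of the original sample) and viability -- the size-exclusion
# mixed-culture logic.

#' Convert a pooled raw count to a concentration
#'
#' `concentration = raw_count / (fields_used * field_area * depth * 1e-12)
#'  * staining dilution * extra_dilution`, i.e. cells per mL of the ORIGINAL
#' undiluted sample.  Counts are pooled over fields (identical expectation
#' to per-field averaging, lower variance).
#'
#' @param raw_count objects counted across all fields (>= 0).
#' @param fields_used number of fields pooled (>= 1).
#' @param chamber a [chamber_spec()].
#' @param staining a [staining_plan()] (its dilution factor is undone).
#' @param extra_dilution any upstream sample fold-dilution to undo (>= 1).
#' @return Concentration, cells/mL.
#' @export
counts_to_concentration <- function(raw_count, fields_used, chamber,
                                    staining, extra_dilution = 1) {
  stopifnot(raw_count >= 0, extra_dilution >= 1,
            inherits(chamber, "chamber_spec"),
            inherits(staining, "staining_plan"))
  if (fields_used < 1)
    stop_mixcount("fields_used must be >= 1", class = "mixcount_domain_error")
  raw_count / (fields_used * chamber_volume_ml(chamber)) *
    staining$dilution_factor * extra_dilution
}

#' Count one population across a set of frames
#'
#' Runs the full detection pipeline (background -> threshold -> label ->
#' decluster -> measure -> filter) on every frame and pools the counts.
#'
#' @param frames list of [image_frame()]s sharing pixel geometry.
#' @param profile a [counting_profile()].
#' @param min_contrast minimum dynamic range (fraction of full scale) below
#'   which a frame counts as object-free; guards the relative threshold
#'   against pure-noise frames.
#' @return List with `raw_count`, `fields_used` and `objects` (the pooled
#'   measurement table).
#' @export
count_population <- function(frames, profile, min_contrast = 0.08) {
  stopifnot(is.list(frames), length(frames) >= 1,
            inherits(profile, "counting_profile"))
  pa <- vapply(frames, function(f) f$pixel_area, numeric(1))
  if (length(unique(pa)) != 1L)
    stop_mixcount("frames have mixed pixel geometries",
                  class = "mixcount_config_error")
  objs <- lapply(frames, detect_frame, profile = profile,
                 min_contrast = min_contrast)
  objects <- do.call(rbind, objs)
  list(raw_count = nrow(objects), fields_used = length(frames),
       objects = objects)
}

#' Per-population counting result
#'
#' @param population `"yeast"`, `"bacteria"`, `"total"` or `"dead"`.
#' @param raw_count pooled object count (integer >= 0).
#' @param fields_used fields pooled.
#' @param concentration cells/mL of the original sample (>= 0).
#' @param viability live fraction in \[0, 1\], or `NA` when no dead channel
#'   was measured.
#' @return Object of class `count_result`.
#' @export
count_result <- function(population, raw_count, fields_used, concentration,
                         viability = NA_real_) {
  stopifnot(population %in% c("yeast", "bacteria", "total", "dead"),
            raw_count >= 0, raw_count == round(raw_count),
            concentration >= 0)
  structure(list(population = population, raw_count = as.integer(raw_count),
                 fields_used = as.integer(fields_used),
                 concentration = concentration, viability = viability),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("%s: %d objects over %d fields -> %.4g cells/mL%s\n",
              x$population, x$raw_count, x$fields_used, x$concentration,
              if (is.na(x$viability)) ""
              else sprintf(" (viability %.1f%%)", 100 * x$viability)))
  invisible(x)
}

#' Simultaneous yeast and bacteria counts by size exclusion
#'
#' The same green-channel frames are analyzed twice -- once with the yeast
#' profile, once with the bacteria profile -- and objects are assigned to a
#' population purely by the equivalent-diameter gates (both organisms are
#' stained green; no intensity classification).  Objects falling between
#' the two gates are counted by neither population and reported in the
#' `spillover` diagnostic.
#'
#' @param frames list of [image_frame()]s (the single green channel).
#' @param yeast_profile,bacteria_profile [counting_profile()]s; a warning is
#'   issued if their diameter gates overlap by more than `overlap_tol` um.
#' @param chamber,staining,extra_dilution concentration bookkeeping, see
#'   [counts_to_concentration()].
#' @param overlap_tol tolerated gate overlap in um (default 0.5).
#' @param spillover compute the between-gate diagnostic (costs one extra
#'   detection pass); when `FALSE`, `spillover` is `NA`.
#' @param min_contrast see [count_population()].
#' @return List with `yeast` and `bacteria` [count_result()]s, `spillover`
#'   (count of between-gate objects) and `objects` (yeast-profile
#'   measurement table, for diagnostics).
#' @export
dual_count <- function(frames, yeast_profile = builtin_profile("mixed_yeast"),
                       bacteria_profile = builtin_profile("mixed_bacteria"),
                       chamber = builtin_chamber("SD025"),
                       staining = builtin_staining("mixed_ao_sytobc"),
                       extra_dilution = 1, overlap_tol = 0.5,
                       spillover = TRUE, min_contrast = 0.08) {
  ov <- min(yeast_profile$diameter_max, bacteria_profile$diameter_max) -
    max(yeast_profile$diameter_min, bacteria_profile$diameter_min)
  if (ov > overlap_tol)
    warning(sprintf("diameter gates overlap by %.2f um; counts may double-count",
                    ov))
  cy <- count_population(frames, yeast_profile, min_contrast)
  cb <- count_population(frames, bacteria_profile, min_contrast)
  gap_lo <- min(yeast_profile$diameter_min, bacteria_profile$diameter_min)
  # spillover: objects of the more permissive (lower-threshold) run falling
  # in the gap between the bacteria and yeast gates
  lo <- min(bacteria_profile$diameter_max, yeast_profile$diameter_max)
  hi <- max(bacteria_profile$diameter_min, yeast_profile$diameter_min)
  perm <- if (yeast_profile$fluorescent_threshold <=
              bacteria_profile$fluorescent_threshold) cy else cb
  spill <- NA_integer_
  if (spillover) {
    all_obj <- count_population(frames, counting_profile(
      gap_lo, max(yeast_profile$diameter_max, bacteria_profile$diameter_max),
      0, min(yeast_profile$fluorescent_threshold,
             bacteria_profile$fluorescent_threshold),
      yeast_profile$decluster_factor), min_contrast)
    spill <- if (lo < hi)
      sum(all_obj$objects$eq_diameter_um > lo &
            all_obj$objects$eq_diameter_um < hi) else 0L
  }
  mk <- function(cp, pop) count_result(
    pop, cp$raw_count, cp$fields_used,
    counts_to_concentration(cp$raw_count, cp$fields_used, chamber, staining,
                            extra_dilution))
  list(yeast = mk(cy, "yeast"), bacteria = mk(cb, "bacteria"),
       spillover = spill, objects = perm$objects)
}

#' Viability from total and dead counts
#'
#' `viability = (total - dead) / total`.  A dead count exceeding the total
#' is clamped with a warning; a zero total yields `NA` with a warning (the
#' degenerate case is signaled in the result, not raised).
#'
#' @param total,dead [count_result()]s or raw counts.
#' @return Live fraction in \[0, 1\], or `NA`.
#' @export
viability <- function(total, dead) {
  nt <- if (inherits(total, "count_result")) total$raw_count else total
  nd <- if (inherits(dead, "count_result")) dead$raw_count else dead
  stopifnot(nt >= 0, nd >= 0)
  if (nt == 0) {
    warning("total count is zero; viability undefined")
    return(NA_real_)
  }
  if (nd > nt) {
    warning("dead count exceeds total; clamping")
    nd <- nt
  }
  (nt - nd) / nt
}

#' Match detected objects to ground-truth objects
#'
#' Greedy nearest-neighbour matching of detected centroids to truth
#' centroids within `max_dist_um`; used by the simulation tests to measure
#' cross-classification between the size gates.
#'
#' @param objects measurement table ([measure_objects()]).
#' @param truth a [sample_field_truth()].
#' @param max_dist_um maximum centroid distance for a match (default 3 um).
#' @return `objects` with an extra `truth_class` column (`NA` = unmatched).
#' @export
match_to_truth <- function(objects, truth, max_dist_um = 3) {
  stopifnot(inherits(truth, "field_truth"))
  tc <- rep(NA_character_, nrow(objects))
  if (nrow(objects) && nrow(truth$objects)) {
    for (i in seq_len(nrow(objects))) {
      d2 <- (truth$objects$x_um - objects$centroid_x_um[i])^2 +
        (truth$objects$y_um - objects$centroid_y_um[i])^2
      j <- which.min(d2)
      if (d2[j] <= max_dist_um^2) tc[i] <- truth$objects$class[j]
    }
  }
  objects$truth_class <- tc
  objects
}
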