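#' Optical configuration of the image cytometer
#'
#' Geometry of the imaging system: a 10X objective on the instrument this
#' package emulates yields a resolution of about 0.5 um^2 per pixel, and four
#' areas of the counting chamber are imaged per sample.
#'
#' @param pixel_area area imaged by one pixel, um^2 (> 0).
#' @param bit_depth integer bit depth of the intensity scale.
#' @param fields_per_sample number of chamber areas imaged per sample (>= 1).
#' @return An object of class `optics_config` with the fields above plus
#'   `pixel_side`, the derived pixel side length in um.
#' @export
optics_config <- function(pixel_area = 0.5, bit_depth = 16L,
                          fields_per_sample = 4L) {
  stopifnot(is.numeric(pixel_area), length(pixel_area) == 1L, pixel_area > 0,
            bit_depth >= 1, fields_per_sample >= 1)
  structure(list(pixel_area = pixel_area,
                 pixel_side = sqrt(pixel_area),
                 bit_depth = as.integer(bit_depth),
                 fields_per_sample = as.integer(fields_per_sample)),
            class = "optics_config")
}

#' Counting-chamber specification
#'
#' A disposable counting chamber has a fixed depth; depth times the imaged
#' field area defines the analysis volume per field.  Chamber depths are not
#' published for the SD consumables, so the defaults follow the product
#' naming convention (SD100 = 100 um, SD025 = 25 um) and every concentration
#' computation reads the depth from the spec rather than hard-coding it.
#'
#' @param name chamber label, e.g. `"SD025"`.
#' @param depth_um chamber depth in um (> 0).
#' @param field_area_um2 imaged area per field in um^2 (> 0); default 1 mm^2.
#' @return An object of class `chamber_spec`.
#' @seealso [builtin_chamber()], [chamber_volume_ml()]
#' @export
chamber_spec <- function(name, depth_um, field_area_um2 = 1e6) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(depth_um), depth_um > 0,
            is.numeric(field_area_um2), field_area_um2 > 0)
  structure(list(name = name, depth_um = depth_um,
                 field_area_um2 = field_area_um2),
            class = "chamber_spec")
}

#' Built-in counting chambers
#'
#' @param name one of `"SD100"`, `"SD025"`.
#' @param field_area_um2 imaged area per field (um^2), default 1 mm^2.
#' @return A [chamber_spec()].
#' @export
builtin_chamber <- function(name, field_area_um2 = 1e6) {
  depths <- c(SD100 = 100, SD025 = 25)
  if (!is.character(name) || length(name) != 1L || !name %in% names(depths))
    stop_mixcount("unknown chamber '%s'; valid chambers: %s",
                  as.character(name)[1], paste(names(depths), collapse = ", "),
                  class = "mixcount_unknown_chamber")
  chamber_spec(name, depths[[name]], field_area_um2)
}

#' Analysis volume per imaged field, in mL
#'
#' `field_area_um2 * depth_um * 1e-12` exactly (1 um^3 = 1e-12 mL).
#'
#' @param chamber a [chamber_spec()].
#' @return Volume per field in mL.
#' @export
chamber_volume_ml <- function(chamber) {
  stopifnot(inherits(chamber, "chamber_spec"))
  chamber$field_area_um2 * chamber$depth_um * 1e-12
}

#' Staining plan
#'
#' Records how the sample that reaches the chamber relates to the original
#' culture (the overall fold-dilution introduced by buffers and dye) and what
#' each imaging channel means.  `"dead"` (a membrane-exclusion dye channel)
#' is only meaningful alongside a `"total"` channel.
#'
#' @param name plan label.
#' @param dilution_factor overall fold-dilution of the original sample
#'   reaching the chamber (>= 1).
#' @param channel_roles named character vector mapping channel ids to roles;
#'   roles must be drawn from `"total"`, `"dead"`, `"yeast"`, `"bacteria"`.
#' @return An object of class `staining_plan`.
#' @export
staining_plan <- function(name, dilution_factor, channel_roles) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(dilution_factor), dilution_factor >= 1,
            is.character(channel_roles), length(channel_roles) >= 1L)
  bad <- setdiff(channel_roles, c("total", "dead", "yeast", "bacteria"))
  if (length(bad))
    stop_mixcount("unknown channel role(s): %s", paste(bad, collapse = ", "),
                  class = "mixcount_bad_role")
  if ("dead" %in% channel_roles && !"total" %in% channel_roles)
    stop_mixcount("a 'dead' channel requires a 'total' channel",
                  class = "mixcount_bad_role")
  structure(list(name = name, dilution_factor = dilution_factor,
                 channel_roles = channel_roles),
            class = "staining_plan")
}

#' Built-in staining plans
#'
#' * `yeast_aopi` -- AO/PI dual stain for yeast monocultures: sample diluted
#'   1:1 with dilution buffer, then mixed 1:1 with dye (4x overall); channel
#'   1 counts all cells (AO), channel 2 counts dead cells (PI).
#' * `bacteria_sytobc` -- SYTO BC single green stain, 1:1 (2x overall).
#' * `mixed_ao_sytobc` -- AO + SYTO BC mixture for mixed cultures, 1:1 (2x
#'   overall).  Both organisms fluoresce in the same green band, so the plan
#'   carries a single `"total"` channel; population discrimination happens
#'   downstream by size gates (see [dual_count()]).
#'
#' @param name one of the plan labels above.
#' @return A [staining_plan()].
#' @export
builtin_staining <- function(name) {
  plans <- list(
    yeast_aopi      = list(4, c(FL1 = "total", FL2 = "dead")),
    bacteria_sytobc = list(2, c(FL1 = "total")),
    mixed_ao_sytobc = list(2, c(FL1 = "total"))
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(plans))
    stop_mixcount("unknown staining plan '%s'; valid plans: %s",
                  as.character(name)[1], paste(names(plans), collapse = ", "),
                  class = "mixcount_unknown_staining")
  p <- plans[[name]]
  staining_plan(name, p[[1]], p[[2]])
}

#' Counting-parameter profile
#'
#' One channel's detection/filter parameter set: the equivalent-diameter
#' gate, the minimum roundness (0 disables roundness filtering, since
#' roundness is always >= 0), the fluorescent threshold (percent of the
#' background-subtracted dynamic range, see [threshold_mask()]) and the
#' decluster factor (see [decluster()]).
#'
#' @param diameter_min,diameter_max equivalent-diameter gate in um,
#'   `0 < diameter_min < diameter_max`.
#' @param roundness_min minimum isoperimetric roundness, in \[0, 1\].
#' @param fluorescent_threshold threshold level (> 0), percent of dynamic
#'   range.
#' @param decluster_factor declustering aggressiveness in (0, 1\].
#' @return An object of class `counting_profile`.
#' @export
counting_profile <- function(diameter_min, diameter_max, roundness_min,
                             fluorescent_threshold, decluster_factor) {
  stopifnot(is.numeric(diameter_min), diameter_min > 0,
            is.numeric(diameter_max), diameter_max > diameter_min,
            is.numeric(roundness_min), roundness_min >= 0, roundness_min <= 1,
            is.numeric(fluorescent_threshold), fluorescent_threshold > 0,
            is.numeric(decluster_factor), decluster_factor > 0,
            decluster_factor <= 1)
  structure(list(diameter_min = diameter_min, diameter_max = diameter_max,
                 roundness_min = roundness_min,
                 fluorescent_threshold = fluorescent_threshold,
                 decluster_factor = decluster_factor),
            class = "counting_profile")
}

# published parameter sets, one per instrument configuration
.builtin_profiles <- list(
  yeast_aopi_fl1 = c(2.0, 30.0, 0.00, 25.0, 0.90),
  yeast_aopi_fl2 = c(2.0, 30.0, 0.00, 20.0, 0.90),
  bacteria_sytobc = c(0.7, 40.0, 0.00, 10.0, 0.90),
  mixed_yeast    = c(6.0, 50.0, 0.00, 8.0, 0.90),
  mixed_bacteria = c(0.5, 5.0, 0.00, 10.0, 0.90)
)

#' Built-in counting profiles
#'
#' The five published counting configurations:
#'
#' | name              | diameter (um) | roundness | threshold | decluster |
#' |-------------------|---------------|-----------|-----------|-----------|
#' | `yeast_aopi_fl1`  | 2.0-30.0      | 0.00      | 25.0      | 0.90      |
#' | `yeast_aopi_fl2`  | 2.0-30.0      | 0.00      | 20.0      | 0.90      |
#' | `bacteria_sytobc` | 0.7-40.0      | 0.00      | 10.0      | 0.90      |
#' | `mixed_yeast`     | 6.0-50.0      | 0.00      | 8.0       | 0.90      |
#' | `mixed_bacteria`  | 0.5-5.0       | 0.00      | 10.0      | 0.90      |
#'
#' @param name profile label.
#' @return A [counting_profile()].
#' @export
builtin_profile <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.builtin_profiles))
    stop_mixcount("unknown profile '%s'; valid profiles: %s",
                  as.character(name)[1],
                  paste(names(.builtin_profiles), collapse = ", "),
                  class = "mixcount_unknown_profile")
  p <- .builtin_profiles[[name]]
  counting_profile(p[1], p[2], p[3], p[4], p[5])
}

#' @export
print.counting_profile <- function(x, ...) {
  cat(sprintf(paste0("counting profile: diameter %.2f-%.2f um, roundness >= ",
                     "%.2f,\n  fluorescent threshold %.1f, decluster factor ",
                     "%.2f\n"),
              x$diameter_min, x$diameter_max, x$roundness_min,
              x$fluorescent_threshold, x$decluster_factor))
  invisible(x)
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat(sprintf("chamber %s: depth %g um, field area %g um^2 (%.3g mL/field)\n",
              x$name, x$depth_um, x$field_area_um2, chamber_volume_ml(x)))
  invisible(x)
}

# ---- flat-config serialization helpers -------------------------------------

profile_as_config <- function(profile) {
  stopifnot(inherits(profile, "counting_profile"))
  unclass(profile)
}

profile_from_config <- function(config) {
  do.call(counting_profile, config[c("diameter_min", "diameter_max",
                                     "roundness_min", "fluorescent_threshold",
                                     "decluster_factor")])
}

chamber_as_config <- function(chamber) unclass(chamber)

chamber_from_config <- function(config) {
  chamber_spec(config$name, config$depth_um, config$field_area_um2)
}
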