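#' Single-channel micrograph frame
#'
#' @param pixels numeric matrix of non-negative intensities within the
#'   declared bit depth.
#' @param pixel_area area per pixel, um^2.
#' @param channel_role what the channel shows (`"total"`, `"dead"`,
#'   `"yeast"`, `"bacteria"`).
#' @param frame_id label for provenance.
#' @param bit_depth intensity bit depth (default 16).
#' @return An object of class `image_frame`.
#' @export
image_frame <- function(pixels, pixel_area = 0.5, channel_role = "total",
                        frame_id = "frame", bit_depth = 16L) {
  stopifnot(is.matrix(pixels), is.numeric(pixels), pixel_area > 0)
  if (any(pixels < 0))
    stop_mixcount("negative intensities in frame '%s'", frame_id,
                  class = "mixcount_bad_frame")
  full <- 2^bit_depth - 1
  if (any(pixels > full))
    stop_mixcount("intensities exceed %d-bit range in frame '%s'",
                  bit_depth, frame_id, class = "mixcount_bad_frame")
  structure(list(pixels = pixels, pixel_area = pixel_area,
                 pixel_side = sqrt(pixel_area),
                 channel_role = channel_role, frame_id = frame_id,
                 bit_depth = as.integer(bit_depth), full_scale = full),
            class = "image_frame")
}

#' Robust background level of a frame
#'
#' The median intensity.  Objects occupy a small fraction of a counting
#' chamber field, so the median is dominated by background pixels.
#'
#' @param frame an [image_frame()].
#' @return Scalar background level.  A fully saturated frame returns the
#'   full-scale value with a warning.
#' @export
estimate_background <- function(frame) {
  stopifnot(inherits(frame, "image_frame"))
  b <- median(frame$pixels)
  if (all(frame$pixels >= frame$full_scale))
    warning(sprintf("frame '%s' is fully saturated", frame$frame_id))
  b
}

#' Threshold a frame into a foreground mask
#'
#' The fluorescent threshold is defined as a percentage of the
#' background-subtracted dynamic range: a pixel is foreground iff
#' `intensity >= background + (threshold/100) * (max - background)`.
#' This is scale-invariant and reproduces the ordering of published values
#' (a yeast AO threshold of 25.0 is stricter than the mixed-mode 8.0).
#' When the frame maximum equals the background the mask is empty.
#'
#' @param frame an [image_frame()].
#' @param profile a [counting_profile()]; only `fluorescent_threshold` is
#'   used.
#' @return Logical matrix, `TRUE` = foreground.
#' @export
threshold_mask <- function(frame, profile) {
  stopifnot(inherits(frame, "image_frame"),
            inherits(profile, "counting_profile"))
  bg <- median(frame$pixels)
  mx <- max(frame$pixels)
  if (mx <= bg) return(matrix(FALSE, nrow(frame$pixels), ncol(frame$pixels)))
  cut <- bg + profile$fluorescent_threshold / 100 * (mx - bg)
  frame$pixels >= cut
}

#' Label connected foreground components
#'
#' 8-connected component labeling (diagonally touching pixels join), so thin
#' diagonal rods at ~0.7 um pixels are not split.  Labels are 1..K; the
#' attribute `n_labels` gives K.
#'
#' @param mask logical (or 0/1 integer) matrix.
#' @return Integer matrix of labels (0 = background) with attribute
#'   `n_labels`.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask
  storage.mode(m) <- "integer"
  .cc_label_cpp(m)
}

#' Split touching cells within labeled components
#'
#' Seeded splitting on the component's Euclidean distance transform.  Local
#' EDT maxima are candidate centres; two lobes with peak heights
#' `p1 <= p2` separated by a saddle of height `h` are merged into one object
#' when `h >= decluster_factor * p1`.  A factor of 0.90 therefore splits
#' only well-separated lobes (a shallow neck merges), a factor near 0 always
#' merges (one child per component), and a factor of 1.0 splits maximally.
#' Each child receives the pixels nearest its centre within the component,
#' so the children always partition the parent exactly.
#'
#' In addition to the relative rule, saddles whose absolute dip below the
#' lower peak is at most `min_drop_px` pixels are always merged: the
#' distance ridge of a thin rod ripples by a fraction of a pixel under
#' discretisation, and those ripples are not cell boundaries.
#'
#' @param labels integer label matrix from [label_components()], or a
#'   logical mask (labeled internally).
#' @param profile a [counting_profile()] (only `decluster_factor` is used),
#'   or a numeric factor in (0, 1].
#' @param min_drop_px absolute saddle-dip tolerance in pixels (default 0.5).
#' @return List with `labels` (child label matrix, 1..M), `parent` (parent
#'   component of each child), `centers` (data.frame of 0-based pixel
#'   coordinates of each child centre) and `n_children`.
#' @export
decluster <- function(labels, profile = 0.90, min_drop_px = 0.5) {
  factor <- if (inherits(profile, "counting_profile"))
    profile$decluster_factor else profile
  stopifnot(is.numeric(factor), factor > 0, factor <= 1)
  if (is.logical(labels)) labels <- label_components(labels)
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  edt <- .edt_cpp(labels)
  res <- .decluster_cpp(labels, edt, factor, min_drop_px)
  list(labels = res$labels, parent = res$parent,
       centers = data.frame(row = res$center_row, col = res$center_col),
       n_children = res$n_children)
}

#' Measure labeled objects
#'
#' Computes, per object: pixel count; area (`pixel_count * pixel_area`);
#' equivalent diameter (`2 * sqrt(area / pi)`); perimeter (chain-code
#' contour length with diagonal correction; the pixel boundary, `4 * pixel
#' side`, for single-pixel objects); isoperimetric roundness
#' (`4 * pi * area / perimeter^2`, clamped to \[0, 1\] after discretisation);
#' centroid in um (pixel centres at `(index + 0.5) * pixel side`, 0-based
#' indices, x = column, y = row); mean and peak intensity.
#'
#' @param labels integer label matrix (e.g. child labels from
#'   [decluster()]).
#' @param frame the [image_frame()] the labels came from.
#' @return `data.frame` with one row per object.
#' @export
measure_objects <- function(labels, frame) {
  stopifnot(is.matrix(labels), inherits(frame, "image_frame"),
            all(dim(labels) == dim(frame$pixels)))
  storage.mode(labels) <- "integer"
  nlab <- max(0L, max(labels))
  if (nlab == 0L) return(empty_objects())
  st <- .region_stats_cpp(labels, frame$pixels, nlab)
  side <- frame$pixel_side
  chain <- .perimeter_cpp(labels, nlab)
  npix <- st[, 1]
  per <- ifelse(chain > 0, chain * side, 4 * side)
  area <- npix * frame$pixel_area
  roundness <- pmin(pmax(4 * pi * area / per^2, 0), 1)
  data.frame(
    object_id = seq_len(nlab),
    pixel_count = as.integer(npix),
    area_um2 = area,
    eq_diameter_um = 2 * sqrt(area / pi),
    roundness = roundness,
    perimeter_um = per,
    centroid_x_um = (st[, 5] / npix + 0.5) * side,  # mean col -> x
    centroid_y_um = (st[, 4] / npix + 0.5) * side,  # mean row -> y
    mean_intensity = st[, 2] / npix,
    peak_intensity = st[, 3],
    touches_border = st[, 6] == 0 | st[, 7] == nrow(labels) - 1 |
      st[, 8] == 0 | st[, 9] == ncol(labels) - 1,
    source_frame = frame$frame_id,
    stringsAsFactors = FALSE
  )
}

empty_objects <- function() {
  data.frame(object_id = integer(0), pixel_count = integer(0),
             area_um2 = numeric(0), eq_diameter_um = numeric(0),
             roundness = numeric(0), perimeter_um = numeric(0),
             centroid_x_um = numeric(0), centroid_y_um = numeric(0),
             mean_intensity = numeric(0), peak_intensity = numeric(0),
             touches_border = logical(0), source_frame = character(0),
             stringsAsFactors = FALSE)
}

#' Apply a profile's size and roundness gates
#'
#' Keeps objects with `diameter_min <= eq_diameter_um <= diameter_max`
#' (inclusive bounds) and `roundness >= roundness_min`; row order is
#' preserved.  A `roundness_min` of 0.00 never excludes anything.
#'
#' @param objects data.frame from [measure_objects()].
#' @param profile a [counting_profile()].
#' @return Filtered data.frame.
#' @export
filter_objects <- function(objects, profile) {
  stopifnot(is.data.frame(objects), inherits(profile, "counting_profile"))
  keep <- objects$eq_diameter_um >= profile$diameter_min &
    objects$eq_diameter_um <= profile$diameter_max &
    objects$roundness >= profile$roundness_min
  objects[keep, , drop = FALSE]
}

# Full single-frame pipeline: background -> threshold -> label (border
# policy) -> decluster -> measure -> filter.  Frames whose dynamic range
# (max - background) is below min_contrast * full_scale are treated as
# object-free: a purely relative threshold would otherwise binarise noise.
detect_frame <- function(frame, profile, min_contrast = 0.08) {
  bg <- median(frame$pixels)
  mx <- max(frame$pixels)
  if ((mx - bg) < min_contrast * frame$full_scale) return(empty_objects())
  mask <- threshold_mask(frame, profile)
  labels <- label_components(mask)
  nlab <- attr(labels, "n_labels")
  if (nlab == 0L) return(empty_objects())
  # border policy: drop border-touching components whose centroid lies in
  # the outermost pixel ring (documented; switchable to strict exclusion by
  # filtering on touches_border downstream)
  st <- .region_stats_cpp(labels, frame$pixels, nlab)
  nr <- nrow(mask); nc <- ncol(mask)
  touches <- st[, 6] == 0 | st[, 7] == nr - 1 | st[, 8] == 0 | st[, 9] == nc - 1
  crow <- st[, 4] / st[, 1] + 0.5
  ccol <- st[, 5] / st[, 1] + 0.5
  interior <- crow >= 1 & crow <= nr - 1 & ccol >= 1 & ccol <= nc - 1
  drop <- which(touches & !interior)
  if (length(drop)) labels[labels %in% drop] <- 0L
  dec <- decluster(labels, profile)
  obj <- measure_objects(dec$labels, frame)
  filter_objects(obj, profile)
}
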