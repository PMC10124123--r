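# Synthetic counting-chamber micrographs with exact ground truth.  The
# simulator emulates what the instrument sees: a fixed-depth chamber field
# containing large round yeast (disks, default equivalent diameter ~7.5 um)
# and small rod-shaped bacteria (capsules, ~1 x 2.5 um), both fluorescing in
# the green channel.  Counts per field are Poisson in the analysis volume;
# positions are uniform.

default_size_params <- function() {
  list(
    # kept inside the mixed-mode yeast gate (6-50 um): the size-exclusion
    # method presumes the yeast population sits above 6 um, and the
    # published gate choice encodes that presumption
    yeast_diameter_mean = 8, yeast_diameter_sd = 0.75,
    yeast_diameter_range = c(6, 10),
    bact_width_mean = 1.0, bact_width_sd = 0.15,
    bact_width_range = c(0.7, 1.5),
    bact_length_mean = 2.5, bact_length_sd = 0.5,
    bact_length_range = c(1.5, 4),
    yeast_intensity_range = c(0.6, 0.9),
    bact_intensity_range = c(0.4, 0.7)
  )
}

#' Sample the ground truth for one chamber field
#'
#' Object counts per class are Poisson with mean
#' `(concentration / staining dilution) * field_area * depth * 1e-12`
#' (volume in mL); positions are uniform over the field; a `"dead"` label is
#' assigned independently with probability `dead_fraction`.  Yeast are disks
#' with truncated-normal diameters, bacteria are rods with truncated-normal
#' width and length and uniform orientation on \[0, pi).
#'
#' @param conc_yeast,conc_bacteria concentrations of the original sample,
#'   cells/mL (>= 0).
#' @param chamber a [chamber_spec()].
#' @param staining a [staining_plan()]; its dilution factor scales the
#'   chamber concentration down.
#' @param dead_fraction probability an object is dead, in \[0, 1\].
#' @param seed integer seed (mandatory; no hidden global randomness).
#' @param cluster_fraction fraction of objects repositioned to touch a
#'   same-class neighbour, to exercise declustering (default 0).
#' @param size_params optional overrides of the size/intensity defaults
#'   (see source of `default_size_params`).
#' @return An object of class `field_truth`: a list with `objects` (one row
#'   per cell), `field_w_um`, `field_h_um`, `field_area_um2`, `chamber`,
#'   `staining`.
#' @export
sample_field_truth <- function(conc_yeast, conc_bacteria, chamber, staining,
                               dead_fraction = 0, seed,
                               cluster_fraction = 0, size_params = list()) {
  stopifnot(inherits(chamber, "chamber_spec"),
            inherits(staining, "staining_plan"),
            dead_fraction >= 0, dead_fraction <= 1,
            cluster_fraction >= 0, cluster_fraction <= 1)
  if (conc_yeast < 0 || conc_bacteria < 0)
    stop_mixcount("concentrations must be non-negative",
                  class = "mixcount_domain_error")
  sp <- modifyList(default_size_params(), size_params)
  vol_ml <- chamber_volume_ml(chamber)
  side <- sqrt(chamber$field_area_um2)
  with_seed(seed, {
    n_y <- rpois(1, conc_yeast / staining$dilution_factor * vol_ml)
    n_b <- rpois(1, conc_bacteria / staining$dilution_factor * vol_ml)
    obj <- data.frame(
      class = c(rep("yeast", n_y), rep("bacteria", n_b)),
      viability = rep("live", n_y + n_b),
      x_um = rep(NA_real_, n_y + n_b),
      y_um = rep(NA_real_, n_y + n_b),
      diameter_um = rep(NA_real_, n_y + n_b),
      length_um = rep(NA_real_, n_y + n_b),
      width_um = rep(NA_real_, n_y + n_b),
      orientation = rep(NA_real_, n_y + n_b),
      peak_intensity = rep(NA_real_, n_y + n_b),
      stringsAsFactors = FALSE
    )
    if (n_y) {
      obj$diameter_um[seq_len(n_y)] <- rtruncnorm(
        n_y, sp$yeast_diameter_mean, sp$yeast_diameter_sd,
        sp$yeast_diameter_range[1], sp$yeast_diameter_range[2])
      obj$peak_intensity[seq_len(n_y)] <-
        runif(n_y, sp$yeast_intensity_range[1], sp$yeast_intensity_range[2])
    }
    if (n_b) {
      ib <- n_y + seq_len(n_b)
      obj$width_um[ib] <- rtruncnorm(
        n_b, sp$bact_width_mean, sp$bact_width_sd,
        sp$bact_width_range[1], sp$bact_width_range[2])
      obj$length_um[ib] <- pmax(rtruncnorm(
        n_b, sp$bact_length_mean, sp$bact_length_sd,
        sp$bact_length_range[1], sp$bact_length_range[2]), obj$width_um[ib])
      obj$orientation[ib] <- runif(n_b, 0, pi)
      obj$peak_intensity[ib] <-
        runif(n_b, sp$bact_intensity_range[1], sp$bact_intensity_range[2])
    }
    # positions: uniform, but wholly inside the field (margin = object
    # radius) so the truth list is an exact counting oracle -- no object is
    # ever clipped by the frame border
    n <- nrow(obj)
    if (n) {
      r <- ifelse(obj$class == "yeast", obj$diameter_um / 2,
                  obj$length_um / 2)
      span <- pmax(side - 2 * r, 0)
      obj$x_um <- r + runif(n) * span
      obj$y_um <- r + runif(n) * span
      obj$viability <- ifelse(runif(n) < dead_fraction, "dead", "live")
    }
    # optional clustering: move a fraction of objects to touching distance
    # of a random earlier same-class object
    if (cluster_fraction > 0 && n >= 2) {
      for (cl in c("yeast", "bacteria")) {
        idx <- which(obj$class == cl)
        if (length(idx) < 2) next
        k <- round(cluster_fraction * length(idx))
        if (k < 1) next
        movers <- idx[seq(length(idx) - k + 1, length(idx))]
        for (m in movers) {
          anchor <- sample(setdiff(idx, m), 1)
          r1 <- obj_radius(obj[m, ]); r2 <- obj_radius(obj[anchor, ])
          ang <- runif(1, 0, 2 * pi)
          d <- 0.9 * (r1 + r2)
          obj$x_um[m] <- min(max(obj$x_um[anchor] + d * cos(ang), r1),
                             side - r1)
          obj$y_um[m] <- min(max(obj$y_um[anchor] + d * sin(ang), r1),
                             side - r1)
        }
      }
    }
    structure(list(objects = obj, field_w_um = side, field_h_um = side,
                   field_area_um2 = chamber$field_area_um2,
                   chamber = chamber, staining = staining),
              class = "field_truth")
  })
}

obj_radius <- function(o) {
  if (o$class == "yeast") o$diameter_um / 2 else o$length_um / 2
}

#' Render a field truth into a micrograph frame
#'
#' Only objects visible in the requested channel role are drawn: `"total"`
#' draws all objects, `"dead"` only dead ones, `"yeast"`/`"bacteria"` only
#' that class.  Yeast are drawn as flat-topped disks, bacteria as capsules
#' (rectangle plus semicircular caps); edges are anti-aliased by 4x
#' supersampling with box downsampling so a ~1 um rod survives at ~0.71 um
#' pixels.  Additive Gaussian noise (sd as a fraction of full scale) and a
#' constant background are applied, then values are rounded and clipped to
#' the bit depth.  Deterministic for a fixed seed.
#'
#' @param truth a [sample_field_truth()] result.
#' @param optics an [optics_config()].
#' @param channel_role role to render; must appear in the truth's staining
#'   plan.
#' @param noise_sd Gaussian noise sd as a fraction of full scale.
#' @param background_level constant background as a fraction of full scale.
#' @param seed integer seed for the noise.
#' @param frame_id frame label.
#' @return An [image_frame()].
#' @export
render_field <- function(truth, optics = optics_config(),
                         channel_role = "total", noise_sd = 0.01,
                         background_level = 0.05, seed = 1,
                         frame_id = "frame") {
  stopifnot(inherits(truth, "field_truth"), inherits(optics, "optics_config"))
  if (!channel_role %in% truth$staining$channel_roles)
    stop_mixcount("channel role '%s' not in staining plan '%s' (roles: %s)",
                  channel_role, truth$staining$name,
                  paste(truth$staining$channel_roles, collapse = ", "),
                  class = "mixcount_bad_role")
  side <- optics$pixel_side
  nrp <- ceiling(truth$field_h_um / side)
  ncp <- ceiling(truth$field_w_um / side)
  canvas <- matrix(0, nrp, ncp)
  obj <- truth$objects
  show <- switch(channel_role,
                 total = rep(TRUE, nrow(obj)),
                 dead = obj$viability == "dead",
                 yeast = obj$class == "yeast",
                 bacteria = obj$class == "bacteria")
  obj <- obj[show, , drop = FALSE]
  for (i in seq_len(nrow(obj))) {
    p <- object_patch(obj[i, ], side, nrp, ncp)
    if (is.null(p)) next
    canvas[p$rows, p$cols] <- canvas[p$rows, p$cols] +
      obj$peak_intensity[i] * p$cov
  }
  full <- 2^optics$bit_depth - 1
  img <- full * (background_level + canvas)
  with_seed(seed, {
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd * full)
    img <- matrix(pmin(pmax(round(img), 0), full), nrp, ncp)
    storage.mode(img) <- "integer"  # halves memory at 16-bit depth
    image_frame(img, pixel_area = optics$pixel_area,
                channel_role = channel_role, frame_id = frame_id,
                bit_depth = optics$bit_depth)
  })
}

# One object's intensity footprint.  Coverage is computed on a 4x
# supersampled grid and sharpened with a linear ramp so the above-half-
# maximum footprint matches the true object area closely.  Returns NULL or
# list(rows, cols, cov) in 1-based canvas indices.
object_patch <- function(o, side, nrp, ncp, ss = 4L) {
  if (o$class == "yeast") {
    r <- o$diameter_um / 2
    x0 <- o$x_um; y0 <- o$y_um
    half <- r + side
  } else {
    r <- o$width_um / 2
    hl <- (o$length_um - o$width_um) / 2  # half length of the core segment
    ux <- cos(o$orientation); uy <- sin(o$orientation)
    x0 <- o$x_um; y0 <- o$y_um
    half <- o$length_um / 2 + side
  }
  c0 <- max(0L, floor((x0 - half) / side)); c1 <- min(ncp - 1L, ceiling((x0 + half) / side))
  r0 <- max(0L, floor((y0 - half) / side)); r1 <- min(nrp - 1L, ceiling((y0 + half) / side))
  if (c1 < c0 || r1 < r0) return(NULL)
  cols <- c0:c1; rows <- r0:r1
  # supersampled coordinates (um) of subpixel centres
  sub <- (seq_len(ss) - 0.5) / ss
  xs <- as.vector(outer(sub, cols, function(s, cc) (cc + s) * side))
  ys <- as.vector(outer(sub, rows, function(s, rr) (rr + s) * side))
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  if (o$class == "yeast") {
    inside <- (X - x0)^2 + (Y - y0)^2 <= r^2
  } else {
    # distance from subpixel to the capsule's core segment
    dx <- X - x0; dy <- Y - y0
    t <- dx * ux + dy * uy
    t <- pmin(pmax(t, -hl), hl)
    inside <- (dx - t * ux)^2 + (dy - t * uy)^2 <= r^2
  }
  # box-downsample ss x ss blocks to per-pixel coverage
  m <- matrix(0, length(rows), length(cols))
  idx_r <- rep(seq_along(rows), each = ss)
  idx_c <- rep(seq_along(cols), each = ss)
  cov <- rowsum(t(rowsum(inside + 0, idx_r)), idx_c) / (ss * ss)
  cov <- t(cov)
  # sharpen the coverage ramp: half-maximum contour sits at the true edge
  cov <- pmin(pmax((cov - 0.35) / 0.3, 0), 1)
  list(rows = rows + 1L, cols = cols + 1L, cov = cov)
}

#' Simulate a whole counting experiment
#'
#' Emits, for every sample x replicate, `fields_per_sample` rendered frames
#' per channel role plus the ground truth.  Designs:
#'
#' * `"titration"`: one organism diluted over `fractions`, the other absent.
#' * `"constant_plus_titration"`: the titrated organism at
#'   `stock * fraction`, the other held at `constant_conc`.
#' * `"ratio_mix"`: `percentages` percent yeast mixed with the complement of
#'   bacteria (`conc_yeast = stock_yeast * p/100`,
#'   `conc_bacteria = stock_bacteria * (1 - p/100)`).
#' * `"chamber_comparison"`: the titration repeated in two chambers.
#'
#' @param design design name (see above).
#' @param stock_yeast,stock_bacteria stock concentrations, cells/mL.
#' @param fractions dilution fractions (titration designs).
#' @param percentages yeast percentages (ratio design).
#' @param titrated which organism is titrated, `"bacteria"` or `"yeast"`.
#' @param constant_conc concentration of the constant organism
#'   (constant_plus_titration).
#' @param replicates replicates per sample (>= 1).
#' @param chamber,chamber2 chambers ([chamber_spec()]); `chamber2` only for
#'   `"chamber_comparison"`.
#' @param staining a [staining_plan()].
#' @param optics an [optics_config()].
#' @param noise_sd,background_level rendering parameters.
#' @param dead_fraction,cluster_fraction truth parameters.
#' @param seed base seed; all per-field seeds derive from it.
#' @return List of samples; each sample is a list with `descriptor` (sample
#'   id, design, fraction/percent, replicate, true concentrations, chamber),
#'   `frames` (a named list: one list of [image_frame()]s per channel role)
#'   and `truths` (one [sample_field_truth()] per field).
#' @export
simulate_experiment <- function(design = c("titration",
                                           "constant_plus_titration",
                                           "ratio_mix", "chamber_comparison"),
                                stock_yeast = 1e7, stock_bacteria = 1e9,
                                fractions = NULL, percentages = NULL,
                                titrated = c("bacteria", "yeast"),
                                constant_conc = NULL, replicates = 3,
                                chamber = builtin_chamber("SD025"),
                                chamber2 = builtin_chamber("SD100"),
                                staining = builtin_staining("mixed_ao_sytobc"),
                                optics = optics_config(), noise_sd = 0.01,
                                background_level = 0.05, dead_fraction = 0,
                                cluster_fraction = 0, seed = 1) {
  design <- match.arg(design)
  titrated <- match.arg(titrated)
  if (replicates < 1)
    stop_mixcount("replicates must be >= 1", class = "mixcount_domain_error")
  if (design == "ratio_mix") {
    if (is.null(percentages) || !length(percentages))
      stop_mixcount("ratio_mix needs a non-empty 'percentages'",
                    class = "mixcount_domain_error")
    levels <- percentages
  } else {
    if (is.null(fractions) || !length(fractions))
      stop_mixcount("design '%s' needs a non-empty 'fractions'", design,
                    class = "mixcount_domain_error")
    levels <- fractions
  }
  samples <- list()
  counter <- 0L
  for (li in seq_along(levels)) {
    lev <- levels[li]
    for (rep_i in seq_len(replicates)) {
      conc <- switch(design,
        titration = ,
        chamber_comparison = if (titrated == "bacteria")
          c(yeast = 0, bacteria = stock_bacteria * lev)
        else c(yeast = stock_yeast * lev, bacteria = 0),
        constant_plus_titration = if (titrated == "bacteria")
          c(yeast = constant_conc %||% stock_yeast,
            bacteria = stock_bacteria * lev)
        else c(yeast = stock_yeast * lev,
               bacteria = constant_conc %||% stock_bacteria),
        ratio_mix = c(yeast = stock_yeast * lev / 100,
                      bacteria = stock_bacteria * (1 - lev / 100))
      )
      chambers <- if (design == "chamber_comparison")
        list(chamber, chamber2) else list(chamber)
      for (ch in chambers) {
        counter <- counter + 1L
        sid <- sprintf("%s_l%02d_r%02d%s", design, li, rep_i,
                       if (design == "chamber_comparison")
                         paste0("_", ch$name) else "")
        samples[[length(samples) + 1L]] <- simulate_sample(
          sid, conc[["yeast"]], conc[["bacteria"]], ch, staining, optics,
          noise_sd, background_level, dead_fraction, cluster_fraction,
          seed, counter,
          descriptor_extra = list(design = design, level = lev,
                                  replicate = rep_i))
      }
    }
  }
  samples
}

# one sample = fields_per_sample truths + rendered frames per channel role
simulate_sample <- function(sample_id, conc_yeast, conc_bacteria, chamber,
                            staining, optics, noise_sd, background_level,
                            dead_fraction, cluster_fraction, seed, counter,
                            descriptor_extra = list(), render_roles = NULL) {
  roles <- unique(unname(staining$channel_roles))
  if (!is.null(render_roles)) roles <- intersect(roles, render_roles)
  truths <- list()
  frames <- setNames(rep(list(list()), length(roles)), roles)
  for (f in seq_len(optics$fields_per_sample)) {
    s_truth <- derive_seed(seed, counter * 1000L + f * 2L)
    s_noise <- derive_seed(seed, counter * 1000L + f * 2L + 1L)
    tr <- sample_field_truth(conc_yeast, conc_bacteria, chamber, staining,
                             dead_fraction, s_truth, cluster_fraction)
    truths[[f]] <- tr
    for (role in roles) {
      fid <- sprintf("%s_f%d_%s", sample_id, f, role)
      frames[[role]][[f]] <- render_field(tr, optics, role, noise_sd,
                                          background_level, s_noise, fid)
    }
  }
  list(descriptor = c(list(sample_id = sample_id, conc_yeast = conc_yeast,
                           conc_bacteria = conc_bacteria,
                           chamber = chamber$name,
                           staining = staining$name),
                      descriptor_extra),
       frames = frames, truths = truths)
}

#' Growth-trajectory scenario for one organism
#'
#' Two shapes cover the mixed-culture fermentation kinetics this package
#' emulates: yeast rise to a peak and then decline slowly (`"rise_fall"`,
#' log-linear in both phases), lactic acid bacteria rise logistically to a
#' plateau (`"logistic"`).  `"constant"` is available for null scenarios.
#'
#' @param model `"rise_fall"`, `"logistic"` or `"constant"`.
#' @param initial initial concentration, cells/mL.
#' @param peak peak (rise_fall) or plateau/carrying-capacity (logistic)
#'   concentration, cells/mL.
#' @param peak_time_hr time of the peak, hr (rise_fall).
#' @param post_peak_rate log10 change per hr after the peak (rise_fall;
#'   negative = decline).
#' @param rate logistic growth rate, 1/hr.
#' @param sampling_times_hr sampling schedule, hr.
#' @return An object of class `growth_scenario`.
#' @export
growth_scenario <- function(model = c("rise_fall", "logistic", "constant"),
                            initial, peak = initial, peak_time_hr = 9,
                            post_peak_rate = -0.02, rate = 0.4,
                            sampling_times_hr = c(0, 3, 6, 9, 12, 24, 48)) {
  model <- match.arg(model)
  stopifnot(initial > 0, peak > 0, peak_time_hr > 0, rate > 0)
  structure(list(model = model, initial = initial, peak = peak,
                 peak_time_hr = peak_time_hr,
                 post_peak_rate = post_peak_rate, rate = rate,
                 sampling_times_hr = sampling_times_hr),
            class = "growth_scenario")
}

#' Concentration of a scenario at given times
#'
#' @param scenario a [growth_scenario()].
#' @param t_hr numeric vector of times, hr.
#' @return Concentrations, cells/mL.
#' @export
scenario_concentration <- function(scenario, t_hr) {
  stopifnot(inherits(scenario, "growth_scenario"))
  with(scenario, switch(model,
    constant = rep(initial, length(t_hr)),
    rise_fall = {
      l0 <- log10(initial); lp <- log10(peak)
      ifelse(t_hr <= peak_time_hr,
             10^(l0 + (lp - l0) * t_hr / peak_time_hr),
             10^(lp + post_peak_rate * (t_hr - peak_time_hr)))
    },
    logistic = {
      K <- peak; C0 <- initial
      K * C0 / (C0 + (K - C0) * exp(-rate * t_hr))
    }
  ))
}

#' Default fermentation scenarios
#'
#' Trajectories shaped like the observed Berliner Weisse mixed-culture
#' kinetics: yeast rise from ~8.5e5 to a ~1.8e7 cells/mL peak at 9 hr then
#' decline to ~3e6 by 48 hr; bacteria rise logistically from ~1.5e8 to a
#' ~3.6e8 cells/mL plateau reached within the first 12 hr.
#'
#' @return Named list with `yeast` and `bacteria` [growth_scenario()]s.
#' @export
default_fermentation_scenarios <- function() {
  list(
    yeast = growth_scenario("rise_fall", initial = 8.5e5, peak = 1.82e7,
                            peak_time_hr = 9, post_peak_rate = -0.02),
    bacteria = growth_scenario("logistic", initial = 1.48e8, peak = 3.55e8,
                               rate = 0.4)
  )
}

#' Simulate a mixed-culture fermentation time course
#'
#' At every sampling time, `replicates` image-cytometry samples are drawn at
#' the sampling dilution (default 1:10) and rendered; paired plate counts
#' are simulated for both organisms.
#'
#' @param yeast_scenario,bacteria_scenario [growth_scenario()]s; defaults
#'   from [default_fermentation_scenarios()].
#' @param chamber,staining,optics imaging configuration.
#' @param extra_dilution sampling fold-dilution before staining (default 10).
#' @param replicates image-cytometry replicates per time point (default 4).
#' @param plates_per_dilution plates per dilution level (default 3).
#' @param noise_sd,background_level rendering parameters.
#' @param seed base seed.
#' @return List with `samples` (as in [simulate_experiment()], descriptors
#'   carrying `time_hr` and true concentrations) and `plate_counts` (a
#'   data.frame of simulated colony counts for both organisms).
#' @export
simulate_fermentation <- function(yeast_scenario = NULL,
                                  bacteria_scenario = NULL,
                                  chamber = builtin_chamber("SD025"),
                                  staining = builtin_staining("mixed_ao_sytobc"),
                                  optics = optics_config(),
                                  extra_dilution = 10, replicates = 4,
                                  plates_per_dilution = 3,
                                  noise_sd = 0.01, background_level = 0.05,
                                  seed = 1) {
  sc <- default_fermentation_scenarios()
  ys <- yeast_scenario %||% sc$yeast
  bs <- bacteria_scenario %||% sc$bacteria
  times <- ys$sampling_times_hr
  stopifnot(identical(times, bs$sampling_times_hr))
  samples <- list()
  plates <- list()
  counter <- 0L
  for (ti in seq_along(times)) {
    cy <- scenario_concentration(ys, times[ti])
    cb <- scenario_concentration(bs, times[ti])
    for (rep_i in seq_len(replicates)) {
      counter <- counter + 1L
      sid <- sprintf("ferment_t%02d_r%02d", ti, rep_i)
      s <- simulate_sample(sid, cy / extra_dilution, cb / extra_dilution,
                           chamber, staining, optics, noise_sd,
                           background_level, 0, 0, seed, counter,
                           descriptor_extra = list(
                             design = "fermentation", time_hr = times[ti],
                             replicate = rep_i,
                             extra_dilution = extra_dilution,
                             true_conc_yeast = cy, true_conc_bacteria = cb))
      samples[[length(samples) + 1L]] <- s
    }
    # paired plating: pick dilutions landing colonies in countable range
    for (org in c("yeast", "bacteria")) {
      conc <- if (org == "yeast") cy else cb
      expo <- -pmax(1, round(log10(conc) - 3))  # aim for ~100 colonies
      pl <- simulate_plate_counts(conc, c(expo - 1, expo, expo + 1), 0.1,
                                  plates_per_dilution,
                                  derive_seed(seed, 90000L + 10L * ti +
                                                (org == "yeast")),
                                  sample_id = sprintf("ferment_t%02d_%s",
                                                      ti, org),
                                  medium = if (org == "yeast") "APDA" else "MRS")
      pl$time_hr <- times[ti]
      pl$organism <- org
      plates[[length(plates) + 1L]] <- pl
    }
  }
  list(samples = samples, plate_counts = do.call(rbind, plates))
}

#' Simulate serial-dilution plate counts
#'
#' Colony counts are Poisson with mean
#' `true_conc * 10^exponent * plated_volume` per plate.
#'
#' @param true_conc true concentration, CFU/mL (>= 0).
#' @param dilution_exponents integer dilution exponents (<= 0; a positive
#'   exponent is a domain error -- dilutions only).
#' @param plated_volume_ml volume plated per plate, mL (> 0).
#' @param plates_per_dilution plates per dilution level.
#' @param seed integer seed.
#' @param sample_id,medium metadata columns.
#' @return data.frame of class `plate_count` rows: `sample_id`,
#'   `dilution_exponent`, `plated_volume_ml`, `colonies`, `medium`.
#' @export
simulate_plate_counts <- function(true_conc, dilution_exponents,
                                  plated_volume_ml, plates_per_dilution,
                                  seed, sample_id = "sample",
                                  medium = "MRS") {
  if (true_conc < 0)
    stop_mixcount("true_conc must be >= 0", class = "mixcount_domain_error")
  if (any(dilution_exponents > 0))
    stop_mixcount("dilution exponents must be <= 0 (dilutions only)",
                  class = "mixcount_domain_error")
  stopifnot(plated_volume_ml > 0, plates_per_dilution >= 1)
  with_seed(seed, {
    rows <- expand.grid(dilution_exponent = dilution_exponents,
                        plate = seq_len(plates_per_dilution))
    mu <- true_conc * 10^rows$dilution_exponent * plated_volume_ml
    data.frame(sample_id = sample_id,
               dilution_exponent = as.integer(rows$dilution_exponent),
               plated_volume_ml = plated_volume_ml,
               colonies = rpois(nrow(rows), mu),
               medium = medium, stringsAsFactors = FALSE)
  })
}
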