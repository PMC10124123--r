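# shared fixtures: all built in code, nothing on disk

# independent flood-fill labeling oracle (BFS, 8-connectivity)
flood_fill_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  k <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    k <- k + 1L
    queue <- matrix(c(i, j), ncol = 2)
    lab[i, j] <- k
    while (nrow(queue)) {
      p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && jj >= 1 && ii <= nr && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- k
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}

# labelings equal up to renaming?
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  fg <- a > 0
  !anyDuplicated(unique(cbind(a[fg], b[fg]))[, 1]) &&
    !anyDuplicated(unique(cbind(a[fg], b[fg]))[, 2])
}

# disk mask fixture: centers/radii in pixel units, 1-based
disk_mask <- function(nr, nc, centers, radii) {
  m <- matrix(FALSE, nr, nc)
  for (k in seq_along(radii)) {
    for (i in seq_len(nr)) for (j in seq_len(nc))
      if ((i - centers[k, 1])^2 + (j - centers[k, 2])^2 <= radii[k]^2)
        m[i, j] <- TRUE
  }
  m
}

# a frame holding one rendered disk with known geometry
one_disk_frame <- function(diameter_um = 6, peak = 0.8, background = 0.1,
                           noise_sd = 0, field_um = 100, seed = 1) {
  ch <- chamber_spec("test", 25, field_um^2)
  st <- builtin_staining("bacteria_sytobc")
  tr <- sample_field_truth(0, 0, ch, st, 0, seed = 1)
  tr$objects <- data.frame(class = "yeast", viability = "live",
                           x_um = field_um / 2, y_um = field_um / 2,
                           diameter_um = diameter_um, length_um = NA_real_,
                           width_um = NA_real_, orientation = NA_real_,
                           peak_intensity = peak)
  render_field(tr, optics_config(), "total", noise_sd = noise_sd,
               background_level = background, seed = seed)
}

# small mixed-culture field with ground truth at comfortable densities
mixed_field <- function(seed, field_um2 = 4e4, conc_yeast = NULL,
                        conc_bacteria = NULL) {
  ch <- builtin_chamber("SD025", field_um2)
  st <- builtin_staining("mixed_ao_sytobc")
  vol <- chamber_volume_ml(ch)
  cy <- conc_yeast %||% (8 / vol * st$dilution_factor)
  cb <- conc_bacteria %||% (20 / vol * st$dilution_factor)
  tr <- sample_field_truth(cy, cb, ch, st, 0, seed = seed)
  fr <- render_field(tr, optics_config(), "total", seed = seed + 100000L)
  list(truth = tr, frame = fr, chamber = ch, staining = st)
}

`%||%` <- mixcount:::`%||%`
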