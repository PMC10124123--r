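# enumeration: concentration arithmetic, population counting, viability

test_that("concentration formula matches the closed-form oracle", {
  ch <- builtin_chamber("SD025", 1e6)     # 2.5e-5 mL per field
  st <- builtin_staining("mixed_ao_sytobc")
  # 125 objects over 4 fields, 2x staining:
  # 125 / (4 * 1e6 * 25 * 1e-12) * 2 = 2.5e6
  expect_equal(counts_to_concentration(125, 4, ch, st),
               125 / (4 * 1e6 * 25 * 1e-12) * 2)
  expect_equal(counts_to_concentration(125, 4, ch, st), 2.5e6)
  expect_equal(counts_to_concentration(0, 4, ch, st, 7), 0)
  # doubling depth halves the concentration for a fixed count
  ch2 <- chamber_spec("deep", 50, 1e6)
  expect_equal(counts_to_concentration(125, 4, ch2, st),
               counts_to_concentration(125, 4, ch, st) / 2)
  # extra dilution multiplies
  expect_equal(counts_to_concentration(125, 4, ch, st, extra_dilution = 10),
               2.5e7)
  expect_error(counts_to_concentration(125, 0, ch, st),
               class = "mixcount_domain_error")
})

test_that("count_population: empty frames, determinism, geometry check", {
  # noisy but empty frames count zero (dynamic-range guard)
  frames <- lapply(1:4, function(s) {
    tr <- sample_field_truth(0, 0, builtin_chamber("SD025", 1e4),
                             builtin_staining("bacteria_sytobc"), 0, s)
    render_field(tr, optics_config(), "total", noise_sd = 0.01, seed = s)
  })
  cp <- count_population(frames, builtin_profile("bacteria_sytobc"))
  expect_equal(cp$raw_count, 0L)
  expect_equal(cp$fields_used, 4L)
  # determinism: same frames, same result
  mf <- mixed_field(3)
  c1 <- count_population(list(mf$frame), builtin_profile("mixed_bacteria"))
  c2 <- count_population(list(mf$frame), builtin_profile("mixed_bacteria"))
  expect_identical(c1$raw_count, c2$raw_count)
  # mixed pixel geometries are a configuration error
  small <- image_frame(matrix(0, 4, 4), pixel_area = 1.0)
  expect_error(count_population(list(mf$frame, small),
                                builtin_profile("mixed_bacteria")),
               class = "mixcount_config_error")
})

test_that("monoculture counts recover the ground truth on clean fields", {
  ch <- builtin_chamber("SD025", 2e4)
  st <- builtin_staining("bacteria_sytobc")
  vol <- chamber_volume_ml(ch)
  conc <- 8 / vol * st$dilution_factor
  hits <- 0; n <- 25
  for (s in 1:n) {
    tr <- sample_field_truth(0, conc, ch, st, 0, seed = s)
    fr <- render_field(tr, optics_config(), "total", seed = 500 + s)
    cp <- count_population(list(fr), builtin_profile("bacteria_sytobc"))
    hits <- hits + (cp$raw_count == nrow(tr$objects))
  }
  expect_gte(hits / n, 0.9)
})

test_that("size exclusion assigns mixed-culture objects to the right gate", {
  mf <- mixed_field(21)
  dc <- dual_count(list(mf$frame), chamber = mf$chamber,
                   staining = mf$staining, min_contrast = 0.08)
  ny <- sum(mf$truth$objects$class == "yeast")
  nb <- sum(mf$truth$objects$class == "bacteria")
  # counts within Poisson-ish tolerance of the truth for this field
  expect_lt(abs(dc$yeast$raw_count - ny), max(2, 0.2 * ny))
  expect_lt(abs(dc$bacteria$raw_count - nb), max(3, 0.2 * nb))
  # bacteria-only field: yeast gate counts nothing
  bf <- mixed_field(22, conc_yeast = 0)
  dcb <- dual_count(list(bf$frame), chamber = bf$chamber,
                    staining = bf$staining)
  expect_equal(dcb$yeast$raw_count, 0L)
  # yeast-only field: bacteria gate counts nothing
  yf <- mixed_field(23, conc_bacteria = 0)
  dcy <- dual_count(list(yf$frame), chamber = yf$chamber,
                    staining = yf$staining)
  expect_equal(dcy$bacteria$raw_count, 0L)
})

test_that("overlapping diameter gates trigger a warning", {
  mf <- mixed_field(31)
  expect_warning(
    dual_count(list(mf$frame), builtin_profile("yeast_aopi_fl1"),
               builtin_profile("bacteria_sytobc"), mf$chamber, mf$staining),
    "overlap")
})

test_that("cross-classification between gates stays below 1 %", {
  tot_y <- 0; tot_b <- 0; y_in_b <- 0; b_in_y <- 0
  for (s in 1:40) {
    mf <- mixed_field(1000 + s)
    dc <- dual_count(list(mf$frame), chamber = mf$chamber,
                     staining = mf$staining)
    cy <- count_population(list(mf$frame), builtin_profile("mixed_yeast"))
    cb <- count_population(list(mf$frame), builtin_profile("mixed_bacteria"))
    my <- match_to_truth(cy$objects, mf$truth)
    mb <- match_to_truth(cb$objects, mf$truth)
    tot_y <- tot_y + sum(mf$truth$objects$class == "yeast")
    tot_b <- tot_b + sum(mf$truth$objects$class == "bacteria")
    y_in_b <- y_in_b + sum(mb$truth_class == "yeast", na.rm = TRUE)
    b_in_y <- b_in_y + sum(my$truth_class == "bacteria", na.rm = TRUE)
  }
  expect_lt(y_in_b / tot_y, 0.01)
  expect_lt(b_in_y / tot_b, 0.01)
})

test_that("viability arithmetic and degenerate cases", {
  expect_equal(viability(100, 0), 1.0)
  expect_equal(viability(100, 25), 0.75)
  expect_warning(v <- viability(0, 0), "undefined")
  expect_true(is.na(v))
  expect_warning(v2 <- viability(10, 12), "clamp")
  expect_equal(v2, 0)
  # via count_result objects
  tot <- count_result("total", 200, 4, 1e6)
  dead <- count_result("dead", 50, 4, 2.5e5)
  expect_equal(viability(tot, dead), 0.75)
})
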