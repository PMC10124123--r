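# synthetic micrograph generator: Poisson counts, rendering, designs

test_that("field truth honours degenerate inputs", {
  ch <- builtin_chamber("SD025", 1e4)
  st <- builtin_staining("mixed_ao_sytobc")
  expect_identical(nrow(sample_field_truth(0, 0, ch, st, 0, 1)$objects), 0L)
  expect_error(sample_field_truth(-1, 0, ch, st, 0, 1),
               class = "mixcount_domain_error")
  tr <- sample_field_truth(5e8, 5e9, ch, st, dead_fraction = 1, seed = 3)
  expect_true(all(tr$objects$viability == "dead"))
  tr2 <- sample_field_truth(5e8, 5e9, ch, st, dead_fraction = 0, seed = 3)
  expect_true(all(tr2$objects$viability == "live"))
})

test_that("object counts follow the closed-form Poisson mean", {
  # 1e7 cells/mL yeast, SD025 (25 um) with 1 mm^2 field, 2x staining:
  # mean per field = 1e7/2 * 1e6 * 25 * 1e-12 = 125
  ch <- builtin_chamber("SD025", 1e6)
  st <- builtin_staining("mixed_ao_sytobc")
  expect_equal(1e7 / st$dilution_factor * chamber_volume_ml(ch), 125)
  n <- vapply(1:200, function(s)
    nrow(sample_field_truth(1e7, 0, ch, st, 0, seed = s)$objects),
    numeric(1))
  se <- sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - 125), 3 * se)
})

test_that("expected counts scale with concentration and chamber volume", {
  st <- builtin_staining("bacteria_sytobc")
  mean_count <- function(conc, field, depth) {
    ch <- chamber_spec("t", depth, field)
    mean(vapply(1:150, function(s)
      nrow(sample_field_truth(0, conc, ch, st, 0, seed = s)$objects),
      numeric(1)))
  }
  base <- mean_count(2e8, 2e4, 25)      # mean 50
  expect_lt(abs(base - 50), 3 * sqrt(50 / 150))
  # doubling concentration, field area, or depth doubles the mean
  expect_lt(abs(mean_count(4e8, 2e4, 25) - 100), 3 * sqrt(100 / 150))
  expect_lt(abs(mean_count(2e8, 4e4, 25) - 100), 3 * sqrt(100 / 150))
  expect_lt(abs(mean_count(2e8, 2e4, 50) - 100), 3 * sqrt(100 / 150))
})

test_that("truth sampling and rendering are deterministic in the seed", {
  ch <- builtin_chamber("SD025", 2e4)
  st <- builtin_staining("mixed_ao_sytobc")
  t1 <- sample_field_truth(5e7, 5e8, ch, st, 0.2, seed = 11)
  t2 <- sample_field_truth(5e7, 5e8, ch, st, 0.2, seed = 11)
  expect_identical(t1, t2)
  f1 <- render_field(t1, optics_config(), "total", seed = 5)
  f2 <- render_field(t2, optics_config(), "total", seed = 5)
  expect_identical(f1$pixels, f2$pixels)
})

test_that("rendering respects channel roles and noise-free limits", {
  ch <- builtin_chamber("SD025", 1e4)
  st <- builtin_staining("yeast_aopi")
  empty <- sample_field_truth(0, 0, ch, st, 0, 1)
  fr <- render_field(empty, optics_config(), "total", noise_sd = 0,
                     background_level = 0, seed = 1)
  expect_true(all(fr$pixels == 0))
  expect_error(render_field(empty, optics_config(), "bacteria", seed = 1),
               class = "mixcount_bad_role")
  # dead channel shows only dead objects
  tr <- sample_field_truth(5e8, 0, ch, st, dead_fraction = 0.5, seed = 9)
  fd <- render_field(tr, optics_config(), "dead", noise_sd = 0,
                     background_level = 0, seed = 1)
  ft <- render_field(tr, optics_config(), "total", noise_sd = 0,
                     background_level = 0, seed = 1)
  expect_lt(sum(fd$pixels > 0), sum(ft$pixels > 0))
})

test_that("a rendered 6 um disk has the analytic half-maximum footprint", {
  fr <- one_disk_frame(diameter_um = 6, peak = 0.8, background = 0.1)
  bg <- median(fr$pixels)
  halfmax_area <- sum(fr$pixels >= bg + 0.5 * (max(fr$pixels) - bg)) *
    fr$pixel_area
  expect_lt(abs(halfmax_area - pi * 3^2) / (pi * 3^2), 0.15)
})

test_that("simulate_experiment emits the declared design structure", {
  opt <- optics_config()
  samples <- simulate_experiment(
    "titration", stock_bacteria = 1e9,
    fractions = c(0.1, 0.25, 0.5, 0.75, 1), titrated = "bacteria",
    replicates = 6, chamber = builtin_chamber("SD025", 4e3),
    staining = builtin_staining("bacteria_sytobc"), seed = 3)
  expect_length(samples, 5 * 6)
  expect_length(samples[[1]]$frames$total, opt$fields_per_sample)
  levs <- vapply(samples, function(s) s$descriptor$level, numeric(1))
  expect_equal(sort(unique(levs)), c(0.1, 0.25, 0.5, 0.75, 1))
  # determinism across runs
  samples2 <- simulate_experiment(
    "titration", stock_bacteria = 1e9,
    fractions = c(0.1, 0.25, 0.5, 0.75, 1), titrated = "bacteria",
    replicates = 6, chamber = builtin_chamber("SD025", 4e3),
    staining = builtin_staining("bacteria_sytobc"), seed = 3)
  expect_identical(samples[[7]]$frames$total[[2]]$pixels,
                   samples2[[7]]$frames$total[[2]]$pixels)
  expect_error(simulate_experiment("titration", fractions = numeric(0)),
               class = "mixcount_domain_error")
  expect_error(simulate_experiment("titration", fractions = 1,
                                   replicates = 0),
               class = "mixcount_domain_error")
})

test_that("ratio_mix boundary samples contain a single organism", {
  samples <- simulate_experiment(
    "ratio_mix", stock_yeast = 5e8, stock_bacteria = 5e9,
    percentages = c(0, 50, 100), replicates = 1,
    chamber = builtin_chamber("SD025", 1e4),
    staining = builtin_staining("mixed_ao_sytobc"), seed = 2)
  expect_length(samples, 3)
  cls0 <- samples[[1]]$truths[[1]]$objects$class   # 0 % yeast
  cls100 <- samples[[3]]$truths[[1]]$objects$class # 100 % yeast
  expect_false("yeast" %in% cls0)
  expect_false("bacteria" %in% cls100)
})

test_that("growth scenarios have the declared shapes", {
  sc <- default_fermentation_scenarios()
  # bacteria: logistic plateau, 24 vs 48 hr within 5 %
  c24 <- scenario_concentration(sc$bacteria, 24)
  c48 <- scenario_concentration(sc$bacteria, 48)
  expect_lt(abs(c48 - c24) / c24, 0.05)
  # yeast: peak at 9 hr above both endpoints
  c0 <- scenario_concentration(sc$yeast, 0)
  c9 <- scenario_concentration(sc$yeast, 9)
  cEnd <- scenario_concentration(sc$yeast, 48)
  expect_gt(c9, c0)
  expect_gt(c9, cEnd)
  expect_equal(c9, 1.82e7)
  # constant scenario: flat
  flat <- growth_scenario("constant", initial = 1e6)
  expect_equal(scenario_concentration(flat, c(0, 3, 48)), rep(1e6, 3))
})

test_that("plate-count simulation matches its Poisson arithmetic", {
  # (1e8 CFU/mL, 10^-5, 0.1 mL) -> mean 100 colonies
  cols <- unlist(lapply(1:200, function(s)
    simulate_plate_counts(1e8, -5, 0.1, 3, seed = s)$colonies))
  se <- sd(cols) / sqrt(length(cols))
  expect_lt(abs(mean(cols) - 100), 3 * se)
  # per-level means 1000 / 100 / 10 at (1e9, -5:-7, 0.1 mL)
  pl <- do.call(rbind, lapply(1:150, function(s)
    simulate_plate_counts(1e9, c(-5, -6, -7), 0.1, 2, seed = 1000 + s)))
  for (e in c(-5, -6, -7)) {
    mu <- 1e9 * 10^e * 0.1
    sub <- pl$colonies[pl$dilution_exponent == e]
    expect_lt(abs(mean(sub) - mu), 3 * sd(sub) / sqrt(length(sub)))
  }
  expect_true(all(simulate_plate_counts(0, -5, 0.1, 4, 1)$colonies == 0))
  expect_error(simulate_plate_counts(1e8, 2, 0.1, 3, 1),
               class = "mixcount_domain_error")
})

test_that("fermentation simulation pairs imaging with plating", {
  sim <- simulate_fermentation(
    chamber = builtin_chamber("SD025", 1e4), replicates = 1, seed = 4)
  times <- vapply(sim$samples, function(s) s$descriptor$time_hr, numeric(1))
  expect_equal(sort(unique(times)), c(0, 3, 6, 9, 12, 24, 48))
  expect_true(all(c("yeast", "bacteria") %in% sim$plate_counts$organism))
  expect_equal(sim$samples[[1]]$descriptor$extra_dilution, 10)
})
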