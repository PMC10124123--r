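# detection engine: background, thresholding, labeling, declustering,
# measurement, filtering

test_that("background estimation is the median, with degenerate handling", {
  fr <- image_frame(matrix(1234, 32, 32))
  expect_equal(estimate_background(fr), 1234)
  # sparse objects: background within 2 % of 0.1 full scale
  fr2 <- one_disk_frame(diameter_um = 6, background = 0.1, noise_sd = 0.01,
                        field_um = 60)
  expect_lt(abs(estimate_background(fr2) - 0.1 * 65535) / (0.1 * 65535),
            0.02)
  sat <- image_frame(matrix(65535, 8, 8))
  expect_warning(b <- estimate_background(sat), "saturated")
  expect_equal(b, 65535)
})

test_that("threshold semantics: percent of background-subtracted range", {
  p10 <- counting_profile(0.5, 5, 0, 10, 0.9)
  flat <- image_frame(matrix(500, 16, 16))
  expect_false(any(threshold_mask(flat, p10)))
  # threshold 100 keeps only frame-maximum pixels
  px <- matrix(100, 10, 10); px[3, 3] <- 900; px[7, 7] <- 900; px[5, 5] <- 899
  p100 <- counting_profile(0.5, 5, 0, 100, 0.9)
  m <- threshold_mask(image_frame(px), p100)
  expect_identical(which(m), which(px == 900))
  # rendered disk at 0.8 scale on 0.1 background, threshold 10:
  # mask area within 10 % of the half-maximum footprint
  fr <- one_disk_frame(diameter_um = 6, peak = 0.8, background = 0.1)
  mask <- threshold_mask(fr, p10)
  bg <- median(fr$pixels)
  halfmax <- sum(fr$pixels >= bg + 0.5 * (max(fr$pixels) - bg))
  expect_lt(abs(sum(mask) - halfmax) / halfmax, 0.10)
})

test_that("labeling is 8-connected and matches a flood-fill oracle", {
  # two disks separated by >= 2 background pixels
  m <- disk_mask(30, 30, rbind(c(9, 9), c(22, 22)), c(5, 5))
  expect_equal(attr(label_components(m), "n_labels"), 2L)
  # diagonal-touching pixels form one component
  d <- matrix(FALSE, 4, 4); d[1, 1] <- TRUE; d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_equal(attr(label_components(d), "n_labels"), 1L)
  # property: identical partitions to brute-force flood fill
  for (s in 1:20) {
    set.seed(s)
    mask <- matrix(runif(64 * 64) < 0.35, 64, 64)
    expect_true(same_partition(label_components(mask),
                               flood_fill_oracle(mask)),
                info = paste("seed", s))
  }
})

test_that("declustering splits touching lobes and partitions parents", {
  # a single disk is untouched
  m1 <- disk_mask(30, 30, rbind(c(15, 15)), 8)
  d1 <- decluster(m1, 0.9)
  expect_equal(d1$n_children, 1L)
  expect_identical(d1$labels > 0, m1)
  # two equal disks overlapping by 20 % of their diameter split in two
  m2 <- disk_mask(40, 60, rbind(c(20, 20), c(20, 36)), c(10, 10))
  d2 <- decluster(m2, 0.9)
  expect_equal(d2$n_children, 2L)
  # children partition the parent exactly
  expect_identical(d2$labels > 0, m2)
  # child centroids within 1 pixel of the true centres
  for (k in 1:2) {
    idx <- which(d2$labels == k, arr.ind = TRUE)
    cen <- colMeans(idx)
    truec <- rbind(c(20, 20), c(20, 36))
    expect_lt(min(sqrt(colSums((t(truec) - cen)^2))), 1.0)
  }
  # area bookkeeping: child areas sum to the parent area
  expect_equal(sum(d2$labels > 0), sum(m2))
  # factor near 0 merges everything into one child
  expect_equal(decluster(m2, 0.01)$n_children, 1L)
})

test_that("declustering children always partition parents (property)", {
  for (s in 1:15) {
    set.seed(s)
    n <- sample(2:5, 1)
    centers <- cbind(sample(10:40, n, TRUE), sample(10:40, n, TRUE))
    mask <- disk_mask(50, 50, centers, sample(3:8, n, TRUE))
    labels <- label_components(mask)
    d <- decluster(labels, 0.9)
    expect_identical(d$labels > 0, mask, info = paste("seed", s))
    # each child lies wholly inside one parent component
    for (k in seq_len(d$n_children)) {
      par <- unique(labels[d$labels == k])
      expect_length(par, 1)
      expect_equal(par, d$parent[k])
    }
  }
})

test_that("measurement formulas hold exactly and on rendered disks", {
  # 1-pixel object: area = pixel_area, diameter = 2 sqrt(area/pi)
  px <- matrix(0, 9, 9); px[5, 5] <- 1000
  fr <- image_frame(px)
  obj <- measure_objects(label_components(px > 0), fr)
  expect_equal(obj$area_um2, 0.5)
  expect_equal(obj$eq_diameter_um, 2 * sqrt(0.5 / pi))
  expect_equal(obj$peak_intensity, 1000)
  # rendered 6 um disk: equivalent diameter within 10 %, roundness >= 0.85
  frd <- one_disk_frame(diameter_um = 6)
  det <- mixcount:::detect_frame(frd, builtin_profile("yeast_aopi_fl1"))
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$eq_diameter_um - 6) / 6, 0.10)
  expect_gte(det$roundness, 0.85)
  expect_lte(det$roundness, 1)
  # invariant identities on arbitrary objects
  mf <- mixed_field(42)
  om <- count_population(list(mf$frame),
                         counting_profile(0.1, 60, 0, 8, 0.9))$objects
  expect_equal(om$area_um2, om$pixel_count * 0.5)
  expect_equal(om$eq_diameter_um, 2 * sqrt(om$area_um2 / pi))
  expect_true(all(om$roundness >= 0 & om$roundness <= 1))
})

test_that("size gates are inclusive and roundness 0 never excludes", {
  obj <- data.frame(eq_diameter_um = c(5.9, 6.0, 3.0, 50.0, 50.1),
                    roundness = c(0, 0.2, 0.9, 1, 1))
  ystd <- filter_objects(obj, builtin_profile("mixed_yeast"))
  expect_equal(ystd$eq_diameter_um, c(6.0, 50.0))  # 5.9 out, bounds in
  bstd <- filter_objects(obj, builtin_profile("mixed_bacteria"))
  expect_equal(bstd$eq_diameter_um, 3.0)
  # roundness_min 0: nothing excluded by shape
  expect_equal(nrow(filter_objects(obj, counting_profile(0.1, 60, 0, 8, .9))),
               nrow(obj))
})

test_that("widening a diameter gate never decreases the count", {
  mf <- mixed_field(7)
  om <- count_population(list(mf$frame),
                         counting_profile(0.1, 60, 0, 8, 0.9))$objects
  gates <- list(c(2, 10), c(1, 20), c(0.5, 40), c(0.2, 60))
  counts <- vapply(gates, function(g)
    nrow(filter_objects(om, counting_profile(g[1], g[2], 0, 8, 0.9))),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})
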