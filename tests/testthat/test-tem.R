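test_that("preprocess inverts and median-filters", {
  cst <- calibrated_image(matrix(40L, 9, 9), 1)
  out <- preprocess(cst, 1)
  expect_true(all(out$pixels == 255 - 40))
  # single-pixel impulse removed by radius-1 median
  m <- matrix(200L, 15, 15); m[8, 8] <- 0L
  out <- preprocess(calibrated_image(m, 1), 1)
  expect_equal(out$pixels[8, 8], 255L - 200L)
  # inversion is an involution (median of a constant-free check on smooth data)
  img <- calibrated_image(matrix(rep(1:15, each = 15), 15, 15), 1)
  twice <- 255L - (255L - img$pixels)
  expect_identical(twice, img$pixels)
  expect_error(preprocess(cst, 0), ">= 1")
})

test_that("otsu_threshold maximizes between-class variance", {
  # two-value image 60%/40%: any cut separates identically; lowest wins
  v <- c(rep(10L, 60), rep(200L, 40))
  img <- calibrated_image(matrix(v, 10, 10), 1)
  thr <- otsu_threshold(img)
  expect_equal(thr, otsu_bruteforce(v, 255))
  expect_equal(thr, 10)
  expect_true(all((img$pixels > thr) == (img$pixels == 200)))
  # seeded bimodal mixtures against the brute-force scan
  set.seed(21)
  for (i in 1:10) {
    v <- as.integer(round(c(stats::rnorm(400, 70, 12), stats::rnorm(200, 180, 15))))
    v <- pmin(pmax(v, 0L), 255L)
    img <- calibrated_image(matrix(v, 20, 30), 1)
    thr <- otsu_threshold(img)
    expect_equal(thr, otsu_bruteforce(v, 255))
    expect_gt(thr, 90); expect_lt(thr, 165)
  }
  # one foreground pixel sits above the threshold
  m <- matrix(5L, 8, 8); m[3, 3] <- 250L
  img <- calibrated_image(m, 1)
  expect_true(m[3, 3] > otsu_threshold(img))
  expect_error(otsu_threshold(calibrated_image(matrix(7L, 5, 5), 1)),
               "constant")
})

test_that("binarize_and_close fills holes and is idempotent", {
  size <- 41
  m <- matrix(0L, size, size)
  m[disk_mask(size, 21, 21, 12)] <- 200L
  m[21, 21] <- 0L  # one-pixel interior hole
  img <- calibrated_image(m, 1)
  mask <- binarize_and_close(img, 100, closing_radius = 2)
  expect_true(mask[21, 21])
  # empty stays empty; closed convex blob unchanged by a second closing
  empty <- binarize_and_close(calibrated_image(matrix(0L, 9, 9), 1), 100, 2)
  expect_false(any(empty))
  again <- spionics:::cpp_morph_disk(spionics:::cpp_morph_disk(mask, 2L, TRUE), 2L, FALSE)
  expect_identical(again, mask)
})

test_that("separate_particles splits touching disks and counts singles", {
  size <- 101
  two <- disk_mask(size, 30, 30, 12) | disk_mask(size, 70, 70, 12)
  lab <- separate_particles(two, 10)
  expect_equal(max(lab), 2)
  one <- disk_mask(size, 50, 50, 15)
  expect_equal(max(separate_particles(one, 10)), 1)
  # two equal disks overlapping by 20% of the radius: split near the waist
  r <- 16
  over <- disk_mask(size, 50, 35, r) | disk_mask(size, 50, 35 + round(1.8 * r), r)
  labo <- separate_particles(over, r)
  expect_equal(max(labo), 2)
  # the two centroids land near the true centres
  cent <- sapply(1:2, function(l) mean(which(labo == l, arr.ind = TRUE)[, 2]))
  expect_equal(sort(cent), c(35, 35 + 1.8 * r), tolerance = 0.1)
  expect_equal(max(separate_particles(matrix(FALSE, 5, 5), 3)), 0)
})

test_that("minimum enclosing circle agrees with the O(n^3) oracle", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(3:15, 1)
    pts <- matrix(stats::runif(2 * n, 0, 50), ncol = 2)
    fast <- min_enclosing_circle(pts)
    slow <- mec_bruteforce(pts)
    expect_equal(fast$radius, slow$radius, tolerance = 1e-9)
    expect_true(all((pts[, 1] - fast$center[1])^2 +
                    (pts[, 2] - fast$center[2])^2 <= fast$radius^2 + 1e-7))
  }
})

test_that("measure_diameters applies the centre + 1 px pad convention", {
  lab <- matrix(0L, 9, 9); lab[5, 5] <- 1L
  d <- measure_diameters(lab, pixel_size_nm = 2)
  expect_equal(d$particles$diameter_px, 1)
  expect_equal(d$particles$diameter_nm, 2)
  # rasterized disk radius 10: diameter 20 +/- 1 px, matches the brute oracle
  size <- 31
  lab <- matrix(0L, size, size)
  lab[disk_mask(size, 16, 16, 10)] <- 1L
  d <- measure_diameters(lab, 1)
  expect_lt(abs(d$particles$diameter_px - 20), 1 + 1e-9)
  pts <- which(lab == 1L, arr.ind = TRUE)
  expect_equal(d$particles$diameter_px,
               2 * mec_bruteforce(cbind(pts[, 2], pts[, 1]))$radius + 1,
               tolerance = 1e-9)
  # two labels, records ordered by label id
  lab[3, 3] <- 2L
  d2 <- measure_diameters(lab, 1)
  expect_equal(d2$particles$label, c(1, 2))
  expect_gt(d2$particles$diameter_px[1], d2$particles$diameter_px[2])
})

test_that("pipeline is deterministic and recovers a small ground truth", {
  pop <- gen_diameters(20, 12, 1.15, seed = 61)
  g <- gen_stem_image(pop$diameters_nm, image_size_px = 700,
                      pixel_size_nm = 0.2, noise_sd = 8, seed = 62)
  res1 <- run_tem_pipeline(g$image)
  res2 <- run_tem_pipeline(g$image)
  expect_identical(res1$segmentation$labels, res2$segmentation$labels)
  expect_equal(res1$distribution$summary$n, 20)
  # the +1 px measurement pad dominates the error at this small n; the 2%
  # bound of the full-scale recovery criterion lives in test-acceptance.R
  expect_equal(res1$distribution$summary$mean_nm, mean(pop$diameters_nm),
               tolerance = 0.03)
  # blank image fails at the threshold stage
  blank <- calibrated_image(matrix(200L, 64, 64), 0.2)
  expect_error(run_tem_pipeline(blank), "constant")
})

test_that("recovered distribution peaks at approximately 12 nm", {
  pop <- gen_diameters(200, 12, 1.2, seed = 71)
  g <- gen_stem_image(pop$diameters_nm, seed = 72)
  res <- run_tem_pipeline(g$image)
  s <- res$distribution$summary
  expect_equal(s$n, 200)
  # true lognormal mode is 12/exp(log(1.2)^2) ~ 11.6, straddling the 11- and
  # 12-centred 1-nm bins: "approximately 12 nm" = within one bin of 12
  expect_lte(abs(s$mode_nm - 12), 1)
  # and the bin containing 12 nm is at (or tied with) the histogram peak
  h <- res$distribution$histogram
  i12 <- findInterval(12, h$edges_nm)
  expect_gte(h$counts[i12], max(h$counts) - 1)
})
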