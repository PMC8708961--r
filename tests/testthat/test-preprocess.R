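test_that("merge places anterior left, posterior right, and inverts by split", {
  a <- matrix(1, 1024, 256); p <- matrix(2, 1024, 256)
  m <- merge_views(list(anterior = a, posterior = p))
  expect_equal(dim(m), c(1024, 512))
  expect_true(all(m[, 1:256] == 1) && all(m[, 257:512] == 2))
  set.seed(2)
  a2 <- matrix(rpois(64 * 32, 5), 64); p2 <- matrix(rpois(64 * 32, 5), 64)
  m2 <- merge_views(list(anterior = a2, posterior = p2))
  expect_identical(m2[, 1:32], a2)
  expect_identical(m2[, 33:64], p2)
  expect_error(merge_views(list(anterior = a2, posterior = matrix(0, 32, 32))),
               "same shape")
})

test_that("channel replication yields three equal planes", {
  g <- matrix(rnorm(100), 10)
  r <- replicate_channels(g)
  expect_equal(dim(r), c(10, 10, 3))
  expect_identical(r[, , 1], g)
  expect_identical(r[, , 2], r[, , 3])
  expect_identical(replicate_channels(matrix(0, 4, 4)),
                   array(0, c(4, 4, 3)))
  expect_error(replicate_channels(array(0, c(2, 2, 2))), "2-D")
})

test_that("roi_mean matches closed forms and a brute-force loop", {
  g <- matrix(7, 50, 50)
  expect_equal(roi_mean(g, c(10, 20, 10, 20)), 7)
  g2 <- matrix(c(1, 3, 2, 4), 2, 2)  # half-open 2x2 window over {1,2,3,4}
  expect_equal(roi_mean(g2, c(0, 2, 0, 2)), 2.5)
  set.seed(5)
  g3 <- matrix(runif(40 * 30), 40, 30)
  roi <- c(3, 17, 5, 22)
  acc <- 0; cnt <- 0
  for (r in (roi[1] + 1):roi[2]) for (cc in (roi[3] + 1):roi[4]) {
    acc <- acc + g3[r, cc]; cnt <- cnt + 1
  }
  expect_equal(roi_mean(g3, roi), acc / cnt)
  expect_error(roi_mean(g3, c(5, 5, 0, 10)), "empty")
  expect_error(roi_mean(g3, c(0, 50, 0, 10)), "bounds")
})

test_that("ROI normalization standardizes scale with a guarded floor", {
  set.seed(6)
  g <- matrix(runif(64 * 64, 1, 10), 64)
  roi <- c(10, 20, 10, 20)
  m <- roi_mean(g, roi)
  out <- normalize_by_roi(g, m)
  expect_equal(roi_mean(out, roi), 1)
  # zero reference mean divides by the floor, stays finite
  expect_true(all(is.finite(normalize_by_roi(g, 0, mean_floor = 1e-3))))
  # composing two normalizations equals one with the product of means
  m2 <- 3.7
  expect_equal(normalize_by_roi(normalize_by_roi(g, m), m2), g / (m * m2))
})

test_that("downscale keeps constants, the shape contract, and the mean", {
  cst <- array(3.5, c(1024, 512, 3))
  d <- downscale(cst, c(256, 256))
  expect_equal(dim(d), c(256, 256, 3))
  expect_true(all(abs(d - 3.5) < 1e-12))
  # smooth gradient: area reduction preserves the mean exactly,
  # bilinear within 2%
  gr <- outer(seq(0, 1, length.out = 512), seq(2, 5, length.out = 256))
  expect_equal(mean(downscale(gr, c(128, 64))), mean(gr), tolerance = 1e-12)
  expect_equal(mean(downscale(gr, c(100, 60), interpolation = "bilinear")),
               mean(gr), tolerance = 0.02)
  expect_error(downscale(gr, c(1024, 64)), "exceeds")
})

test_that("preprocess_pair equals the staged manual composition", {
  pair <- generate_phantom(tiny_spec(), 1, seed = 12)
  cfg <- preproc_config(target_size = c(64, 64))
  got <- preprocess_pair(pair, cfg)
  merged <- cbind(pair$anterior, pair$posterior)
  roi <- scintimet:::default_thigh_roi(nrow(merged), ncol(merged))
  stacked <- array(merged, c(dim(merged), 3))
  m <- mean(merged[(roi[1] + 1):roi[2], (roi[3] + 1):roi[4]])
  manual <- downscale(stacked / m, c(64, 64))
  expect_equal(got$pixels, manual, tolerance = 1e-12)
  expect_equal(got$roi_mean_used, m)
  expect_equal(dim(got$pixels), c(64, 64, 3))
})

test_that("preprocessing is invariant to global activity scale", {
  cfg <- preproc_config(target_size = c(64, 64))
  for (seed in 1:4) {
    pair <- generate_phantom(tiny_spec(), seed %% 2, seed = seed)
    base <- preprocess_pair(pair, cfg)
    for (k in c(0.25, 42)) {
      scaled <- list(anterior = pair$anterior * k, posterior = pair$posterior * k,
                     label = pair$label, patient_id = pair$patient_id)
      expect_equal(preprocess_pair(scaled, cfg)$pixels, base$pixels,
                   tolerance = 1e-6)
    }
  }
})

test_that("channel equality survives the whole chain", {
  pair <- generate_phantom(tiny_spec(), 0, seed = 31)
  px <- preprocess_pair(pair, preproc_config(target_size = c(32, 32)))$pixels
  expect_identical(px[, , 1], px[, , 2])
  expect_identical(px[, , 2], px[, , 3])
})

test_that("preprocess_batch agrees with per-pair preprocessing", {
  scans <- generate_scans(tiny_spec(), 3, seed = 8)
  cfg <- preproc_config(target_size = c(32, 32))
  b <- preprocess_batch(scans, cfg)
  expect_equal(dim(b$x), c(32, 32, 3, 3))
  for (i in 1:3) {
    expect_equal(b$x[, , , i], preprocess_pair(scans[[i]], cfg)$pixels,
                 tolerance = 1e-12)
  }
  expect_equal(b$labels, vapply(scans, function(s) s$label, integer(1)))
})

test_that("preproc_config validates the ROI rectangle and floor", {
  expect_error(preproc_config(thigh_roi = c(10, 5, 0, 4)), "half-open")
  expect_error(preproc_config(mean_floor = 0), "positive")
  # reference rectangle reproduces the clinical coordinates at full size
  expect_equal(scintimet:::default_thigh_roi(1024, 512), c(700, 820, 32, 96))
})
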