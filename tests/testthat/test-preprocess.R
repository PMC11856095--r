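test_that("normalize_image rescales exactly and handles degenerate input", {
  expect_equal(normalize_image(matrix(c(0, 100, 50, 200), 2, 2)),
               matrix(c(0, 0.5, 0.25, 1), 2, 2))
  # idempotent on an already-normalized image
  ramp <- matrix(seq(0, 1, length.out = 16), 4, 4)
  expect_equal(normalize_image(ramp), ramp)
  # constant image maps to zeros with a logged warning
  expect_message(z <- normalize_image(matrix(7, 2, 2)), "constant")
  expect_equal(z, matrix(0, 2, 2))
})

test_that("normalize_image hits 0 and 1 exactly on random non-constant images", {
  set.seed(21)
  for (i in 1:20) {
    img <- matrix(runif(100, -50, 800), 10, 10)
    out <- normalize_image(img)
    expect_identical(range(out), c(0, 1))
  }
})

test_that("enhance_contrast stretches between percentiles and clips", {
  ramp <- matrix(seq(0, 1, length.out = 101), 1, 101)
  # identity cases
  expect_equal(enhance_contrast(ramp, 0, 100), ramp)
  # 25th/75th percentile of the ramp are exactly 0.25/0.75 (type-7 quantile)
  out <- enhance_contrast(ramp, 25, 75)
  expect_equal(out[ramp <= 0.25], rep(0, sum(ramp <= 0.25)))
  expect_equal(out[ramp >= 0.75], rep(1, sum(ramp >= 0.75)))
  mid <- ramp > 0.25 & ramp < 0.75
  expect_equal(out[mid], (ramp[mid] - 0.25) / 0.5)
  expect_error(enhance_contrast(ramp, 50, 50), class = "lungprep_validation_error")
  expect_message(same <- enhance_contrast(matrix(c(0.5, 0.5, 0.5, 1), 2, 2), 1, 60),
                 "unchanged")
  expect_equal(same, matrix(c(0.5, 0.5, 0.5, 1), 2, 2))
})

test_that("otsu_threshold separates a bimodal image and matches the brute-force oracle", {
  img <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10, 10)
  o <- otsu_threshold(img)
  expect_s3_class(o, "otsu_result")
  expect_gt(o$threshold, 0.1)
  expect_lt(o$threshold, 0.9)
  expect_identical(sum(o$histogram), 100L)
  # unbalanced class proportions keep the separating property
  img2 <- matrix(c(rep(0.1, 25), rep(0.9, 75)), 10, 10)
  o2 <- otsu_threshold(img2)
  expect_gt(o2$threshold, 0.1)
  expect_lt(o2$threshold, 0.9)

  set.seed(33)
  for (i in 1:10) {
    img <- matrix(runif(256), 16, 16)
    got <- otsu_threshold(img)
    oracle <- brute_force_otsu(img)
    expect_equal(got$threshold, oracle$threshold)
    expect_equal(got$between_class_variance, oracle$between_class_variance,
                 tolerance = 1e-12)
  }
  expect_error(otsu_threshold(matrix(0.5, 3, 3)), class = "lungprep_validation_error")
})

test_that("binarize_lungs keeps low-density pixels", {
  expect_identical(binarize_lungs(matrix(c(0.1, 0.9), 1, 2), 0.5),
                   matrix(c(1L, 0L), 1, 2))
  expect_identical(binarize_lungs(matrix(0.8, 2, 2), 0.5), matrix(0L, 2, 2))
  # Otsu threshold on a bimodal image recovers the low class exactly
  img <- matrix(runif(400, 0, 0.3), 20, 20)
  img[1:10, ] <- runif(200, 0.7, 1)
  o <- otsu_threshold(img)
  expect_identical(binarize_lungs(img, o$threshold),
                   matrix(as.integer(img < o$threshold), 20, 20))
})

test_that("identify_body keeps the largest filled dense component", {
  m <- matrix(0L, 20, 20)
  m[2:15, 2:15] <- 1L          # big blob with a hole
  m[6:9, 6:9] <- 0L
  m[18:19, 18:19] <- 1L        # small separate blob
  body <- identify_body(m)
  expect_true(all(body[2:15, 2:15] == 1L))   # hole filled
  expect_true(all(body[18:19, 18:19] == 0L)) # small blob dropped
  expect_error(identify_body(matrix(0L, 4, 4)), class = "lungprep_validation_error")
})

test_that("clear_outside_body is a pointwise AND", {
  ph <- tiny_phantom()
  cand <- matrix(1L, 128, 128)       # everything a candidate
  inside <- clear_outside_body(cand, ph$body_mask)
  expect_identical(inside, ph$body_mask)
  expect_error(clear_outside_body(matrix(1L, 2, 2), matrix(1L, 3, 3)),
               class = "lungprep_validation_error")
})

test_that("segment_slice recovers phantom lungs and excludes the table", {
  ph <- tiny_phantom()
  m <- segment_slice(ph$image)
  expect_gte(iou(m, ph$lung_mask), 0.9)

  pht <- tiny_phantom(defects = "TABLE_ARTIFACT")
  mt <- segment_slice(pht$image)
  table_region <- pht$image > 0.7 * 255 & pht$body_mask == 0L
  expect_identical(sum(mt[table_region]), 0L)

  # determinism: identical input and config give bit-identical masks
  expect_identical(segment_slice(ph$image), m)
})
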