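test_that("boundary_filter flags edge contact within the margin", {
  m <- matrix(0L, 40, 40); m[1, 30] <- 1L
  expect_identical(boundary_filter(m), "BORDER_TOUCH")
  inside <- matrix(0L, 40, 40); inside[3:10, 3:10] <- 1L
  expect_null(boundary_filter(inside, filter_config(border_margin_px = 1)))
  expect_identical(boundary_filter(inside, filter_config(border_margin_px = 3)),
                   "BORDER_TOUCH")
  expect_null(boundary_filter(matrix(0L, 5, 5)))  # vacuous pass
})

test_that("object_count_filter enforces the 1-2 object rule", {
  mk <- function(n) component_stats({
    m <- matrix(0L, 30, 60)
    for (i in seq_len(n)) m[10:15, (i * 12 - 5):(i * 12 - 2)] <- 1L
    m
  })
  cfg <- filter_config()
  expect_null(object_count_filter(mk(1), cfg))
  expect_null(object_count_filter(mk(2), cfg))
  expect_identical(object_count_filter(mk(3), cfg), "OBJECT_COUNT")
  expect_identical(object_count_filter(mk(0), cfg), "OBJECT_COUNT")
})

test_that("shape_filter checks per-object area (inclusive at 5%) and aspect", {
  # 512x512 with a 3.0% object: 7864 px < 5%
  m <- matrix(0L, 512, 512)
  m[101:200, 101:178] <- 1L                   # 100x78 = 7800 px ~ 2.98%
  st <- component_stats(m)
  expect_identical(shape_filter(st, filter_config()), "AREA_TOO_SMALL")

  bar <- matrix(0L, 512, 512)
  bar[200:239, 50:449] <- 1L                  # 400 wide x 40 tall, ratio 10
  expect_true("BAD_ASPECT" %in% shape_filter(component_stats(bar), filter_config()))

  # exactly 5.0% with ratio 1.5 passes (inclusive cutoff)
  sq <- matrix(0L, 100, 100)
  sq[11:30, 11:35] <- 1L                      # 20x25 = 500 px = 5.0%, ratio 1.25
  expect_identical(length(shape_filter(component_stats(sq), filter_config())), 0L)
})

test_that("compute_roi_bbox returns union extremes", {
  m <- matrix(0L, 50, 50); m[10:20, 5:15] <- 1L
  expect_identical(compute_roi_bbox(m),
                   c(row_min = 10L, col_min = 5L, row_max = 20L, col_max = 15L))
  s <- matrix(0L, 10, 10); s[7, 3] <- 1L
  expect_identical(unname(compute_roi_bbox(s)), c(7L, 3L, 7L, 3L))
  two <- matrix(0L, 500, 500)
  two[100:400, 50:200] <- 1L; two[150:380, 300:450] <- 1L
  expect_identical(unname(compute_roi_bbox(two)), c(100L, 50L, 400L, 450L))
  expect_error(compute_roi_bbox(matrix(0L, 3, 3)), class = "lungprep_validation_error")
})

test_that("apply_filters accepts clean phantoms and reports defect reasons", {
  ph <- tiny_phantom(size = 256)
  res <- apply_filters(ph$lung_mask)
  expect_true(res$accepted)
  expect_identical(res$reasons, character(0))
  expect_identical(res$roi_bbox, compute_roi_bbox(ph$lung_mask))
  expect_identical(res$mask, ph$lung_mask)    # pure classification

  shifted <- tiny_phantom(size = 256, defects = "BORDER_TOUCH")
  res <- apply_filters(shifted$lung_mask)
  expect_false(res$accepted)
  expect_true("BORDER_TOUCH" %in% res$reasons)
  expect_null(res$roi_bbox)

  speck <- tiny_phantom(size = 256, defects = "EXTRA_OBJECT")
  res <- apply_filters(speck$lung_mask)
  expect_false(res$accepted)
  expect_true(all(c("OBJECT_COUNT", "AREA_TOO_SMALL") %in% res$reasons))

  merged <- tiny_phantom(size = 256, defects = "MERGED_LUNGS")
  expect_true(apply_filters(merged$lung_mask)$accepted)  # 1 object is allowed
})

test_that("filter verdicts are invariant under relabeling (mask transposition of labels)", {
  # permuting component discovery order by flipping the mask must not
  # change the verdict
  ph <- tiny_phantom(size = 128)
  m <- ph$lung_mask
  flipped <- m[, rev(seq_len(ncol(m)))]
  expect_identical(apply_filters(m)$accepted, apply_filters(flipped)$accepted)
  expect_identical(sort(apply_filters(m)$reasons), sort(apply_filters(flipped)$reasons))
})

test_that("filter_config validates bounds", {
  expect_error(filter_config(min_area_frac = 0), class = "lungprep_validation_error")
  expect_error(filter_config(aspect_min = 3, aspect_max = 1),
               class = "lungprep_validation_error")
  expect_error(filter_config(min_objects = 3, max_objects = 2),
               class = "lungprep_validation_error")
})

test_that("process_directory writes accepted masks and a faithful summary", {
  d <- withr::local_tempdir()
  phantoms <- c(
    lapply(1:4, function(i) tiny_phantom(size = 128, seed = i)),
    list(tiny_phantom(size = 128, seed = 5, defects = "EXTRA_OBJECT"))
  )
  names(phantoms) <- sprintf("p%02d", seq_along(phantoms))
  write_cohort(phantoms, file.path(d, "img"), file.path(d, "msk"))

  summary <- process_directory(file.path(d, "img"), file.path(d, "out"),
                               pipeline_config())
  expect_identical(summary$n_images, 5L)
  expect_identical(summary$n_accepted, 4L)
  expect_identical(summary$rejection_counts$OBJECT_COUNT, 1L)
  expect_equal(summary$pass_rate, 0.8)
  written <- list.files(file.path(d, "out"), pattern = "^p.*png$")
  expect_identical(length(written), 4L)
  expect_true(file.exists(file.path(d, "out", "report.csv")))
  expect_true(file.exists(file.path(d, "out", "summary.json")))
  expect_true(file.exists(file.path(d, "out", "config_used.yaml")))

  # every written mask re-passes the filters (post-hoc re-verification)
  for (f in written) {
    expect_true(apply_filters(read_mask(file.path(d, "out", f)))$accepted)
  }
})
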