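test_that("confusion counts enumerate pixels and conserve the total", {
  p <- matrix(c(1L, 0L, 1L, 0L), 2, 2)   # column-major: [[1,1],[0,0]]
  g <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  cts <- confusion(p, g)
  expect_identical(cts, list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))

  set.seed(8)
  m <- random_mask(16, 16)
  same <- confusion(m, m)
  expect_identical(same$tp, sum(m))
  expect_identical(same$fp + same$fn, 0L)
  expect_identical(same$tn, length(m) - sum(m))
  expect_error(confusion(m, matrix(0L, 2, 2)), class = "lungprep_validation_error")
})

test_that("iou, dice and iou_loss match hand-counted examples", {
  # two 2x2 blocks overlapping in 2 px: intersection 2, union 6
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
  b <- matrix(0L, 4, 4); b[1:2, 2:3] <- 1L
  expect_equal(iou(a, b), 2 / 6)
  expect_equal(dice(a, b), 0.5)
  expect_equal(iou_loss(a, b), 1 - 1 / 3)

  expect_equal(iou(a, a), 1)
  disjoint <- matrix(0L, 4, 4); disjoint[3:4, 3:4] <- 1L
  expect_equal(iou(a, disjoint), 0)
  expect_equal(iou_loss(a, disjoint), 1)

  # both-empty convention
  e <- matrix(0L, 3, 3)
  expect_equal(suppressMessages(iou(e, e)), 1)
  expect_equal(suppressMessages(dice(e, e)), 1)
})

test_that("dice, iou and the confusion total satisfy their algebraic identities", {
  set.seed(9)
  for (i in 1:50) {
    p <- random_mask(16, 16, runif(1, 0.1, 0.9))
    g <- random_mask(16, 16, runif(1, 0.1, 0.9))
    iv <- iou(p, g)
    expect_equal(dice(p, g), 2 * iv / (1 + iv), tolerance = 1e-12)
    expect_equal(iou_loss(p, g), 1 - iv, tolerance = 1e-15)
    expect_gte(dice(p, g), iv)
    expect_equal(iou(g, p), iv)                       # symmetry
    cts <- confusion(p, g)
    expect_identical(cts$tp + cts$fp + cts$fn + cts$tn, 256L)
  }
})

test_that("precision/recall/specificity honor the 0/0 convention", {
  expect_equal(unname(precision_recall_specificity(
    list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))), c(0.5, 0.5, 0.5))
  perfect <- confusion(matrix(1L, 2, 2), matrix(1L, 2, 2))
  expect_equal(unname(precision_recall_specificity(perfect))[1:2], c(1, 1))
  expect_message(
    prs <- precision_recall_specificity(list(tp = 0L, fp = 0L, fn = 5L, tn = 5L)),
    "0/0")
  expect_equal(unname(prs[c("precision", "recall")]), c(1, 0))
})

test_that("plc and asymmetry follow their definitions", {
  m <- matrix(0L, 512, 512); m[seq_len(26214)] <- 1L
  expect_equal(plc(m), 100 * 26214 / 262144)
  expect_equal(plc(matrix(0L, 4, 4)), 0)
  expect_equal(plc(matrix(1L, 4, 4)), 100)

  sym <- matrix(0L, 10, 10); sym[3:6, 2:4] <- 1L; sym[3:6, 7:9] <- 1L
  expect_equal(asymmetry(sym), 0)
  asym <- matrix(0L, 10, 20)
  asym[1:10, 1:10][seq_len(100)] <- 1L   # A_L = 100
  asym[1:4, 11:20][seq_len(40)] <- 1L    # A_R = 40
  expect_equal(asymmetry(asym), 0.6)
  onesided <- matrix(0L, 6, 6); onesided[2:4, 4:6] <- 1L
  expect_equal(asymmetry(onesided), 1)
  expect_equal(asymmetry(matrix(0L, 5, 5)), 0)
})

test_that("weighted_quality_score combines IoU, symmetry and the PLC gate", {
  cfg <- qc_config()
  expect_equal(weighted_quality_score(1, 0, 20, cfg), 1)
  expect_equal(weighted_quality_score(0.9, 0.2, 2, cfg), (0.9 + 0.8 + 0) / 3)
  w_iou_only <- qc_config(weights = c(1, 0, 0))
  expect_equal(weighted_quality_score(0.73, 0.9, 2, w_iou_only), 0.73)
  expect_error(weighted_quality_score(1.2, 0, 20, cfg),
               class = "lungprep_validation_error")
})

test_that("qc_mask raises exactly the designated flags at the thresholds", {
  # symmetric in-range reference case: no flags
  ph <- tiny_phantom()
  rep <- qc_mask(ph$lung_mask, ph$lung_mask)
  expect_identical(rep$flags, character(0))
  expect_equal(unname(rep$metrics["iou"]), 1)

  # iou 0.80 < 0.85: LOW_IOU only (mask kept symmetric and in range)
  truth <- matrix(0L, 100, 100)
  truth[31:70, 11:35] <- 1L; truth[31:70, 66:90] <- 1L   # 2000 px total
  pred <- truth
  pred[31:38, 11:35] <- 0L; pred[31:38, 66:90] <- 0L     # drop 400 px: iou = 1600/2000 = 0.80
  r <- qc_mask(pred, truth)
  expect_equal(unname(r$metrics["iou"]), 0.80)
  expect_identical(r$flags, "LOW_IOU")

  # asymmetry 0.6 > 0.5: ASYMMETRIC only (PLC kept in range, no reference)
  asymm <- matrix(0L, 40, 40)
  asymm[11:30, 6:15] <- 1L            # left 200 px
  asymm[11:18, 26:35] <- 1L           # right 80 px -> asym = 120/200 = 0.6
  r <- suppressMessages(qc_mask(asymm))
  expect_equal(r$asymmetry, 0.6)
  expect_identical(r$flags, "ASYMMETRIC")

  # PLC 3% and 60% vs [5, 50]: PLC_OUT_OF_RANGE only
  low <- matrix(0L, 100, 100)
  low[49:52, 21:45] <- 1L; low[49:52, 56:80] <- 1L   # 200 px = 2%
  r <- suppressMessages(qc_mask(low))
  expect_identical(r$flags, "PLC_OUT_OF_RANGE")
  high <- matrix(0L, 100, 100)
  high[21:80, 1:100] <- 1L                           # 6000 px = 60%
  r <- suppressMessages(qc_mask(high))
  expect_equal(r$plc, 60)
  expect_identical(r$flags, "PLC_OUT_OF_RANGE")
})

test_that("qc_directory pairs masks and writes a CSV report", {
  d <- withr::local_tempdir()
  dir.create(file.path(d, "pred")); dir.create(file.path(d, "truth"))
  ph <- tiny_phantom()
  write_mask(ph$lung_mask, file.path(d, "pred", "a.png"))
  write_mask(ph$lung_mask, file.path(d, "truth", "a.png"))
  write_mask(ph$lung_mask, file.path(d, "pred", "b.png"))  # no reference
  out_csv <- file.path(d, "report.csv")
  rep <- suppressMessages(qc_directory(file.path(d, "pred"), file.path(d, "truth"),
                                       out_csv))
  expect_identical(nrow(rep), 2L)
  expect_equal(rep$iou[rep$filename == "a.png"], 1)
  expect_true(is.na(rep$iou[rep$filename == "b.png"]))
  expect_true(file.exists(out_csv))
})
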