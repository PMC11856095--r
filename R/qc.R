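## mask_qc: agreement metrics (IoU/Dice/precision/recall/specificity, IoU
## loss), reference-free plausibility (PLC, left-right asymmetry), threshold
## flags and the weighted quality score.

QC_FLAGS <- c("LOW_IOU", "ASYMMETRIC", "PLC_OUT_OF_RANGE")

#' Quality-control configuration
#'
#' Thresholds used when flagging masks: reference agreement is adequate at
#' IoU >= 0.85; asymmetry above 50% between left and right lung areas is
#' implausible; masks covering < 5% or > 50% of the slice are out of the
#' anatomical coverage range.
#'
#' @param iou_min minimum acceptable IoU against the reference (default 0.85).
#' @param asym_max maximum acceptable left-right asymmetry (default 0.5).
#' @param plc_min,plc_max acceptable percentage-of-lung-coverage band in
#'   percent (defaults 5 and 50).
#' @param weights length-3 non-negative weights (IoU, symmetry, PLC) summing
#'   to 1 for the weighted quality score (default equal thirds).
#' @return object of class `qc_config`.
#' @export
qc_config <- function(iou_min = 0.85, asym_max = 0.5, plc_min = 5,
                      plc_max = 50, weights = c(1, 1, 1) / 3) {
  if (length(weights) != 3L || any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop_validation("weights must be 3 non-negative values summing to 1")
  }
  if (!(plc_min < plc_max)) stop_validation("plc_min must be < plc_max")
  structure(list(iou_min = iou_min, asym_max = asym_max, plc_min = plc_min,
                 plc_max = plc_max, weights = as.numeric(weights)),
            class = "qc_config")
}

#' Pixel confusion counts between a prediction and a reference mask
#'
#' @param pred,truth 0/1 matrices of identical shape.
#' @return named list `tp`, `fp`, `fn`, `tn`; the four counts always sum to
#'   the pixel count.
#' @export
confusion <- function(pred, truth) {
  assert_mask(pred, "pred"); assert_mask(truth, "truth")
  assert_same_shape(pred, truth)
  p <- as_mask(pred); g <- as_mask(truth)
  tp <- sum(p == 1L & g == 1L)
  fp <- sum(p == 1L & g == 0L)
  fn <- sum(p == 0L & g == 1L)
  tn <- length(p) - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Intersection over Union (Jaccard index)
#'
#' `|P intersect G| / |P union G|`; 1 by convention (logged) when both masks
#' are empty.
#'
#' @inheritParams confusion
#' @return scalar in \[0, 1\].
#' @export
iou <- function(pred, truth) {
  assert_mask(pred, "pred"); assert_mask(truth, "truth")
  assert_same_shape(pred, truth)
  p <- as_mask(pred); g <- as_mask(truth)
  inter <- sum(p & g)
  union <- sum(p | g)
  if (union == 0L) {
    lp_log("info", "both masks empty: IoU = 1 by convention")
    return(1)
  }
  inter / union
}

#' Dice coefficient
#'
#' `2 |P intersect G| / (|P| + |G|)`; 1 by convention when both masks are
#' empty. Related to IoU by `Dice = 2 IoU / (1 + IoU)`.
#'
#' @inheritParams confusion
#' @return scalar in \[0, 1\].
#' @export
dice <- function(pred, truth) {
  assert_mask(pred, "pred"); assert_mask(truth, "truth")
  assert_same_shape(pred, truth)
  p <- as_mask(pred); g <- as_mask(truth)
  denom <- sum(p) + sum(g)
  if (denom == 0L) {
    lp_log("info", "both masks empty: Dice = 1 by convention")
    return(1)
  }
  2 * sum(p & g) / denom
}

#' IoU loss
#'
#' `1 - IoU(P, G)`: the overlap-based loss used to train segmentation
#' networks under class imbalance.
#'
#' @inheritParams confusion
#' @return scalar in \[0, 1\].
#' @export
iou_loss <- function(pred, truth) 1 - iou(pred, truth)

#' Precision, recall and specificity from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`; any 0/0 is defined as 1 with a logged
#' warning.
#'
#' @param c confusion counts from [confusion()].
#' @return named numeric vector `precision`, `recall`, `specificity`.
#' @export
precision_recall_specificity <- function(c) {
  ratio <- function(num, denom, what) {
    if (denom == 0) {
      lp_log("warn", what, " is 0/0: defined as 1 by convention")
      return(1)
    }
    num / denom
  }
  c(precision = ratio(c$tp, c$tp + c$fp, "precision"),
    recall = ratio(c$tp, c$tp + c$fn, "recall"),
    specificity = ratio(c$tn, c$tn + c$fp, "specificity"))
}

#' Percentage of lung coverage (PLC)
#'
#' Mask foreground area as a percentage of the total pixel count.
#'
#' @param mask 0/1 matrix.
#' @return scalar in \[0, 100\] (percent).
#' @export
plc <- function(mask) {
  assert_mask(mask)
  100 * sum(as_mask(mask)) / length(mask)
}

#' Left-right asymmetry of a lung mask
#'
#' The image is split at the vertical midline (first `floor(W/2)` columns =
#' left half); asymmetry is `|A_L - A_R| / max(A_L, A_R)` of the foreground
#' areas per half, and 0 when both halves are empty. A value above 0.5
#' (i.e. 50%) is anatomically implausible for paired lung fields.
#'
#' @param mask 0/1 matrix.
#' @return scalar in \[0, 1\].
#' @export
asymmetry <- function(mask) {
  assert_mask(mask)
  m <- as_mask(mask)
  w <- ncol(m)
  half <- w %/% 2L
  a_l <- if (half >= 1L) sum(m[, seq_len(half), drop = FALSE]) else 0L
  a_r <- sum(m) - a_l
  if (a_l == 0L && a_r == 0L) return(0)
  abs(a_l - a_r) / max(a_l, a_r)
}

#' Weighted mask quality score
#'
#' Linear combination `w_iou * iou + w_sym * (1 - asymmetry) + w_plc *
#' in_range(plc)`, where the PLC component is 1 when the coverage lies
#' inside `[plc_min, plc_max]` and 0 otherwise. With the default equal
#' weights the score lies in \[0, 1\] and equals 1 only for a perfectly
#' agreeing, symmetric, in-range mask.
#'
#' @param iou_val IoU against the reference (or 1 when no reference exists).
#' @param asym asymmetry in \[0, 1\].
#' @param plc_val coverage in percent.
#' @param cfg a [qc_config()].
#' @return scalar in \[0, 1\].
#' @export
weighted_quality_score <- function(iou_val, asym, plc_val, cfg = qc_config()) {
  if (iou_val < 0 || iou_val > 1 || asym < 0 || asym > 1 || plc_val < 0 || plc_val > 100) {
    stop_validation("inputs out of range for weighted_quality_score")
  }
  plc_component <- as.numeric(plc_val >= cfg$plc_min && plc_val <= cfg$plc_max)
  w <- cfg$weights
  w[1] * iou_val + w[2] * (1 - asym) + w[3] * plc_component
}

#' Full quality-control report for a mask
#'
#' Computes agreement metrics against the reference (when given),
#' reference-free plausibility statistics, threshold flags and the weighted
#' quality score. Without a reference, the IoU term of the score uses a
#' placeholder of 1 (logged) and no agreement metrics or `LOW_IOU` flag are
#' produced.
#'
#' @param pred 0/1 matrix under evaluation.
#' @param truth optional 0/1 reference matrix of the same shape.
#' @param cfg a [qc_config()].
#' @return object of class `qc_report`: list with `metrics` (named numeric
#'   vector or `NULL`), `plc`, `asymmetry`, `weighted_score` and `flags`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(size = c(96, 96), noise_sigma = 0))
#' qc_mask(ph$lung_mask, ph$lung_mask)
qc_mask <- function(pred, truth = NULL, cfg = qc_config()) {
  assert_mask(pred, "pred")
  metrics <- NULL
  if (!is.null(truth)) {
    assert_mask(truth, "truth")
    assert_same_shape(pred, truth)
    cts <- confusion(pred, truth)
    iou_val <- iou(pred, truth)
    metrics <- c(iou = iou_val, dice = dice(pred, truth),
                 precision_recall_specificity(cts),
                 iou_loss = 1 - iou_val)
  } else {
    lp_log("info", "no reference mask: IoU term of the quality score set to 1")
    iou_val <- 1
  }
  plc_val <- plc(pred)
  asym <- asymmetry(pred)
  flags <- character(0)
  if (!is.null(truth) && iou_val < cfg$iou_min) flags <- c(flags, "LOW_IOU")
  if (asym > cfg$asym_max) flags <- c(flags, "ASYMMETRIC")
  if (plc_val < cfg$plc_min || plc_val > cfg$plc_max) {
    flags <- c(flags, "PLC_OUT_OF_RANGE")
  }
  structure(list(metrics = metrics, plc = plc_val, asymmetry = asym,
                 weighted_score = weighted_quality_score(iou_val, asym, plc_val, cfg),
                 flags = flags),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  if (!is.null(x$metrics)) {
    cat(sprintf("  iou %.4f  dice %.4f  precision %.4f  recall %.4f  specificity %.4f  iou_loss %.4f\n",
                x$metrics["iou"], x$metrics["dice"], x$metrics["precision"],
                x$metrics["recall"], x$metrics["specificity"], x$metrics["iou_loss"]))
  }
  cat(sprintf("  plc %.2f%%  asymmetry %.4f  weighted score %.4f\n",
              x$plc, x$asymmetry, x$weighted_score))
  cat(sprintf("  flags: %s\n",
              if (length(x$flags)) paste(x$flags, collapse = ", ") else "none"))
  invisible(x)
}

#' Quality-control report for paired mask directories
#'
#' Pairs predicted masks with reference masks by filename stem and runs
#' [qc_mask()] on each pair; predictions without a reference get
#' reference-free QC only.
#'
#' @param pred_dir directory of predicted masks.
#' @param truth_dir optional directory of reference masks.
#' @param out_csv optional path for the per-file CSV report.
#' @param cfg a [qc_config()].
#' @return data.frame with one row per predicted mask.
#' @export
qc_directory <- function(pred_dir, truth_dir = NULL, out_csv = NULL,
                         cfg = qc_config()) {
  pairs <- pair_dataset(pred_dir, truth_dir)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pred <- read_mask(pairs$image_path[i])
    truth <- if (!is.na(pairs$mask_path[i])) read_mask(pairs$mask_path[i]) else NULL
    rep <- qc_mask(pred, truth, cfg)
    m <- rep$metrics
    data.frame(filename = basename(pairs$image_path[i]),
               iou = if (is.null(m)) NA_real_ else m[["iou"]],
               dice = if (is.null(m)) NA_real_ else m[["dice"]],
               precision = if (is.null(m)) NA_real_ else m[["precision"]],
               recall = if (is.null(m)) NA_real_ else m[["recall"]],
               specificity = if (is.null(m)) NA_real_ else m[["specificity"]],
               plc = rep$plc, asymmetry = rep$asymmetry,
               weighted_score = rep$weighted_score,
               flags = paste(rep$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}
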