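## roi_filters: rule-based acceptance of candidate lung masks, rejection
## reasons, ROI bounding boxes, and batch directory processing.

REJECTION_REASONS <- c("BORDER_TOUCH", "OBJECT_COUNT", "AREA_TOO_SMALL", "BAD_ASPECT")

#' Acceptance-filter configuration
#'
#' Thresholds for the three mask filters: border contact, object count,
#' and per-object area/aspect. An accepted lung mask must keep every
#' foreground pixel at least `border_margin_px` away from the image edge,
#' contain 1-2 objects (both lungs; a fused pair counts as one), and each
#' object must cover at least 5% of the image with a plausible
#' width-to-height ratio.
#'
#' @param min_area_frac minimum per-object area as a fraction of image area
#'   (default 0.05; the test is inclusive at exactly 5%).
#' @param aspect_min,aspect_max allowed bounding-box width/height ratio
#'   (defaults 0.2 and 3.0: passes upright lung fields, rejects the
#'   full-width scanning-table bar at ratio ~10).
#' @param min_objects,max_objects allowed component count (defaults 1 and 2).
#' @param border_margin_px foreground within this many pixels of any edge
#'   triggers rejection (default 1 = strict edge contact).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(min_area_frac = 0.05, aspect_min = 0.2,
                          aspect_max = 3.0, max_objects = 2L,
                          min_objects = 1L, border_margin_px = 1L) {
  if (!(min_area_frac > 0 && min_area_frac < 1)) {
    stop_validation("min_area_frac must be in (0, 1)")
  }
  if (!(aspect_min < aspect_max)) stop_validation("aspect_min must be < aspect_max")
  if (!(min_objects <= max_objects)) stop_validation("min_objects must be <= max_objects")
  if (border_margin_px < 0L) stop_validation("border_margin_px must be >= 0")
  structure(list(min_area_frac = min_area_frac, aspect_min = aspect_min,
                 aspect_max = aspect_max, max_objects = as.integer(max_objects),
                 min_objects = as.integer(min_objects),
                 border_margin_px = as.integer(border_margin_px)),
            class = "filter_config")
}

#' Border-contact filter
#'
#' @param mask 0/1 matrix.
#' @param cfg a [filter_config()].
#' @return `"BORDER_TOUCH"` if any foreground pixel lies within
#'   `border_margin_px` of any image edge, else `NULL`.
#' @export
boundary_filter <- function(mask, cfg = filter_config()) {
  assert_mask(mask)
  m <- as_mask(mask)
  k <- cfg$border_margin_px
  if (k == 0L) return(NULL)
  h <- nrow(m); w <- ncol(m)
  rows <- unique(c(seq_len(min(k, h)), seq.int(max(1L, h - k + 1L), h)))
  cols <- unique(c(seq_len(min(k, w)), seq.int(max(1L, w - k + 1L), w)))
  if (any(m[rows, ] == 1L) || any(m[, cols] == 1L)) "BORDER_TOUCH" else NULL
}

#' Object-count filter
#'
#' @param components data.frame from [component_stats()].
#' @param cfg a [filter_config()].
#' @return `"OBJECT_COUNT"` if the component count is outside
#'   `[min_objects, max_objects]`, else `NULL`.
#' @export
object_count_filter <- function(components, cfg = filter_config()) {
  n <- nrow(components)
  if (n < cfg$min_objects || n > cfg$max_objects) "OBJECT_COUNT" else NULL
}

#' Per-object area and aspect-ratio filter
#'
#' Flags `AREA_TOO_SMALL` for every component below `min_area_frac` of the
#' image area (inclusive at the cutoff: exactly 5% passes) and `BAD_ASPECT`
#' for every component whose bounding-box width/height ratio falls outside
#' `[aspect_min, aspect_max]`. All violations are reported.
#'
#' @param components data.frame from [component_stats()].
#' @param cfg a [filter_config()].
#' @return character vector of rejection reasons (possibly empty).
#' @export
shape_filter <- function(components, cfg = filter_config()) {
  reasons <- character(0)
  for (i in seq_len(nrow(components))) {
    if (components$area_frac[i] < cfg$min_area_frac) {
      reasons <- c(reasons, "AREA_TOO_SMALL")
    }
    ar <- components$aspect_ratio[i]
    if (ar < cfg$aspect_min || ar > cfg$aspect_max) {
      reasons <- c(reasons, "BAD_ASPECT")
    }
  }
  reasons
}

#' Lung region-of-interest bounding box
#'
#' The extreme coordinates of the mask foreground: the tightest box
#' containing every foreground pixel.
#'
#' @param mask 0/1 matrix with at least one foreground pixel.
#' @return named integer vector `(row_min, col_min, row_max, col_max)`,
#'   1-based inclusive.
#' @export
compute_roi_bbox <- function(mask) {
  assert_mask(mask)
  idx <- which(as_mask(mask) == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop_validation("ROI undefined for an empty mask")
  c(row_min = min(idx[, 1]), col_min = min(idx[, 2]),
    row_max = max(idx[, 1]), col_max = max(idx[, 2]))
}

#' Apply the acceptance filters to a candidate mask
#'
#' Runs the border, object-count and shape filters in that order, collecting
#' *all* violated rules (no short-circuit) for auditability. The mask is
#' accepted iff no rule fires; the ROI bounding box is computed only for
#' accepted masks. Pure classification: mask pixels are never modified.
#'
#' @param mask 0/1 matrix.
#' @param cfg a [filter_config()].
#' @return object of class `pipeline_result`: list with `mask`, `accepted`,
#'   `reasons` (ordered, deduplicated), `components` and `roi_bbox`
#'   (`NULL` unless accepted).
#' @export
apply_filters <- function(mask, cfg = filter_config()) {
  assert_mask(mask)
  m <- as_mask(mask)
  comps <- component_stats(m)
  reasons <- c(boundary_filter(m, cfg),
               object_count_filter(comps, cfg),
               shape_filter(comps, cfg))
  reasons <- unique(reasons)
  accepted <- length(reasons) == 0L
  structure(list(mask = m,
                 accepted = accepted,
                 reasons = reasons,
                 components = comps,
                 roi_bbox = if (accepted) compute_roi_bbox(m) else NULL),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result %s; %d component(s)%s>\n",
              if (x$accepted) "ACCEPTED" else "REJECTED",
              nrow(x$components),
              if (x$accepted) {
                sprintf("; roi rows %d-%d cols %d-%d", x$roi_bbox["row_min"],
                        x$roi_bbox["row_max"], x$roi_bbox["col_min"],
                        x$roi_bbox["col_max"])
              } else {
                paste0("; reasons: ", paste(x$reasons, collapse = ", "))
              }))
  invisible(x)
}

#' Segment and filter every image in a directory
#'
#' Runs [segment_slice()] and [apply_filters()] on each PNG/TIFF image in
#' `image_dir`, writes accepted masks to `out_dir` (same stem, extension
#' from `config$output_format`), and writes `report.csv` (one row per
#' image), `summary.json` (counts per rejection reason, pass rate) and the
#' resolved configuration (`config_used.yaml`) next to the outputs. A
#' failing image is logged and skipped, never aborts the run.
#'
#' @param image_dir directory of input slices.
#' @param out_dir output directory (created if missing).
#' @param config a [pipeline_config()].
#' @return the run summary (list), invisibly.
#' @export
process_directory <- function(image_dir, out_dir, config = pipeline_config()) {
  pairs <- pair_dataset(image_dir)            # errors if empty/missing
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop_io("cannot create output directory: ", out_dir)
  }
  rows <- vector("list", nrow(pairs))
  reason_counts <- setNames(integer(length(REJECTION_REASONS)), REJECTION_REASONS)
  n_accepted <- 0L
  n_failed <- 0L
  for (i in seq_len(nrow(pairs))) {
    stem <- pairs$stem[i]
    res <- tryCatch({
      img <- read_image(pairs$image_path[i])
      mask <- segment_slice(img, config)
      apply_filters(mask, config$filter)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      lp_log("warn", "failed on ", stem, ": ", conditionMessage(res))
      n_failed <- n_failed + 1L
      rows[[i]] <- data.frame(filename = basename(pairs$image_path[i]),
                              accepted = FALSE, reasons = "ERROR",
                              n_components = NA_integer_,
                              row_min = NA, col_min = NA, row_max = NA, col_max = NA,
                              error = conditionMessage(res),
                              stringsAsFactors = FALSE)
      next
    }
    if (res$accepted) {
      n_accepted <- n_accepted + 1L
      out_path <- file.path(out_dir, paste0(stem, ".", config$output_format))
      write_mask(res$mask, out_path)
    } else {
      for (r in res$reasons) reason_counts[r] <- reason_counts[r] + 1L
    }
    bb <- if (res$accepted) res$roi_bbox else rep(NA_integer_, 4)
    rows[[i]] <- data.frame(filename = basename(pairs$image_path[i]),
                            accepted = res$accepted,
                            reasons = paste(res$reasons, collapse = ";"),
                            n_components = nrow(res$components),
                            row_min = bb[1], col_min = bb[2],
                            row_max = bb[3], col_max = bb[4],
                            error = "",
                            stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
  summary <- list(n_images = nrow(pairs),
                  n_accepted = n_accepted,
                  n_failed = n_failed,
                  pass_rate = n_accepted / nrow(pairs),
                  rejection_counts = as.list(reason_counts))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  yaml::write_yaml(config_to_list(config), file.path(out_dir, "config_used.yaml"))
  lp_log("info", sprintf("processed %d image(s): %d accepted (%.1f%%), %d failed",
                         nrow(pairs), n_accepted, 100 * summary$pass_rate, n_failed))
  invisible(summary)
}
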