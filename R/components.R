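## Connected components, hole filling, small-object removal, per-component
## statistics. Foreground uses 8-connectivity, background (hole filling)
## uses 4-connectivity — the standard duality pair.

#' Label connected components of a binary mask
#'
#' @param mask 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of component labels (0 = background); labels are
#'   assigned in column-major scan order, so labeling is deterministic.
#' @export
label_components <- function(mask, connectivity = 8L) {
  assert_mask(mask)
  if (!connectivity %in% c(4L, 8L)) stop_validation("connectivity must be 4 or 8")
  cc_label(as_mask(mask), as.integer(connectivity))
}

#' Fill interior holes of a binary mask
#'
#' Background components that are not 4-connected to the image border are
#' turned into foreground. Idempotent.
#'
#' @param mask 0/1 matrix.
#' @return 0/1 integer matrix.
#' @export
fill_holes <- function(mask) {
  assert_mask(mask)
  m <- as_mask(mask)
  bg <- 1L - m
  lab <- cc_label(bg, 4L)
  h <- nrow(m); w <- ncol(m)
  border_labels <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  border_labels <- border_labels[border_labels != 0L]
  holes <- lab != 0L & !(lab %in% border_labels)
  m[holes] <- 1L
  m
}

#' Remove small connected components
#'
#' Deletes 8-connected foreground components whose pixel area is below
#' `min_area_frac` of the total image area.
#'
#' @param mask 0/1 matrix.
#' @param min_area_frac area cutoff as a fraction of image area (default
#'   0.001, i.e. 0.1%).
#' @return 0/1 integer matrix.
#' @export
remove_small_objects <- function(mask, min_area_frac = 0.001) {
  assert_mask(mask)
  if (min_area_frac < 0 || min_area_frac >= 1) {
    stop_validation("min_area_frac must be in [0, 1)")
  }
  m <- as_mask(mask)
  if (min_area_frac == 0) return(m)
  cutoff <- min_area_frac * length(m)
  lab <- cc_label(m, 8L)
  if (max(lab) == 0L) return(m)
  areas <- tabulate(lab, nbins = max(lab))
  small <- which(areas < cutoff)
  if (length(small)) m[lab %in% small] <- 0L
  m
}

#' Per-component statistics of a binary mask
#'
#' One row per 8-connected component, sorted by area descending (ties broken
#' by scan-order label, so the output is deterministic).
#'
#' @param mask 0/1 matrix.
#' @return data.frame with columns `label`, `area_px`, `area_frac`,
#'   `row_min`, `col_min`, `row_max`, `col_max` (1-based, inclusive),
#'   `aspect_ratio` (bounding-box width / height) and `touches_border`.
#' @export
component_stats <- function(mask) {
  assert_mask(mask)
  m <- as_mask(mask)
  h <- nrow(m); w <- ncol(m)
  lab <- cc_label(m, 8L)
  n <- max(lab)
  if (n == 0L) {
    return(data.frame(label = integer(0), area_px = integer(0),
                      area_frac = numeric(0), row_min = integer(0),
                      col_min = integer(0), row_max = integer(0),
                      col_max = integer(0), aspect_ratio = numeric(0),
                      touches_border = logical(0)))
  }
  idx <- which(lab != 0L, arr.ind = TRUE)
  lv <- lab[lab != 0L]
  area <- tabulate(lv, nbins = n)
  row_min <- as.integer(tapply(idx[, 1], lv, min))
  row_max <- as.integer(tapply(idx[, 1], lv, max))
  col_min <- as.integer(tapply(idx[, 2], lv, min))
  col_max <- as.integer(tapply(idx[, 2], lv, max))
  stats <- data.frame(
    label = seq_len(n),
    area_px = area,
    area_frac = area / (h * w),
    row_min = row_min, col_min = col_min,
    row_max = row_max, col_max = col_max,
    aspect_ratio = (col_max - col_min + 1) / (row_max - row_min + 1),
    touches_border = row_min == 1L | col_min == 1L | row_max == h | col_max == w
  )
  stats[order(-stats$area_px, stats$label), , drop = FALSE]
}
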