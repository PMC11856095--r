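## preprocess_core: raw CT slice -> candidate lung mask.
##
## Chain: min-max normalization -> percentile contrast stretch -> Otsu
## threshold -> low-density binarization -> body identification on the dense
## complement -> outside-body clearing -> morphological refinement.

#' Min-max normalize an image to \[0, 1\]
#'
#' `out = (I - I_min) / (I_max - I_min)` over the whole image. A constant
#' image maps to all zeros (with a logged warning) so batch runs survive
#' degenerate slices.
#'
#' @param img numeric matrix of intensities (any scale).
#' @return numeric matrix in \[0, 1\].
#' @export
normalize_image <- function(img) {
  assert_image(img)
  lo <- min(img); hi <- max(img)
  if (hi == lo) {
    lp_log("warn", "constant image: normalization returns all zeros")
    return(matrix(0, nrow(img), ncol(img)))
  }
  matrix((as.numeric(img) - lo) / (hi - lo), nrow(img), ncol(img))
}

#' Percentile contrast stretch
#'
#' Linear stretch mapping the `low_pct` percentile to 0 and the `high_pct`
#' percentile to 1, clipping outside; corrects illumination inconsistencies
#' between slices while staying deterministic (no adaptive histogram
#' methods).
#'
#' @param img numeric matrix in \[0, 1\].
#' @param low_pct,high_pct percentiles in \[0, 100\], `low_pct < high_pct`.
#' @return numeric matrix in \[0, 1\].
#' @export
enhance_contrast <- function(img, low_pct = 1, high_pct = 99) {
  assert_image(img)
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100)) {
    stop_validation("need 0 <= low_pct < high_pct <= 100")
  }
  q <- quantile(img, probs = c(low_pct, high_pct) / 100, names = FALSE, type = 7)
  if (q[1] == q[2]) {
    lp_log("warn", "equal contrast percentiles; image returned unchanged")
    return(img)
  }
  out <- (img - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Otsu threshold of a normalized image
#'
#' Builds a 256-bin histogram of \[0, 1\] and exhaustively evaluates the
#' between-class variance at every bin edge, returning the cut that
#' maximizes it (ties broken toward the smaller threshold). The returned
#' threshold is the bin edge `k / bins`, so `value < threshold` reproduces
#' the class split exactly.
#'
#' @param img numeric matrix with values in \[0, 1\], not constant.
#' @param bins number of histogram bins (default 256).
#' @return object of class `otsu_result`: list with `threshold`,
#'   `between_class_variance` and `histogram` (bin counts).
#' @export
otsu_threshold <- function(img, bins = 256L) {
  assert_image(img)
  bins <- as.integer(bins)
  if (bins < 2L) stop_validation("bins must be >= 2")
  if (min(img) == max(img)) stop_validation("Otsu threshold undefined for a constant image")
  v <- as.numeric(img)
  if (any(v < 0 | v > 1)) stop_validation("otsu_threshold expects values in [0, 1]")
  bin <- pmin(floor(v * bins), bins - 1L)          # 0-based bin index
  counts <- tabulate(bin + 1L, nbins = bins)
  p <- counts / length(v)
  centers <- (seq_len(bins) - 0.5) / bins
  w0 <- cumsum(p)                                  # class 0: bins 1..k
  mu_cum <- cumsum(p * centers)
  mu_total <- mu_cum[bins]
  k <- seq_len(bins - 1L)                          # candidate cuts
  w1 <- 1 - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  sigma_b <- rep(-Inf, bins - 1L)
  mu0 <- mu_cum[k] / w0[k]
  mu1 <- (mu_total - mu_cum[k]) / w1
  sigma_b[valid] <- (w0[k] * w1 * (mu0 - mu1)^2)[valid]
  best <- which.max(sigma_b)                       # first max = smallest cut
  structure(list(threshold = best / bins,
                 between_class_variance = sigma_b[best],
                 histogram = counts),
            class = "otsu_result")
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf("<otsu_result threshold=%.6f between-class variance=%.6g>\n",
              x$threshold, x$between_class_variance))
  invisible(x)
}

#' Binarize low-density (lung/air) pixels
#'
#' On CT, lungs are air-filled and dark; the lung-candidate foreground is
#' the set of pixels *below* the threshold.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param threshold scalar in (0, 1), e.g. from [otsu_threshold()].
#' @return 0/1 integer matrix.
#' @export
binarize_lungs <- function(img, threshold) {
  assert_image(img)
  if (inherits(threshold, "otsu_result")) threshold <- threshold$threshold
  if (!(threshold > 0 && threshold < 1)) stop_validation("threshold must be in (0, 1)")
  matrix(as.integer(img < threshold), nrow(img), ncol(img))
}

#' Identify the patient body from the dense-tissue mask
#'
#' The body is the largest 8-connected component of the dense
#' (above-threshold) mask with its interior holes filled, so it includes
#' the lungs. A scanning table, being a smaller separate dense object, is
#' discarded at this step.
#'
#' @param binary 0/1 matrix of *dense* pixels (complement of the
#'   [binarize_lungs()] output).
#' @return 0/1 integer matrix of the filled body region.
#' @export
identify_body <- function(binary) {
  assert_mask(binary)
  m <- as_mask(binary)
  lab <- cc_label(m, 8L)
  if (max(lab) == 0L) stop_validation("no body found: dense mask is empty")
  areas <- tabulate(lab, nbins = max(lab))
  biggest <- which.max(areas)
  body <- matrix(as.integer(lab == biggest), nrow(m), ncol(m))
  fill_holes(body)
}

#' Clear lung candidates outside the body
#'
#' Pointwise AND with the body mask: removes background air, the air gap
#' around the scanning table, and anything else outside the patient.
#'
#' @param lung_candidates,body 0/1 matrices of identical shape.
#' @return 0/1 integer matrix.
#' @export
clear_outside_body <- function(lung_candidates, body) {
  assert_mask(lung_candidates, "lung_candidates")
  assert_mask(body, "body")
  assert_same_shape(lung_candidates, body)
  as_mask(as_mask(lung_candidates) & as_mask(body))
}

#' Morphological refinement of a candidate mask
#'
#' Applies closing (dilate then erode) with the structuring element
#' `iterations` times, then fills holes and removes small objects. Smooths
#' edges, closes gaps narrower than the element, and deletes specks.
#'
#' @param mask 0/1 matrix.
#' @param se structuring element (default 5x5 square).
#' @param iterations number of closing passes (default 3).
#' @param small_object_frac area cutoff for [remove_small_objects()].
#' @return 0/1 integer matrix.
#' @export
refine_morphology <- function(mask, se = structuring_element(5L),
                              iterations = 3L, small_object_frac = 0.001) {
  assert_mask(mask)
  if (iterations < 1L) stop_validation("iterations must be >= 1")
  m <- as_mask(mask)
  for (i in seq_len(iterations)) {
    m <- morph_close(m, se)
  }
  m <- fill_holes(m)
  remove_small_objects(m, small_object_frac)
}

#' Segment a raw CT slice into a candidate lung mask
#'
#' Full preprocessing chain: normalize, contrast-stretch, Otsu-threshold,
#' binarize low-density pixels, identify the body on the dense complement,
#' keep candidates inside the body, refine morphologically. The result is
#' the *unfiltered* candidate mask; pass it to [apply_filters()] for the
#' acceptance verdict.
#'
#' @param img numeric matrix of raw intensities (e.g. from [read_image()]).
#' @param config a [pipeline_config()].
#' @return 0/1 integer matrix.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(size = c(128, 128), noise_sigma = 0))
#' m <- segment_slice(ph$image, pipeline_config())
#' iou(m, ph$lung_mask)
segment_slice <- function(img, config = pipeline_config()) {
  assert_image(img)
  x <- if (isTRUE(config$normalize)) normalize_image(img) else img
  x <- enhance_contrast(x, config$contrast_low, config$contrast_high)
  ot <- otsu_threshold(x, config$otsu_bins)
  candidates <- binarize_lungs(x, ot$threshold)
  dense <- as_mask(1L - candidates)
  body <- identify_body(dense)
  inside <- clear_outside_body(candidates, body)
  refine_morphology(inside,
                    se = structuring_element(config$se_size),
                    iterations = config$morph_iterations,
                    small_object_frac = config$small_object_frac)
}
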