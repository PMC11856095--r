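## Binary mathematical morphology on 0/1 matrices.
##
## Implementation: shift-and-combine over the structuring-element offsets.
## Out-of-image pixels are background for both dilation and erosion, so
## foreground touching the image border erodes away (clipped-domain
## convention; see the methods vignette for border-effect caveats).

#' Create a structuring element
#'
#' @param size odd side length of a square element, or a 0/1 matrix to use
#'   directly.
#' @param anchor 1-based (row, col) anchor; defaults to the center.
#' @return object of class `structuring_element` with fields `pixels` and
#'   `anchor`.
#' @export
#' @examples
#' structuring_element(5)    # the default 5x5 square used by the pipeline
structuring_element <- function(size = 5L, anchor = NULL) {
  if (is.matrix(size)) {
    px <- as_mask(size)
  } else {
    size <- as.integer(size)
    if (size < 1L || size %% 2L == 0L) {
      stop_validation("structuring element size must be odd and >= 1")
    }
    px <- matrix(1L, size, size)
  }
  if (is.null(anchor)) {
    anchor <- c((nrow(px) + 1L) %/% 2L, (ncol(px) + 1L) %/% 2L)
  }
  anchor <- as.integer(anchor)
  if (anchor[1] < 1L || anchor[1] > nrow(px) || anchor[2] < 1L || anchor[2] > ncol(px)) {
    stop_validation("anchor must lie inside the structuring element")
  }
  structure(list(pixels = px, anchor = anchor), class = "structuring_element")
}

#' @export
print.structuring_element <- function(x, ...) {
  cat(sprintf("<structuring_element %dx%d, anchor (%d,%d)>\n",
              nrow(x$pixels), ncol(x$pixels), x$anchor[1], x$anchor[2]))
  invisible(x)
}

## Offsets (dr, dc) of the SE foreground relative to its anchor.
se_offsets <- function(se) {
  idx <- which(se$pixels == 1L, arr.ind = TRUE)
  cbind(dr = idx[, 1] - se$anchor[1], dc = idx[, 2] - se$anchor[2])
}

## Translate a mask by (dr, dc); vacated pixels become background.
shift_mask <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  r_dst <- max(1L, 1L + dr):min(h, h + dr)
  c_dst <- max(1L, 1L + dc):min(w, w + dc)
  if (length(r_dst) < 1L || length(c_dst) < 1L || r_dst[1] > r_dst[length(r_dst)]) return(out)
  out[r_dst, c_dst] <- m[r_dst - dr, c_dst - dc]
  out
}

#' Binary dilation
#'
#' Set dilation of the mask by the structuring element: a pixel is
#' foreground in the output if the reflected element placed there hits any
#' input foreground pixel. Out-of-image pixels count as background.
#'
#' @param mask 0/1 matrix.
#' @param se a [structuring_element()].
#' @return 0/1 integer matrix.
#' @export
dilate <- function(mask, se = structuring_element(5L)) {
  assert_mask(mask)
  m <- as_mask(mask)
  offs <- se_offsets(se)
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(offs))) {
    out <- out | shift_mask(m, offs[i, 1], offs[i, 2])
  }
  as_mask(out)
}

#' Binary erosion
#'
#' A pixel survives if the whole structuring element placed at it fits in
#' the input foreground. Out-of-image pixels count as background, so border
#' foreground erodes.
#'
#' @inheritParams dilate
#' @return 0/1 integer matrix.
#' @export
erode <- function(mask, se = structuring_element(5L)) {
  assert_mask(mask)
  m <- as_mask(mask)
  offs <- se_offsets(se)
  out <- matrix(1L, nrow(m), ncol(m))
  for (i in seq_len(nrow(offs))) {
    out <- out & shift_mask(m, -offs[i, 1], -offs[i, 2])
  }
  as_mask(out)
}

## Closing: dilation then erosion with the same element.
morph_close <- function(mask, se = structuring_element(5L)) {
  erode(dilate(mask, se), se)
}
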