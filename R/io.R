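## io_formats: PNG/TIFF grayscale images and binary masks, dataset pairing.

IMAGE_EXTENSIONS <- c("png", "tif", "tiff")

image_ext <- function(path) tolower(tools::file_ext(path))

#' Read a grayscale CT slice image
#'
#' Reads a PNG or TIFF image and returns its pixels as an integer matrix of
#' the *stored* intensity values (0..255 for 8-bit, 0..65535 for 16-bit),
#' row-major with origin at the top-left. Multi-channel (RGB/RGBA) input is
#' converted to grayscale by averaging the color channels; a warning is
#' logged since CT slices are expected to be single-channel.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return integer-valued matrix with attributes `source_path` and `bits`
#'   (bit depth as stored on disk).
#' @export
#' @examples
#' p <- generate_phantom(phantom_spec(size = c(64, 64)))
#' f <- tempfile(fileext = ".png")
#' write_mask(p$lung_mask, f)
#' img <- read_image(f)
#' dim(img)
read_image <- function(path) {
  if (!file.exists(path)) stop_io("file not found: ", path)
  ext <- image_ext(path)
  if (!ext %in% IMAGE_EXTENSIONS) {
    stop_format("unsupported image format '", ext, "' (expected PNG or TIFF): ", path)
  }
  if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    info <- attr(x, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    scale <- 2^bits - 1
    if (length(dim(x)) == 3L) {
      nch <- dim(x)[3]
      if (nch == 2L) {
        x <- x[, , 1]                      # gray + alpha
      } else {
        lp_log("warn", "multi-channel image averaged to grayscale: ", path)
        x <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
      }
    }
    pixels <- round(x * scale)
  } else {
    x <- read_tiff_raw(path)
    bits <- attr(x, "bits")
    if (length(dim(x)) == 3L) {
      nch <- dim(x)[3]
      if (nch == 2L) {
        x <- x[, , 1]
      } else {
        lp_log("warn", "multi-channel image averaged to grayscale: ", path)
        x <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
      }
    }
    pixels <- round(x * 1.0)
  }
  if (is.null(dim(pixels)) || any(dim(pixels) < 1L)) {
    stop_validation("zero-sized image: ", path)
  }
  out <- matrix(as.numeric(pixels), nrow = nrow(pixels), ncol = ncol(pixels))
  attr(out, "source_path") <- path
  attr(out, "bits") <- as.integer(bits)
  out
}

#' Write a binary mask to disk as an 8-bit grayscale image
#'
#' Foreground (1) is stored as 255, background (0) as 0, single-channel
#' 8-bit, so that `read_mask(write_mask(m))` round-trips bit-exactly. The
#' container is chosen from the file extension (PNG or TIFF).
#'
#' @param mask 0/1 matrix.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  mask <- as_mask(mask)
  ext <- image_ext(path)
  if (!ext %in% IMAGE_EXTENSIONS) {
    stop_format("unsupported mask format '", ext, "' (expected PNG or TIFF): ", path)
  }
  if (ext == "png") {
    ok <- tryCatch({
      png::writePNG(mask * 1.0, target = path)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop_io("cannot write mask: ", path)
  } else {
    write_tiff_raw(mask * 255L, path, bits = 8L)
  }
  invisible(path)
}

#' Read a binary mask from an 8-bit grayscale image
#'
#' Pixels with stored value > 127 decode to 1, all others to 0.
#'
#' @param path path to a single-channel 8-bit PNG or TIFF.
#' @return 0/1 integer matrix.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  if (attr(img, "bits") != 8L) {
    stop_format("mask must be 8-bit, got ", attr(img, "bits"), "-bit: ", path)
  }
  sp <- attr(img, "source_path")
  ## reject inputs that were multi-channel with non-identical channels:
  ## read_image averaging would yield non-integer values there.
  if (any(abs(img - round(img)) > 1e-9)) {
    stop_format("mask is not grayscale: ", path)
  }
  matrix(as.integer(img > 127), nrow = nrow(img), ncol = ncol(img))
}

#' Pair images with ground-truth masks by filename stem
#'
#' Lists PNG/TIFF files in `image_dir`, optionally matches each to a mask in
#' `mask_dir` sharing the same extension-stripped filename, and returns the
#' pairs in deterministic lexicographic stem order. Masks without a matching
#' image are logged, not errors. Duplicate stems within a directory (e.g.
#' `a.png` and `a.tif`) are an error since the pairing key is ambiguous.
#'
#' @param image_dir directory of slice images.
#' @param mask_dir optional directory of paired masks.
#' @return data.frame with columns `stem`, `image_path`, `mask_path`
#'   (`NA` when unmatched).
#' @export
pair_dataset <- function(image_dir, mask_dir = NULL) {
  if (!dir.exists(image_dir)) stop_io("image directory not found: ", image_dir)
  list_images <- function(dir) {
    files <- list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
    stems <- tools::file_path_sans_ext(files)
    if (anyDuplicated(stems)) {
      stop_validation("duplicate filename stems in ", dir, ": ",
                      paste(unique(stems[duplicated(stems)]), collapse = ", "))
    }
    ord <- order(stems, method = "radix")
    data.frame(stem = stems[ord], file = files[ord], stringsAsFactors = FALSE)
  }
  imgs <- list_images(image_dir)
  if (nrow(imgs) == 0L) stop_validation("no PNG/TIFF images in ", image_dir)
  mask_path <- rep(NA_character_, nrow(imgs))
  if (!is.null(mask_dir)) {
    if (!dir.exists(mask_dir)) stop_io("mask directory not found: ", mask_dir)
    masks <- list_images(mask_dir)
    idx <- match(imgs$stem, masks$stem)
    mask_path[!is.na(idx)] <- file.path(mask_dir, masks$file[idx[!is.na(idx)]])
    orphans <- setdiff(masks$stem, imgs$stem)
    if (length(orphans)) {
      lp_log("warn", "masks without matching image: ", paste(orphans, collapse = ", "))
    }
  }
  data.frame(stem = imgs$stem,
             image_path = file.path(image_dir, imgs$file),
             mask_path = mask_path,
             stringsAsFactors = FALSE)
}
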