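## synthetic_phantom: seeded CT-slice phantoms with exact ground truth.
##
## A phantom is a dark air background, a bright soft-tissue body ellipse,
## two low-density lung ellipses inside the body, optionally a bright
## elongated scanning-table bar near the bottom edge, additive Gaussian
## noise, and 8-bit quantization. Ground-truth masks are the exact pre-noise
## ellipse rasterizations (center-of-pixel inclusion), so expected areas are
## computable in closed form.

PHANTOM_DEFECTS <- c("BORDER_TOUCH", "EXTRA_OBJECT", "TINY_LUNGS",
                     "MERGED_LUNGS", "TABLE_ARTIFACT")

## rasterize an ellipse: pixel (r, c) is inside iff its center satisfies
## ((r - cr)/ar)^2 + ((c - cc)/ac)^2 <= 1 (1-based pixel centers).
ellipse_mask <- function(h, w, center, axes) {
  rr <- ((seq_len(h) - center[1]) / axes[1])^2
  cc <- ((seq_len(w) - center[2]) / axes[2])^2
  m <- outer(rr, cc, "+") <= 1
  matrix(as.integer(m), h, w)
}

#' Specify a synthetic CT-slice phantom
#'
#' Geometry defaults are fractions of the image size chosen to mimic an
#' axial chest slice: the body ellipse spans ~78% of the width, each lung
#' ~23% of the width and ~42% of the height (about 7.6% of the image area
#' per lung, so total coverage sits comfortably inside the 5-50% PLC band).
#' Intensities (on \[0, 1\] before quantization) give a clean bimodal
#' air/tissue histogram for Otsu: background 0.05, body tissue 0.65, lung
#' 0.15, table 0.75.
#'
#' @param size `c(H, W)` in pixels (default 512 x 512).
#' @param body_center,body_axes ellipse center `(row, col)` and semi-axes
#'   `(row, col)`; defaults derived from `size`.
#' @param lung_centers 2 x 2 matrix of lung ellipse centers (rows = lungs);
#'   default symmetric about the midline.
#' @param lung_axes semi-axes `(row, col)` shared by both lungs.
#' @param intensities named vector with entries `background`, `body`,
#'   `lung`, `table`, all in \[0, 1\].
#' @param noise_sigma standard deviation of additive Gaussian noise on the
#'   \[0, 1\] scale (default 0.01).
#' @param defects character subset of
#'   `c("BORDER_TOUCH", "EXTRA_OBJECT", "TINY_LUNGS", "MERGED_LUNGS",
#'   "TABLE_ARTIFACT")`.
#' @param seed integer RNG seed for the noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(512L, 512L), body_center = NULL,
                         body_axes = NULL, lung_centers = NULL,
                         lung_axes = NULL,
                         intensities = c(background = 0.05, body = 0.65,
                                         lung = 0.15, table = 0.75),
                         noise_sigma = 0.01, defects = character(),
                         seed = 1L) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 16L)) {
    stop_validation("size must be c(H, W) with both >= 16")
  }
  h <- size[1]; w <- size[2]
  if (is.null(body_center)) body_center <- c(0.52 * h, 0.50 * w)
  if (is.null(body_axes)) body_axes <- c(0.34 * h, 0.39 * w)
  if (is.null(lung_centers)) {
    lung_centers <- rbind(c(0.50 * h, 0.50 * w - 0.185 * w),
                          c(0.50 * h, 0.50 * w + 0.185 * w))
  }
  if (is.null(lung_axes)) lung_axes <- c(0.21 * h, 0.115 * w)
  if (!all(defects %in% PHANTOM_DEFECTS)) {
    stop_validation("unknown defect(s): ",
                    paste(setdiff(defects, PHANTOM_DEFECTS), collapse = ", "))
  }
  if (any(intensities < 0) || any(intensities > 1)) {
    stop_validation("intensities must lie in [0, 1]")
  }
  if (noise_sigma < 0) stop_validation("noise_sigma must be >= 0")
  structure(list(size = size, body_center = body_center,
                 body_axes = body_axes, lung_centers = lung_centers,
                 lung_axes = lung_axes, intensities = intensities,
                 noise_sigma = noise_sigma, defects = defects,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Render a phantom from its specification
#'
#' Applies the defects to the stated geometry, rasterizes body and lungs,
#' adds seeded Gaussian noise, clips to \[0, 1\] and quantizes to 8 bits.
#' Ground-truth masks are the exact pre-noise rasterizations. The same spec
#' (including seed) always yields a bit-identical phantom.
#'
#' Defects: `TINY_LUNGS` shrinks the lung semi-axes to 45% (area ~20% of
#' normal, below the 5% acceptance cutoff); `MERGED_LUNGS` widens and moves
#' the lungs so they fuse into one component; `EXTRA_OBJECT` adds a
#' lung-density disc of ~0.3% image area between the lungs (a third
#' object); `BORDER_TOUCH` shifts the anatomy upward until the lungs cross
#' the top image edge; `TABLE_ARTIFACT` draws a bright bar of aspect ratio
#' above 5 below the body, disjoint from it.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom`: list with `image` (numeric matrix of
#'   stored 8-bit values 0..255), `lung_mask`, `body_mask`, `spec`,
#'   `defects`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop_validation("spec must be a phantom_spec")
  h <- spec$size[1]; w <- spec$size[2]
  body_center <- spec$body_center
  lung_centers <- spec$lung_centers
  lung_axes <- spec$lung_axes
  defects <- spec$defects

  if ("TINY_LUNGS" %in% defects) lung_axes <- lung_axes * 0.45
  if ("MERGED_LUNGS" %in% defects) {
    lung_centers[, 2] <- c(0.44, 0.56) * w
    lung_axes[2] <- 0.16 * w
  }

  extra_center <- NULL
  if ("EXTRA_OBJECT" %in% defects) {
    extra_center <- c(mean(lung_centers[, 1]), 0.5 * w)
  }

  if ("BORDER_TOUCH" %in% defects) {
    lung_top <- min(lung_centers[, 1] - lung_axes[1])
    shift <- floor(lung_top) + max(2, round(0.01 * h))
    body_center[1] <- body_center[1] - shift
    lung_centers[, 1] <- lung_centers[, 1] - shift
    if (!is.null(extra_center)) extra_center[1] <- extra_center[1] - shift
  }

  body_mask <- ellipse_mask(h, w, body_center, spec$body_axes)
  lung_mask <- as_mask(ellipse_mask(h, w, lung_centers[1, ], lung_axes) |
                       ellipse_mask(h, w, lung_centers[2, ], lung_axes))
  if (!is.null(extra_center)) {
    ## radius 3% of the width keeps the disc clear of the lungs in the
    ## mediastinal corridor at every image size (the 5x5 closing bridges
    ## gaps up to 4 px, so the gap must stay wider than that), while its
    ## area (~0.3% of the image) still survives small-object removal
    r_extra <- 0.03 * w
    lung_mask <- as_mask(lung_mask | ellipse_mask(h, w, extra_center,
                                                  c(r_extra, r_extra)))
  }

  table_mask <- matrix(0L, h, w)
  if ("TABLE_ARTIFACT" %in% defects) {
    rows <- round(0.94 * h):round(0.97 * h)
    cols <- round(0.15 * w):round(0.85 * w)
    table_mask[rows, cols] <- 1L
  }

  if (!all(lung_mask <= body_mask) && !("BORDER_TOUCH" %in% defects)) {
    stop_validation("invalid phantom geometry: lungs exceed the body ellipse")
  }
  if (any(table_mask & body_mask)) {
    stop_validation("invalid phantom geometry: table overlaps the body")
  }

  int <- spec$intensities
  img <- matrix(int[["background"]], h, w)
  img[body_mask == 1L] <- int[["body"]]
  img[lung_mask == 1L] <- int[["lung"]]
  img[table_mask == 1L] <- int[["table"]]

  img <- with_local_seed(spec$seed, {
    if (spec$noise_sigma > 0) img + rnorm(h * w, 0, spec$noise_sigma) else img
  })
  img[img < 0] <- 0
  img[img > 1] <- 1
  image <- matrix(round(img * 255), h, w)
  attr(image, "bits") <- 8L

  structure(list(image = image, lung_mask = lung_mask, body_mask = body_mask,
                 spec = spec, defects = defects),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %dx%d, lung coverage %.1f%%, defects: %s>\n",
              nrow(x$image), ncol(x$image), plc(x$lung_mask),
              if (length(x$defects)) paste(x$defects, collapse = ", ") else "none"))
  invisible(x)
}

#' Generate a reproducible cohort of phantoms
#'
#' Geometry is jittered within safe anatomical bounds (body semi-axes
#' +/-4%, lung offset/axes +/-5%, center jitter +/-1% of the image size);
#' each defect is injected independently per its stated rate. The cohort is
#' a pure function of `(n, defect_rates, size, noise_sigma, seed)`.
#'
#' @param n number of phantoms.
#' @param defect_rates named numeric vector of per-defect injection
#'   probabilities in \[0, 1\] (names from the defect set); defaults to no
#'   defects.
#' @param seed integer master seed.
#' @param size image size `c(H, W)`.
#' @param noise_sigma noise level passed to every phantom.
#' @return list of `phantom` objects with names `phantom_0001`, ...
#' @export
generate_cohort <- function(n, defect_rates = numeric(), seed = 1L,
                            size = c(512L, 512L), noise_sigma = 0.01) {
  if (n < 1L) stop_validation("n must be >= 1")
  if (length(defect_rates)) {
    if (is.null(names(defect_rates)) || !all(names(defect_rates) %in% PHANTOM_DEFECTS)) {
      stop_validation("defect_rates must be named with known defects")
    }
    if (any(defect_rates < 0 | defect_rates > 1)) {
      stop_validation("defect rates must lie in [0, 1]")
    }
  }
  h <- size[1]; w <- size[2]
  draws <- with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      geo <- list(
        body_center = c((0.52 + runif(1, -0.01, 0.01)) * h,
                        (0.50 + runif(1, -0.01, 0.01)) * w),
        body_axes = c(0.34 * h * runif(1, 0.96, 1.04),
                      0.39 * w * runif(1, 0.96, 1.04)),
        lung_offset = 0.185 * w * runif(1, 0.95, 1.05),
        lung_row = (0.50 + runif(1, -0.01, 0.01)) * h,
        lung_axes = c(0.21 * h * runif(1, 0.95, 1.05),
                      0.115 * w * runif(1, 0.95, 1.05))
      )
      defects <- names(defect_rates)[runif(length(defect_rates)) < defect_rates]
      list(geo = geo, defects = defects,
           seed = sample.int(2147483646L, 1L))
    })
  })
  out <- lapply(seq_len(n), function(i) {
    d <- draws[[i]]
    geo <- d$geo
    spec <- phantom_spec(
      size = size,
      body_center = geo$body_center,
      body_axes = geo$body_axes,
      lung_centers = rbind(c(geo$lung_row, 0.5 * w - geo$lung_offset),
                           c(geo$lung_row, 0.5 * w + geo$lung_offset)),
      lung_axes = geo$lung_axes,
      noise_sigma = noise_sigma,
      defects = d$defects,
      seed = d$seed
    )
    generate_phantom(spec)
  })
  names(out) <- sprintf("phantom_%04d", seq_len(n))
  out
}

#' Write a phantom cohort to disk
#'
#' Writes each phantom image and its ground-truth lung mask (matching
#' filename stems) plus a `manifest.csv` of seeds, defect labels and lung
#' area fractions into `image_dir`.
#'
#' @param phantoms list of `phantom` objects (e.g. from [generate_cohort()]).
#' @param image_dir output directory for images (+ manifest), created if
#'   missing.
#' @param mask_dir output directory for ground-truth masks, created if
#'   missing.
#' @param format `"png"` (default) or `"tiff"`.
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(phantoms, image_dir, mask_dir, format = "png") {
  if (!format %in% c("png", "tif", "tiff")) stop_validation("format must be png or tiff")
  for (d in c(image_dir, mask_dir)) {
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE)) {
      stop_io("cannot create directory: ", d)
    }
  }
  stems <- names(phantoms)
  if (is.null(stems)) stems <- sprintf("phantom_%04d", seq_along(phantoms))
  rows <- lapply(seq_along(phantoms), function(i) {
    p <- phantoms[[i]]
    img_path <- file.path(image_dir, paste0(stems[i], ".", format))
    if (format == "png") {
      png::writePNG(p$image / 255, target = img_path)
    } else {
      write_tiff_raw(p$image, img_path, bits = 8L)
    }
    write_mask(p$lung_mask, file.path(mask_dir, paste0(stems[i], ".", format)))
    data.frame(stem = stems[i], seed = p$spec$seed,
               defects = paste(p$defects, collapse = ";"),
               lung_area_frac = sum(p$lung_mask) / length(p$lung_mask),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(image_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
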