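## Internal helpers shared across modules.

lp_stop <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "lungprep_error")))
}

#' @noRd
stop_validation <- function(...) lp_stop(..., class = "lungprep_validation_error")

#' @noRd
stop_io <- function(...) lp_stop(..., class = "lungprep_io_error")

#' @noRd
stop_format <- function(...) lp_stop(..., class = "lungprep_format_error")

## A mask is an integer (or logical/numeric) matrix whose entries are 0/1.
assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) {
    stop_validation(arg, " must be a matrix")
  }
  if (length(mask) == 0L) {
    stop_validation(arg, " must have at least one pixel")
  }
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1, TRUE, FALSE))) {
    stop_validation(arg, " must contain only 0/1 values")
  }
  invisible(TRUE)
}

as_mask <- function(x) {
  m <- matrix(as.integer(x != 0), nrow = nrow(x), ncol = ncol(x))
  m
}

assert_same_shape <- function(a, b, what = "masks") {
  if (!identical(dim(a), dim(b))) {
    stop_validation(what, " have mismatched shapes: ",
                    paste(dim(a), collapse = "x"), " vs ",
                    paste(dim(b), collapse = "x"))
  }
  invisible(TRUE)
}

assert_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop_validation(arg, " must be a numeric matrix")
  }
  if (nrow(img) < 1L || ncol(img) < 1L || length(img) == 0L) {
    stop_validation(arg, " must have height >= 1 and width >= 1")
  }
  invisible(TRUE)
}

## Run an expression with a locally-seeded RNG, restoring global RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## Minimal leveled logger; level set through option lungprep.log_level.
lp_log <- function(level = c("info", "warn", "debug"), ...) {
  level <- match.arg(level)
  threshold <- getOption("lungprep.log_level", "info")
  ranks <- c(debug = 1L, info = 2L, warn = 3L)
  if (ranks[[level]] >= ranks[[threshold]]) {
    message(sprintf("[lungprep %s] %s", level, paste0(...)))
  }
  invisible(NULL)
}
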