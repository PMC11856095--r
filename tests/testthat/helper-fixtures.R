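# Shared fixtures: random masks, a brute-force Otsu oracle, tiny phantoms.

random_mask <- function(h = 32L, w = h, density = 0.4) {
  matrix(as.integer(runif(h * w) < density), h, w)
}

# Independent Otsu oracle: literal scan of every candidate cut on the
# 256-bin histogram, first maximum wins (smallest threshold on ties).
brute_force_otsu <- function(img, bins = 256L) {
  v <- as.numeric(img)
  b <- pmin(floor(v * bins), bins - 1L)
  counts <- tabulate(b + 1L, nbins = bins)
  p <- counts / length(v)
  centers <- (seq_len(bins) - 0.5) / bins
  best_k <- NA_integer_
  best_s <- -Inf
  for (k in seq_len(bins - 1L)) {
    w0 <- sum(p[1:k])
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:k] * centers[1:k]) / w0
    mu1 <- sum(p[(k + 1):bins] * centers[(k + 1):bins]) / w1
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best_s) {
      best_s <- s
      best_k <- k
    }
  }
  list(threshold = best_k / bins, between_class_variance = best_s)
}

# small noiseless phantom for fast unit tests
tiny_phantom <- function(size = 128L, defects = character(), seed = 1L,
                         noise_sigma = 0) {
  generate_phantom(phantom_spec(size = c(size, size), defects = defects,
                                noise_sigma = noise_sigma, seed = seed))
}

pad_mask <- function(m, k, value = 0L) {
  h <- nrow(m) + 2L * k
  w <- ncol(m) + 2L * k
  out <- matrix(as.integer(value), h, w)
  out[(k + 1):(k + nrow(m)), (k + 1):(k + ncol(m))] <- m
  out
}
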