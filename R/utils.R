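# Internal helpers: seeded RNG scoping, 2D FFT wrappers, small validators.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All stochastic operations in the package go through this,
# which is what makes every output a pure function of (inputs, seed).
with_local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream seed from a master seed and integer indices, staying inside
# the 32-bit signed range R requires of set.seed().
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in idx) {
    x <- (x * 48271 + as.double(k) * 2654435761) %% 2147483647
  }
  as.integer(x)
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Centered frequency coordinates (cycles per micron) for an nr x nc grid,
# in FFT (wrap-around) order. Rows are y, columns are x.
freq_grid <- function(nr, nc, pixel_size) {
  fy <- c(0:(ceiling(nr / 2) - 1), -(floor(nr / 2):1)) / (nr * pixel_size)
  fx <- c(0:(ceiling(nc / 2) - 1), -(floor(nc / 2):1)) / (nc * pixel_size)
  list(
    fy = matrix(fy, nr, nc, byrow = FALSE),
    fx = matrix(fx, nr, nc, byrow = TRUE)
  )
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

as_mask <- function(x, name = "mask") {
  if (is.logical(x) && is.matrix(x)) return(x)
  if (is.numeric(x) && is.matrix(x)) return(x != 0)
  stop(sprintf("`%s` must be a logical matrix", name), call. = FALSE)
}

# Otsu's threshold on a numeric vector (used for Canny hysteresis defaults).
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L || diff(range(x)) == 0) return(ifelse(length(x), x[1], 0))
  h <- hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1L),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' @importFrom graphics hist
NULL
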