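# Forward DPC simulation and Tikhonov inversion.
#
# Model: first-order weak-object phase transfer function for partially
# coherent oblique illumination. The effective source for each shear axis is a
# half-pupil (the pupil disc restricted to positive frequency along that
# axis), which yields an antisymmetric, DC-null transfer function — the two
# properties the reconstruction relies on. The DPC convention is the
# normalized difference (I_a - I_b) / (I_a + I_b), making DPC values
# dimensionless and bounded in [-1, 1].
#
# The DC component of phase is unrecoverable (H(0) = 0): recovered phase is
# reported mean-zero, and RI maps derived from it are relative to the field
# mean plus the medium RI. Absolute wall-RI comparisons inherit this offset.

#' Phase image container
#'
#' @param grid 2D numeric matrix of phase differences (radians).
#' @param pixel_size um per pixel.
#' @return an object of class `"phase_image"`.
#' @export
phase_image <- function(grid, pixel_size) {
  stopifnot(is.matrix(grid), all(is.finite(grid)))
  stopifnot_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  structure(list(grid = grid, pixel_size = pixel_size), class = "phase_image")
}

.tf_cache <- new.env(parent = emptyenv())

#' Compute the DPC phase transfer functions for an image grid
#'
#' Builds the weak-object phase transfer function pair (x-shear, y-shear) on
#' the FFT frequency grid of an `image_shape` image: a circular pupil of
#' radius `NA / wavelength` (cycles/um) correlated against itself weighted by
#' a half-pupil source, normalized by the background intensity, then
#' antisymmetrized exactly so that `H(-u) = -H(u)` along the shear axis and
#' `H(0, 0) = 0` hold to machine precision. Support is clipped to the
#' partially coherent cutoff `2 NA / wavelength`.
#'
#' @param config an [optical_config()].
#' @param image_shape integer pair `(ny, nx)`, both at least 8.
#' @return an object of class `"transfer_function_set"`: list with complex
#'   matrices `Hx`, `Hy` (FFT wrap order), `shape`, and `config`.
#' @export
compute_transfer_functions <- function(config, image_shape) {
  stopifnot(inherits(config, "optical_config"))
  if (length(image_shape) != 2L || any(image_shape < 8)) {
    stop("`image_shape` must be two integers >= 8")
  }
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  key <- paste(nr, nc, config$pixel_size, config$numerical_aperture,
               config$wavelength, sep = "|")
  if (!is.null(.tf_cache[[key]])) return(.tf_cache[[key]])

  cutoff <- config$numerical_aperture / config$wavelength # coherent, cycles/um
  fg <- freq_grid(nr, nc, config$pixel_size)
  if (!any(sqrt(fg$fx^2 + fg$fy^2) <= cutoff & (fg$fx != 0 | fg$fy != 0))) {
    stop("numerical aperture yields an empty passband on this grid")
  }

  # correlations are computed on a 2x zero-padded frequency lattice (same
  # frequency spacing, wider extent) to avoid circular wrap-around
  mr <- 2L * nr; mc <- 2L * nc
  # the padded lattice keeps the image grid's frequency spacing but doubles
  # its extent; coordinates are built explicitly (wrap order, frequency s*df)
  df_y <- 1 / (nr * config$pixel_size)
  df_x <- 1 / (nc * config$pixel_size)
  sy <- c(0:(mr / 2 - 1), -(mr / 2):-1)
  sx <- c(0:(mc / 2 - 1), -(mc / 2):-1)
  fyp <- matrix(sy * df_y, mr, mc, byrow = FALSE)
  fxp <- matrix(sx * df_x, mr, mc, byrow = TRUE)
  rho <- sqrt(fxp^2 + fyp^2)
  P <- (rho <= cutoff) * 1.0

  corr <- function(S) {
    A <- S * P
    # circular cross-correlation C[k] = sum_s A[s] B[s+k], B = P
    Re(ifft2(Conj(fft2(A)) * fft2(P)))
  }
  half_x <- P * (fxp > 0)
  half_y <- P * (fyp > 0)
  Cx <- corr(half_x)
  Cy <- corr(half_y)
  bgx <- sum(half_x * P^2)
  bgy <- sum(half_y * P^2)

  # map padded-lattice values onto the image FFT grid (signed index mod m)
  pick <- function(C) {
    isy <- c(0:(ceiling(nr / 2) - 1), -(floor(nr / 2)):-1)
    isx <- c(0:(ceiling(nc / 2) - 1), -(floor(nc / 2)):-1)
    ry <- (isy %% mr) + 1L
    rx <- (isx %% mc) + 1L
    C[ry, rx, drop = FALSE]
  }
  neg_index <- function(n) ((-(c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1))) %% n) + 1L

  make_H <- function(C, bg_axis, axis) {
    Cn <- pick(C)
    # H_raw(u) = C(u) - C(-u): negate both axes on the padded result
    isy <- c(0:(ceiling(nr / 2) - 1), -(floor(nr / 2)):-1)
    isx <- c(0:(ceiling(nc / 2) - 1), -(floor(nc / 2)):-1)
    ryn <- ((-isy) %% mr) + 1L
    rxn <- ((-isx) %% mc) + 1L
    Cneg <- C[ryn, rxn, drop = FALSE]
    H <- (Cn - Cneg) / bg_axis
    # exact antisymmetrization along the shear axis
    if (axis == "x") {
      H <- (H - H[, neg_index(nc), drop = FALSE]) / 2
    } else {
      H <- (H - H[neg_index(nr), , drop = FALSE]) / 2
    }
    # clip to the partially coherent support
    H[sqrt(fg$fx^2 + fg$fy^2) > 2 * cutoff] <- 0
    H[1, 1] <- 0
    (1i) * H
  }
  tfs <- structure(
    list(Hx = make_H(Cx, bgx, "x"), Hy = make_H(Cy, bgy, "y"),
         shape = c(nr, nc), config = config),
    class = "transfer_function_set"
  )
  .tf_cache[[key]] <- tfs
  tfs
}

#' Simulate a four-direction DPC acquisition from a phase image
#'
#' Weak-phase forward model: the normalized intensity modulation along each
#' shear axis is the real part of the inverse transform of `H * F[phi]`;
#' opposing source azimuths carry opposite modulation sign. With a finite
#' `photon_budget` the four images are Poisson realizations with that expected
#' count per pixel; with `photon_budget = Inf` they are exact (noiseless).
#'
#' @param phase a [phase_image()].
#' @param tfs a [compute_transfer_functions()] result on the same grid.
#' @param photon_budget expected photons per pixel (`Inf` = noiseless).
#' @param seed integer seed for the Poisson noise (ignored when noiseless).
#' @return an object of class `"raw_quad"`: intensity matrices `I000`, `I090`,
#'   `I180`, `I270` (source azimuth in degrees) plus `exposure`.
#' @export
simulate_acquisition <- function(phase, tfs, photon_budget = Inf, seed = 1L) {
  stopifnot(inherits(phase, "phase_image"),
            inherits(tfs, "transfer_function_set"))
  if (!all(dim(phase$grid) == tfs$shape)) stop("phase/tfs grid mismatch")
  if (!(photon_budget > 0)) stop("`photon_budget` must be > 0")
  PH <- fft2(phase$grid)
  mx <- Re(ifft2(tfs$Hx * PH))
  my <- Re(ifft2(tfs$Hy * PH))
  mmax <- max(abs(mx), abs(my))
  if (mmax >= 1) {
    stop(sprintf(
      "phase violates the weak-phase regime (max |modulation| = %.3f >= 1)",
      mmax))
  }
  scale <- if (is.finite(photon_budget)) photon_budget else 1
  I000 <- scale * (1 + mx); I180 <- scale * (1 - mx)
  I090 <- scale * (1 + my); I270 <- scale * (1 - my)
  if (is.finite(photon_budget)) {
    d <- dim(I000)
    noisify <- function(I) matrix(rpois(length(I), lambda = I), d[1], d[2])
    quad <- with_local_seed(seed, list(
      I000 = noisify(I000), I090 = noisify(I090),
      I180 = noisify(I180), I270 = noisify(I270)))
  } else {
    quad <- list(I000 = I000, I090 = I090, I180 = I180, I270 = I270)
  }
  structure(c(quad, list(exposure = photon_budget)), class = "raw_quad")
}

#' Form the normalized DPC image pair from a four-direction acquisition
#'
#' Each DPC image is the per-pixel normalized difference of one opposing
#' source pair: `(I_a - I_b) / (I_a + I_b)`. Pixels where the pair sums to
#' zero are mapped to 0 and counted in the `n_zero_sum` attribute.
#'
#' @param quad a [simulate_acquisition()] result, or any list with
#'   nonnegative matrices `I000`, `I090`, `I180`, `I270` of equal shape.
#' @return an object of class `"dpc_pair"`: matrices `dx` (0/180 shear) and
#'   `dy` (90/270 shear), values in `[-1, 1]`.
#' @export
form_dpc <- function(quad) {
  imgs <- quad[c("I000", "I090", "I180", "I270")]
  if (any(vapply(imgs, is.null, logical(1)))) {
    stop("`quad` must contain I000, I090, I180, I270")
  }
  dims <- unique(lapply(imgs, dim))
  if (length(dims) != 1L) stop("intensity images differ in shape")
  if (min(vapply(imgs, min, numeric(1))) < 0) stop("intensities must be >= 0")
  nd <- function(a, b) {
    s <- a + b
    out <- (a - b) / s
    out[s == 0] <- 0
    out
  }
  dx <- nd(quad$I000, quad$I180)
  dy <- nd(quad$I090, quad$I270)
  n_zero <- sum(quad$I000 + quad$I180 == 0) + sum(quad$I090 + quad$I270 == 0)
  structure(list(dx = dx, dy = dy, n_zero_sum = n_zero), class = "dpc_pair")
}

#' Recover phase from a DPC pair by Tikhonov-regularized deconvolution
#'
#' Frequency-domain inversion
#' `phi = F^-1[ (conj(Hx) F[dx] + conj(Hy) F[dy]) / (|Hx|^2 + |Hy|^2 + alpha) ]`.
#' The DC phase component is unrecoverable; the output is reported mean-zero
#' (stated convention).
#'
#' @param dpc a [form_dpc()] result.
#' @param tfs the [compute_transfer_functions()] set on the same grid.
#' @param alpha Tikhonov regularization constant (> 0); defaults to the
#'   config's `tikhonov_alpha`.
#' @return a [phase_image()].
#' @export
recover_phase <- function(dpc, tfs, alpha = NULL) {
  stopifnot(inherits(dpc, "dpc_pair"), inherits(tfs, "transfer_function_set"))
  if (is.null(alpha)) alpha <- tfs$config$tikhonov_alpha
  if (!(alpha > 0)) stop("`alpha` must be > 0")
  if (!all(dim(dpc$dx) == tfs$shape)) stop("dpc/tfs grid mismatch")
  num <- Conj(tfs$Hx) * fft2(dpc$dx) + Conj(tfs$Hy) * fft2(dpc$dy)
  den <- Mod(tfs$Hx)^2 + Mod(tfs$Hy)^2 + alpha
  phi <- Re(ifft2(num / den))
  phi <- phi - mean(phi)
  phase_image(phi, tfs$config$pixel_size)
}

#' Convert a phase image to an absolute refractive-index map
#'
#' Per pixel, `n = nm + wavelength * phi / (2 * pi * slice_thickness_dz)`:
#' the RI excess over the medium is proportional to the measured phase
#' difference through the effective optical slice thickness.
#'
#' @param phase a [phase_image()] or bare numeric matrix of radians.
#' @param config an [optical_config()].
#' @return numeric matrix of absolute RI.
#' @export
phase_to_ri <- function(phase, config) {
  stopifnot(inherits(config, "optical_config"))
  g <- if (inherits(phase, "phase_image")) phase$grid else phase
  config$medium_ri_nm +
    config$wavelength * g / (2 * pi * config$slice_thickness_dz)
}

#' Convert a refractive-index map to a phase image
#'
#' Exact inverse of [phase_to_ri()]:
#' `phi = 2 * pi * slice_thickness_dz * (n - nm) / wavelength`.
#'
#' @param ri_map numeric matrix of absolute RI.
#' @param config an [optical_config()].
#' @return a [phase_image()].
#' @export
ri_to_phase <- function(ri_map, config) {
  stopifnot(inherits(config, "optical_config"), is.matrix(ri_map))
  g <- 2 * pi * config$slice_thickness_dz *
    (ri_map - config$medium_ri_nm) / config$wavelength
  phase_image(g, config$pixel_size)
}

#' Simulate acquisition and recover an RI stack from a ground-truth volume
#'
#' Runs, per axial slice: RI -> phase -> simulated four-direction acquisition
#' (optionally noisy) -> normalized DPC -> Tikhonov phase recovery -> RI.
#' Because the DC phase is unrecoverable, each recovered slice is relative to
#' its field mean plus the medium RI.
#'
#' @param vol an `"ri_volume"` (from [build_ri_volume()]) or array `[y, x, z]`.
#' @param config an [optical_config()].
#' @param photon_budget photons per pixel (`Inf` = noiseless).
#' @param seed integer seed (one independent noise stream per slice).
#' @param alpha Tikhonov constant; default from `config`.
#' @return `"ri_volume"`-shaped list with the recovered `grid`.
#' @export
reconstruct_volume <- function(vol, config, photon_budget = Inf, seed = 1L,
                               alpha = NULL) {
  grid <- if (inherits(vol, "ri_volume")) vol$grid else vol
  stopifnot(is.array(grid), length(dim(grid)) == 3L)
  tfs <- compute_transfer_functions(config, dim(grid)[1:2])
  nz <- dim(grid)[3]
  out <- array(config$medium_ri_nm, dim = dim(grid))
  for (k in seq_len(nz)) {
    ph <- ri_to_phase(grid[, , k], config)
    quad <- simulate_acquisition(ph, tfs, photon_budget,
                                 seed = derive_seed(seed, k))
    rec <- recover_phase(form_dpc(quad), tfs, alpha)
    out[, , k] <- phase_to_ri(rec, config)
  }
  structure(
    list(grid = out, labels = if (inherits(vol, "ri_volume")) vol$labels,
         pixel_size = config$pixel_size, z_step = config$z_step,
         widest_z = if (inherits(vol, "ri_volume")) vol$widest_z,
         spec = if (inherits(vol, "ri_volume")) vol$spec),
    class = "ri_volume"
  )
}

#' Export a transfer-function set as a paired real/imaginary TIFF
#'
#' @param tfs a [compute_transfer_functions()] result.
#' @param path output TIFF path (two float32 pages: real, imaginary of `Hx`,
#'   then of `Hy` — four pages total).
#' @return `path`, invisibly.
#' @export
export_transfer_functions <- function(tfs, path) {
  stopifnot(inherits(tfs, "transfer_function_set"))
  write_tiff(path, list(Re(tfs$Hx), Im(tfs$Hx), Re(tfs$Hy), Im(tfs$Hy)))
}
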