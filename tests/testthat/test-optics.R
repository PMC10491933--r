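oc <- default_oc()

test_that("transfer functions have an exact DC null and odd symmetry", {
  tfs <- compute_transfer_functions(oc, c(64, 96))
  neg_idx <- function(n) ((-(c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1))) %% n) + 1
  expect_identical(tfs$Hx[1, 1], 0 + 0i)
  expect_identical(tfs$Hy[1, 1], 0 + 0i)
  expect_equal(max(Mod(tfs$Hx + tfs$Hx[, neg_idx(96)])), 0)
  expect_equal(max(Mod(tfs$Hy + tfs$Hy[neg_idx(64), ])), 0)
  # support bounded by the partially coherent cutoff 2 NA / lambda
  fy <- c(0:31, -32:-1) / (64 * oc$pixel_size)
  fx <- c(0:47, -48:-1) / (96 * oc$pixel_size)
  rho <- sqrt(outer(fy^2, fx^2, "+"))
  cutoff2 <- 2 * oc$numerical_aperture / oc$wavelength
  expect_true(all(Mod(tfs$Hx)[rho > cutoff2] == 0))
})

test_that("passband support grows with numerical aperture", {
  n_sup <- vapply(c(0.3, 0.6), function(na) {
    tfs <- compute_transfer_functions(optical_config(pixel_size = 0.5,
                                                     numerical_aperture = na),
                                      c(64, 64))
    sum(Mod(tfs$Hx) > 1e-6)
  }, numeric(1))
  expect_gt(n_sup[2], n_sup[1])
  expect_error(
    compute_transfer_functions(optical_config(pixel_size = 0.5,
                                              numerical_aperture = 1e-4),
                               c(16, 16)),
    "empty passband")
})

test_that("form_dpc is the normalized difference with zero-sum handling", {
  u <- matrix(3, 8, 8)
  quad <- list(I000 = u, I090 = u, I180 = matrix(1, 8, 8), I270 = u)
  d <- form_dpc(quad)
  expect_equal(d$dx, matrix(0.5, 8, 8))
  expect_equal(d$dy, matrix(0, 8, 8))
  z <- matrix(0, 8, 8)
  dz <- form_dpc(list(I000 = z, I090 = z, I180 = z, I270 = z))
  expect_equal(dz$dx, z)
  expect_equal(dz$n_zero_sum, 128)
  # property: random nonnegative quads give values in [-1, 1]
  set.seed(4)
  for (k in 1:20) {
    q <- lapply(1:4, function(i) matrix(rexp(64), 8, 8))
    names(q) <- c("I000", "I090", "I180", "I270")
    dd <- form_dpc(q)
    expect_true(all(abs(dd$dx) <= 1), all(abs(dd$dy) <= 1))
  }
  expect_error(form_dpc(list(I000 = u, I090 = u, I180 = matrix(1, 4, 4),
                             I270 = u)), "shape")
})

# band-pass random phase phantom (independent of the transfer functions)
band_phantom <- function(n, oc, amplitude = 0.3, seed = 42) {
  withr::with_seed(seed, {
    F <- stats::fft(matrix(rnorm(n * n), n, n))
    fr <- c(0:(n / 2 - 1), -(n / 2):-1) / (n * oc$pixel_size)
    rho <- sqrt(outer(fr^2, fr^2, "+"))
    cutoff <- oc$numerical_aperture / oc$wavelength
    band <- exp(-((rho - 0.45 * cutoff) / (0.18 * cutoff))^2)
    phi <- Re(stats::fft(F * band, inverse = TRUE)) / (n * n)
    phi <- amplitude * phi / max(abs(phi))
    phase_image(phi - mean(phi), oc$pixel_size)
  })
}

test_that("zero phase gives four identical images; seeds reproduce noise", {
  tfs <- compute_transfer_functions(oc, c(32, 32))
  ph <- phase_image(matrix(0, 32, 32), oc$pixel_size)
  q <- simulate_acquisition(ph, tfs, photon_budget = Inf)
  expect_identical(q$I000, q$I180)
  expect_identical(q$I090, q$I270)
  q1 <- simulate_acquisition(ph, tfs, photon_budget = 100, seed = 7)
  q2 <- simulate_acquisition(ph, tfs, photon_budget = 100, seed = 7)
  expect_identical(q1$I000, q2$I000)
  q3 <- simulate_acquisition(ph, tfs, photon_budget = 100, seed = 8)
  expect_false(identical(q1$I000, q3$I000))
  # weak-phase violation is diagnosed
  big <- phase_image(matrix(20 * sin(seq_len(32) / 2), 32, 32), oc$pixel_size)
  expect_error(simulate_acquisition(big, tfs, Inf), "weak-phase")
})

test_that("noiseless round trip recovers a band-limited phantom", {
  tfs <- compute_transfer_functions(oc, c(128, 128))
  ph <- band_phantom(128, oc)
  rec <- recover_phase(form_dpc(simulate_acquisition(ph, tfs, Inf)), tfs,
                       alpha = 1e-4)
  expect_equal(mean(rec$grid), 0)
  expect_gte(cor(as.vector(rec$grid), as.vector(ph$grid)), 0.99)
  den <- Mod(tfs$Hx)^2 + Mod(tfs$Hy)^2
  pb <- den > 1e-2 * max(den)
  Ft <- stats::fft(ph$grid); Fr <- stats::fft(rec$grid)
  rel <- sqrt(sum(Mod(Fr - Ft)[pb]^2) / sum(Mod(Ft)[pb]^2))
  expect_lte(rel, 0.05)
})

test_that("zero DPC recovers zero phase and alpha damps noise variance", {
  tfs <- compute_transfer_functions(oc, c(64, 64))
  z <- matrix(0, 64, 64)
  dpc0 <- form_dpc(list(I000 = z + 1, I090 = z + 1, I180 = z + 1, I270 = z + 1))
  expect_equal(recover_phase(dpc0, tfs)$grid, z)
  ph <- band_phantom(64, oc, amplitude = 0.1)
  q <- simulate_acquisition(ph, tfs, photon_budget = 100, seed = 1)
  d <- form_dpc(q)
  vars <- vapply(c(1e-4, 1e-2, 1), function(a) {
    var(as.vector(recover_phase(d, tfs, alpha = a)$grid))
  }, numeric(1))
  expect_true(all(diff(vars) <= 0))
  expect_error(recover_phase(d, tfs, alpha = 0), "alpha")
})

test_that("recover_phase is linear in its DPC input", {
  tfs <- compute_transfer_functions(oc, c(32, 32))
  set.seed(5)
  mk <- function() {
    structure(list(dx = matrix(rnorm(1024, sd = 0.1), 32, 32),
                   dy = matrix(rnorm(1024, sd = 0.1), 32, 32)),
              class = "dpc_pair")
  }
  d1 <- mk(); d2 <- mk()
  dsum <- structure(list(dx = d1$dx + 2 * d2$dx, dy = d1$dy + 2 * d2$dy),
                    class = "dpc_pair")
  lhs <- recover_phase(dsum, tfs, alpha = 1e-3)$grid
  rhs <- recover_phase(d1, tfs, alpha = 1e-3)$grid +
    2 * recover_phase(d2, tfs, alpha = 1e-3)$grid
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("recovered-phase RMSE decreases with photon budget", {
  tfs <- compute_transfer_functions(oc, c(64, 64))
  ph <- band_phantom(64, oc, amplitude = 0.2)
  rmse <- function(budget, seed) {
    rec <- recover_phase(form_dpc(simulate_acquisition(ph, tfs, budget,
                                                       seed = seed)), tfs)
    sqrt(mean((rec$grid - ph$grid)^2))
  }
  for (s in 1:3) {
    r <- vapply(c(1e2, 1e3, 1e4), rmse, numeric(1), seed = s)
    expect_true(all(diff(r) < 0))
  }
})

test_that("phase/RI conversion matches the linear relation exactly", {
  # lambda 0.72 um, dz 3.2 um, dphi 1 rad: delta n = 0.72 / (2 pi 3.2)
  ri <- phase_to_ri(phase_image(matrix(1, 4, 4), 0.5), oc)
  expect_equal(ri, matrix(1.3440 + 0.72 / (2 * pi * 3.2), 4, 4))
  expect_equal(phase_to_ri(phase_image(matrix(0, 4, 4), 0.5), oc),
               matrix(1.3440, 4, 4))
  # dphi = 2 pi dz / lambda yields delta n = 1 exactly
  phi1 <- 2 * pi * oc$slice_thickness_dz / oc$wavelength
  expect_equal(phase_to_ri(phase_image(matrix(phi1, 2, 2), 0.5), oc),
               matrix(1.3440 + 1, 2, 2))
  # inverse: delta n 0.01 -> 0.2793 rad, and an exact round trip
  ph <- ri_to_phase(matrix(1.3540, 3, 3), oc)
  expect_equal(ph$grid[1, 1], 2 * pi * 3.2 * 0.01 / 0.72)
  set.seed(6)
  m <- matrix(1.3440 + rnorm(64, sd = 0.01), 8, 8)
  expect_equal(phase_to_ri(ri_to_phase(m, oc), oc), m, tolerance = 1e-14)
})
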