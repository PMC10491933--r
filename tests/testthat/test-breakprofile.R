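test_that("break endpoints: closed annulus none, broken arc two near truth", {
  ann <- mk_annulus(201, 90, 100)
  expect_equal(nrow(find_break_endpoints(ann)), 0)
  theta <- theta_map(201)
  broken <- ann & !(theta > 0.3 & theta < 0.8)
  ep <- find_break_endpoints(broken)
  expect_equal(nrow(ep), 2)
  analytic <- rbind(c(101 + 95 * sin(0.3), 101 + 95 * cos(0.3)),
                    c(101 + 95 * sin(0.8), 101 + 95 * cos(0.8)))
  for (k in 1:2) {
    d <- sqrt(rowSums((analytic - matrix(as.numeric(ep[k, ]), 2, 2,
                                         byrow = TRUE))^2))
    expect_lte(min(d), 3)
  }
})

test_that("a straight open band has endpoints exactly at its ends", {
  band <- matrix(FALSE, 40, 80)
  band[20, 10:70] <- TRUE
  ep <- find_break_endpoints(band)
  expect_equal(nrow(ep), 2)
  expect_setequal(ep[, "col"], c(10, 70))
  expect_true(all(ep[, "row"] == 20))
})

test_that("geodesic distances match the brute-force Dijkstra oracle exactly", {
  set.seed(31)
  for (trial in 1:4) {
    m <- matrix(runif(48 * 48) < 0.55, 48, 48)
    src_idx <- which(m)
    if (length(src_idx) == 0) next
    s <- src_idx[1]
    src <- c((s - 1) %% 48 + 1, (s - 1) %/% 48 + 1)
    got <- wall_distance_from_break(m, src, pixel_size = 1)
    want <- bf_geodesic(m, src)
    expect_equal(got, want)
  }
})

test_that("geodesic path arithmetic: straight, diagonal, and the source", {
  band <- matrix(FALSE, 40, 64); band[20, 5:60] <- TRUE
  d <- wall_distance_from_break(band, c(20, 5), 1)
  expect_equal(d[20, 5], 0)
  expect_equal(d[20, 35], 30)
  diagm <- matrix(FALSE, 64, 64)
  for (k in 0:20) diagm[10 + k, 10 + k] <- TRUE
  dd <- wall_distance_from_break(diagm, c(10, 10), 1)
  expect_equal(dd[20, 20], 10 * sqrt(2))
  # scaling by pixel size
  expect_equal(wall_distance_from_break(band, c(20, 5), 0.5)[20, 35], 15)
  expect_error(wall_distance_from_break(band, c(1, 1), 1), "disconnected")
})

test_that("distances never decrease when the source moves and grow with the mask", {
  # monotone under mask growth: adding pixels can only shorten or keep paths
  m_small <- matrix(FALSE, 30, 30)
  m_small[15, 3:27] <- TRUE
  m_small[3:27, 15] <- TRUE
  m_big <- m_small
  m_big[10, 3:27] <- TRUE
  m_big[3:27, 10] <- TRUE
  d_small <- wall_distance_from_break(m_small, c(15, 3), 1)
  d_big <- wall_distance_from_break(m_big, c(15, 3), 1)
  on_both <- m_small & is.finite(d_small)
  expect_true(all(d_big[on_both] <= d_small[on_both] + 1e-12))
})

test_that("moving profile: constants, step transition, degenerate windows", {
  set.seed(8)
  d <- runif(300, 0, 120)
  v <- rep(1.38, 300)
  mp <- moving_profile(d, v, window = 20, step = 1)
  ok <- mp$n_samples >= 3
  expect_true(all(abs(mp$moving_mean[ok] - 1.38) < 1e-12))
  expect_true(all(mp$moving_sd[ok] == 0))
  expect_true(all(is.na(mp$moving_mean[!ok])))
  # agreement with the direct windowed oracle on random data
  v2 <- rnorm(300, 1.37, 0.01)
  mp2 <- moving_profile(d, v2, window = 20, step = 1)
  want <- bf_moving(d, v2, mp2$distance, 20)
  expect_equal(mp2$moving_mean, want[, 1])
  expect_equal(mp2$moving_sd, want[, 2])
  # step profile transitions monotonically within one window of the step
  ds <- seq(0, 200, by = 0.5)
  vs <- ifelse(ds < 100, 1.35, 1.39)
  mps <- moving_profile(ds, vs, window = 20, step = 1)
  inwin <- mps$distance >= 90 & mps$distance <= 110
  expect_true(all(diff(mps$moving_mean[inwin]) >= 0))
  expect_true(all(mps$moving_mean[mps$distance < 90] == 1.35))
  expect_true(all(mps$moving_mean[mps$distance > 110] == 1.39))
  # window smaller than sample spacing: gaps, not exceptions
  sparse <- moving_profile(c(0, 10, 20, 30), rep(1, 4), window = 2, step = 5)
  expect_true(any(sparse$n_samples < 3))
  # window covering the whole span equals the plain mean
  wide <- moving_profile(ds, vs, window = 1000, step = 50)
  expect_true(all(abs(wide$moving_mean - mean(vs)) < 1e-12))
})

test_that("region classification follows the 50/350 um bounds", {
  cr <- classify_regions(c(10, 200, 400), c(1.35, 1.36, 1.37))
  expect_identical(cr$labels, c("near", "mid", "far"))
  # boundary pixels at exactly 50 and 350 go to mid
  cb <- classify_regions(c(50, 350), c(1, 2))
  expect_identical(cb$labels, c("mid", "mid"))
  # pixel counts sum to the total
  set.seed(10)
  d <- runif(500, 0, 600)
  cs <- classify_regions(d, rnorm(500))
  expect_equal(sum(cs$summary$n), 500)
  # all-near inputs leave mid and far empty without error
  ca <- classify_regions(c(5, 12, 40), c(1, 2, 3))
  expect_equal(ca$summary$n[ca$summary$region %in% c("mid", "far")], c(0, 0))
})

test_that("a constructed break phantom reproduces the near/mid/far structure", {
  # long straight wall: RI depressed near the break, erratic in the mid zone
  n_len <- 1200
  wall <- matrix(FALSE, 24, n_len)
  wall[11:14, 3:(n_len - 2)] <- TRUE
  px <- 0.5 # um/px: distances up to ~600 um
  ri <- matrix(1.3440, 24, n_len)
  dist_um <- (col(wall) - 3) * px
  set.seed(12)
  base <- 1.380
  vals <- ifelse(dist_um < 50, base - 0.010,
                 ifelse(dist_um <= 350, base + rnorm(length(dist_um), 0, 0.008),
                        base + rnorm(length(dist_um), 0, 0.001)))
  ri[wall] <- vals[wall]
  bp <- break_profile(wall, ri, pixel_size = px,
                      break_points = c(12, 3), window = 20)
  s <- bp$region_summary
  near <- s[s$region == "near", ]; mid <- s[s$region == "mid", ]
  far <- s[s$region == "far", ]
  expect_lt(near$mean_ri, far$mean_ri)
  expect_gt(mid$sd_ri, far$sd_ri)
  expect_equal(sum(s$n), length(bp$distances))
})
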