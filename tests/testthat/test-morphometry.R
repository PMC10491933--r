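test_that("annulus wall thickness concentrates at the analytic value", {
  # inner 40 px, outer 50 px at 0.25 um/px: true thickness 10 px = 2.5 um
  ann <- mk_annulus(129, 40, 50)
  th <- wall_thickness(ann, 0.25)
  expect_gte(median(th), 2.5 - 0.25)
  expect_lte(median(th), 2.5 + 0.25)
  expect_true(all(th > 0))
})

test_that("a one-pixel-wide ring measures exactly one pixel", {
  ring <- mk_square_ring(41, 15)
  th <- wall_thickness(ring, 0.25)
  expect_true(all(th == 0.25))
})

test_that("break-tip samples are excluded, the rest unchanged", {
  ann <- mk_annulus(129, 40, 50)
  theta <- theta_map(129)
  broken <- ann & !(theta > 0.2 & theta < 0.7)
  th_closed <- wall_thickness(ann, 0.25)
  th_broken <- wall_thickness(broken, 0.25)
  expect_lt(length(th_broken), length(th_closed))
  expect_equal(median(th_broken), median(th_closed), tolerance = 0.1)
  # the ray-casting cross-check agrees within 15% (no warning raised)
  expect_no_warning(wall_thickness(ann, 0.25, cross_check = TRUE))
})

test_that("lumen diameter is the maximal inscribed circle", {
  expect_equal(as.numeric(lumen_diameter(mk_disc(161, 60), 0.25)), 30.0)
  # single pixel
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  expect_equal(as.numeric(lumen_diameter(one, 0.25)), 0.5)
  # ellipse with 80 x 40 px semi-axes is limited by the minor axis
  n <- 201; c0 <- 101
  el <- outer(((1:n) - c0)^2 / 40^2, ((1:n) - c0)^2 / 80^2, "+") < 1
  expect_equal(as.numeric(lumen_diameter(el, 1)), 80)
  expect_error(lumen_diameter(matrix(FALSE, 4, 4), 1), "empty")
})

test_that("the diameter filter is a strict inequality and idempotent", {
  df <- data.frame(diameter = c(19, 20, 25))
  out <- apply_diameter_filter(df, threshold = 20)
  expect_identical(out$included, c(FALSE, FALSE, TRUE))
  expect_identical(apply_diameter_filter(out, 20), out)
})

test_that("wall RI statistics are the sample mean and SD", {
  ri <- matrix(1.3440, 5, 5)
  wall <- matrix(FALSE, 5, 5)
  wall[1, 1:3] <- TRUE
  ri[1, 1:3] <- c(1.36, 1.38, 1.40)
  st <- wall_ri_stats(ri, wall)
  expect_equal(st$wall_ri_mean, 1.38)
  expect_equal(st$wall_ri_sd, 0.02)
  wall1 <- matrix(FALSE, 5, 5); wall1[2, 2] <- TRUE
  ri[2, 2] <- 1.38
  st1 <- wall_ri_stats(ri, wall1)
  expect_equal(st1$wall_ri_sd, 0)
  expect_error(wall_ri_stats(ri, wall & FALSE), "empty")
})

test_that("length outputs scale exactly with pixel size", {
  ann <- mk_annulus(101, 25, 32)
  expect_equal(wall_thickness(ann, 1.0), 2 * wall_thickness(ann, 0.5))
  expect_equal(as.numeric(lumen_diameter(mk_disc(101, 30), 1.0)),
               2 * as.numeric(lumen_diameter(mk_disc(101, 30), 0.5)))
})

test_that("thickness is robust to rotation of the mask", {
  # exact invariance under 90-degree raster rotation of an off-center annulus
  ann <- mk_annulus(161, 30, 38, ci = 61)
  rot90 <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  t0 <- wall_thickness(ann, 1)
  t90 <- wall_thickness(rot90(ann), 1)
  expect_equal(sort(t0), sort(t90))
  # a band rotated off-lattice by 30 degrees stays within one pixel of the
  # continuous-width annulus reading at the same wall width
  mk_band <- function(angle) {
    n <- 161; c0 <- 81
    yy <- outer(seq_len(n) - c0, rep(1, n))
    xx <- outer(rep(1, n), seq_len(n) - c0)
    u <- yy * cos(angle) - xx * sin(angle)
    v <- yy * sin(angle) + xx * cos(angle)
    abs(u) <= 5 & abs(v) <= 60 # continuous width 10
  }
  t30 <- median(wall_thickness(mk_band(pi / 6), 1))
  expect_lte(abs(t30 - 10), 1 + 1e-9)
})

test_that("vessel_metrics assembles a coherent record", {
  intm <- mk_disc(161, 50)
  wall <- mk_annulus(161, 50, 58)
  cells <- mk_disc(161, 20)
  ms <- vessel_mask_set(intm, wall, cells, slice_index = 2, pixel_size = 0.5)
  ri <- matrix(1.3440, 161, 161)
  ri[wall] <- 1.364
  vm <- vessel_metrics(ri, ms, vessel_id = "v1")
  expect_s3_class(vm, "vessel_metrics")
  expect_equal(vm$diameter, 50, tolerance = 0.02)
  expect_true(vm$included) # 50 um > 20 um
  expect_equal(vm$percent_fill, 100 * sum(cells) / sum(intm))
  expect_equal(vm$wall_ri_mean, 1.364)
  expect_equal(vm$mean_thickness, mean(vm$thickness_samples))
})
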