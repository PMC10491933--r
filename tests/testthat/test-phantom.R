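oc <- optical_config(pixel_size = 0.5)

test_that("empty phantom is exactly the medium RI everywhere", {
  sp <- phantom_spec(volume_shape = c(3, 64, 64), lumen_radius = 8,
                     wall_thickness = 3, wall_delta_n = 0,
                     target_fill_fraction = 0, seed = 1)
  vol <- build_ri_volume(sp, oc)
  expect_true(all(vol$grid == oc$medium_ri_nm))
})

test_that("cross-sectional central slice is an annulus matching analytic area", {
  # lumen 10 um, wall 4 um at 0.5 um/px: annulus inner radius 20 px, outer 28 px
  sp <- phantom_spec(volume_shape = c(3, 80, 80), lumen_radius = 10,
                     wall_thickness = 4, axis = "z", seed = 3)
  vol <- build_ri_volume(sp, oc)
  wall_px <- sum(vol$labels[, , 2] == 2L)
  expect_lt(abs(wall_px / (pi * (28^2 - 20^2)) - 1), 0.02)
  # background voxels are exactly nm; wall voxels exactly nm + delta
  expect_true(all(vol$grid[vol$labels == 0L] == oc$medium_ri_nm))
  expect_true(all(vol$grid[vol$labels == 2L] == oc$medium_ri_nm + 0.020))
})

test_that("generation is a pure function of the seed", {
  sp <- phantom_spec(volume_shape = c(5, 96, 96), target_fill_fraction = 40,
                     fiber_density = 5, seed = 11)
  v1 <- build_ri_volume(sp, oc)
  v2 <- build_ri_volume(sp, oc)
  expect_identical(v1$grid, v2$grid)
  expect_identical(v1$labels, v2$labels)
})

test_that("increasing wall_delta_n strictly increases mean wall RI", {
  means <- vapply(c(0.01, 0.02, 0.03), function(d) {
    sp <- phantom_spec(volume_shape = c(3, 64, 64), lumen_radius = 8,
                       wall_thickness = 3, wall_delta_n = d, seed = 2)
    vol <- build_ri_volume(sp, oc)
    mean(vol$grid[vol$labels == 2L])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("geometry that does not fit and invalid delta_n are rejected", {
  expect_error(
    build_ri_volume(phantom_spec(volume_shape = c(3, 40, 40),
                                 lumen_radius = 15, wall_thickness = 5), oc),
    "does not fit")
  expect_error(
    build_ri_volume(phantom_spec(volume_shape = c(3, 64, 64), lumen_radius = 8,
                                 wall_thickness = 3, wall_delta_n = -0.5), oc),
    "below 1.0")
})

test_that("break_arc removes wall material in the stated interval", {
  sp_closed <- phantom_spec(volume_shape = c(3, 100, 100), lumen_radius = 10,
                            wall_thickness = 4, axis = "z", seed = 4)
  sp_broken <- phantom_spec(volume_shape = c(3, 100, 100), lumen_radius = 10,
                            wall_thickness = 4, axis = "z",
                            break_arc = c(0.4, 1.0), seed = 4)
  w_closed <- build_ri_volume(sp_closed, oc)$labels[, , 2] == 2L
  broken <- build_ri_volume(sp_broken, oc)
  w_broken <- broken$labels[, , 2] == 2L
  expect_lt(sum(w_broken), sum(w_closed))
  # removed voxels revert exactly to the medium RI
  slice <- broken$grid[, , 2]
  expect_true(all(slice[w_closed & !w_broken] == oc$medium_ri_nm))
})

test_that("realize_fill hits its target within tolerance and respects seeds", {
  lum <- matrix(FALSE, 120, 120)
  lum[11:110, 11:110] <- TRUE
  sp <- phantom_spec(volume_shape = c(3, 64, 64), lumen_radius = 8,
                     wall_thickness = 3, cell_radius = 2.5,
                     target_fill_fraction = 50, seed = 5)
  expect_equal(nrow(realize_fill(
    phantom_spec(volume_shape = c(3, 64, 64), lumen_radius = 8,
                 wall_thickness = 3, target_fill_fraction = 0),
    lum, seed = 1, pixel_size = 0.5)$centers), 0)
  r1 <- realize_fill(sp, lum, seed = 5, pixel_size = 0.5)
  expect_gte(r1$achieved_fraction, 45)
  expect_lte(r1$achieved_fraction, 55)
  # cells fully inside the lumen
  expect_false(any(r1$cell_mask & !lum))
  r2 <- realize_fill(sp, lum, seed = 6, pixel_size = 0.5)
  expect_false(identical(r1$centers, r2$centers))
  expect_gte(r2$achieved_fraction, 45)
  expect_lte(r2$achieved_fraction, 55)
})

test_that("generate_cohort writes the right number of stacks, reproducibly", {
  outdir <- withr::local_tempdir()
  spec <- phantom_spec(volume_shape = c(3, 64, 64), lumen_radius = 8,
                       wall_thickness = 3)
  groups <- list(
    list(label = "g1", n_animals = 3L, n_vessels = 2L, spec = spec),
    list(label = "g2", n_animals = 3L, n_vessels = 2L, spec = spec))
  man <- generate_cohort(groups, oc, outdir, seed = 9)
  expect_equal(nrow(man), 12)
  expect_true(all(file.exists(man$stack_path)))
  expect_error(generate_cohort(groups, oc, outdir, seed = 9),
               "already exists")
  man2 <- generate_cohort(groups, oc, outdir, seed = 9, force = TRUE)
  expect_identical(man, man2)
})

test_that("per-animal parameter draws track their group distributions", {
  outdir <- withr::local_tempdir()
  spec_lo <- phantom_spec(volume_shape = c(3, 64, 64), lumen_radius = 8,
                          wall_thickness = 3, wall_delta_n = 0.020)
  spec_hi <- phantom_spec(volume_shape = c(3, 64, 64), lumen_radius = 8,
                          wall_thickness = 3, wall_delta_n = 0.030)
  groups <- list(
    list(label = "lo", n_animals = 10L, n_vessels = 1L, spec = spec_lo,
         vary = list(wall_delta_n = 0.002)),
    list(label = "hi", n_animals = 10L, n_vessels = 1L, spec = spec_hi,
         vary = list(wall_delta_n = 0.002)))
  man <- generate_cohort(groups, oc, outdir, seed = 17, write_stacks = FALSE)
  m_lo <- mean(man$wall_delta_n[man$group == "lo"])
  m_hi <- mean(man$wall_delta_n[man$group == "hi"])
  tol <- 3 * 0.002 / sqrt(10)
  expect_lt(abs(m_lo - 0.020), tol)
  expect_lt(abs(m_hi - 0.030), tol)
})

test_that("fiber structures raise wall RI without leaving the wall", {
  oc <- optical_config(pixel_size = 0.5)
  base <- phantom_spec(volume_shape = c(3, 96, 96), lumen_radius = 10,
                       wall_thickness = 4, seed = 21)
  fib <- base; fib$fiber_density <- 20; fib$fiber_length <- 5
  v0 <- build_ri_volume(base, oc)
  v1 <- build_ri_volume(fib, oc)
  expect_gt(mean(v1$grid[v1$labels == 2L]), mean(v0$grid[v0$labels == 2L]))
  # fiber excess is confined to wall voxels
  expect_identical(v1$grid[v1$labels != 2L], v0$grid[v0$labels != 2L])
  expect_identical(build_ri_volume(fib, oc)$grid, v1$grid)
})
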