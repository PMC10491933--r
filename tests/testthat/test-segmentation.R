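test_that("select_widest_slice maximizes lumen diameter with first-index ties", {
  stack <- lapply(c(5, 10, 7), function(r) mk_disc(41, r))
  expect_equal(select_widest_slice(stack, 1), 2L)
  ties <- lapply(c(4, 4, 4), function(r) mk_disc(41, r))
  expect_equal(select_widest_slice(ties, 1), 1L)
  expect_error(select_widest_slice(list(matrix(FALSE, 4, 4)), 1), "empty")
})

test_that("a tilted cylinder's selected slice is at least as wide as any other", {
  oc <- default_oc()
  sp <- phantom_spec(volume_shape = c(11, 96, 96), lumen_radius = 10,
                     wall_thickness = 3, tilt_deg = 8, seed = 2)
  vol <- build_ri_volume(sp, oc)
  slices <- lapply(seq_len(dim(vol$labels)[3]),
                   function(k) vol$labels[, , k] == 1L)
  k <- select_widest_slice(slices, oc$pixel_size)
  dmax <- lumen_diameter(slices[[k]], oc$pixel_size)
  for (s in slices) {
    if (any(s)) expect_lte(lumen_diameter(s, oc$pixel_size), dmax)
  }
})

test_that("uniform lumen yields no cells; discs are found and contained", {
  intm <- matrix(FALSE, 128, 128); intm[6:123, 6:123] <- TRUE
  flat <- matrix(1.3440, 128, 128)
  expect_equal(sum(segment_cells(flat, intm)), 0)

  ph <- flat
  truth <- matrix(FALSE, 128, 128)
  ctr <- rbind(c(30, 30), c(30, 90), c(90, 40), c(80, 95), c(64, 64))
  for (i in 1:5) {
    d2 <- outer((1:128 - ctr[i, 1])^2, (1:128 - ctr[i, 2])^2, "+")
    truth[d2 < 36] <- TRUE
    ph[d2 < 36] <- 1.384
  }
  cells <- segment_cells(ph, intm)
  expect_equal(max(vesselqpi:::cpp_label(cells)), 5)
  expect_gte(sum(cells & truth) / sum(cells | truth), 0.8)
  expect_false(any(cells & !intm))
  # determinism
  expect_identical(cells, segment_cells(ph, intm))
})

test_that("cells touching the wall never leak outside the interior", {
  intm <- mk_disc(101, 40)
  ph <- matrix(1.3440, 101, 101)
  d2 <- outer((1:101 - 51)^2, (1:101 - 88)^2, "+") # centered on the boundary
  ph[d2 < 64] <- 1.384
  cells <- segment_cells(ph, intm)
  expect_false(any(cells & !intm))
})

test_that("percent_fill is exact arithmetic with containment checks", {
  intm <- matrix(FALSE, 120, 120); intm[11:110, 11:110] <- TRUE
  none <- intm & FALSE
  expect_equal(percent_fill(none, intm), 0)
  expect_equal(percent_fill(intm, intm), 100)
  half <- intm; half[61:110, 11:110] <- FALSE
  expect_equal(percent_fill(half, intm), 50)
  expect_error(percent_fill(!intm, intm), "contained")
  expect_error(percent_fill(none, none), "empty")
})

test_that("percent_fill is invariant under rotation and translation", {
  set.seed(9)
  intm <- mk_disc(61, 25)
  cells <- intm & (matrix(runif(61 * 61), 61, 61) < 0.3)
  base <- percent_fill(cells, intm)
  rot90 <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  expect_equal(percent_fill(rot90(cells), rot90(intm)), base)
  shift <- function(m, k) rbind(matrix(FALSE, k, ncol(m)),
                                m[1:(nrow(m) - k), , drop = FALSE])
  expect_equal(percent_fill(shift(cells, 5), shift(intm, 5)), base)
})

test_that("mask sets enforce their invariants and round trip through TIFF", {
  intm <- mk_disc(61, 20)
  wall <- mk_annulus(61, 20, 25)
  cells <- mk_disc(61, 5)
  ms <- vessel_mask_set(intm, wall, cells, slice_index = 4, pixel_size = 0.5)
  path <- withr::local_tempfile(fileext = ".tif")
  save_masks(ms, path)
  back <- load_masks(path, slice_index = 4, pixel_size = 0.5)
  expect_identical(back$interior_mask, ms$interior_mask)
  expect_identical(back$wall_mask, ms$wall_mask)
  expect_identical(back$cell_mask, ms$cell_mask)
  # invariants
  expect_error(vessel_mask_set(intm, intm), "disjoint")
  expect_error(vessel_mask_set(intm, wall, wall), "contained")
  expect_error(vessel_mask_set(intm, wall[1:30, ]), "shape")
  # unknown labels rejected by name
  bad <- withr::local_tempfile(fileext = ".tif")
  write_tiff(bad, matrix(4, 8, 8), sample_format = "uint8")
  expect_error(load_masks(bad), "unknown mask label")
})
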