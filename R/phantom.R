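# Synthetic vessel phantoms: seeded RI volumes with ground-truth label masks.
#
# Geometry convention: volumes are stored as arrays indexed [y, x, z] so that
# `grid[, , k]` is the k-th axial slice; `volume_shape` in the spec object is
# (nz, ny, nx). Labels: 0 background, 1 lumen interior, 2 wall, 3 cell.

LABEL_BG <- 0L
LABEL_INTERIOR <- 1L
LABEL_WALL <- 2L
LABEL_CELL <- 3L

#' Build a synthetic refractive-index volume from a phantom specification
#'
#' Voxels outside vessel structures are exactly `medium_ri_nm`; wall voxels are
#' `medium_ri_nm + wall_delta_n` (plus the fiber excess where fiber segments
#' are placed); cell inclusions sit strictly inside the lumen and are centered
#' on the widest axial plane, so the widest slice shows them at full radius.
#' If `break_arc` is set the corresponding wall material is removed (set back
#' to the medium RI and relabeled background). Output is a pure function of
#' `(spec, config)` including `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param config an [optical_config()]; supplies `pixel_size`, `z_step`,
#'   `medium_ri_nm`.
#' @return an object of class `"ri_volume"`: list with `grid` (array
#'   `[y, x, z]` of absolute RI), `labels` (integer array, same shape),
#'   `pixel_size`, `z_step`, `widest_z` (ground-truth index of the widest
#'   slice), and `spec`.
#' @export
build_ri_volume <- function(spec, config) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(config, "optical_config"))
  nm <- config$medium_ri_nm
  if (spec$wall_delta_n < 1.0 - nm || spec$cell_delta_n < 1.0 - nm) {
    stop("delta_n would push the RI below 1.0")
  }
  nz <- spec$volume_shape[1]; ny <- spec$volume_shape[2]; nx <- spec$volume_shape[3]
  px <- config$pixel_size; dz <- config$z_step
  r_out <- spec$lumen_radius + spec$wall_thickness
  yy <- (seq_len(ny) - 1) * px
  xx <- (seq_len(nx) - 1) * px
  zz <- (seq_len(nz) - 1) * dz
  yc <- (ny - 1) / 2 * px
  xc <- (nx - 1) / 2 * px
  zc <- (nz - 1) / 2 * dz

  grid <- array(nm, dim = c(ny, nx, nz))
  labels <- array(LABEL_BG, dim = c(ny, nx, nz))

  if (spec$axis == "x") {
    tilt <- tan(spec$tilt_deg * pi / 180)
    z_axis <- zc + tilt * (xx - xc)            # axis height per x column
    # the tube must fit laterally; in z it may be truncated by the acquisition
    # range (as in a real z-stack), but its axis plane must lie inside it
    if (r_out > yc + px / 2) {
      stop("vessel (outer radius ", r_out, " um) does not fit the volume")
    }
    if (any(z_axis < 0 | z_axis > (nz - 1) * dz)) {
      stop("vessel axis leaves the acquired z-range (reduce tilt_deg)")
    }
    dy2 <- (yy - yc)^2
    # break gap: axial interval on the y < yc wall band
    brk <- spec$break_arc
    x_gap <- NULL
    if (!is.null(brk)) {
      len <- nx * px
      x_gap <- range(len * (brk / (2 * pi)))
    }
    for (k in seq_len(nz)) {
      dz2 <- (zz[k] - z_axis)^2               # length nx
      r2 <- outer(dy2, dz2, "+")              # ny x nx
      r <- sqrt(r2)
      lum <- r < spec$lumen_radius
      wall <- !lum & r < r_out
      if (!is.null(x_gap)) {
        in_gap <- outer(yy < yc, xx >= x_gap[1] & xx <= x_gap[2], "&")
        wall <- wall & !in_gap
      }
      sl <- matrix(nm, ny, nx)
      sl[wall] <- nm + spec$wall_delta_n
      lb <- matrix(LABEL_BG, ny, nx)
      lb[lum] <- LABEL_INTERIOR
      lb[wall] <- LABEL_WALL
      grid[, , k] <- sl
      labels[, , k] <- lb
    }
    widest_z <- which.min(abs(zz - zc))
  } else { # axis == "z": annulus in every slice
    if (r_out > min(yc, xc) + px / 2) {
      stop("vessel (outer radius ", r_out, " um) does not fit the volume")
    }
    r <- sqrt(outer((yy - yc)^2, (xx - xc)^2, "+"))
    theta <- atan2(outer(yy - yc, rep(1, nx)), outer(rep(1, ny), xx - xc))
    lum <- r < spec$lumen_radius
    wall <- !lum & r < r_out
    if (!is.null(spec$break_arc)) {
      th <- theta %% (2 * pi)
      a <- spec$break_arc %% (2 * pi)
      in_arc <- if (a[1] <= a[2]) th >= a[1] & th <= a[2] else th >= a[1] | th <= a[2]
      wall <- wall & !in_arc
    }
    sl <- matrix(nm, ny, nx)
    sl[wall] <- nm + spec$wall_delta_n
    lb <- matrix(LABEL_BG, ny, nx)
    lb[lum] <- LABEL_INTERIOR
    lb[wall] <- LABEL_WALL
    for (k in seq_len(nz)) { grid[, , k] <- sl; labels[, , k] <- lb }
    widest_z <- 1L
  }

  # fibers: thin high-RI segments within the wall, running along the vessel
  if (spec$fiber_density > 0 && spec$fiber_delta_n != 0) {
    grid <- with_local_seed(derive_seed(spec$seed, 7L), {
      add_fibers(grid, labels, spec, config)
    })
  }

  # align the ground-truth widest plane with what select_widest_slice() will
  # pick downstream (discretization can tie several slices; the analyzer
  # breaks ties by the smallest index, so the generator must follow suit)
  interior_slices <- lapply(seq_len(nz), function(k) labels[, , k] == LABEL_INTERIOR)
  if (any(vapply(interior_slices, any, logical(1)))) {
    widest_z <- select_widest_slice(interior_slices, px)
  }

  # cells: spheres centered on the widest plane, placed to hit the target fill
  if (spec$target_fill_fraction > 0) {
    lum_slice <- labels[, , widest_z] == LABEL_INTERIOR
    placed <- realize_fill(spec, lum_slice, seed = derive_seed(spec$seed, 13L),
                           pixel_size = px)
    if (nrow(placed$centers) > 0) {
      rc <- spec$cell_radius
      z_span <- which(abs(zz - zz[widest_z]) < rc)
      for (k in z_span) {
        dzk <- zz[k] - zz[widest_z]
        r_eff2 <- rc^2 - dzk^2
        if (r_eff2 <= 0) next
        sl <- grid[, , k]; lb <- labels[, , k]
        for (ci in seq_len(nrow(placed$centers))) {
          cy <- yy[placed$centers[ci, 1]]
          cx <- xx[placed$centers[ci, 2]]
          d2 <- outer((yy - cy)^2, (xx - cx)^2, "+")
          inside <- d2 < r_eff2 & lb == LABEL_INTERIOR
          sl[inside] <- nm + spec$cell_delta_n
          lb[inside] <- LABEL_CELL
        }
        grid[, , k] <- sl; labels[, , k] <- lb
      }
    }
  }

  structure(
    list(grid = grid, labels = labels, pixel_size = px, z_step = dz,
         widest_z = widest_z, spec = spec),
    class = "ri_volume"
  )
}

# Fiber segments: short axial runs of elevated RI at random positions within
# the wall. Segment length controls fragmentation (long = continuous fibers,
# short = fragmented). Density is per 100 um of wall length per wall side.
add_fibers <- function(grid, labels, spec, config) {
  dims <- dim(grid)
  ny <- dims[1]; nx <- dims[2]; nz <- dims[3]
  px <- config$pixel_size
  wall_len_um <- if (spec$axis == "x") nx * px else
    2 * pi * (spec$lumen_radius + spec$wall_thickness / 2)
  n_fib <- rpois(1, spec$fiber_density * wall_len_um / 100 * 2)
  if (n_fib == 0) return(grid)
  wall_idx <- which(labels == LABEL_WALL, arr.ind = FALSE)
  if (length(wall_idx) == 0) return(grid)
  seg_px <- max(1L, round(spec$fiber_length / px))
  for (f in seq_len(n_fib)) {
    start <- wall_idx[sample.int(length(wall_idx), 1)]
    k <- (start - 1) %/% (ny * nx) + 1
    rem <- (start - 1) %% (ny * nx)
    j <- rem %/% ny + 1
    i <- rem %% ny + 1
    if (spec$axis == "x") {
      jj <- j:min(nx, j + seg_px - 1L)
      sel <- cbind(i, jj, k)
    } else { # run azimuthally: approximate with a row run
      ii <- i:min(ny, i + seg_px - 1L)
      sel <- cbind(ii, j, k)
    }
    keep <- labels[sel] == LABEL_WALL
    sel <- sel[keep, , drop = FALSE]
    grid[sel] <- grid[sel] + spec$fiber_delta_n
  }
  grid
}

#' Place cell-like inclusions in a lumen mask to achieve a target fill
#'
#' Random sequential placement of discs of radius `spec$cell_radius` with
#' centers restricted so every disc lies fully inside the lumen; discs may
#' overlap one another (the fill statistic is the union area). Placement stops
#' once the covered fraction reaches `spec$target_fill_fraction`, so the
#' achieved fraction overshoots by at most one cell's area; if the target is
#' unreachable (packing limit) the best-effort result is returned with
#' `best_effort = TRUE`.
#'
#' @param spec a [phantom_spec()] (uses `cell_radius`, `target_fill_fraction`).
#' @param lumen_mask 2D logical lumen mask.
#' @param seed integer seed.
#' @param pixel_size um per pixel.
#' @return list with `centers` (n x 2 matrix of row/col pixel indices),
#'   `cell_mask` (logical), `achieved_fraction` (percent), `best_effort`.
#' @export
realize_fill <- function(spec, lumen_mask, seed, pixel_size) {
  lumen_mask <- as_mask(lumen_mask, "lumen_mask")
  target <- spec$target_fill_fraction
  rc_px <- spec$cell_radius / pixel_size
  lum_area <- sum(lumen_mask)
  if (lum_area == 0) stop("empty lumen mask")
  empty <- list(centers = matrix(numeric(0), 0, 2),
                cell_mask = lumen_mask & FALSE,
                achieved_fraction = 0, best_effort = FALSE)
  if (target <= 0) return(empty)
  if (lum_area * pixel_size^2 <= pi * spec$cell_radius^2) {
    stop("lumen area must exceed one cell's area")
  }
  allowed <- cpp_erode_disc(lumen_mask, rc_px)
  allowed_idx <- which(allowed)
  if (length(allowed_idx) == 0) {
    warning("no placement fits a whole cell inside the lumen; returning empty")
    return(modifyList(empty, list(best_effort = TRUE)))
  }
  nr <- nrow(lumen_mask)
  with_local_seed(seed, {
    cell_mask <- matrix(FALSE, nr, ncol(lumen_mask))
    centers <- matrix(0L, 0, 2)
    frac <- 0
    max_tries <- 200L + ceiling(4 * target / 100 * lum_area / (pi * rc_px^2))
    tries <- 0L
    while (frac < target && tries < max_tries) {
      tries <- tries + 1L
      idx <- allowed_idx[sample.int(length(allowed_idx), 1)]
      i <- (idx - 1) %% nr + 1
      j <- (idx - 1) %/% nr + 1
      stamp <- stamp_disc(nr, ncol(lumen_mask), i, j, rc_px)
      new_cov <- sum(stamp & !cell_mask & lumen_mask)
      if (new_cov == 0) next
      cell_mask <- cell_mask | (stamp & lumen_mask)
      centers <- rbind(centers, c(i, j))
      frac <- 100 * sum(cell_mask) / lum_area
    }
    list(centers = centers, cell_mask = cell_mask,
         achieved_fraction = frac,
         best_effort = frac < target - 5)
  })
}

stamp_disc <- function(nr, nc, i, j, r_px) {
  ii <- pmax(1L, floor(i - r_px)):pmin(nr, ceiling(i + r_px))
  jj <- pmax(1L, floor(j - r_px)):pmin(nc, ceiling(j + r_px))
  sub <- outer((ii - i)^2, (jj - j)^2, "+") < r_px^2
  m <- matrix(FALSE, nr, nc)
  m[ii, jj] <- sub
  m
}

#' Generate a synthetic cohort of vessel stacks on disk
#'
#' Draws per-animal phantom parameters from per-group distributions, builds
#' one RI volume per animal per vessel, writes float32 TIFF stacks with label
#' masks and JSON sidecars, and records everything in a manifest CSV. Fully
#' reproducible from `seed`.
#'
#' @param groups list of group descriptors; each a list with `label`,
#'   `n_animals`, `spec` (a [phantom_spec()] giving the group means),
#'   optionally `n_vessels` (default 2) and `vary` (named list of normal SDs
#'   for fields drawn per animal, e.g. `list(wall_delta_n = 0.002)`).
#' @param config an [optical_config()].
#' @param outdir output directory (created if needed).
#' @param seed master seed.
#' @param force overwrite an existing manifest (default `FALSE`: refuse).
#' @param write_stacks write TIFF stacks (default `TRUE`); with `FALSE` only
#'   the manifest is produced and volumes are built on demand downstream.
#' @return the manifest `data.frame`, invisibly; also written to
#'   `file.path(outdir, "manifest.csv")`.
#' @export
generate_cohort <- function(groups, config, outdir, seed = 1L, force = FALSE,
                            write_stacks = TRUE) {
  stopifnot(length(groups) >= 1)
  manifest_path <- file.path(outdir, "manifest.csv")
  if (file.exists(manifest_path) && !force) {
    stop("manifest already exists at ", manifest_path, " (use force = TRUE)")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  varying_fields <- c("lumen_radius", "wall_thickness", "wall_delta_n",
                      "cell_delta_n", "target_fill_fraction")
  for (g in seq_along(groups)) {
    grp <- groups[[g]]
    stopifnot(!is.null(grp$label), grp$n_animals >= 1)
    n_vessels <- if (is.null(grp$n_vessels)) 2L else grp$n_vessels
    vary <- if (is.null(grp$vary)) list() else grp$vary
    for (a in seq_len(grp$n_animals)) {
      animal_id <- sprintf("%s_a%02d", grp$label, a)
      aspec <- grp$spec
      aseed <- derive_seed(seed, g, a)
      draws <- with_local_seed(aseed, {
        out <- list()
        for (f in names(vary)) {
          if (!f %in% varying_fields) stop("cannot vary field: ", f)
          out[[f]] <- rnorm(1, mean = aspec[[f]], sd = vary[[f]])
        }
        out
      })
      for (f in names(draws)) {
        v <- draws[[f]]
        if (f == "target_fill_fraction") v <- min(100, max(0, v))
        if (f %in% c("lumen_radius", "wall_thickness")) v <- max(v, 1e-3)
        aspec[[f]] <- v
      }
      for (v in seq_len(n_vessels)) {
        vspec <- aspec
        vspec$seed <- derive_seed(seed, g, a, v)
        stack_path <- file.path(outdir, sprintf("%s_v%02d_ri.tif", animal_id, v))
        labels_path <- file.path(outdir, sprintf("%s_v%02d_labels.tif", animal_id, v))
        if (write_stacks) {
          vol <- build_ri_volume(vspec, config)
          write_tiff(stack_path, vol$grid)
          write_tiff(labels_path, vol$labels, sample_format = "uint8")
          sidecar <- file.path(outdir, sprintf("%s_v%02d_meta.json", animal_id, v))
          jsonlite::write_json(
            list(pixel_size = config$pixel_size, z_step = config$z_step,
                 seed = vspec$seed, widest_z = vol$widest_z,
                 spec = vspec[!vapply(vspec, is.null, logical(1))]),
            sidecar, auto_unbox = TRUE, digits = NA)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          group = grp$label, animal_id = animal_id, vessel_id = v,
          stack_path = stack_path, labels_path = labels_path,
          lumen_radius = vspec$lumen_radius,
          wall_thickness = vspec$wall_thickness,
          wall_delta_n = vspec$wall_delta_n,
          cell_delta_n = vspec$cell_delta_n,
          target_fill_fraction = vspec$target_fill_fraction,
          noise_photon_budget = vspec$noise_photon_budget,
          seed = vspec$seed,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest)
}
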