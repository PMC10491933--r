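# Per-vessel morphometry: wall thickness distribution, lumen diameter,
# inclusion filter, wall RI statistics.

#' Wall thickness samples along the wall's medial axis
#'
#' One sample per medial-axis (skeleton) pixel: the local thickness is
#' `2 * EDT - 1` pixels, where EDT is the exact Euclidean distance from the
#' medial pixel to the nearest non-wall pixel (the `-1` makes a one-pixel-wide
#' band measure exactly one pixel). Samples within one local wall-thickness of
#' a skeleton endpoint (a break tip or field-of-view truncation) are excluded
#' to avoid tip artifacts; this exclusion is skipped for closed walls, which
#' have no endpoints.
#'
#' A ray-casting estimator (`method = "ray"`) is provided as a cross-check: it
#' marches from each medial pixel along the local normal in both directions
#' until leaving the wall. If the two methods' medians disagree by more than
#' 15 percent a warning is raised when `cross_check = TRUE`.
#'
#' @param wall_mask 2D logical wall mask (a connected or piecewise-connected
#'   band), nonempty.
#' @param pixel_size um per pixel.
#' @param method `"medial"` (default) or `"ray"`.
#' @param exclude_tips exclude samples near skeleton endpoints (default TRUE).
#' @param cross_check also run the other estimator and warn on > 15 percent
#'   median disagreement (default FALSE).
#' @return numeric vector of thickness samples in um (histogram-ready).
#' @export
wall_thickness <- function(wall_mask, pixel_size, method = c("medial", "ray"),
                           exclude_tips = TRUE, cross_check = FALSE) {
  method <- match.arg(method)
  wall_mask <- as_mask(wall_mask, "wall_mask")
  if (!any(wall_mask)) stop("empty wall mask")
  stopifnot_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  skel <- cpp_thin(wall_mask)
  if (!any(skel)) skel <- wall_mask # degenerate tiny masks
  edt <- sqrt(cpp_edt_sq(wall_mask))
  keep <- skel
  if (exclude_tips) {
    ends <- skeleton_endpoints(skel)
    if (nrow(ends) > 0) {
      src <- (ends[, 2] - 1L) * nrow(skel) + (ends[, 1] - 1L)
      gd <- cpp_geodesic(skel, as.integer(src))
      # one typical wall-thickness (median over the skeleton)
      tip_thick <- median(2 * edt[skel] - 1)
      keep <- skel & !(gd <= tip_thick)
      if (!any(keep)) keep <- skel # never drop everything
    }
  }
  if (method == "medial") {
    samples <- (2 * edt[keep] - 1) * pixel_size
  } else {
    samples <- ray_thickness(wall_mask, keep) * pixel_size
  }
  samples <- samples[samples > 0]
  if (cross_check) {
    other <- if (method == "medial") {
      ray_thickness(wall_mask, keep) * pixel_size
    } else {
      (2 * edt[keep] - 1) * pixel_size
    }
    other <- other[other > 0]
    if (length(other) && length(samples)) {
      rel <- abs(median(samples) - median(other)) / median(samples)
      if (rel > 0.15) {
        warning(sprintf(
          "thickness estimators disagree by %.0f%% (medial vs ray)", 100 * rel))
      }
    }
  }
  samples
}

# Endpoints of a skeleton: pixels with exactly one 8-connected skeleton
# neighbour.
skeleton_endpoints <- function(skel) {
  nb <- neighbor_count(skel)
  which(skel & nb == 1, arr.ind = TRUE)
}

neighbor_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- mask * 1L
  out <- matrix(0L, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- out + p[2:(nr + 1) + dy, 2:(nc + 1) + dx]
  }
  out
}

# March from each medial pixel along +/- the local normal (perpendicular to
# the skeleton tangent estimated from the nearest skeleton neighbours).
ray_thickness <- function(wall_mask, medial) {
  idx <- which(medial, arr.ind = TRUE)
  nr <- nrow(wall_mask); nc <- ncol(wall_mask)
  inb <- function(i, j) i >= 1 && j >= 1 && i <= nr && j <= nc
  vapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    # tangent: principal direction of nearby medial pixels
    win <- idx[abs(idx[, 1] - i) <= 3 & abs(idx[, 2] - j) <= 3, , drop = FALSE]
    if (nrow(win) >= 2) {
      cv <- stats::cov(win)
      ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
    } else {
      ev <- c(1, 0)
    }
    nrm <- c(-ev[2], ev[1]) # normal
    count <- 1
    for (s in c(-1, 1)) {
      t <- 1
      repeat {
        ii <- round(i + s * t * nrm[1]); jj <- round(j + s * t * nrm[2])
        if (!inb(ii, jj) || !wall_mask[ii, jj]) break
        count <- count + 1
        t <- t + 1
      }
    }
    count
  }, numeric(1))
}

#' Lumen diameter as the maximal inscribed circle
#'
#' The diameter is `2 * max(EDT) * pixel_size`, where the EDT is the exact
#' Euclidean distance transform of the interior mask: twice the Euclidean
#' distance from the vessel center — defined as the EDT argmax — to the outer
#' boundary of the interior, excluding the wall.
#'
#' @param interior_mask 2D logical interior mask, nonempty.
#' @param pixel_size um per pixel.
#' @return diameter in um, with the center pixel attached as attribute
#'   `"center"` (row, col).
#' @export
lumen_diameter <- function(interior_mask, pixel_size) {
  interior_mask <- as_mask(interior_mask, "interior_mask")
  if (!any(interior_mask)) stop("empty interior mask")
  stopifnot_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  edt <- sqrt(cpp_edt_sq(interior_mask))
  if (!any(is.finite(edt) & interior_mask)) {
    # mask covers the whole image: bounded only by the frame
    edt[!is.finite(edt)] <- max(dim(interior_mask))
  }
  m <- which.max(edt)
  d <- 2 * edt[m] * pixel_size
  ctr <- c((m - 1) %% nrow(interior_mask) + 1, (m - 1) %/% nrow(interior_mask) + 1)
  structure(d, center = ctr)
}

#' Mark a vessel as included by the diameter filter
#'
#' Strict inequality: `included <- diameter > threshold`. Vessels at exactly
#' the threshold are excluded. Idempotent.
#'
#' @param metrics a `"vessel_metrics"` object or a data.frame with a
#'   `diameter` column.
#' @param threshold diameter threshold in um (default 20).
#' @return the input with `included` set.
#' @export
apply_diameter_filter <- function(metrics, threshold = 20) {
  if (inherits(metrics, "vessel_metrics")) {
    metrics$included <- metrics$diameter > threshold
    metrics$provenance$diameter_threshold <- threshold
  } else if (is.data.frame(metrics)) {
    metrics$included <- metrics$diameter > threshold
  } else {
    stop("`metrics` must be a vessel_metrics object or data.frame")
  }
  metrics
}

#' Mean and sample standard deviation of RI over the wall
#'
#' @param ri_slice 2D numeric RI map.
#' @param wall_mask 2D logical wall mask, nonempty.
#' @return list with `wall_ri_mean` and `wall_ri_sd` (0 for a single pixel).
#' @export
wall_ri_stats <- function(ri_slice, wall_mask) {
  wall_mask <- as_mask(wall_mask, "wall_mask")
  stopifnot(is.matrix(ri_slice), all(dim(ri_slice) == dim(wall_mask)))
  if (!any(wall_mask)) stop("empty wall mask")
  v <- ri_slice[wall_mask]
  list(wall_ri_mean = mean(v),
       wall_ri_sd = if (length(v) > 1) sd(v) else 0)
}

#' Assemble the per-vessel metric record
#'
#' Computes, on one analysis slice: the wall thickness sample distribution and
#' its mean, the lumen diameter, %Fill, wall RI mean/SD, and the >threshold
#' diameter inclusion flag.
#'
#' @param ri_slice 2D numeric RI map of the analysis slice.
#' @param masks a [vessel_mask_set()] for that slice.
#' @param vessel_id identifier string.
#' @param diameter_threshold um (default 20).
#' @param provenance named list echoed into the record (parameters, mask
#'   source, ...).
#' @return an object of class `"vessel_metrics"`.
#' @export
vessel_metrics <- function(ri_slice, masks, vessel_id = "vessel",
                           diameter_threshold = 20, provenance = list()) {
  stopifnot(inherits(masks, "vessel_mask_set"))
  thick <- wall_thickness(masks$wall_mask, masks$pixel_size)
  diam <- lumen_diameter(masks$interior_mask, masks$pixel_size)
  ri <- wall_ri_stats(ri_slice, masks$wall_mask)
  out <- structure(
    list(vessel_id = vessel_id,
         thickness_samples = thick,
         mean_thickness = mean(thick),
         diameter = as.numeric(diam),
         percent_fill = percent_fill(masks$cell_mask, masks$interior_mask),
         wall_ri_mean = ri$wall_ri_mean,
         wall_ri_sd = ri$wall_ri_sd,
         included = NA,
         provenance = c(provenance, list(slice_index = masks$slice_index,
                                         pixel_size = masks$pixel_size))),
    class = "vessel_metrics"
  )
  apply_diameter_filter(out, diameter_threshold)
}

#' @export
print.vessel_metrics <- function(x, ...) {
  cat(sprintf("<vessel_metrics> %s\n", x$vessel_id))
  cat(sprintf("  diameter      %.2f um (%s)\n", x$diameter,
              if (isTRUE(x$included)) "included" else "excluded"))
  cat(sprintf("  thickness     mean %.2f um (%d samples)\n",
              x$mean_thickness, length(x$thickness_samples)))
  cat(sprintf("  %%Fill         %.1f\n", x$percent_fill))
  cat(sprintf("  wall RI       %.4f +/- %.4f\n", x$wall_ri_mean, x$wall_ri_sd))
  invisible(x)
}

#' @importFrom stats cov
NULL
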