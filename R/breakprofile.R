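# RI-versus-distance-from-break profiling along the vessel wall: geodesic
# distances on the wall mask's 8-connected pixel graph, 20 um moving mean/SD,
# and the three-region (<50 / 50-350 / >350 um) classification.

#' Find break endpoints of a vessel wall
#'
#' Skeletonizes the wall band and locates its degree-1 skeleton nodes (pixels
#' with exactly one skeleton neighbour); a closed annulus has none. Because
#' thinning retracts the free end of a thick band inward by about half the
#' band width, each skeleton endpoint is then extended along the outward
#' skeleton direction to the last wall pixel, which recovers the actual break
#' face. Endpoints within `exclude_border` pixels of the image border are
#' treated as field-of-view truncations, not ruptures, and dropped (set
#' `exclude_border = 0` to keep them). Manual break annotations, when
#' available, should be passed directly to [wall_distance_from_break()]
#' instead.
#'
#' @param wall_mask 2D logical wall mask, nonempty.
#' @param exclude_border margin in pixels (default 2).
#' @return integer matrix with columns `row`, `col` (possibly 0 rows).
#' @export
find_break_endpoints <- function(wall_mask, exclude_border = 2) {
  wall_mask <- as_mask(wall_mask, "wall_mask")
  if (!any(wall_mask)) stop("empty wall mask")
  skel <- cpp_thin(wall_mask)
  ends <- skeleton_endpoints(skel)
  nr <- nrow(wall_mask); nc <- ncol(wall_mask)
  if (nrow(ends) > 0) {
    edt <- sqrt(cpp_edt_sq(wall_mask))
    w <- max(3, 2 * median(2 * edt[skel] - 1))
    for (k in seq_len(nrow(ends))) {
      e <- ends[k, ]
      gd <- cpp_geodesic(skel, as.integer((e[2] - 1L) * nr + (e[1] - 1L)))
      local <- which(skel & gd <= w, arr.ind = TRUE)
      if (nrow(local) < 2) next
      dir <- e - colMeans(local)
      nv <- sqrt(sum(dir^2))
      if (nv < 1e-9) next
      dir <- dir / nv
      # march outward to the last in-mask pixel (the true break face)
      best <- e
      for (t in seq_len(ceiling(3 * w))) {
        p <- round(e + t * dir)
        if (p[1] < 1 || p[2] < 1 || p[1] > nr || p[2] > nc) break
        if (!wall_mask[p[1], p[2]]) break
        best <- p
      }
      ends[k, ] <- best
    }
  }
  if (nrow(ends) > 0 && exclude_border > 0) {
    keep <- ends[, 1] > exclude_border & ends[, 1] <= nr - exclude_border &
      ends[, 2] > exclude_border & ends[, 2] <= nc - exclude_border
    ends <- ends[keep, , drop = FALSE]
  }
  colnames(ends) <- c("row", "col")
  ends
}

#' Geodesic distance from a break point to every wall pixel
#'
#' Shortest-path distance within the wall mask on its 8-connected pixel
#' graph, with unit axial and `sqrt(2)` diagonal steps, scaled by
#' `pixel_size`. If the given point is not on the mask it is snapped to an
#' 8-adjacent mask pixel; otherwise an error is raised. Multiple break points
#' may be given (one per row): each pixel then takes the minimum distance
#' over the sources, which is the conservative reading of "distance to the
#' breakage" when a rupture has two tips.
#'
#' @param wall_mask 2D logical wall mask.
#' @param break_point integer vector `(row, col)` or matrix with one source
#'   per row.
#' @param pixel_size um per pixel.
#' @return numeric matrix of distances in um; `Inf` off-mask and on
#'   unreachable components.
#' @export
wall_distance_from_break <- function(wall_mask, break_point, pixel_size) {
  wall_mask <- as_mask(wall_mask, "wall_mask")
  stopifnot_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  if (is.null(dim(break_point))) break_point <- matrix(break_point, 1)
  nr <- nrow(wall_mask); nc <- ncol(wall_mask)
  src <- integer(0)
  for (k in seq_len(nrow(break_point))) {
    i <- break_point[k, 1]; j <- break_point[k, 2]
    if (i < 1 || j < 1 || i > nr || j > nc) stop("break point out of range")
    if (!wall_mask[i, j]) {
      # snap to an adjacent wall pixel
      found <- FALSE
      for (dj in -1:1) for (di in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && jj >= 1 && ii <= nr && jj <= nc && wall_mask[ii, jj]) {
          i <- ii; j <- jj; found <- TRUE; break
        }
      }
      if (!found) stop("break point is disconnected from the wall mask")
    }
    src <- c(src, (j - 1L) * nr + (i - 1L))
  }
  cpp_geodesic(wall_mask, as.integer(src)) * pixel_size
}

#' Moving mean and SD of RI versus distance from the break
#'
#' At each grid distance `d` (grid step = `pixel_size` by default, starting at
#' 0), the mean and sample SD of the `ri_values` whose distance falls in the
#' centered window `[d - window/2, d + window/2]`. Windows holding fewer than
#' 3 samples yield `NA` (no estimate) rather than an error.
#'
#' @param distances numeric vector of per-pixel distances (um); non-finite
#'   entries are dropped together with their RI values.
#' @param ri_values numeric vector, same length as `distances`.
#' @param window window width in um (default 20).
#' @param step grid step in um (default 1; pass the pixel size).
#' @return a data.frame with columns `distance`, `moving_mean`, `moving_sd`,
#'   `n_samples`, of class `c("moving_profile", "data.frame")`.
#' @export
moving_profile <- function(distances, ri_values, window = 20, step = 1) {
  stopifnot(length(distances) == length(ri_values))
  if (!(window > 0)) stop("`window` must be > 0")
  ok <- is.finite(distances) & is.finite(ri_values)
  d <- distances[ok]; v <- ri_values[ok]
  if (length(d) == 0) stop("no finite (distance, RI) pairs")
  grid <- seq(0, max(d), by = step)
  ord <- order(d)
  d <- d[ord]; v <- v[ord]
  lo <- findInterval(grid - window / 2, d, left.open = TRUE) + 1L
  hi <- findInterval(grid + window / 2, d)
  n <- pmax(hi - lo + 1L, 0L)
  mm <- rep(NA_real_, length(grid))
  ms <- rep(NA_real_, length(grid))
  for (k in which(n >= 3)) {
    w <- v[lo[k]:hi[k]]
    mm[k] <- mean(w)
    ms[k] <- sd(w)
  }
  structure(
    data.frame(distance = grid, moving_mean = mm, moving_sd = ms,
               n_samples = n),
    class = c("moving_profile", "data.frame")
  )
}

#' Classify wall pixels into near / mid / far break-distance regions
#'
#' Region bounds follow the break analysis: near is `< 50 um` from the break,
#' mid is `[50, 350] um` (boundary values assigned to mid, a stated
#' convention), far is `> 350 um`. Pixels with infinite distance (unreachable
#' components) are left unlabeled and excluded from the summaries.
#'
#' @param distances numeric vector of distances in um.
#' @param ri_values optional numeric vector of RI values for the summaries.
#' @param bounds numeric pair, default `c(50, 350)` um.
#' @return list with `labels` (character vector: `"near"`, `"mid"`, `"far"`,
#'   or `NA`) and `summary` (data.frame with one row per region: `n`,
#'   `mean_ri`, `sd_ri` — the latter `NA` when no `ri_values` given or the
#'   region is empty).
#' @export
classify_regions <- function(distances, ri_values = NULL, bounds = c(50, 350)) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  lab <- rep(NA_character_, length(distances))
  fin <- is.finite(distances)
  lab[fin & distances < bounds[1]] <- "near"
  lab[fin & distances >= bounds[1] & distances <= bounds[2]] <- "mid"
  lab[fin & distances > bounds[2]] <- "far"
  regions <- c("near", "mid", "far")
  summ <- do.call(rbind, lapply(regions, function(r) {
    sel <- !is.na(lab) & lab == r
    data.frame(
      region = r, n = sum(sel),
      mean_ri = if (!is.null(ri_values) && sum(sel) > 0)
        mean(ri_values[sel]) else NA_real_,
      sd_ri = if (!is.null(ri_values) && sum(sel) > 1)
        sd(ri_values[sel]) else NA_real_
    )
  }))
  list(labels = lab, summary = summ)
}

#' Build the full break profile for one vessel wall
#'
#' Convenience wrapper: finds (or accepts) break endpoints, computes geodesic
#' distances, extracts per-pixel RI, and attaches the moving profile and the
#' three-region classification.
#'
#' @param wall_mask 2D logical wall mask.
#' @param ri_slice 2D numeric RI map, same shape.
#' @param pixel_size um per pixel.
#' @param break_points optional matrix of `(row, col)` break annotations;
#'   `NULL` (default) detects skeleton endpoints automatically.
#' @param window moving-window width in um (default 20).
#' @param bounds region bounds in um (default `c(50, 350)`).
#' @return an object of class `"break_profile"`: `break_points`, `distances`
#'   and `ri_values` (per wall pixel), `profile` (a [moving_profile()] frame),
#'   `labels`, `region_summary`; or `NULL` when no break is found.
#' @export
break_profile <- function(wall_mask, ri_slice, pixel_size,
                          break_points = NULL, window = 20,
                          bounds = c(50, 350)) {
  wall_mask <- as_mask(wall_mask, "wall_mask")
  stopifnot(all(dim(ri_slice) == dim(wall_mask)))
  if (is.null(break_points)) {
    break_points <- find_break_endpoints(wall_mask)
  }
  if (is.null(dim(break_points))) break_points <- matrix(break_points, 1)
  if (nrow(break_points) == 0) return(NULL)
  dmat <- wall_distance_from_break(wall_mask, break_points, pixel_size)
  sel <- wall_mask & is.finite(dmat)
  distances <- dmat[sel]
  ri_values <- ri_slice[sel]
  prof <- moving_profile(distances, ri_values, window = window,
                         step = pixel_size)
  cls <- classify_regions(distances, ri_values, bounds = bounds)
  structure(
    list(break_points = break_points, distances = distances,
         ri_values = ri_values, window = window, bounds = bounds,
         profile = prof, labels = cls$labels, region_summary = cls$summary),
    class = "break_profile"
  )
}

#' @export
print.break_profile <- function(x, ...) {
  cat(sprintf("<break_profile> %d break point(s), %d wall pixels\n",
              nrow(x$break_points), length(x$distances)))
  print(x$region_summary, row.names = FALSE)
  invisible(x)
}
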