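#' Optical system configuration
#'
#' Bundles the acquisition-geometry and reconstruction parameters shared by the
#' forward simulation and the phase/RI conversions. Defaults describe an
#' epi-illumination quantitative phase system with 720 nm LED illumination, a
#' 0.6 NA objective, 3.2 um optical sectioning, and a brain-tissue background
#' medium of refractive index 1.3440.
#'
#' @param wavelength illumination wavelength in um (default 0.72).
#' @param slice_thickness_dz effective optical slice thickness in um used in
#'   the phase-to-RI conversion (default 3.2, the system's axial resolution).
#' @param pixel_size lateral sampling in um per pixel.
#' @param medium_ri_nm refractive index of the surrounding medium
#'   (default 1.3440, brain tissue).
#' @param numerical_aperture objective NA (default 0.6).
#' @param tikhonov_alpha Tikhonov regularization constant for phase recovery
#'   (default 1e-3; a convention, chosen on the synthetic bench).
#' @param z_step spacing between acquired z-slices in um (default 1).
#' @return an object of class `"optical_config"`.
#' @export
optical_config <- function(wavelength = 0.72,
                           slice_thickness_dz = 3.2,
                           pixel_size = 0.5,
                           medium_ri_nm = 1.3440,
                           numerical_aperture = 0.6,
                           tikhonov_alpha = 1e-3,
                           z_step = 1.0) {
  stopifnot_scalar_num(wavelength, "wavelength", positive = TRUE)
  stopifnot_scalar_num(slice_thickness_dz, "slice_thickness_dz", positive = TRUE)
  stopifnot_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  stopifnot_scalar_num(medium_ri_nm, "medium_ri_nm")
  stopifnot_scalar_num(numerical_aperture, "numerical_aperture")
  stopifnot_scalar_num(tikhonov_alpha, "tikhonov_alpha")
  stopifnot_scalar_num(z_step, "z_step", positive = TRUE)
  if (medium_ri_nm <= 1) stop("`medium_ri_nm` must be > 1")
  if (numerical_aperture <= 0 || numerical_aperture >= 1.5) {
    stop("`numerical_aperture` must lie in (0, 1.5)")
  }
  if (tikhonov_alpha < 0) stop("`tikhonov_alpha` must be >= 0")
  structure(
    list(
      wavelength = wavelength,
      slice_thickness_dz = slice_thickness_dz,
      pixel_size = pixel_size,
      medium_ri_nm = medium_ri_nm,
      numerical_aperture = numerical_aperture,
      tikhonov_alpha = tikhonov_alpha,
      z_step = z_step
    ),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  wavelength        %.4g um\n", x$wavelength))
  cat(sprintf("  slice thickness   %.4g um\n", x$slice_thickness_dz))
  cat(sprintf("  pixel size        %.4g um/px\n", x$pixel_size))
  cat(sprintf("  medium RI (nm)    %.4f\n", x$medium_ri_nm))
  cat(sprintf("  NA                %.3g\n", x$numerical_aperture))
  cat(sprintf("  Tikhonov alpha    %.3g\n", x$tikhonov_alpha))
  cat(sprintf("  z step            %.4g um\n", x$z_step))
  invisible(x)
}

#' Synthetic vessel phantom specification
#'
#' Describes one tubular vessel phantom: a cylindrical lumen surrounded by an
#' elevated-RI wall, embedded in a uniform background medium, with optional
#' cell-like inclusions in the lumen, an optional wall break (an angular arc of
#' wall removed), and optional thin fiber-like high-RI structures inside the
#' wall. All lengths are in um; RI excesses (`*_delta_n`) are dimensionless
#' offsets over the medium RI.
#'
#' The vessel axis runs along the lateral x grid axis by default, so axial
#' (z) slices are longitudinal sections and the widest slice is the one
#' through the tube center. With `axis = "z"` the tube is perpendicular to the
#' slicing plane and every slice is an annulus (cross-sectional geometry).
#'
#' @param volume_shape integer triple `(nz, ny, nx)`.
#' @param lumen_radius lumen radius in um.
#' @param wall_thickness wall thickness in um.
#' @param wall_delta_n RI excess of the wall over the medium.
#' @param cell_radius radius of cell-like inclusions in um.
#' @param cell_delta_n RI excess of cells.
#' @param target_fill_fraction percent of the widest-slice lumen area to be
#'   covered by cells, in `[0, 100]`.
#' @param break_arc optional numeric pair (radians) giving the angular
#'   interval of wall removed, measured in the tube's cross-sectional plane
#'   (`axis = "z"`) or the fraction-of-length interval in `[0, 2*pi)` mapped
#'   to an axial gap for `axis = "x"` (see Details).
#' @param fiber_density expected number of fiber segments per 100 um of wall
#'   length (default 0).
#' @param fiber_delta_n RI excess of fiber structures.
#' @param fiber_length mean fiber segment length in um; short lengths emulate
#'   fragmented fibers, long lengths continuous ones.
#' @param noise_photon_budget expected photon counts per pixel at acquisition
#'   (`Inf` for noiseless).
#' @param seed integer seed making the phantom reproducible.
#' @param axis `"x"` (default, vessel along a lateral axis) or `"z"`.
#' @param tilt_deg tilt of the vessel axis out of the slicing plane in
#'   degrees (only for `axis = "x"`); exercises widest-slice selection.
#'
#' @details For `axis = "x"` a "break" is a gap in the wall: wall material is
#' removed where the axial coordinate falls inside
#' `lumen length * break_arc / (2*pi)`, on the upper wall only, which mimics a
#' localized rupture in a longitudinal section. For `axis = "z"` the break is
#' the classic removed angular arc of the annulus.
#'
#' Defaults for the RI excesses are package assumptions (the source study
#' reports only the medium RI): wall 0.020, cells 0.040, fibers 0.020.
#' @return an object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(volume_shape = c(9L, 128L, 128L),
                         lumen_radius = 15,
                         wall_thickness = 4,
                         wall_delta_n = 0.020,
                         cell_radius = 3,
                         cell_delta_n = 0.040,
                         target_fill_fraction = 0,
                         break_arc = NULL,
                         fiber_density = 0,
                         fiber_delta_n = 0.020,
                         fiber_length = 10,
                         noise_photon_budget = Inf,
                         seed = 1L,
                         axis = c("x", "z"),
                         tilt_deg = 0) {
  axis <- match.arg(axis)
  if (length(volume_shape) != 3L || any(volume_shape < 1)) {
    stop("`volume_shape` must be three positive integers (nz, ny, nx)")
  }
  stopifnot_scalar_num(lumen_radius, "lumen_radius", positive = TRUE)
  stopifnot_scalar_num(wall_thickness, "wall_thickness", positive = TRUE)
  stopifnot_scalar_num(wall_delta_n, "wall_delta_n")
  stopifnot_scalar_num(cell_radius, "cell_radius", positive = TRUE)
  stopifnot_scalar_num(cell_delta_n, "cell_delta_n")
  stopifnot_scalar_num(target_fill_fraction, "target_fill_fraction")
  if (cell_radius >= lumen_radius) {
    stop("`cell_radius` must be smaller than `lumen_radius`")
  }
  if (target_fill_fraction < 0 || target_fill_fraction > 100) {
    stop("`target_fill_fraction` must lie in [0, 100]")
  }
  if (!is.null(break_arc)) {
    if (length(break_arc) != 2L || !all(is.finite(break_arc)) ||
        break_arc[2] <= break_arc[1]) {
      stop("`break_arc` must be an increasing numeric pair (radians)")
    }
  }
  if (fiber_density < 0) stop("`fiber_density` must be >= 0")
  if (!(noise_photon_budget > 0)) stop("`noise_photon_budget` must be > 0")
  structure(
    list(
      volume_shape = as.integer(volume_shape),
      lumen_radius = lumen_radius,
      wall_thickness = wall_thickness,
      wall_delta_n = wall_delta_n,
      cell_radius = cell_radius,
      cell_delta_n = cell_delta_n,
      target_fill_fraction = target_fill_fraction,
      break_arc = break_arc,
      fiber_density = fiber_density,
      fiber_delta_n = fiber_delta_n,
      fiber_length = fiber_length,
      noise_photon_budget = noise_photon_budget,
      seed = as.integer(seed),
      axis = axis,
      tilt_deg = tilt_deg
    ),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n")
  cat(sprintf("  volume (nz,ny,nx)  %s\n", paste(x$volume_shape, collapse = " x ")))
  cat(sprintf("  lumen radius       %.4g um, wall %.4g um (axis %s)\n",
              x$lumen_radius, x$wall_thickness, x$axis))
  cat(sprintf("  delta n: wall %.4g, cell %.4g, fiber %.4g\n",
              x$wall_delta_n, x$cell_delta_n, x$fiber_delta_n))
  cat(sprintf("  target fill        %.4g %%\n", x$target_fill_fraction))
  if (!is.null(x$break_arc)) {
    cat(sprintf("  break arc          [%.3g, %.3g] rad\n",
                x$break_arc[1], x$break_arc[2]))
  }
  cat(sprintf("  seed               %d\n", x$seed))
  invisible(x)
}
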