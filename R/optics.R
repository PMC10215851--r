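#' Acquisition optics and scan-geometry configuration
#'
#' Describes the swept-source OCT acquisition used throughout the package:
#' spectral parameters of the source, pixel calibration, scan grid, and the
#' repetition protocol (a B-scan of `alines_per_bscan` A-lines repeated
#' `repeats` times at each of `positions` slow-axis locations).
#'
#' Defaults reproduce a 1300 nm source with 70 nm bandwidth at 3 dB sampling a
#' 3.0 x 3.2 mm^2 field at 500 x 500 lateral positions, 1024 depth pixels at
#' 2.7 um/pixel, and 8 repeats per position. The axial pixel size is taken as
#' the in-tissue sampling (already corrected for the mean tissue refractive
#' index), so no further division by `refractive_index` is applied anywhere.
#'
#' @param center_wavelength_nm Source center wavelength (nm).
#' @param bandwidth_nm Spectral bandwidth at 3 dB (nm); must be smaller than
#'   the center wavelength.
#' @param axial_pixel_um Axial (depth) pixel size in tissue (um/pixel).
#' @param lateral_pixel_x_um,lateral_pixel_y_um Lateral pixel pitch along the
#'   fast (x) and slow (y) scan axes (um).
#' @param depth_pixels,alines_per_bscan,positions,repeats Scan-grid counts.
#' @param noise_snr_db Additive-noise SNR (dB) relative to a unit-reflectivity
#'   voxel, used by the phantom renderer.
#' @param refractive_index Mean tissue refractive index (recorded for
#'   provenance; see note on `axial_pixel_um`).
#' @return An object of class `oct_optics` (a validated list).
#' @export
oct_optics <- function(center_wavelength_nm = 1300,
                       bandwidth_nm = 70,
                       axial_pixel_um = 2.7,
                       lateral_pixel_x_um = 6.0,
                       lateral_pixel_y_um = 6.4,
                       depth_pixels = 1024L,
                       alines_per_bscan = 500L,
                       positions = 500L,
                       repeats = 8L,
                       noise_snr_db = 25,
                       refractive_index = 1.37) {
  counts <- c(depth_pixels = depth_pixels, alines_per_bscan = alines_per_bscan,
              positions = positions, repeats = repeats)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all scan-grid counts must be integers >= 1")
  if (axial_pixel_um <= 0 || lateral_pixel_x_um <= 0 || lateral_pixel_y_um <= 0)
    stop("pixel sizes must be > 0")
  if (bandwidth_nm <= 0 || bandwidth_nm >= center_wavelength_nm)
    stop("bandwidth must be positive and smaller than the center wavelength")
  structure(list(
    center_wavelength_nm = center_wavelength_nm,
    bandwidth_nm = bandwidth_nm,
    axial_pixel_um = axial_pixel_um,
    lateral_pixel_x_um = lateral_pixel_x_um,
    lateral_pixel_y_um = lateral_pixel_y_um,
    depth_pixels = as.integer(depth_pixels),
    alines_per_bscan = as.integer(alines_per_bscan),
    positions = as.integer(positions),
    repeats = as.integer(repeats),
    noise_snr_db = noise_snr_db,
    refractive_index = refractive_index
  ), class = "oct_optics")
}

#' @export
print.oct_optics <- function(x, ...) {
  cat(sprintf("<oct_optics> %d x %d x %d (z,x,y), %d repeats\n",
              x$depth_pixels, x$alines_per_bscan, x$positions, x$repeats))
  cat(sprintf("  pixels: %.3g um (z), %.3g x %.3g um (x,y); field %.2f x %.2f mm\n",
              x$axial_pixel_um, x$lateral_pixel_x_um, x$lateral_pixel_y_um,
              fov_mm(x)[["x"]], fov_mm(x)[["y"]]))
  cat(sprintf("  source: %g nm, %g nm @3dB; SNR %g dB\n",
              x$center_wavelength_nm, x$bandwidth_nm, x$noise_snr_db))
  invisible(x)
}

#' Rescale the scan grid while preserving the physical field of view
#'
#' Produces a configuration with a coarser (or finer) voxel grid covering the
#' same physical extent: counts are replaced and the pixel pitches rescaled so
#' that `count * pitch` is unchanged on every axis. All micrometer-denominated
#' parameters elsewhere in the package (slab offsets, ROI diameters, window
#' sizes) are honored at any grid size through these pitch fields.
#'
#' @param optics An [oct_optics()] object.
#' @param depth_pixels,alines_per_bscan,positions New grid counts.
#' @return A rescaled `oct_optics` object.
#' @export
scale_optics <- function(optics, depth_pixels, alines_per_bscan, positions) {
  stopifnot(inherits(optics, "oct_optics"))
  oct_optics(
    center_wavelength_nm = optics$center_wavelength_nm,
    bandwidth_nm = optics$bandwidth_nm,
    axial_pixel_um = optics$axial_pixel_um * optics$depth_pixels / depth_pixels,
    lateral_pixel_x_um = optics$lateral_pixel_x_um * optics$alines_per_bscan / alines_per_bscan,
    lateral_pixel_y_um = optics$lateral_pixel_y_um * optics$positions / positions,
    depth_pixels = depth_pixels,
    alines_per_bscan = alines_per_bscan,
    positions = positions,
    repeats = optics$repeats,
    noise_snr_db = optics$noise_snr_db,
    refractive_index = optics$refractive_index
  )
}

#' Desk-scale phantom optics
#'
#' The reduced acquisition grid used for simulation work: 256 x 128 x 128
#' voxels covering the same 3.0 x 3.2 mm^2 x 2.76 mm field as the full
#' 1024 x 500 x 500 protocol, with 8 repeats. Full-size grids are available by
#' calling [oct_optics()] directly.
#'
#' @param depth_pixels,alines_per_bscan,positions Grid counts (defaults
#'   256/128/128).
#' @param repeats Repeats per slow-axis position.
#' @param noise_snr_db Renderer noise SNR (dB).
#' @return An `oct_optics` object.
#' @export
phantom_optics <- function(depth_pixels = 256L, alines_per_bscan = 128L,
                           positions = 128L, repeats = 8L, noise_snr_db = 25) {
  full <- oct_optics(repeats = repeats, noise_snr_db = noise_snr_db)
  scale_optics(full, depth_pixels, alines_per_bscan, positions)
}

#' Physical field of view in millimetres
#' @param optics An [oct_optics()] object.
#' @return Named numeric `c(x =, y =, z =)` in mm.
#' @export
fov_mm <- function(optics) {
  c(x = optics$alines_per_bscan * optics$lateral_pixel_x_um / 1000,
    y = optics$positions * optics$lateral_pixel_y_um / 1000,
    z = optics$depth_pixels * optics$axial_pixel_um / 1000)
}

#' Total slow-axis B-scan frame count of the repetition protocol
#'
#' With the default protocol (500 positions x 8 repeats) this is 4000: the
#' cube holds `positions * repeats` B-scan frames along the slow axis.
#'
#' @param optics An [oct_optics()] object.
#' @return Integer frame count.
#' @export
n_bscans <- function(optics) optics$positions * optics$repeats

#' Gaussian-spectrum round-trip axial resolution
#'
#' \eqn{\delta z = (2 \ln 2 / \pi) \lambda_0^2 / \Delta\lambda}, the standard
#' coherence-length formula for a Gaussian source spectrum (in air). For a
#' 1300 nm / 70 nm source this evaluates to 10.65 um.
#'
#' @param optics An [oct_optics()] object.
#' @return Axial resolution in micrometres.
#' @export
axial_resolution_um <- function(optics) {
  (2 * log(2) / pi) * optics$center_wavelength_nm^2 / optics$bandwidth_nm / 1000
}

#' Convert a physical length to axial pixels
#'
#' Rounds half away from zero, so 200 um at 2.7 um/pixel gives 74 px and
#' 400 um gives 148 px.
#'
#' @param length_um Length in micrometres (>= 0).
#' @param axial_pixel_um Axial pixel size (um/pixel).
#' @return Integer pixel count.
#' @export
um_to_px <- function(length_um, axial_pixel_um = 2.7) {
  if (any(length_um < 0)) stop("length_um must be >= 0")
  as.integer(floor(length_um / axial_pixel_um + 0.5))
}

#' Wrap a complex backscatter volume as an OCT cube
#'
#' The cube is a 4-D complex array ordered depth x fast axis x slow axis x
#' repeat, carrying its acquisition metadata. The slow-axis frame-count
#' bookkeeping invariant (`positions * repeats` total B-scans) is validated on
#' construction.
#'
#' @param data Complex 4-D array `(Z, X, Y, N)`.
#' @param optics The matching [oct_optics()] object.
#' @return An `oct_cube` (the array with attributes).
#' @export
oct_cube <- function(data, optics) {
  d <- dim(data)
  if (length(d) != 4) stop("cube must be a 4-D array (depth, x, y, repeat)")
  expect <- c(optics$depth_pixels, optics$alines_per_bscan,
              optics$positions, optics$repeats)
  if (!all(d == expect))
    stop(sprintf("cube dims (%s) do not match optics (%s)",
                 paste(d, collapse = "x"), paste(expect, collapse = "x")))
  if (d[3] * d[4] != n_bscans(optics))
    stop("slow-axis frame bookkeeping violated")  # unreachable by construction
  structure(data, optics = optics, class = c("oct_cube", class(data)))
}

#' Mean backscatter intensity of a cube
#'
#' Averages `|signal|^2` over the repeat axis, giving the structural
#' (log-free) intensity volume used for surface detection and layer views.
#'
#' @param cube An [oct_cube()] or plain complex 4-D array.
#' @return Numeric array `(Z, X, Y)`.
#' @export
cube_intensity <- function(cube) {
  d <- dim(cube)
  out <- cube_power_mean(cube, d[4])
  dim(out) <- d[1:3]
  out
}
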