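#' Grow a tubular vessel field inside the vascular band of a phantom
#'
#' Vessels are persistent random-walk polylines in the lateral plane whose
#' depth meanders inside the tissue's vessel band (hypodermis + upper muscle,
#' referenced to the local surface). They are rasterized voxel by voxel at
#' their physical radius (anisotropic pixels honored; a centerline always
#' marks at least its own voxel) and added until the en-face projected area
#' fraction inside `roi` reaches `target_area_fraction`; growth is stopped
#' mid-vessel when the target is reached, so the achieved fraction tracks the
#' target to well within the +/-20% relative contract.
#'
#' @param tissue A [build_tissue()] phantom (supplies surface and band).
#' @param target_area_fraction Desired projected vessel area fraction inside
#'   the ROI, in `[0, 0.5]`.
#' @param seed Integer RNG seed.
#' @param roi Optional logical X x Y mask restricting the vessels; default the
#'   whole field.
#' @param radius_um Length-2 range of vessel radii (um).
#' @param speed_mmps Length-2 range of flow speeds (mm/s), one draw per vessel.
#' @param max_vessels Attempt bound before declaring the target unreachable.
#' @return A `vessel_field`: list with `idx` (linear voxel indices into the
#'   Z x X x Y grid), `speed_mmps` (per voxel, > 0), `proj` (logical X x Y
#'   ground-truth projected mask), `achieved_fraction`, `target_fraction`,
#'   `centerlines` (list of matrices with columns x_px, y_px, depth_um),
#'   `dims`.
#' @export
build_vessels <- function(tissue, target_area_fraction, seed,
                          roi = NULL, radius_um = c(4, 15),
                          speed_mmps = c(0.5, 2), max_vessels = 500L) {
  stopifnot(inherits(tissue, "tissue_model"),
            target_area_fraction >= 0, target_area_fraction <= 0.5)
  optics <- tissue$optics
  Z <- optics$depth_pixels
  dims_xy <- dim(tissue$surface_px)
  X <- dims_xy[1]; Y <- dims_xy[2]
  dims <- c(Z, X, Y)
  if (is.null(roi)) roi <- matrix(TRUE, X, Y)
  stopifnot(identical(dim(roi), dims_xy))
  a_roi <- sum(roi)
  if (a_roi == 0) stop("empty ROI")

  empty <- function() structure(list(
    idx = integer(0), speed_mmps = numeric(0),
    proj = matrix(FALSE, X, Y), achieved_fraction = 0,
    target_fraction = target_area_fraction, centerlines = list(),
    dims = dims, band_um = tissue$vessel_band_um), class = "vessel_field")
  if (target_area_fraction == 0) return(empty())

  goal_px <- target_area_fraction * a_roi
  ax <- optics$axial_pixel_um
  pxx <- optics$lateral_pixel_x_um; pxy <- optics$lateral_pixel_y_um
  band <- tissue$vessel_band_um
  surf <- tissue$surface_px

  res <- with_seed(as.integer(seed), {
    mask <- array(FALSE, dims)
    proj <- matrix(FALSE, X, Y)
    n_proj <- 0L
    idx_all <- integer(0); speed_all <- numeric(0)
    centerlines <- list()
    roi_cells <- which(roi)
    step_px <- 0.7
    max_steps <- as.integer(6 * sqrt(a_roi))
    v <- 0L
    while (n_proj < 0.97 * goal_px && v < max_vessels) {
      v <- v + 1L
      start <- arrayInd(sample(roi_cells, 1), dims_xy)
      x <- start[1] + stats::runif(1, -0.5, 0.5)
      y <- start[2] + stats::runif(1, -0.5, 0.5)
      theta <- stats::runif(1, 0, 2 * pi)
      zrel <- stats::runif(1, band[1], band[2])     # um below local surface
      r_um <- stats::runif(1, radius_um[1], radius_um[2])
      speed <- stats::runif(1, speed_mmps[1], speed_mmps[2])
      # ellipsoid voxel offsets at this radius (at least the center voxel)
      rx <- r_um / pxx; ry <- r_um / pxy; rz <- r_um / ax
      og <- expand.grid(dx = -ceiling(rx):ceiling(rx),
                        dy = -ceiling(ry):ceiling(ry),
                        dz = -ceiling(rz):ceiling(rz))
      keep <- (og$dx / max(rx, 0.5))^2 + (og$dy / max(ry, 0.5))^2 +
        (og$dz / max(rz, 0.5))^2 <= 1
      og <- og[keep | (og$dx == 0 & og$dy == 0 & og$dz == 0), , drop = FALSE]
      pts <- matrix(NA_real_, max_steps, 3)
      vidx <- integer(0)
      for (s in seq_len(max_steps)) {
        ix <- as.integer(.round_half_up(x)); iy <- as.integer(.round_half_up(y))
        if (ix < 1 || ix > X || iy < 1 || iy > Y || !roi[ix, iy]) break
        zi <- surf[ix, iy] + um_to_px(max(zrel, 0), ax)
        pts[s, ] <- c(x, y, zrel)
        xs <- pmin(pmax(ix + og$dx, 1L), X)
        ys <- pmin(pmax(iy + og$dy, 1L), Y)
        zs <- pmin(pmax(zi + og$dz, 1L), Z)
        lin <- zs + (xs - 1L) * Z + (ys - 1L) * (Z * X)
        new <- lin[!mask[lin]]
        if (length(new)) {
          mask[new] <- TRUE
          vidx <- c(vidx, new)
          lat <- unique(.voxel_lateral_index(new, dims))
          fresh <- lat[!proj[lat]]
          if (length(fresh)) {
            proj[fresh] <- TRUE
            n_proj <- n_proj + sum(roi[fresh])
          }
        }
        if (n_proj >= 0.97 * goal_px) break
        x <- x + cos(theta) * step_px
        y <- y + sin(theta) * step_px
        theta <- theta + stats::rnorm(1, 0, 0.15)
        zrel <- min(max(zrel + stats::rnorm(1, 0, ax * 0.3), band[1]), band[2])
      }
      if (length(vidx)) {
        idx_all <- c(idx_all, vidx)
        speed_all <- c(speed_all, rep(speed, length(vidx)))
        centerlines[[length(centerlines) + 1L]] <-
          pts[stats::complete.cases(pts), , drop = FALSE]
      }
    }
    list(idx = idx_all, speed = speed_all, proj = proj,
         n_proj = n_proj, centerlines = centerlines)
  })

  achieved <- res$n_proj / a_roi
  if (achieved < 0.8 * target_area_fraction)
    stop(sprintf(
      "vessel target unreachable: achieved fraction %.4f < 80%% of target %.4f after %d attempts",
      achieved, target_area_fraction, max_vessels))
  structure(list(
    idx = res$idx, speed_mmps = res$speed, proj = res$proj,
    achieved_fraction = achieved, target_fraction = target_area_fraction,
    centerlines = res$centerlines, dims = dims,
    band_um = tissue$vessel_band_um), class = "vessel_field")
}

#' Render a repeated-B-scan complex OCT cube from a phantom
#'
#' Per voxel the complex field is `sqrt(reflectivity) * speckle * attenuation`
#' plus additive circular complex noise per repeat, with single-pass
#' attenuation `exp(-2 mu z)` below the surface. Speckle is circular complex
#' Gaussian: static voxels share one draw across all repeats; vessel voxels
#' follow an AR(1) chain across consecutive repeats with correlation
#' `rho = exp(-(v / v_c)^2)`, so fast flow decorrelates completely.
#' Inflammatory extra-dynamic voxels (if present) use a fixed moderate
#' correlation. An optional global per-repeat phase offset emulates bulk
#' tissue motion.
#'
#' @param tissue A [build_tissue()] (possibly wounded) phantom.
#' @param vessels A [build_vessels()] field, or `NULL` for avascular tissue.
#' @param optics Acquisition optics (defaults to the tissue's).
#' @param seed Integer RNG seed.
#' @param v_c_mmps Decorrelation speed scale of the AR(1) model (mm/s). The
#'   flow-speed-to-correlation mapping is a free phantom parameter, not a
#'   measured property of zebrafish skin.
#' @param bulk_phase_sd_rad SD of the random global per-repeat phase (rad);
#'   0 disables bulk motion.
#' @param noise_snr_db Additive-noise SNR in dB relative to unit reflectivity;
#'   `Inf` disables noise.
#' @return An [oct_cube()].
#' @export
render_cube <- function(tissue, vessels = NULL, optics = tissue$optics, seed,
                        v_c_mmps = 0.3, bulk_phase_sd_rad = 0,
                        noise_snr_db = optics$noise_snr_db) {
  stopifnot(inherits(tissue, "tissue_model"))
  Z <- optics$depth_pixels; X <- optics$alines_per_bscan
  Y <- optics$positions; R <- optics$repeats
  n <- Z * X * Y
  ax <- optics$axial_pixel_um

  rel <- (matrix(seq_len(Z), Z, X * Y) -
            matrix(rep(as.vector(tissue$surface_px), each = Z), Z, X * Y)) * ax
  amp <- sqrt(as.vector(tissue$reflectivity) *
                exp(-2 * tissue$attenuation_per_um * pmax(rel, 0)))

  didx <- integer(0); rho <- numeric(0)
  if (!is.null(vessels)) {
    didx <- vessels$idx
    rho <- exp(-(vessels$speed_mmps / v_c_mmps)^2)
    ex <- vessels$extra_dynamic_idx %||% integer(0)
    if (length(ex)) {
      didx <- c(didx, ex)
      rho <- c(rho, rep(0.3, length(ex)))
    }
  }
  sigma2 <- if (is.finite(noise_snr_db)) 10^(-noise_snr_db / 10) else 0
  sd_c <- sqrt(sigma2 / 2)

  cube <- with_seed(as.integer(seed), {
    phases <- if (bulk_phase_sd_rad > 0) c(0, stats::rnorm(R - 1, 0, bulk_phase_sd_rad))
              else numeric(R)
    out <- render_speckle_cube(amp, as.integer(didx), rho, phases, sd_c, R)
    dim(out) <- c(Z, X, Y, R)
    out
  })
  oct_cube(cube, optics)
}

#' Assemble a complete wound scene and its rendered cube
#'
#' Convenience constructor used per fish and timepoint: layered tissue,
#' baseline vasculature at the healing-curve baseline fraction, the wound and
#' its angiogenic response for the requested group/timepoint, and the rendered
#' repeated-B-scan cube. All randomness derives from `seed`.
#'
#' @param group `"control"` or `"diabetic"`.
#' @param timepoint_dpw Timepoint (dpw; `-1` = pre-wound).
#' @param seed Integer RNG seed.
#' @param optics Acquisition grid (defaults to [phantom_optics()]).
#' @param healing A [healing_params()] object.
#' @param wound A [wound_model()] (its timepoint is overridden); `NULL` uses
#'   defaults centered in the field.
#' @param bulk_phase_sd_rad Per-repeat bulk-motion phase SD (rad).
#' @return List with `cube`, `tissue`, `vessels`, `truth` (see
#'   [apply_wound()]), `group`, `timepoint_dpw`.
#' @export
phantom_scene <- function(group = c("control", "diabetic"), timepoint_dpw,
                          seed, optics = phantom_optics(),
                          healing = healing_params(), wound = NULL,
                          bulk_phase_sd_rad = 0.2) {
  group <- match.arg(group)
  seed <- as.integer(seed)
  tissue <- build_tissue(optics, seed)
  vessels <- build_vessels(tissue, healing$v0, seed = seed + 1L)
  w <- wound %||% wound_model(timepoint_dpw = timepoint_dpw)
  w$timepoint_dpw <- as.numeric(timepoint_dpw)
  scene <- apply_wound(tissue, vessels, w, healing, group, seed = seed + 2L)
  cube <- render_cube(scene$tissue, scene$vessels, optics, seed = seed + 5L,
                      bulk_phase_sd_rad = bulk_phase_sd_rad)
  list(cube = cube, tissue = scene$tissue, vessels = scene$vessels,
       truth = scene$truth, group = group,
       timepoint_dpw = as.numeric(timepoint_dpw))
}
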