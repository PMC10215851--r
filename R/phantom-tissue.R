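#' @importFrom withr with_seed
NULL

# sentinel for the pre-wound timepoint on the numeric dpw axis
PRE_WOUND <- -1

#' Is a timepoint the pre-wound baseline?
#' @param t Numeric timepoint(s) in days post-wounding; the pre-wound baseline
#'   is encoded as `-1` (3 hpw is `0.125`).
#' @return Logical vector.
#' @export
is_prewound <- function(t) !is.na(t) & t < 0

.round_half_up <- function(x) floor(x + 0.5)

#' Skin layer stack of the tissue phantom
#'
#' Layer bottoms are measured in micrometres below the local skin surface;
#' reflectivities are relative to the brightest (scale) layer. The stack
#' mirrors adult zebrafish trunk skin: scale, pigmented layer, epidermis +
#' dermis, hypodermis, then muscle.
#'
#' @param breaks_um Increasing depths (um below surface) ending each of the
#'   first four layers.
#' @param reflectivity Five nonnegative reflectivities (one per layer,
#'   muscle last).
#' @return A list with components `breaks_um`, `reflectivity`, `names`.
#' @export
tissue_layers <- function(breaks_um = c(15, 40, 200, 400),
                          reflectivity = c(1.0, 0.85, 0.5, 0.32, 0.45)) {
  stopifnot(length(breaks_um) == 4, all(diff(breaks_um) > 0),
            length(reflectivity) == 5, all(reflectivity >= 0))
  list(breaks_um = breaks_um, reflectivity = reflectivity,
       names = c("scale", "pigment", "epidermis_dermis", "hypodermis", "muscle"))
}

# piecewise-constant reflectivity profile vs depth below surface (um);
# negative depths (above the surface) are empty
.layer_profile <- function(rel_um, layers) {
  c(0, layers$reflectivity)[findInterval(rel_um, c(0, layers$breaks_um)) + 1L]
}

#' Build the layered static-tissue phantom
#'
#' Constructs a reflectivity volume with a gently undulating skin surface, a
#' periodic scale-tile relief, and the five-layer stack of [tissue_layers()]
#' below it at every lateral position. The surface map used for construction
#' is returned as ground truth. Deterministic given `seed`.
#'
#' @param optics An [oct_optics()] object (use [phantom_optics()] for the
#'   desk-scale grid).
#' @param seed Integer RNG seed.
#' @param surface_depth_um Nominal surface depth below the top of the cube.
#' @param undulation_um Peak amplitude of the smooth random surface
#'   undulation; set 0 for a deterministic plane.
#' @param scale_tile_um Amplitude of the periodic scale-tile surface relief.
#' @param tilt_um_per_mm Length-2 surface tilt along x and y (um per mm).
#' @param flat_surface_px If given, overrides the surface with a constant
#'   depth index (ground-truth forcing for tests).
#' @param layers A [tissue_layers()] stack.
#' @param attenuation_per_um Single-pass attenuation coefficient (1/um).
#' @param vessel_band_um Depth band below the surface (um) that vessels are
#'   confined to (hypodermis and upper muscle).
#' @return A `tissue_model`: list with `optics`, `surface_px` (X x Y integer
#'   matrix of 1-based depth indices), `reflectivity` (Z x X x Y array),
#'   `layers`, `attenuation_per_um`, `vessel_band_um`.
#' @export
build_tissue <- function(optics, seed,
                         surface_depth_um = 170, undulation_um = 25,
                         scale_tile_um = 8, tilt_um_per_mm = c(0, 0),
                         flat_surface_px = NULL,
                         layers = tissue_layers(),
                         attenuation_per_um = 5e-4,
                         vessel_band_um = c(210, 590)) {
  stopifnot(inherits(optics, "oct_optics"))
  Z <- optics$depth_pixels; X <- optics$alines_per_bscan; Y <- optics$positions
  x_mm <- (seq_len(X) - 0.5) * optics$lateral_pixel_x_um / 1000
  y_mm <- (seq_len(Y) - 0.5) * optics$lateral_pixel_y_um / 1000

  if (is.null(flat_surface_px)) {
    surface_um <- with_seed(as.integer(seed), {
      u <- matrix(surface_depth_um, X, Y)
      # three smooth random harmonics across the field
      amps <- undulation_um * c(0.5, 0.3, 0.2)
      for (k in 1:3) {
        fx <- sample(1:3, 1); fy <- sample(1:3, 1)
        ph <- stats::runif(2, 0, 2 * pi)
        u <- u + amps[k] *
          outer(sin(2 * pi * fx * x_mm / max(x_mm) + ph[1]),
                cos(2 * pi * fy * y_mm / max(y_mm) + ph[2]))
      }
      # tiled scale relief, ~0.55 mm period
      u <- u + scale_tile_um *
        outer(sin(2 * pi * x_mm / 0.55), sin(2 * pi * y_mm / 0.55))
      u + outer(tilt_um_per_mm[1] * x_mm, rep(1, Y)) +
        outer(rep(1, X), tilt_um_per_mm[2] * y_mm)
    })
    surface_px <- matrix(pmin(pmax(
      .round_half_up(surface_um / optics$axial_pixel_um) + 1L, 1L), Z), X, Y)
  } else {
    surface_px <- matrix(as.integer(flat_surface_px), X, Y)
  }
  storage.mode(surface_px) <- "integer"

  reflectivity <- .tissue_reflectivity(Z, surface_px, optics$axial_pixel_um, layers)
  structure(list(
    optics = optics, surface_px = surface_px, reflectivity = reflectivity,
    layers = layers, attenuation_per_um = attenuation_per_um,
    vessel_band_um = vessel_band_um, seed = as.integer(seed)
  ), class = "tissue_model")
}

.tissue_reflectivity <- function(Z, surface_px, axial_pixel_um, layers) {
  XY <- length(surface_px)
  rel <- (matrix(seq_len(Z), Z, XY) -
            matrix(rep(as.vector(surface_px), each = Z), Z, XY)) * axial_pixel_um
  refl <- .layer_profile(rel, layers)
  dim(refl) <- c(Z, dim(surface_px))
  refl
}

#' Healing-curve parameters for wound angiogenesis
#'
#' The wound-zone vessel area fraction over time is a log-normal-shaped pulse:
#' \eqn{f(t) = A \exp(-\log^2(t/t_p) / (2 w^2))}, peaking at `peak_time`.
#' The diabetic group is scaled by `diabetic_fraction` through day 10; on
#' (10, 15] both groups blend quadratically to the common day-15 level
#' `day15_recovery * v0`, emulating the return to normoglycemia. Pre-wound
#' (`t = -1`) returns the baseline fraction `v0`.
#'
#' @param v0 Baseline (pre-wound) vessel area fraction.
#' @param peak_time Day of maximal angiogenesis (dpw).
#' @param amplitude Peak control-group vessel area fraction.
#' @param width Log-domain pulse width (SD of log t).
#' @param diabetic_fraction Diabetic/control amplitude ratio in (0, 1].
#' @param day15_recovery Fraction of baseline reached by both groups at 15 dpw.
#' @return A `healing_params` list.
#' @export
healing_params <- function(v0 = 0.05, peak_time = 4, amplitude = 0.30,
                           width = 0.6, diabetic_fraction = 0.4,
                           day15_recovery = 0.7) {
  stopifnot(v0 >= 0, v0 <= 1, amplitude >= 0, amplitude <= 1,
            peak_time > 0, width > 0,
            diabetic_fraction > 0, diabetic_fraction <= 1,
            day15_recovery >= 0)
  structure(list(v0 = v0, peak_time = peak_time, amplitude = amplitude,
                 width = width, diabetic_fraction = diabetic_fraction,
                 day15_recovery = day15_recovery), class = "healing_params")
}

#' Wound-zone vessel area fraction at a timepoint
#'
#' @param t Timepoint(s) in days post-wounding (`-1` = pre-wound baseline;
#'   3 hpw is 0.125). Negative values other than the sentinel are an error.
#' @param params A [healing_params()] object.
#' @param group `"control"` or `"diabetic"`.
#' @return Vessel area fraction(s) in `[0, 1]`.
#' @export
healing_vad_curve <- function(t, params = healing_params(),
                              group = c("control", "diabetic")) {
  group <- match.arg(group)
  t <- as.numeric(t)
  if (any(!is.na(t) & t < 0 & t != PRE_WOUND))
    stop("negative timepoints are invalid (pre-wound sentinel is -1)")
  amp <- params$amplitude *
    if (group == "diabetic") params$diabetic_fraction else 1
  pulse <- ifelse(t > 0,
                  exp(-(log(pmax(t, 1e-12) / params$peak_time))^2 /
                        (2 * params$width^2)), 0)
  v <- amp * pulse
  # blend to the shared day-15 recovery level
  beta <- pmin(pmax((t - 10) / 5, 0), 1)^2
  v <- (1 - beta) * v + beta * (params$day15_recovery * params$v0)
  v[is_prewound(t)] <- params$v0
  pmin(pmax(v, 0), 1)
}

#' Full-thickness punch-wound description
#'
#' @param timepoint_dpw Time since wounding in days (`-1` = pre-wound,
#'   0.125 = 3 hpw).
#' @param center_mm Lateral wound center `c(x, y)` in mm; `NULL` centers the
#'   wound in the field of view.
#' @param diameter_mm Punch diameter (mm).
#' @param zone_factor The perilesional angiogenic zone diameter as a multiple
#'   of the wound diameter (default 2, matching the 2 mm analysis mask for a
#'   1 mm punch).
#' @param neo_epidermis_um Thickness of the thin neo-epidermis that covers the
#'   wound from 3 hpw.
#' @param granulation_amp Relative amplitude of the fine-grained granulation
#'   texture appearing from 4 dpw.
#' @return A `wound_model` list.
#' @export
wound_model <- function(timepoint_dpw, center_mm = NULL, diameter_mm = 1.0,
                        zone_factor = 2, neo_epidermis_um = 15,
                        granulation_amp = 0.35) {
  stopifnot(diameter_mm > 0, zone_factor >= 1)
  t <- as.numeric(timepoint_dpw)
  if (!is_prewound(t) && t < 0) stop("timepoint must be >= 0 or the pre-wound sentinel")
  structure(list(timepoint_dpw = t, center_mm = center_mm,
                 diameter_mm = diameter_mm, zone_factor = zone_factor,
                 neo_epidermis_um = neo_epidermis_um,
                 granulation_amp = granulation_amp), class = "wound_model")
}

# crater depth (um of excised tissue) vs time: excision to mid-muscle early,
# progressively filled by granulation/remodeling
.crater_depth_um <- function(t) {
  stats::approx(x = c(0, 1, 4, 7, 10, 15), y = c(260, 260, 120, 80, 40, 10),
                xout = pmin(t, 15), rule = 2)$y
}

# granulation texture persistence: regresses by day 15 in control, persists
# (downsized) in the diabetic group
.granulation_gain <- function(t, group) {
  if (t < 4) return(0)
  pts <- if (group == "diabetic") c(1, 0.9, 0.8, 0.5) else c(1, 0.7, 0.4, 0)
  stats::approx(x = c(4, 7, 10, 15), y = pts, xout = pmin(t, 15), rule = 2)$y
}

#' Apply a full-thickness wound and its angiogenic response to a phantom
#'
#' Inside the punch disc the layer stack is excised to mid-muscle at early
#' timepoints, covered by a thin neo-epidermis from 3 hpw, and filled with
#' fine-grained granulation texture from 4 dpw (regressing by day 15 in the
#' control group, persisting in the diabetic group). The vessel field inside
#' the perilesional angiogenic zone is replaced by angiogenic vessels whose
#' projected area fraction follows [healing_vad_curve()] for the group. At
#' 1 dpw sparse bright dynamic voxels emulate inflammatory infiltrate; they
#' are rendered as decorrelating scatterers but excluded from the
#' ground-truth vessel mask.
#'
#' @param tissue A [build_tissue()] phantom.
#' @param vessels A [build_vessels()] field (the pre-wound vasculature).
#' @param wound A [wound_model()].
#' @param healing A [healing_params()] object.
#' @param group `"control"` or `"diabetic"`.
#' @param seed Integer RNG seed for the angiogenic vessel field.
#' @return A list with the modified `tissue` and `vessels` plus `truth`:
#'   `target_fraction` (the healing-curve value), `zone_fraction` and
#'   `wound_fraction` (pixel counts of the generator's own projected mask in
#'   the zone and the punch disc), `zone_mask`, `wound_mask`, `center_mm`.
#' @export
apply_wound <- function(tissue, vessels, wound, healing = healing_params(),
                        group = c("control", "diabetic"), seed = 1) {
  group <- match.arg(group)
  stopifnot(inherits(tissue, "tissue_model"), inherits(wound, "wound_model"))
  optics <- tissue$optics
  t <- wound$timepoint_dpw
  fov <- fov_mm(optics)
  center <- wound$center_mm %||% c(fov[["x"]] / 2, fov[["y"]] / 2)
  r_mm <- wound$diameter_mm / 2
  if (center[1] - r_mm < 0 || center[1] + r_mm > fov[["x"]] ||
      center[2] - r_mm < 0 || center[2] + r_mm > fov[["y"]])
    stop("wound disc extends outside the field of view")

  dims_xy <- dim(tissue$surface_px)
  px_mm <- c(optics$lateral_pixel_x_um, optics$lateral_pixel_y_um) / 1000
  wound_mask <- circular_mask(dims_xy, center, wound$diameter_mm, px_mm)
  zone_mask <- circular_mask(dims_xy, center,
                             wound$diameter_mm * wound$zone_factor, px_mm)

  if (is_prewound(t)) {
    truth <- list(target_fraction = healing$v0,
                  zone_fraction = mean(vessels$proj[zone_mask]),
                  wound_fraction = mean(vessels$proj[wound_mask]),
                  zone_mask = zone_mask, wound_mask = wound_mask,
                  center_mm = center)
    return(list(tissue = tissue, vessels = vessels, truth = truth))
  }

  ax <- optics$axial_pixel_um
  Z <- optics$depth_pixels
  crater_px <- um_to_px(.crater_depth_um(t), ax)
  surface_px <- tissue$surface_px
  surface_px[wound_mask] <- pmin(surface_px[wound_mask] + crater_px, Z)

  # rebuild the reflectivity profile of the wounded columns
  neo_px <- max(1L, um_to_px(wound$neo_epidermis_um, ax))
  gran_gain <- .granulation_gain(t, group) * wound$granulation_amp
  wcols <- which(wound_mask)
  refl <- tissue$reflectivity
  refl <- with_seed(as.integer(seed) + 1L, {
    idx2 <- arrayInd(wcols, dims_xy)
    zz <- seq_len(Z)
    for (k in seq_along(wcols)) {
      ix <- idx2[k, 1]; iy <- idx2[k, 2]
      s <- surface_px[ix, iy]
      rel <- (zz - s) * ax
      col <- numeric(Z)
      col[rel >= 0] <- 0.42
      col[rel >= 0 & rel < neo_px * ax] <- 0.7
      col[rel >= 300] <- tissue$layers$reflectivity[5]
      if (gran_gain > 0) {
        g <- which(rel >= neo_px * ax & rel < 300)
        col[g] <- col[g] * (1 + gran_gain * stats::runif(length(g), -1, 1))
      }
      refl[, ix, iy] <- col
    }
    refl
  })

  tissue_w <- tissue
  tissue_w$surface_px <- surface_px
  tissue_w$reflectivity <- refl

  # replace the vasculature of the angiogenic zone by the healing-curve field
  target <- healing_vad_curve(t, healing, group)
  keep <- !zone_mask[.voxel_lateral_index(vessels$idx, c(Z, dims_xy))]
  base_idx <- vessels$idx[keep]
  base_speed <- vessels$speed_mmps[keep]
  angio <- build_vessels(tissue_w, target, seed = as.integer(seed) + 2L,
                         roi = zone_mask)
  vessels_w <- vessels
  vessels_w$idx <- c(base_idx, angio$idx)
  vessels_w$speed_mmps <- c(base_speed, angio$speed_mmps)
  vessels_w$proj <- .project_idx(vessels_w$idx, c(Z, dims_xy))

  # inflammatory bright spots around 1 dpw: dynamic, not vessels
  extra <- integer(0)
  if (t >= 0.5 && t <= 2) {
    extra <- with_seed(as.integer(seed) + 3L, {
      bed <- wcols
      n_spots <- min(60L, length(bed))
      cols <- sample(bed, n_spots)
      idx2 <- arrayInd(cols, dims_xy)
      zoff <- um_to_px(stats::runif(n_spots, 40, 200), ax)
      zi <- pmin(surface_px[cbind(idx2[, 1], idx2[, 2])] + zoff, Z)
      as.integer(zi + (idx2[, 1] - 1) * Z + (idx2[, 2] - 1) * Z * dims_xy[1])
    })
    refl_flat <- as.vector(tissue_w$reflectivity)
    refl_flat[extra] <- 1.2
    tissue_w$reflectivity <- array(refl_flat, dim = dim(tissue_w$reflectivity))
  }
  vessels_w$extra_dynamic_idx <- extra

  truth <- list(target_fraction = target,
                zone_fraction = mean(vessels_w$proj[zone_mask]),
                wound_fraction = mean(vessels_w$proj[wound_mask]),
                zone_mask = zone_mask, wound_mask = wound_mask,
                center_mm = center)
  list(tissue = tissue_w, vessels = vessels_w, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# lateral (x,y) linear index of voxel linear indices in a (Z, X, Y) array
.voxel_lateral_index <- function(idx, dims) {
  ((idx - 1L) %/% dims[1]) + 1L
}

# project voxel indices to the lateral plane
.project_idx <- function(idx, dims) {
  proj <- matrix(FALSE, dims[2], dims[3])
  proj[unique(.voxel_lateral_index(idx, dims))] <- TRUE
  proj
}
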