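#' Moving-window surface detection on a single A-line
#'
#' Slides a `window`-pixel moving window down the intensity A-line from the
#' top and returns the (1-based) start index of the first window whose mean
#' intensity exceeds `threshold`, or `NA` if none qualifies.
#'
#' @param aline Numeric intensity vector (one depth profile).
#' @param window Window size in pixels.
#' @param threshold Mean-intensity threshold.
#' @return Integer start index, or `NA_integer_`.
#' @export
detect_surface_aline <- function(aline, window = 60L, threshold) {
  n <- length(aline)
  if (window > n) stop("window larger than A-line")
  cs <- cumsum(c(0, aline))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  hit <- which(means > threshold)
  if (length(hit)) as.integer(hit[1]) else NA_integer_
}

#' Detect the skin surface over a whole intensity cube
#'
#' Runs the moving-window detector on every A-line, then refines the window
#' start to the first supra-threshold pixel inside the qualifying window (so
#' the returned index estimates the surface itself rather than the window
#' start), fills undetected positions from their nearest valid neighbors
#' (flagged, never guessed silently), and median-smooths the index map.
#'
#' When `threshold` is `NULL` it is set automatically to
#' `mean + 4 * SD` of the top `noise_rows` rows of the cube (assumed above the
#' tissue), which makes detection invariant to global intensity scaling.
#' When `optics` is supplied, `window` and `noise_rows` default to the
#' physical equivalents of 60 px and 20 px at 2.7 um/pixel (162 um and 54 um).
#'
#' @param intensity Numeric `(Z, X, Y)` intensity array (see
#'   [cube_intensity()]).
#' @param window Moving-window size in pixels (default 60, or scaled via
#'   `optics`).
#' @param threshold Intensity threshold; `NULL` for automatic.
#' @param optics Optional [oct_optics()] for physical-unit defaults.
#' @param noise_rows Number of top rows used for the automatic threshold.
#' @param median_size Median smoothing window (odd; default 5 for 5 x 5).
#' @param max_invalid Maximum tolerated fraction of undetected A-lines before
#'   hard failure.
#' @return A `surface_map`: list with `index` (X x Y integer matrix of depth
#'   indices) and `valid` (logical X x Y).
#' @export
detect_surface <- function(intensity, window = NULL, threshold = NULL,
                           optics = NULL, noise_rows = NULL,
                           median_size = 5L, max_invalid = 0.5) {
  d <- dim(intensity)
  if (length(d) != 3) stop("intensity must be (Z, X, Y)")
  Z <- d[1]; X <- d[2]; Y <- d[3]
  if (is.null(window))
    window <- if (!is.null(optics)) max(3L, um_to_px(162, optics$axial_pixel_um)) else 60L
  if (is.null(noise_rows))
    noise_rows <- if (!is.null(optics)) max(3L, um_to_px(54, optics$axial_pixel_um)) else 20L
  if (window > Z) stop("window larger than cube depth")
  m <- matrix(intensity, Z, X * Y)
  if (is.null(threshold)) {
    top <- m[seq_len(min(noise_rows, Z)), , drop = FALSE]
    threshold <- mean(top) + 4 * stats::sd(as.vector(top))
  }
  # vectorized moving-window scan over all A-lines at once
  cs <- apply(m, 2, cumsum)
  nw <- Z - window + 1L
  mm <- (cs[window:Z, , drop = FALSE] -
           rbind(0, cs[seq_len(nw - 1L), , drop = FALSE])) / window
  qual <- mm > threshold
  ws <- max.col(t(qual), ties.method = "first")
  ws[!qual[cbind(ws, seq_len(X * Y))]] <- NA_integer_
  # refine to the first supra-threshold pixel at or below the window start
  above <- m > threshold
  above[matrix(seq_len(Z), Z, X * Y) <
          matrix(rep(ifelse(is.na(ws), Z + 1L, ws), each = Z), Z, X * Y)] <- FALSE
  fp <- max.col(t(above), ties.method = "first")
  hit <- above[cbind(fp, seq_len(X * Y))]
  idx <- ifelse(is.na(ws), NA_integer_, ifelse(hit, fp, ws))
  valid <- !is.na(idx)
  if (mean(valid) < 1 - max_invalid)
    stop(sprintf("surface not detectable: %.0f%% of A-lines below threshold",
                 100 * mean(!valid)))
  index <- matrix(idx, X, Y)
  index <- .fill_nearest(index)
  index <- .median2d(index, median_size)
  structure(list(index = matrix(as.integer(.round_half_up(index)), X, Y),
                 valid = matrix(valid, X, Y)),
            class = "surface_map")
}

# iterative nearest-neighbor fill of NA entries (4-neighborhood means)
.fill_nearest <- function(mat) {
  while (anyNA(mat)) {
    na <- which(is.na(mat), arr.ind = TRUE)
    X <- nrow(mat); Y <- ncol(mat)
    vals <- apply(na, 1, function(p) {
      nb <- rbind(c(p[1] - 1, p[2]), c(p[1] + 1, p[2]),
                  c(p[1], p[2] - 1), c(p[1], p[2] + 1))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= X & nb[, 2] >= 1 & nb[, 2] <= Y, , drop = FALSE]
      v <- mat[nb]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
    if (all(is.na(vals))) stop("no valid surface positions to fill from")
    mat[is.na(mat)] <- vals
  }
  mat
}

# 2-D running median with edge replication
.median2d <- function(mat, size = 5L) {
  if (size <= 1) return(mat)
  r <- (size - 1L) %/% 2L
  X <- nrow(mat); Y <- ncol(mat)
  stack <- array(NA_real_, c(X, Y, size * size))
  l <- 0L
  for (dx in -r:r) for (dy in -r:r) {
    l <- l + 1L
    xi <- pmin(pmax(seq_len(X) + dx, 1L), X)
    yi <- pmin(pmax(seq_len(Y) + dy, 1L), Y)
    stack[, , l] <- mat[xi, yi]
  }
  matrix(apply(matrix(stack, X * Y, size * size), 1, stats::median), X, Y)
}

#' Extract a surface-referenced flattened slab
#'
#' Per lateral position, copies the rows `[surface + offset_px, surface +
#' offset_px + thickness_px)` of the volume into a flattened slab; rows beyond
#' the cube bottom are zero-filled and flagged. Physical lengths convert via
#' [um_to_px()] at the supplied axial pixel size (defaults: a slab from 200 to
#' 600 um below the surface, covering hypodermis and muscle).
#'
#' @param volume Numeric `(Z, X, Y)` array (flow or intensity).
#' @param surface A [detect_surface()] map, or an X x Y integer index matrix.
#' @param offset_um Slab top depth below the surface (um).
#' @param thickness_um Slab thickness (um).
#' @param axial_pixel_um Axial pixel size (um/pixel).
#' @return A `slab`: list with `data` (`thickness_px` x X x Y array),
#'   `clipped` (logical X x Y, positions with zero-padded rows), `offset_px`,
#'   `thickness_px`.
#' @export
extract_slab <- function(volume, surface, offset_um = 200, thickness_um = 400,
                         axial_pixel_um = 2.7) {
  d <- dim(volume)
  if (length(d) != 3) stop("volume must be (Z, X, Y)")
  Z <- d[1]
  surf <- if (inherits(surface, "surface_map")) surface$index else surface
  stopifnot(identical(dim(surf), d[2:3]))
  offset_px <- um_to_px(offset_um, axial_pixel_um)
  if (offset_px >= Z) stop("slab offset beyond cube depth")
  th_px <- max(1L, um_to_px(thickness_um, axial_pixel_um))
  XY <- d[2] * d[3]
  start <- as.vector(surf) + offset_px
  rows <- outer(0:(th_px - 1L), start, "+")          # th_px x XY depth indices
  ok <- rows >= 1L & rows <= Z
  lin <- pmin(pmax(rows, 1L), Z) + rep((seq_len(XY) - 1L) * Z, each = th_px)
  vals <- as.vector(volume)[lin]
  vals[!ok] <- 0
  structure(list(
    data = array(vals, c(th_px, d[2], d[3])),
    clipped = matrix(colSums(!ok) > 0, d[2], d[3]),
    offset_px = offset_px, thickness_px = th_px), class = "slab")
}

#' Maximum intensity projection of a slab
#'
#' Per lateral position, the maximum over the slab depth. The depth-coded
#' variant also records the argmax depth (1 = top of slab, i.e. closest to
#' the surface), the basis of depth-colored en face renderings.
#'
#' @param slab An [extract_slab()] result or a `(D, X, Y)` array.
#' @param depth_coded Also return the per-pixel argmax depth.
#' @return X x Y matrix; with `depth_coded = TRUE`, a list `(map, depth)`.
#' @export
mip <- function(slab, depth_coded = FALSE) {
  a <- if (inherits(slab, "slab")) slab$data else slab
  d <- dim(a)
  if (is.null(d) || length(d) != 3 || any(d == 0)) stop("slab must be a non-empty (D, X, Y) array")
  cur <- a[1, , ]
  amx <- matrix(1L, d[2], d[3])
  if (d[1] > 1) for (i in 2:d[1]) {
    s <- a[i, , ]
    upd <- s > cur
    cur[upd] <- s[upd]
    amx[upd] <- i
  }
  cur <- matrix(cur, d[2], d[3])
  if (depth_coded) list(map = cur, depth = amx) else cur
}

#' Depth-resolved structural layer views
#'
#' Convenience wrapper producing thin-slab MIPs of an intensity cube centered
#' at given depths below the surface (default 50 um thickness), used to
#' visualize individual layers such as scales or the pigmented stripes.
#'
#' @param intensity `(Z, X, Y)` intensity array.
#' @param surface A [detect_surface()] map or index matrix.
#' @param center_depth_um Vector of slab center depths below the surface (um).
#' @param thickness_um Slab thickness (um).
#' @param axial_pixel_um Axial pixel size (um/pixel).
#' @return Named list of X x Y en face maps (one per center depth).
#' @export
layer_slab_views <- function(intensity, surface, center_depth_um,
                             thickness_um = 50, axial_pixel_um = 2.7) {
  out <- lapply(center_depth_um, function(cz) {
    mip(extract_slab(intensity, surface,
                     offset_um = max(cz - thickness_um / 2, 0),
                     thickness_um = thickness_um,
                     axial_pixel_um = axial_pixel_um))
  })
  names(out) <- sprintf("%gum", center_depth_um)
  out
}
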