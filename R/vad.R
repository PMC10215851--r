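#' Circular region-of-interest mask in physical coordinates
#'
#' A pixel is included iff its physical center lies within `diameter_mm / 2`
#' of the ROI center; anisotropic lateral pixel sizes are honored (the circle
#' is an ellipse in pixel space). Pixel centers sit at `(i - 0.5) * pitch`.
#'
#' @param dim_xy Length-2 image dimensions `c(X, Y)`.
#' @param center_mm ROI center `c(x, y)` in mm.
#' @param diameter_mm ROI diameter in mm (default 2, the wound analysis mask).
#' @param pixel_mm Length-2 lateral pixel pitch `c(x, y)` in mm.
#' @return Logical X x Y mask.
#' @export
circular_mask <- function(dim_xy, center_mm, diameter_mm = 2,
                          pixel_mm = c(6.0, 6.4) / 1000) {
  stopifnot(length(dim_xy) == 2, diameter_mm >= 0, all(pixel_mm > 0))
  x_mm <- (seq_len(dim_xy[1]) - 0.5) * pixel_mm[1]
  y_mm <- (seq_len(dim_xy[2]) - 0.5) * pixel_mm[2]
  r2 <- (diameter_mm / 2)^2
  mask <- outer((x_mm - center_mm[1])^2, (y_mm - center_mm[2])^2, "+") < r2
  if (diameter_mm > 0 && !any(mask) &&
      (center_mm[1] < -diameter_mm || center_mm[1] > max(x_mm) + diameter_mm ||
       center_mm[2] < -diameter_mm || center_mm[2] > max(y_mm) + diameter_mm))
    stop("ROI lies fully outside the image")
  mask
}

#' Binarize an en face angiogram inside an ROI
#'
#' Computes a threshold from the ROI pixels only and zeroes everything outside
#' the ROI. The default `"otsu"` method is Otsu's threshold on the ROI
#' intensities clamped from below by a robust noise floor
#' (`median + 3 * MAD` of the ROI), which keeps avascular ROIs (where Otsu
#' would bisect the noise) essentially empty. `"fixed"` applies
#' `fixed_threshold` directly.
#'
#' @param enface Numeric X x Y en face map.
#' @param roi Logical X x Y ROI mask.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Threshold for `method = "fixed"`.
#' @param noise_floor Apply the robust noise-floor clamp under `"otsu"`
#'   (default `TRUE`).
#' @return A `vessel_mask`: logical X x Y matrix with attributes `method` and
#'   `threshold`.
#' @export
binarize <- function(enface, roi, method = c("otsu", "fixed"),
                     fixed_threshold = NULL, noise_floor = TRUE) {
  method <- match.arg(method)
  stopifnot(identical(dim(enface), dim(roi)))
  v <- enface[roi]
  if (!length(v)) stop("empty ROI")
  if (method == "otsu") {
    if (max(v) == min(v))
      stop("constant intensities inside ROI: Otsu undefined, use method = \"fixed\"")
    rng <- range(v)
    thr <- EBImage::otsu(EBImage::Image(matrix(v, ncol = 1)),
                         range = rng, levels = 256L)
    if (noise_floor)
      thr <- max(thr, stats::median(v) + 3 * stats::mad(v))
  } else {
    if (is.null(fixed_threshold)) stop("fixed_threshold required for method = \"fixed\"")
    thr <- fixed_threshold
  }
  mask <- enface > thr & roi
  structure(mask, method = method, threshold = as.numeric(thr))
}

#' Scalar vessel area density inside an ROI
#'
#' The unitless ratio of vessel pixels to total pixels of the ROI in the
#' binary vessel map.
#'
#' @param mask Logical X x Y vessel mask.
#' @param roi Logical X x Y ROI mask (non-empty).
#' @return Fraction in `[0, 1]`.
#' @export
vad_scalar <- function(mask, roi) {
  stopifnot(identical(dim(mask), dim(roi)))
  n_roi <- sum(roi)
  if (n_roi == 0) stop("empty ROI")
  sum(mask & roi) / n_roi
}

#' Block-wise vessel area density map
#'
#' Tiles the binary image with non-overlapping `kernel x kernel` blocks
#' (partial edge blocks use their actual pixel counts), computes the vessel
#' fraction per block, resizes the block grid back to the original image size
#' by bilinear interpolation, and smooths with a small Gaussian kernel.
#'
#' @param mask Logical X x Y vessel mask.
#' @param kernel Block size in pixels (default 25).
#' @param smooth Gaussian kernel size in pixels (default 3; 0 disables).
#' @param sigma Gaussian SD in pixels.
#' @return A `vad_map` list: `map` (X x Y field in `[0, 1]`), `tiles` (the
#'   block-fraction matrix), `kernel`, `sigma`.
#' @export
vad_map <- function(mask, kernel = 25L, smooth = 3L, sigma = 0.8) {
  d <- dim(mask)
  if (any(d < kernel)) stop("image smaller than kernel")
  bx <- ceiling(d[1] / kernel); by <- ceiling(d[2] / kernel)
  gx <- pmin(((seq_len(d[1]) - 1L) %/% kernel) + 1L, bx)
  gy <- pmin(((seq_len(d[2]) - 1L) %/% kernel) + 1L, by)
  fx <- factor(gx, levels = seq_len(bx)); fy <- factor(gy, levels = seq_len(by))
  sums <- rowsum(t(rowsum(mask + 0, fx)), fy)      # by x bx
  cnts <- tcrossprod(tabulate(fy, by), tabulate(fx, bx))
  tiles <- t(sums) / t(cnts)                        # bx x by
  up <- EBImage::resize(EBImage::Image(tiles), w = d[1], h = d[2])
  map <- EBImage::imageData(up)
  if (smooth > 1) {
    half <- (smooth - 1) / 2
    g1 <- stats::dnorm(seq(-half, half), sd = sigma)
    kk <- outer(g1, g1); kk <- kk / sum(kk)
    map <- EBImage::imageData(
      EBImage::filter2(EBImage::Image(map), kk, boundary = "replicate"))
  }
  map <- matrix(pmin(pmax(map, 0), 1), d[1], d[2])
  list(map = map, tiles = tiles, kernel = as.integer(kernel), sigma = sigma)
}

#' One-call wound VAD quantification of an en face angiogram
#'
#' Applies the circular wound mask, binarizes inside it, and returns the
#' scalar VAD together with the block-wise VAD map and full provenance
#' (method, threshold, ROI geometry).
#'
#' @param enface Numeric X x Y en face flow map.
#' @param center_mm ROI center `c(x, y)` in mm.
#' @param diameter_mm ROI diameter (mm, default 2).
#' @param pixel_mm Lateral pixel pitch `c(x, y)` in mm.
#' @param method,fixed_threshold Passed to [binarize()].
#' @param map Also compute the block-wise [vad_map()] (default `TRUE`).
#' @param kernel Block size for the VAD map.
#' @return List with `vad`, `threshold`, `method`, `mask`, `roi`,
#'   `vadmap` (or `NULL`), `center_mm`, `diameter_mm`.
#' @export
quantify_wound <- function(enface, center_mm, diameter_mm = 2,
                           pixel_mm = c(6.0, 6.4) / 1000,
                           method = c("otsu", "fixed"), fixed_threshold = NULL,
                           map = TRUE, kernel = 25L) {
  method <- match.arg(method)
  roi <- circular_mask(dim(enface), center_mm, diameter_mm, pixel_mm)
  mask <- binarize(enface, roi, method = method, fixed_threshold = fixed_threshold)
  vm <- if (map && all(dim(mask) >= kernel))
    vad_map(unclass(mask), kernel = kernel) else NULL
  list(vad = vad_scalar(mask, roi),
       threshold = attr(mask, "threshold"), method = attr(mask, "method"),
       mask = mask, roi = roi, vadmap = vm,
       center_mm = center_mm, diameter_mm = diameter_mm)
}
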