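#' Write / read an OCT or flow cube container
#'
#' Stores the complex (or flow) volume together with its acquisition metadata
#' and optional ground truth in a single-file container mirroring the layout
#' `complex` (or `flow`), `ground_truth$vessel_mask`, `ground_truth$surface`,
#' and optics attributes.
#'
#' @param cube An [oct_cube()], `flow_cube`, or plain array.
#' @param path Output file path.
#' @param ground_truth Optional list (e.g. `vessel_mask`, `surface`).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, ground_truth = NULL) {
  is_flow <- inherits(cube, "flow_cube")
  payload <- list(optics = attr(cube, "optics"),
                  clutter_rank = attr(cube, "clutter_rank"),
                  ground_truth = ground_truth)
  payload[[if (is_flow) "flow" else "complex"]] <-
    array(as.vector(cube), dim(cube))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  p <- readRDS(path)
  if (!is.null(p$complex)) {
    out <- if (!is.null(p$optics)) oct_cube(p$complex, p$optics) else p$complex
  } else {
    out <- structure(p$flow, optics = p$optics, clutter_rank = p$clutter_rank,
                     class = c("flow_cube", class(p$flow)))
  }
  attr(out, "ground_truth") <- p$ground_truth
  out
}

#' Export an en face map as 32-bit float TIFF (with optional PNG preview)
#'
#' The TIFF stores the raw values; the PNG preview is min-max scaled to 8 bit.
#'
#' @param map Numeric X x Y matrix.
#' @param path Output TIFF path.
#' @param png_preview Optional PNG path.
#' @return `path`, invisibly.
#' @export
write_enface_tiff <- function(map, path, png_preview = NULL) {
  tiff::writeTIFF(map, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  if (!is.null(png_preview)) {
    rng <- range(map)
    scaled <- if (diff(rng) > 0) (map - rng[1]) / diff(rng) else map * 0
    png::writePNG(scaled, png_preview)
  }
  invisible(path)
}

#' @rdname write_enface_tiff
#' @export
read_enface_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}
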