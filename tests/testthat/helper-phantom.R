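# shared fixtures: small grids keep individual tests fast; scenes that several
# tests inspect are built once and memoized here

tiny_optics <- function(repeats = 4L, noise_snr_db = 25)
  phantom_optics(64L, 32L, 32L, repeats = repeats, noise_snr_db = noise_snr_db)

small_optics <- function() phantom_optics(96L, 64L, 64L)

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a rendered control day-4 wound scene plus its measured en face flow map
small_scene <- function(group = "control", timepoint = 4, seed = 77) {
  key <- paste("scene", group, timepoint, seed, sep = "_")
  memo(key, {
    opt <- small_optics()
    sc <- phantom_scene(group, timepoint, seed = seed, optics = opt)
    fl <- flow_cube(sc$cube, with_intensity = TRUE)
    surf <- detect_surface(attr(fl, "intensity"), optics = opt)
    slab <- extract_slab(unclass(fl), surf, axial_pixel_um = opt$axial_pixel_um)
    enface <- mip(slab)
    px_mm <- c(opt$lateral_pixel_x_um, opt$lateral_pixel_y_um) / 1000
    c(sc, list(flow = fl, surface = surf, enface = enface, pixel_mm = px_mm,
               optics = opt))
  })
}

random_complex_ensemble <- function(m, n, seed = 1) {
  withr::with_seed(seed, {
    matrix(complex(real = stats::rnorm(m * n), imaginary = stats::rnorm(m * n)),
           m, n)
  })
}
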