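test_that("tissue phantom is deterministic with ordered layers", {
  opt <- tiny_optics()
  t1 <- build_tissue(opt, seed = 1)
  t2 <- build_tissue(opt, seed = 1)
  expect_identical(t1$surface_px, t2$surface_px)
  expect_identical(t1$reflectivity, t2$reflectivity)
  expect_false(identical(t1$surface_px, build_tissue(opt, seed = 2)$surface_px))
  # layer stack ordered with depth at a sample of columns
  breaks <- t1$layers$breaks_um
  expect_true(all(diff(breaks) > 0))
  ax <- opt$axial_pixel_um
  for (ix in c(1, 10, 25)) for (iy in c(3, 17, 30)) {
    s <- t1$surface_px[ix, iy]
    col <- t1$reflectivity[, ix, iy]
    expect_true(all(col[seq_len(s - 1)] == 0))      # empty above the surface
    expect_equal(col[s], t1$layers$reflectivity[1]) # scale layer at the top
    deep <- s + um_to_px(breaks[4] + 50, ax)
    expect_equal(col[min(deep, opt$depth_pixels)], t1$layers$reflectivity[5])
  }
})

test_that("flat-surface override forces constant ground truth", {
  opt <- tiny_optics()
  tis <- build_tissue(opt, seed = 1, flat_surface_px = 20)
  expect_true(all(tis$surface_px == 20L))
})

test_that("healing curve has the canonical wound-revascularization shape", {
  hp <- healing_params()
  tps <- c(0.125, 1, 4, 7, 10, 15)
  ctrl <- healing_vad_curve(tps, hp, "control")
  diab <- healing_vad_curve(tps, hp, "diabetic")
  expect_equal(healing_vad_curve(-1, hp, "control"), hp$v0)   # pre-wound
  expect_equal(healing_vad_curve(0, hp, "control"), 0)
  expect_error(healing_vad_curve(-0.5, hp), "negative")
  # maximum at day 4 and unimodal on the sampled grid, both groups
  for (v in list(ctrl, diab)) {
    expect_equal(tps[which.max(v)], 4)
    expect_true(all(diff(v[1:3]) > 0))
    expect_true(all(diff(v[3:6]) < 0))
  }
  # diabetic amplitude fraction 0.4 through day 10 -> reduction 60% > 50%
  expect_equal(diab[1:5] / ctrl[1:5], rep(0.4, 5), tolerance = 1e-12)
  expect_true(all(1 - diab[3:5] / ctrl[3:5] > 0.5))
  # convergence at day 15: below the binarization noise floor
  expect_lt(abs(ctrl[6] - diab[6]), 0.005)
})

test_that("vessel generator hits its projected-area target with exact bookkeeping", {
  opt <- tiny_optics()
  tis <- build_tissue(opt, seed = 3)
  expect_length(build_vessels(tis, 0, seed = 1)$idx, 0)
  v <- build_vessels(tis, 0.15, seed = 7)
  # brute-force recount of the generator's own projected mask
  proj <- matrix(FALSE, 32, 32)
  proj[unique(((v$idx - 1) %/% 64) + 1)] <- TRUE
  expect_identical(proj, v$proj)
  expect_gte(mean(proj), 0.12)
  expect_lte(mean(proj), 0.18)
  expect_equal(v$achieved_fraction, mean(proj))
  # determinism and positive speeds on every vessel voxel
  expect_identical(v$idx, build_vessels(tis, 0.15, seed = 7)$idx)
  expect_true(all(v$speed_mmps > 0))
  expect_identical(length(v$speed_mmps), length(v$idx))
})

test_that("vessels stay inside the hypodermis-muscle band", {
  opt <- tiny_optics()
  tis <- build_tissue(opt, seed = 3)
  v <- build_vessels(tis, 0.1, seed = 5)
  ai <- arrayInd(v$idx, c(64, 32, 32))
  rel_um <- (ai[, 1] - tis$surface_px[ai[, 2:3]]) * opt$axial_pixel_um
  # rasterization tolerance: half an axial pixel plus the maximum radius
  pad <- opt$axial_pixel_um / 2 + 15
  expect_true(all(rel_um >= tis$vessel_band_um[1] - pad))
  expect_true(all(rel_um <= tis$vessel_band_um[2] + pad))
})

test_that("wounding follows the healing time course", {
  opt <- tiny_optics()
  tis <- build_tissue(opt, seed = 11)
  ves <- build_vessels(tis, 0.05, seed = 12)
  hp <- healing_params()

  pre <- apply_wound(tis, ves, wound_model(-1), hp, "control", seed = 13)
  expect_identical(pre$tissue$reflectivity, tis$reflectivity)
  expect_identical(pre$vessels$idx, ves$idx)

  early <- apply_wound(tis, ves, wound_model(0.125), hp, "control", seed = 13)
  expect_lt(early$truth$wound_fraction, 0.02)   # avascular wound at 3 hpw

  c4 <- apply_wound(tis, ves, wound_model(4), hp, "control", seed = 13)
  d4 <- apply_wound(tis, ves, wound_model(4), hp, "diabetic", seed = 13)
  expect_equal(d4$truth$target_fraction / c4$truth$target_fraction,
               hp$diabetic_fraction, tolerance = 1e-12)
  expect_gt(d4$truth$zone_fraction / c4$truth$zone_fraction, 0.3)
  expect_lt(d4$truth$zone_fraction / c4$truth$zone_fraction, 0.5)

  far <- wound_model(4, center_mm = c(-1, 0.5))
  expect_error(apply_wound(tis, ves, far, hp, "control", seed = 1), "field of view")
})

test_that("renderer separates static and dynamic voxels exactly", {
  opt <- tiny_optics(noise_snr_db = Inf)
  tis <- build_tissue(opt, seed = 21)
  # static tissue, no noise: all repeats identical
  cube0 <- render_cube(tis, NULL, opt, seed = 22)
  for (r in 2:opt$repeats) expect_identical(cube0[, , , r], cube0[, , , 1])
  # with vessels: the varying-voxel set is exactly the vessel-voxel set
  ves <- build_vessels(tis, 0.08, seed = 23)
  cube <- render_cube(tis, ves, opt, seed = 24)
  varying <- which(apply(array(Mod(sweep(cube, c(1, 2, 3), cube[, , , 1], "-")),
                               dim(cube)), c(1, 2, 3), max) > 0)
  expect_setequal(varying, ves$idx)
  # determinism
  expect_identical(unclass(render_cube(tis, ves, opt, seed = 24)), unclass(cube))
})

test_that("fast flow decorrelates the speckle between repeats", {
  opt <- tiny_optics(repeats = 8L, noise_snr_db = Inf)
  tis <- build_tissue(opt, seed = 31)
  ves <- build_vessels(tis, 0.1, seed = 32, speed_mmps = c(1.5, 2))  # v >> v_c
  cube <- render_cube(tis, ves, opt, seed = 33, v_c_mmps = 0.3)
  idx <- ves$idx
  expect_gte(length(idx), 64)
  x <- matrix(cube, prod(dim(cube)[1:3]), dim(cube)[4])[idx, ]
  # complex inter-repeat correlation estimated over all vessel voxels
  num <- sum(x[, -1] * Conj(x[, -ncol(x)]))
  den <- sqrt(sum(Mod(x[, -1])^2) * sum(Mod(x[, -ncol(x)])^2))
  expect_lt(Mod(num / den), 0.2)
})

test_that("cohort simulation reproduces the configured study design", {
  sim <- simulate_cohort()
  tb <- sim$table
  for (tp in unique(tb$timepoint_dpw)) {
    expect_identical(sum(tb$timepoint_dpw == tp & tb$group == "control"), 9L)
    expect_identical(sum(tb$timepoint_dpw == tp & tb$group == "diabetic"), 9L)
  }
  expect_false(any(duplicated(tb[, c("fish_id", "timepoint_dpw")])))
  # glucose ordering: hyperglycemic at 4 and 8 dpi, normal range by 14 dpi
  gl <- sim$glucose
  ctrl <- gl$level[gl$group == "control"]
  ok_diab <- unique(tb$fish_id[tb$group == "diabetic" & tb$status == "ok"])
  for (d in c(4, 8)) {
    lv <- gl$level[gl$fish_id %in% ok_diab & gl$dpi == d]
    expect_true(all(lv > mean(ctrl) + 3 * stats::sd(ctrl)))
  }
  lv14 <- gl$level[gl$fish_id %in% ok_diab & gl$dpi == 14]
  expect_true(all(lv14 < mean(ctrl) + 3 * stats::sd(ctrl)))
  # determinism
  expect_identical(simulate_cohort()$table, tb)
})
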