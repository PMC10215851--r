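test_that("bulk-phase alignment removes a pure global phase exactly", {
  base <- random_complex_ensemble(50, 1, seed = 4)[, 1]
  phis <- c(0, 0.3, -0.5, 1.2)
  ens <- vapply(phis, function(p) base * exp(1i * p), complex(50))
  out <- align_bulk_phase(ens)
  for (k in 2:4) expect_lt(max(Mod(out[, k] - out[, 1])), 1e-10)
  # already-aligned input is unchanged
  aligned <- align_bulk_phase(random_complex_ensemble(200, 4, seed = 5))
  expect_equal(align_bulk_phase(aligned), aligned, tolerance = 1e-12)
})

test_that("post-alignment adjacent-pair weighted mean phase vanishes", {
  ens <- random_complex_ensemble(500, 6, seed = 6)
  out <- align_bulk_phase(ens)
  for (k in 1:5) {
    expect_lt(abs(Arg(sum(out[, k + 1] * Conj(out[, k])))), 1e-8)
  }
})

test_that("repeat-space covariance matches hand computation", {
  # identical unit-power repeats -> all-ones matrix, rank 1, trace N
  ones <- matrix(complex(real = 1), 100, 3)
  C1 <- ed_covariance(ones)
  expect_equal(C1, matrix(complex(real = 1), 3, 3))
  # single pixel x = (1, i): C = x x^H
  C2 <- ed_covariance(matrix(c(1 + 0i, 1i), 1, 2))
  expect_equal(C2, matrix(c(1 + 0i, 1i, -1i, 1 + 0i), 2, 2))
  expect_error(ed_covariance(matrix(c(NaN + 0i, 1i, 0i, 1i), 2, 2)), "non-finite")
})

test_that("covariance of i.i.d. noise converges to the identity", {
  m <- 20000
  ens <- random_complex_ensemble(m, 4, seed = 7) / sqrt(2)  # unit ensemble power
  C <- ed_covariance(ens)
  off <- C - diag(diag(C))
  expect_lt(max(Mod(off)), 3 / sqrt(m))
  expect_equal(Re(sum(diag(C))), 4, tolerance = 0.05)
})

test_that("clutter-rank selection follows the cumulative-energy rule", {
  expect_identical(select_clutter_rank(c(8, 1, 1), 0.79), 1L)
  expect_identical(select_clutter_rank(c(8, 1, 1), 0.81), 2L)
  expect_identical(select_clutter_rank(c(1, 1, 1, 1), 0.9), 3L)  # clip at N-1
  expect_identical(select_clutter_rank(c(5, 4, 3), fixed_k = 1), 1L)
  expect_identical(select_clutter_rank(c(0, 0, 0)), 1L)
  expect_error(select_clutter_rank(c(1, 2, 3)), "descending")
})

test_that("ED filter cancels static tissue and passes outlier flow", {
  # noiseless static ensemble: rank-1 in repeat space, K = 1 -> zero flow
  static <- matrix(rep(random_complex_ensemble(64, 1, seed = 8)[, 1], 4), 64, 4)
  expect_equal(max(ed_filter(static, 1)), 0, tolerance = 1e-24)
  # hand-computed 2x2 case: covariance from the flow pixel alone
  x <- matrix(c(1 + 0i, -1 + 0i), 1, 2)
  expect_equal(ed_filter(x, 1, C = ed_covariance(x))[1], 0, tolerance = 1e-24)
  # static-dominated covariance: e1 ~ (1,1)/sqrt(2), flow value of (1,-1) is 1
  pop <- rbind(matrix(rep(c(1 + 0i, 1 + 0i), each = 500), 500, 2), x)
  expect_equal(ed_filter(pop, 1, C = ed_covariance(pop))[501], 1, tolerance = 1e-6)
})

test_that("ED filter of pure noise retains (N-1)/N of the power", {
  for (n_rep in c(4, 8)) {
    ens <- random_complex_ensemble(10000, n_rep, seed = n_rep) / sqrt(2)
    f <- ed_filter(ens, 1)
    expect_equal(mean(f), (n_rep - 1) / n_rep, tolerance = 0.05)
  }
})

test_that("energy conservation and trace identity hold to 1e-6 relative", {
  for (seed in 1:5) {
    ens <- random_complex_ensemble(800, 8, seed = seed)
    C <- ed_covariance(ens)
    ev <- eigen(C, symmetric = TRUE)
    for (k in c(1, 3)) {
      flow <- ed_filter(ens, k, C = C)
      E <- ev$vectors[, seq_len(k), drop = FALSE]
      proj <- (ens %*% Conj(E)) %*% t(E)
      clutter <- rowSums(Mod(proj)^2)
      total <- rowSums(Mod(ens)^2)
      expect_equal(sum(clutter + flow * 8), sum(total), tolerance = 1e-6)
      expect_equal(mean(flow), sum(ev$values[(k + 1):8]) / 8, tolerance = 1e-6)
    }
  }
})

test_that("filter is idempotent and matches the explicit-projector oracle", {
  ens <- random_complex_ensemble(8 * 8, 4, seed = 42)
  C <- ed_covariance(ens)
  for (k in 1:3) {
    flow <- ed_filter(ens, k, C = C)
    # oracle: form P = I - E E^H explicitly and multiply per pixel
    E <- eigen(C, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
    P <- diag(4) - E %*% Conj(t(E))
    oracle <- vapply(seq_len(nrow(ens)), function(p) {
      r <- P %*% ens[p, ]
      Re(sum(Mod(r)^2)) / 4
    }, numeric(1))
    expect_equal(flow, oracle, tolerance = 1e-10)
    # filtering the residual again with the same basis changes nothing
    resid <- ens - (ens %*% Conj(E)) %*% t(E)
    expect_equal(ed_filter(resid, k, C = C), flow, tolerance = 1e-10)
  }
  expect_error(ed_filter(ens, 4), "rank")
})

test_that("flow values scale quadratically with input amplitude", {
  ens <- random_complex_ensemble(200, 4, seed = 9)
  expect_equal(ed_filter(2 * ens, 1), 4 * ed_filter(ens, 1), tolerance = 1e-10)
})

test_that("avascular noiseless phantom yields an exactly zero flow cube", {
  opt <- tiny_optics(noise_snr_db = Inf)
  tis <- build_tissue(opt, seed = 51)
  cube <- render_cube(tis, NULL, opt, seed = 52)
  fl <- flow_cube(cube)
  expect_equal(max(fl), 0, tolerance = 1e-20)
  expect_identical(attr(fl, "clutter_rank"), rep(1L, 32))
})

test_that("a straight vessel dominates the en face flow projection", {
  opt <- tiny_optics(repeats = 8L)
  tis <- build_tissue(opt, seed = 53, flat_surface_px = 6)
  Z <- opt$depth_pixels
  # hand-built vessel field: a line along x at fixed y and depth
  z0 <- 6 + um_to_px(300, opt$axial_pixel_um)
  xs <- 5:28; y0 <- 16
  idx <- as.integer(z0 + (xs - 1) * Z + (y0 - 1) * Z * 32)
  ves <- structure(list(idx = idx, speed_mmps = rep(2, length(idx)),
                        proj = {p <- matrix(FALSE, 32, 32); p[xs, y0] <- TRUE; p},
                        dims = c(Z, 32L, 32L), extra_dynamic_idx = integer(0)),
                   class = "vessel_field")
  cube <- render_cube(tis, ves, opt, seed = 54)
  fl <- flow_cube(cube)
  ef <- mip(unclass(fl))
  pk <- arrayInd(which.max(ef), dim(ef))
  expect_true(pk[1] %in% (min(xs) - 2):(max(xs) + 2))
  expect_true(abs(pk[2] - y0) <= 2)
  # detection contrast: vessel voxels >= 10x static voxels in median flow
  static <- setdiff(which(tis$reflectivity > 0), idx)
  expect_gte(stats::median(fl[idx]) / stats::median(fl[static]), 10)
})

test_that("flow cube failures carry the slow-axis position", {
  cube <- array(0i, c(4, 4, 3, 2))
  cube[1, 1, 2, 1] <- NaN + 0i
  expect_error(flow_cube(cube, align_phase = FALSE), "position 2")
})
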