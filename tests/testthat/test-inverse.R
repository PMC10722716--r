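test_that("the 10-20 montage is well formed", {
  mon <- montage_1020()
  expect_length(mon$channel_names, 19)
  expect_false(any(duplicated(mon$channel_names)))
  expect_lt(max(abs(rowSums(mon$positions^2) - 1)), 1e-9)
  # left/right homologue symmetry under x-mirroring
  expect_equal(mon$positions["C3", c("y", "z")],
               mon$positions["C4", c("y", "z")])
  expect_equal(mon$positions["C3", "x"], -mon$positions["C4", "x"])
})

test_that("spherical forward model has the right symmetries and decay", {
  mon <- montage_1020()
  # mirror-symmetric sources give mirror-symmetric scalp patterns
  sp <- point_source_space(c(30, 20, 30, -30, 20, 30))
  K <- build_forward(mon, sp)$K
  swap <- c("Fp2", "Fp1", "F4", "F3", "C4", "C3", "P4", "P3", "O2", "O1",
            "F8", "F7", "T4", "T3", "T6", "T5", "Fz", "Cz", "Pz")
  expect_lt(max(abs(K[, 1] - K[swap, 2])), 1e-12 * max(abs(K)))
  # potential magnitude decreases monotonically with depth
  mags <- vapply(c(70, 55, 40, 25, 10), function(d) {
    max(abs(build_forward(mon, point_source_space(c(0, 0, d, 30, 0, 0)))$K[, 1]))
  }, 0)
  expect_true(all(diff(mags) < 0))
  # centre source: radial direction undefined, column is zero by convention
  K0 <- build_forward(mon, point_source_space(c(0, 0, 0, 0, 0, 50)))$K
  expect_lt(max(abs(K0[, 1])), 1e-6 * max(abs(K0[, 2])))
  expect_error(build_forward(mon, point_source_space(c(0, 0, 90, 0, 0, 10))),
               "inside the brain sphere")
})

test_that("identity-weight solver equals the closed-form minimum norm", {
  ss <- tiny_source_space()
  lf <- build_forward(montage_1020(), ss)
  alpha <- 1e-3 * mean(diag(lf$K %*% t(lf$K)))
  inv <- compute_inverse(lf, regularization = alpha, weights = "identity")
  ne <- nrow(lf$K)
  H <- diag(ne) - matrix(1 / ne, ne, ne)
  M <- lf$K %*% t(lf$K) + alpha * H
  e <- eigen(M, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-12
  Minv <- e$vectors[, keep] %*% (t(e$vectors[, keep]) / e$values[keep])
  T0 <- t(lf$K) %*% Minv
  expect_lt(max(abs(inv$T - T0)), 1e-8 * max(abs(T0)))
  # inverse linearity and the zero map
  set.seed(3)
  v1 <- rnorm(ne); v2 <- rnorm(ne)
  full <- compute_inverse(lf)
  expect_lt(max(abs(apply_inverse(full, 3 * v1 + v2) -
                      (3 * apply_inverse(full, v1) + apply_inverse(full, v2)))),
            1e-8)
  expect_equal(max(abs(apply_inverse(full, rep(0, ne)))), 0)
})

test_that("weighted inverse localizes noiseless point sources exactly", {
  ss <- tiny_source_space()   # 32-voxel grid; the wider grid runs in acceptance
  lf <- build_forward(montage_1020(), ss)
  inv <- compute_inverse(lf, regularization = 0)
  expect_true(inv$converged)
  hits <- vapply(seq_len(ss$n_voxels), function(v)
    which.max(apply_inverse(inv, lf$K[, v])^2) == v, TRUE)
  expect_true(all(hits))
})

test_that("source band power integrates the PSD over the clinical bands", {
  ss <- tiny_source_space()
  lf <- build_forward(montage_1020(), ss)
  inv <- compute_inverse(lf)
  # a pure 10 Hz pattern puts > 90% of the peak voxel's power in alpha
  t <- seq(0, 20 - 1 / 500, by = 1 / 500)
  rec10 <- eeg_recording(lf$K[, 7] %*% t(50 * sin(2 * pi * 10 * t)))
  im <- band_power_source(rec10, inv)
  v <- which.max(rowSums(im$power))
  expect_gt(im$power[v, "alpha"] / sum(im$power[v, ]), 0.9)
  expect_true(all(im$power >= 0))
  expect_equal(dim(im$power), c(ss$n_voxels, 5L))
  # partition: band powers over 2-60 Hz sum to the total 2-60 Hz power
  set.seed(8)
  recw <- eeg_recording(matrix(rnorm(19 * 500 * 20), 19))
  imw <- band_power_source(recw, inv)
  total_band <- structure(data.frame(band = "all", lo_hz = 2, hi_hz = 60),
                          class = c("band_scheme", "data.frame"))
  imt <- band_power_source(recw, inv, bands = total_band)
  expect_lt(max(abs(rowSums(imw$power) - imt$power[, 1]) / imt$power[, 1]),
            0.01)
  expect_error(band_power_source(recw, inv,
                                 bands = within(band_scheme(),
                                                hi_hz[5] <- 300)),
               "Nyquist")
  short <- eeg_recording(matrix(rnorm(19 * 500 * 5), 19))
  expect_error(band_power_source(short, inv), "10 s")
})

test_that("white-noise sources have bandwidth-proportional band power", {
  ss <- tiny_source_space()
  lf <- build_forward(montage_1020(), ss)
  inv <- compute_inverse(lf)
  set.seed(12)
  rec <- eeg_recording(matrix(rnorm(19 * 500 * 300), 19))
  im <- band_power_source(rec, inv)
  bw <- c(2, 4, 5, 17, 30)
  rel <- sweep(im$power, 2, bw, "/")
  ratio <- rel / rowMeans(rel)
  expect_lt(max(abs(ratio - 1)), 0.10)
})

test_that("global field power is the spatial SD with its scaling laws", {
  expect_equal(global_field_power(matrix(5, 19, 7)), rep(0, 7))
  g <- global_field_power(matrix(rep(c(1, -1), length.out = 19), 19, 4))
  # direct oracle: root mean squared deviation from the channel mean
  x <- rep(c(1, -1), length.out = 19)
  expect_equal(g, rep(sqrt(mean((x - mean(x))^2)), 4))
  set.seed(5)
  X <- matrix(rnorm(19 * 50), 19)
  expect_equal(global_field_power(-2.5 * X), 2.5 * global_field_power(X))
  expect_error(global_field_power(matrix(1, 1, 10)), "2 channels")
})
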