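test_that("regional mean volume equals the brute-force mean", {
  ts <- list(matrix(rnorm(8 * 40), 8, 40), matrix(rnorm(8 * 40), 8, 40))
  gm <- rbind(rep(0.5, 8), c(0.2, 0.4, 0.9, 0.5, 0.5, 0.5, 0.5, 0.5))
  s <- manual_subject(ts, gm = gm)
  v <- roi_mean_volume(s, "gm")
  expect_equal(unname(v[1]), 0.5)
  expect_equal(unname(v[2]), sum(gm[2, ]) / 8)

  s2 <- tiny_subject()
  v2 <- roi_mean_volume(s2, "wm")
  brute <- apply(s2$wm_values, 1, function(x) sum(x) / length(x))
  expect_equal(v2, brute)
})

test_that("voxel ALFF matches a direct DFT oracle and band rules", {
  tr <- 2
  n <- 200
  t_sec <- (0:(n - 1)) * tr
  expect_equal(voxel_alff(rep(3.7, n), tr), 0)

  # independent direct DFT of the detrended series
  direct_alff <- function(x, tr, band = c(0.01, 0.08)) {
    n <- length(x)
    fit <- lm(x ~ seq_len(n))
    xd <- residuals(fit)
    ks <- seq_len(n %/% 2)
    amp <- vapply(ks, function(k) {
      re <- sum(xd * cos(-2 * pi * k * (0:(n - 1)) / n))
      im <- sum(xd * sin(-2 * pi * k * (0:(n - 1)) / n))
      2 * sqrt(re^2 + im^2) / n
    }, numeric(1))
    f <- ks / (n * tr)
    mean(amp[f >= band[1] & f <= band[2]])
  }
  x <- 1.4 * sin(2 * pi * 0.05 * t_sec) + 0.3 * rnorm(n)
  expect_equal(voxel_alff(x, tr), direct_alff(x, tr), tolerance = 1e-10)

  # sinusoid exactly on an in-band bin: the band mean approaches
  # a / n_band_bins (exact up to the detrending step's spectral leakage)
  x_pure <- 1.4 * sin(2 * pi * 0.05 * t_sec)
  n_band <- sum(seq_len(n %/% 2) / (n * tr) >= 0.01 &
                  seq_len(n %/% 2) / (n * tr) <= 0.08)
  expect_equal(voxel_alff(x_pure, tr), 1.4 / n_band, tolerance = 0.1)
  expect_equal(voxel_alff(x_pure, tr), direct_alff(x_pure, tr),
               tolerance = 1e-10)

  # out-of-band sinusoid contributes only leakage
  x_out <- sin(2 * pi * 0.2 * t_sec)
  expect_lt(voxel_alff(x_out, tr), 0.01 * voxel_alff(x_pure, tr))

  expect_error(voxel_alff(rnorm(16), tr), "32")
  expect_error(voxel_alff(rnorm(64), tr, band = c(0.01, 0.3)), "Nyquist")
})

test_that("regional ALFF normalization: global mean one, identical voxels give 1", {
  s <- tiny_subject()
  a <- roi_alff(s, tr = 2, band = c(0.03, 0.2))
  expect_equal(mean(a), 1, tolerance = 1e-12)  # equal voxel counts per ROI

  one <- matrix(rep(sin(2 * pi * 0.05 * (0:63) * 2), each = 8), 8, 64,
                byrow = FALSE)
  s_same <- manual_subject(list(one, one, one))
  expect_equal(unname(roi_alff(s_same, tr = 2)), rep(1, 3), tolerance = 1e-12)

  # ROI ranking matches the voxelwise direct computation
  per_roi_direct <- vapply(s$timeseries, function(ts)
    mean(apply(ts, 1, voxel_alff, tr = 2, band = c(0.03, 0.2))), numeric(1))
  expect_equal(order(a), order(per_roi_direct))
})

test_that("Kendall's W: limits, toy oracle, tie handling", {
  base <- c(0.3, 1.1, 2.4, 3.0, 4.9)
  m_same <- rbind(base, base * 2 + 1, base * 0.5)  # identical rank vectors
  expect_equal(kendall_w(m_same), 1)

  m_rev <- rbind(1:6, 6:1)
  expect_equal(kendall_w(m_rev), 0)

  toy <- rbind(c(1, 3, 2, 4), c(2, 3, 1, 4), c(1, 2, 4, 3))
  expect_equal(kendall_w(toy), kendall_oracle(toy))

  set.seed(4)
  for (i in 1:20) {
    m <- matrix(sample(1:5, 4 * 6, replace = TRUE) + rnorm(24, 0, 1e-6), 4)
    w <- kendall_w(m)
    expect_gte(w, 0); expect_lte(w, 1)
    expect_equal(w, kendall_oracle(m))
  }

  m_const <- rbind(rep(1, 4), c(1, 2, 3, 4))
  expect_error(kendall_w(m_const), "constant")
  expect_equal(kendall_w(m_const, constant = "zero"), 0)
})

test_that("ReHo: normalization, agreement with kendall_w, incoherent ROI is minimal", {
  atlas <- tiny_atlas(10L)
  s <- tiny_subject(seed = 31, atlas = atlas)
  r <- roi_reho(s, atlas)
  expect_equal(mean(r), 1, tolerance = 1e-12)

  # dual route: fast rank path equals kendall_w on every voxel of one ROI
  nbs <- braingcn:::block_neighbors(atlas)
  ts <- s$timeseries[[4]]
  w_ref <- vapply(seq_len(nrow(ts)), function(v)
    kendall_w(ts[c(v, nbs[[v]]), , drop = FALSE]), numeric(1))
  raw <- lapply(s$timeseries, function(tsr)
    vapply(seq_len(nrow(tsr)), function(v)
      kendall_w(tsr[c(v, nbs[[v]]), , drop = FALSE]), numeric(1)))
  expect_equal(unname(r),
               unname(vapply(raw, mean, numeric(1)) / mean(unlist(raw))),
               tolerance = 1e-12)
  expect_equal(raw[[4]], w_ref)

  # one ROI with independent voxel noise is the cohort minimum
  set.seed(8)
  shared <- sin(2 * pi * 0.05 * (0:39) * 2)
  coherent <- function() sweep(matrix(rnorm(8 * 40, 0, 0.3), 8, 40), 2,
                               shared, `+`)
  ts_list <- c(replicate(2, coherent(), simplify = FALSE),
               list(matrix(rnorm(8 * 40), 8, 40)),
               replicate(7, coherent(), simplify = FALSE))
  s2 <- manual_subject(ts_list)
  r2 <- roi_reho(s2, atlas)
  expect_equal(which.min(unname(r2)), 3L)

  # ReHo is invariant under a joint permutation of timepoints
  perm <- sample(40)
  s_perm <- s2
  s_perm$timeseries <- lapply(s2$timeseries, function(m) m[, perm])
  expect_equal(roi_reho(s_perm, atlas), r2, tolerance = 1e-12)
})

test_that("degree centrality: row sums, linearity, symmetry guard", {
  m <- rbind(c(0, 0.5, 0.2), c(0.5, 0, 0.1), c(0.2, 0.1, 0))
  expect_equal(degree_centrality(m), c(0.7, 0.6, 0.3))
  expect_equal(degree_centrality(matrix(0, 4, 4)), rep(0, 4))

  set.seed(2)
  m10 <- random_sym_matrix(10)
  brute <- numeric(10)
  for (i in 1:10) for (j in 1:10) if (i != j) brute[i] <- brute[i] + m10[i, j]
  expect_equal(degree_centrality(m10), brute)

  m2 <- random_sym_matrix(10)
  expect_equal(degree_centrality(2 * m10 + 3 * m2),
               2 * degree_centrality(m10) + 3 * degree_centrality(m2))

  bad <- m10; bad[1, 2] <- bad[1, 2] + 1
  expect_error(degree_centrality(bad), "symmetric")
})

test_that("node-feature assembly: column sets, order, shapes", {
  atlas <- tiny_atlas(10L)
  s <- tiny_subject(seed = 17, atlas = atlas)
  gmm <- gmm_matrix(s)
  fbm <- fbm_matrix(s)
  sm <- assemble_node_features(s, gmm = gmm, fbm = fbm, selection = "sMRI")
  expect_equal(colnames(sm), c("GMV", "WMV", "sDC"))
  fm <- assemble_node_features(s, fbm = fbm, selection = "fMRI", atlas = atlas)
  expect_equal(dim(fm), c(10L, 3L))
  expect_equal(colnames(fm), c("ReHo", "ALFF", "fDC"))
  both <- assemble_node_features(s, gmm = gmm, fbm = fbm,
                                 selection = "sMRI+fMRI", atlas = atlas)
  expect_equal(colnames(both), c("GMV", "WMV", "sDC", "ReHo", "ALFF", "fDC"))
  expect_equal(both[, 1:3], sm)
  expect_equal(both[, "sDC"], degree_centrality(gmm))
  expect_error(assemble_node_features(s, fbm = fbm, selection = "sMRI"),
               "GMM")
})
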