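test_that("KDE probability vectors: normalization, determinism, closed-form check", {
  set.seed(10)
  grid <- seq(-4, 4, length.out = 200)
  x <- rnorm(1000)
  d <- roi_value_density(x, grid)
  expect_equal(sum(d), 1, tolerance = 1e-12)
  expect_true(all(d > 0))
  expect_identical(d, roi_value_density(x, grid))

  # versus the analytic standard-normal density discretized on the grid
  x5 <- rnorm(5000)
  d5 <- roi_value_density(x5, grid)
  ref <- dnorm(grid); ref <- ref / sum(ref)
  expect_lt(sum(abs(d5 - ref)), 0.1)

  expect_error(roi_value_density(rep(1, 10), grid), "variance")
  expect_error(roi_value_density(x, rev(grid)), "increasing")
})

test_that("symmetric KL: identity, symmetry, hand-expanded toy", {
  p <- c(0.2, 0.3, 0.5)
  q <- c(0.4, 0.4, 0.2)
  expect_equal(sym_kl(p, p), 0)
  expect_equal(sym_kl(p, q), sym_kl(q, p))
  hand <- 0.7 * log(1.4) + 0.3 * log(0.6) + 0.5 * log(5 / 7) + 0.5 * log(5 / 3)
  expect_equal(sym_kl(c(0.7, 0.3), c(0.5, 0.5)), hand)
  expect_error(sym_kl(c(1, 0), c(0.5, 0.5)), "positive")
})

test_that("gray-matter similarity matrix: range, identical ROIs, separation monotonicity", {
  set.seed(3)
  v <- rnorm(8, 0, 0.1)
  offsets <- c(0, 0, 0.05, 0.1, 0.2, 0.3)
  gm <- do.call(rbind, lapply(offsets, function(o) v + o))
  ts <- replicate(6, matrix(rnorm(8 * 40), 8, 40), simplify = FALSE)
  s <- manual_subject(ts, gm = gm)
  g <- gmm_matrix(s)$values
  expect_true(isSymmetric(g))
  expect_equal(unname(diag(g)), rep(0, 6))
  expect_true(all(g[upper.tri(g)] > 0 & g[upper.tri(g)] <= 1))
  # ROIs 1 and 2 hold identical voxel multisets
  expect_equal(g[1, 2], 1)
  # similarity to ROI 1 decreases as the mean offset grows
  expect_true(all(diff(g[1, 3:6]) < 0))

  # dual route: vectorized construction equals the scalar reference path
  bw <- apply(gm, 1, stats::bw.nrd0)
  for (pair in list(c(1, 3), c(2, 6), c(4, 5))) {
    i <- pair[1]; j <- pair[2]
    b <- 3 * max(bw[i], bw[j])
    grid <- seq(min(gm[i, ], gm[j, ]) - b, max(gm[i, ], gm[j, ]) + b,
                length.out = 128)
    di <- roi_value_density(gm[i, ], grid, bw = bw[i])
    dj <- roi_value_density(gm[j, ], grid, bw = bw[j])
    expect_equal(g[i, j], exp(-sym_kl(di, dj)), tolerance = 1e-12)
  }
})

test_that("functional correlation matrix: perfect anticorrelation, null bound, oracle", {
  tt <- 40
  base <- sin(2 * pi * 0.05 * (0:(tt - 1)) * 2) + rnorm(tt, 0, 0.1)
  ts1 <- matrix(rep(base, each = 8), 8, tt) + rnorm(8 * tt, 0, 1e-8)
  ts2 <- matrix(rep(-2 * base, each = 8), 8, tt) + rnorm(8 * tt, 0, 1e-8)
  s <- manual_subject(list(ts1, ts2))
  f <- fbm_matrix(s)$values
  expect_equal(f[1, 2], 1, tolerance = 1e-6)
  expect_equal(unname(diag(f)), c(0, 0))

  set.seed(5)
  t_long <- 2000
  s_ind <- manual_subject(list(matrix(rnorm(4 * t_long), 4, t_long),
                               matrix(rnorm(4 * t_long), 4, t_long)))
  expect_lt(fbm_matrix(s_ind)$values[1, 2], 3 / sqrt(t_long))

  # 5-ROI toy versus a definitional covariance-ratio computation
  set.seed(6)
  ts5 <- replicate(5, matrix(rnorm(4 * 30), 4, 30), simplify = FALSE)
  s5 <- manual_subject(ts5)
  f5 <- fbm_matrix(s5)$values
  means <- sapply(ts5, colMeans)
  for (i in 1:4) for (j in (i + 1):5) {
    xi <- means[, i]; xj <- means[, j]
    r <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(f5[i, j], abs(r), tolerance = 1e-12)
  }

  s_const <- manual_subject(list(matrix(1, 4, 30) ,
                                 matrix(rnorm(120), 4, 30)))
  expect_error(fbm_matrix(s_const), "constant")
})

test_that("min-max off-diagonal rescaling: bounds, idempotence, affine invariance", {
  set.seed(9)
  m <- random_sym_matrix(6)
  r <- minmax_offdiag(m)
  ut <- upper.tri(r)
  expect_equal(min(r[ut]), 0)
  expect_equal(max(r[ut]), 1)
  expect_equal(unname(diag(r)), rep(0, 6))
  expect_equal(minmax_offdiag(r), r)                     # attains both bounds
  expect_equal(minmax_offdiag(3.2 * m - 1.7), r)         # affine invariance
  expect_error(minmax_offdiag(matrix(1, 3, 3) - diag(3)), "constant")
})

test_that("combined structural-functional matrix: sum of rescaled parts", {
  set.seed(12)
  a <- random_sym_matrix(4)
  b <- random_sym_matrix(4)
  cm <- gmm_fbm_matrix(a, b)$values
  expect_equal(cm, minmax_offdiag(a) + minmax_offdiag(b))
  expect_true(isSymmetric(cm))
  expect_equal(unname(diag(cm)), rep(0, 4))
  expect_true(all(cm[upper.tri(cm)] >= 0 & cm[upper.tri(cm)] <= 2))
  expect_equal(gmm_fbm_matrix(a, a)$values, 2 * minmax_offdiag(a))
  expect_error(gmm_fbm_matrix(a, random_sym_matrix(5)), "dimension")
})

test_that("proportional binarization: exact counts, ordering, invariances", {
  set.seed(14)
  m90 <- random_sym_matrix(90)
  b <- proportional_binarize(m90, 0.10)
  # k rounds half away from zero: 0.10 * 4005 = 400.5 -> 401 edges
  expect_equal(sum(b$values) / 2, 401)

  # 4-node toy with distinct weights: the 3 largest of 6 edges survive
  m4 <- matrix(0, 4, 4)
  w <- c(0.9, 0.1, 0.5, 0.8, 0.3, 0.6)
  m4[upper.tri(m4)] <- w
  m4 <- m4 + t(m4)
  b4 <- suppressWarnings(proportional_binarize(m4, 0.5))$values
  kept <- m4[upper.tri(m4)][b4[upper.tri(b4)] == 1]
  expect_equal(sort(kept), sort(w)[4:6])

  # near-complete retention
  expect_equal(sum(proportional_binarize(m4, 0.999)$values) / 2, 6)

  # scale invariance
  expect_equal(proportional_binarize(5 * m90, 0.2)$values,
               proportional_binarize(m90, 0.2)$values)

  # exact count under massive ties, and deterministic lexicographic tie-break
  m_tie <- matrix(1, 10, 10); diag(m_tie) <- 0
  bt <- suppressWarnings(proportional_binarize(m_tie, 0.3))
  expect_equal(sum(bt$values) / 2, round(0.3 * 45))
  expect_identical(bt$values,
                   suppressWarnings(proportional_binarize(m_tie, 0.3))$values)
  # lexicographically smallest pairs kept: (1,2) first
  expect_equal(bt$values[1, 2], 1)

  expect_warning(proportional_binarize(m90, 0.03), "floor")
  expect_error(proportional_binarize(m90, 1.2), "proportion")
})

test_that("connectivity floor 2 ln(N)/N and its monotonicity", {
  expect_equal(min_sparsity(90), 2 * log(90) / 90)
  expect_equal(min_sparsity(246), 2 * log(246) / 246)
  ns <- 8:300
  expect_true(all(diff(vapply(ns, min_sparsity, numeric(1))) < 0))
})
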