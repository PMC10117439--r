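#' @title Connectivity matrices: KL-similarity, correlation, and their sum
#' @description Internal constructor for the connectivity container used by
#'   all three matrix kinds (GMM, FBM, GMM-FBM) in weighted or binary form.
#' @param values N x N numeric matrix.
#' @param kind `"GMM"`, `"FBM"` or `"GMM-FBM"`.
#' @param form `"weighted"` or `"binary"`.
#' @param sparsity Retained-edge fraction (binary form only).
#' @param subject_id Label.
#' @return A `connectivity_matrix`.
#' @keywords internal
connectivity_matrix <- function(values, kind, form = "weighted",
                                sparsity = NA_real_, subject_id = NA_character_) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity matrix must be square")
  structure(list(values = values, kind = kind, form = form,
                 sparsity = sparsity, subject_id = subject_id),
            class = "connectivity_matrix")
}

connectivity_values <- function(m) {
  if (inherits(m, "connectivity_matrix")) m$values else as.matrix(m)
}

#' Discrete probability vector from a kernel density estimate
#'
#' Gaussian-kernel density estimate of a ROI's voxel values, evaluated on a
#' shared grid, floored at a small positive value and renormalized to sum to 1.
#' The floor guarantees the strictly positive aligned supports that the
#' symmetric KL divergence requires.
#'
#' @param values Numeric sample (>= 2 values, non-zero variance).
#' @param grid Strictly increasing evaluation grid.
#' @param bw Kernel bandwidth; Silverman's rule ([stats::bw.nrd0()]) if NULL.
#' @param floor Probability floor applied before renormalization.
#' @return Probability vector over `grid`, strictly positive, summing to 1.
#' @export
roi_value_density <- function(values, grid, bw = NULL, floor = 1e-12) {
  if (length(values) < 2L) stop("need at least 2 values for density estimation")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (stats::sd(values) == 0)
    stop("zero-variance values: density estimate degenerates to a point mass")
  if (is.null(bw)) bw <- stats::bw.nrd0(values)
  d <- colMeans(matrix(
    stats::dnorm(outer(values, grid, "-") / bw), length(values)
  )) / bw
  d <- pmax(d, floor)
  d / sum(d)
}

#' Symmetric Kullback–Leibler divergence
#'
#' `KL(p || q) + KL(q || p)` with `KL(p || q) = sum_i p_i log(p_i / q_i)`
#' (natural log). Zero if and only if the distributions coincide.
#'
#' @param p,q Strictly positive probability vectors of equal length.
#' @return Non-negative scalar.
#' @export
sym_kl <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (any(p <= 0) || any(q <= 0)) stop("probability vectors must be strictly positive")
  sum(p * log(p / q)) + sum(q * log(q / p))
}

#' Gray-matter similarity matrix (GMM)
#'
#' Morphological similarity network: entry (i, j) is
#' `exp(-symKL(d_i, d_j))` where `d_r` is the kernel density estimate of ROI
#' r's gray-matter voxel values. Densities for a pair are evaluated on a
#' shared grid spanning the pooled range of the two ROIs extended by three
#' bandwidths. Entries lie in (0, 1]; the diagonal is 0.
#'
#' @param subject A `subject_raw`.
#' @param n_grid Number of shared grid points per pair (default 128).
#' @return A weighted `connectivity_matrix` of kind `"GMM"`.
#' @export
gmm_matrix <- function(subject, n_grid = 128L, floor = 1e-12) {
  gm <- subject$gm_values
  n <- nrow(gm)
  v <- ncol(gm)
  bw <- vapply(seq_len(n), function(r) {
    b <- stats::bw.nrd0(gm[r, ])
    if (!is.finite(b) || b <= 0)
      stop("degenerate gray-matter density for ROI ", r)
    b
  }, numeric(1))
  rng <- t(apply(gm, 1L, range))
  inv_sqrt2pi <- 1 / sqrt(2 * pi)
  t01 <- seq(0, 1, length.out = n_grid)
  m <- matrix(0, n, n)
  # All pairs (i, j > i) are evaluated in one vectorized sweep per i: each
  # pair's shared grid spans the pooled range of the two ROIs +- 3 bandwidths,
  # and both kernel density estimates are accumulated column-per-pair. The
  # arithmetic is identical to roi_value_density()/sym_kl() applied per pair.
  for (i in seq_len(n - 1L)) {
    jj <- (i + 1L):n
    mm <- length(jj)
    pad <- 3 * pmax(bw[i], bw[jj])
    lo <- pmin(rng[i, 1], rng[jj, 1]) - pad
    hi <- pmax(rng[i, 2], rng[jj, 2]) + pad
    g <- outer(t01, hi - lo) + matrix(lo, n_grid, mm, byrow = TRUE)
    di <- matrix(0, n_grid, mm)
    for (k in seq_len(v))
      di <- di + exp(-0.5 * ((g - gm[i, k]) / bw[i])^2)
    di <- di * (inv_sqrt2pi / (v * bw[i]))
    dj <- matrix(0, n_grid, mm)
    bwj <- matrix(bw[jj], n_grid, mm, byrow = TRUE)
    for (k in seq_len(v))
      dj <- dj + exp(-0.5 * ((g - matrix(gm[jj, k], n_grid, mm,
                                         byrow = TRUE)) / bwj)^2)
    dj <- dj * (inv_sqrt2pi / v) / bwj
    di <- pmax(di, floor); di <- sweep(di, 2L, colSums(di), `/`)
    dj <- pmax(dj, floor); dj <- sweep(dj, 2L, colSums(dj), `/`)
    lr <- log(di / dj)
    skl <- colSums(di * lr) - colSums(dj * lr)
    m[i, jj] <- m[jj, i] <- exp(-skl)
  }
  dimnames(m) <- list(rownames(gm), rownames(gm))
  connectivity_matrix(m, "GMM", subject_id = subject$subject_id)
}

#' Functional correlation matrix (FBM)
#'
#' Entry (i, j) is the absolute Pearson correlation between the voxel-mean
#' time series of ROIs i and j; the diagonal is 0.
#'
#' @param subject A `subject_raw`.
#' @return A weighted `connectivity_matrix` of kind `"FBM"`.
#' @export
fbm_matrix <- function(subject) {
  means <- vapply(subject$timeseries, colMeans,
                  numeric(ncol(subject$timeseries[[1]])))
  sds <- apply(means, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant mean time series for ROI(s) ",
         paste(which(sds == 0), collapse = ", "))
  m <- abs(stats::cor(means))
  diag(m) <- 0
  connectivity_matrix(m, "FBM", subject_id = subject$subject_id)
}

#' Min–max rescale the off-diagonal entries of a connectivity matrix
#'
#' Maps the strictly-upper-triangle entries affinely onto \[0, 1\] and mirrors
#' them; the diagonal stays 0. Used to put the structural and functional
#' matrices on a common scale before summation.
#'
#' @param matrix Symmetric matrix (or `connectivity_matrix`).
#' @return Matrix of the same shape.
#' @export
minmax_offdiag <- function(matrix) {
  m <- connectivity_values(matrix)
  ut <- upper.tri(m)
  lo <- min(m[ut]); hi <- max(m[ut])
  if (hi == lo) stop("constant off-diagonal entries: min-max rescaling undefined")
  out <- (m - lo) / (hi - lo)
  out[!ut & !lower.tri(out)] <- 0
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  diag(out) <- 0
  out
}

#' Combined structural–functional matrix (GMM-FBM)
#'
#' The gray-matter similarity and functional correlation matrices are min–max
#' normalized separately and then added; entries lie in \[0, 2\].
#'
#' @param gmm,fbm Weighted `connectivity_matrix` objects of matching size for
#'   the same subject.
#' @return A weighted `connectivity_matrix` of kind `"GMM-FBM"`.
#' @export
gmm_fbm_matrix <- function(gmm, fbm) {
  a <- connectivity_values(gmm); b <- connectivity_values(fbm)
  if (!all(dim(a) == dim(b))) stop("GMM and FBM dimensions differ")
  connectivity_matrix(minmax_offdiag(a) + minmax_offdiag(b), "GMM-FBM",
                      subject_id = if (inherits(gmm, "connectivity_matrix"))
                        gmm$subject_id else NA_character_)
}

#' Proportional thresholding to a binary graph
#'
#' Retains exactly `k = round(proportion * E)` of the `E = N(N-1)/2` undirected
#' edges — those with the largest weights — and sets them to 1 (both
#' triangles), zeroing the rest. Rounding is half-away-from-zero; ties at the
#' cut are broken deterministically in favour of the lexicographically
#' smallest (i, j) pair, so the retained count is exact regardless of ties.
#' A warning (not an error) is issued when the proportion falls below the
#' Erdős–Rényi connectivity floor `2 ln(N) / N`.
#'
#' @param matrix Weighted symmetric matrix (or `connectivity_matrix`).
#' @param proportion Fraction of edges to keep, in (0, 1).
#' @return A binary `connectivity_matrix` with `sparsity = proportion`.
#' @export
proportional_binarize <- function(matrix, proportion) {
  m <- connectivity_values(matrix)
  n <- nrow(m)
  if (proportion <= 0 || proportion >= 1) stop("proportion must lie in (0, 1)")
  e <- n * (n - 1) / 2
  k <- floor(proportion * e + 0.5)   # round half away from zero (positive arg)
  if (k < 1) stop("proportion too small: no edge retained")
  if (proportion < min_sparsity(n))
    warning(sprintf(
      "proportion %.4f is below the connectivity floor 2 ln(N)/N = %.4f; the binary graph may fragment",
      proportion, min_sparsity(n)))
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[upper.tri(m)]
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(k)]
  out <- base::matrix(0, n, n, dimnames = dimnames(m))
  out[ut[keep, , drop = FALSE]] <- 1
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  connectivity_matrix(out,
                      kind = if (inherits(matrix, "connectivity_matrix"))
                        matrix$kind else NA_character_,
                      form = "binary", sparsity = proportion,
                      subject_id = if (inherits(matrix, "connectivity_matrix"))
                        matrix$subject_id else NA_character_)
}

#' Erdős–Rényi connectivity floor
#'
#' The minimum edge fraction `2 ln(N) / N` below which a random graph on N
#' nodes is not expected to stay connected; proportional thresholds are chosen
#' at or above this floor (about 10% for N = 90 and 5% for N = 246).
#'
#' @param n_rois Number of nodes (>= 2).
#' @return Fraction.
#' @export
min_sparsity <- function(n_rois) {
  if (n_rois < 2) stop("need at least 2 nodes")
  2 * log(n_rois) / n_rois
}

#' Write a connectivity matrix as a tab-delimited square table
#' @param matrix A `connectivity_matrix` or plain matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(matrix, path) {
  utils::write.table(connectivity_values(matrix), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
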