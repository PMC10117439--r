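#' Mean regional tissue volume
#'
#' The gray-matter volume (GMV) or white-matter volume (WMV) of a ROI is the
#' arithmetic mean of the tissue values of all voxels in that ROI.
#'
#' @param subject A `subject_raw`.
#' @param tissue `"gm"` or `"wm"`.
#' @return Named numeric vector, one value per ROI.
#' @export
roi_mean_volume <- function(subject, tissue = c("gm", "wm")) {
  tissue <- match.arg(tissue)
  m <- if (tissue == "gm") subject$gm_values else subject$wm_values
  if (is.null(m) || ncol(m) == 0L) stop("no ", tissue, " voxel values present")
  rowMeans(m)
}

# Remove the least-squares linear trend from a series (standard ALFF practice;
# the DC and drift components otherwise dominate the spectrum).
detrend_linear <- function(x) {
  t_idx <- seq_along(x)
  stats::lm.fit(cbind(1, t_idx), x)$residuals
}

#' Amplitude of low-frequency fluctuation of one voxel series
#'
#' The series is linearly detrended, transformed with an FFT, and the one-sided
#' amplitude spectrum `2|X_k|/n` is averaged over the frequency bins falling in
#' the closed band (default 0.01–0.08 Hz). The DC bin is always excluded.
#'
#' @param series Numeric time series (length >= 32).
#' @param tr Repetition time, seconds.
#' @param band Closed frequency band in Hz, `c(low, high)`.
#' @return Non-negative scalar.
#' @export
voxel_alff <- function(series, tr, band = c(0.01, 0.08)) {
  n <- length(series)
  if (n < 32L) stop("series too short for spectral estimation (need >= 32 points)")
  if (tr <= 0) stop("tr must be positive")
  nyquist <- 1 / (2 * tr)
  if (band[2] >= nyquist)
    stop("band upper limit must be below the Nyquist frequency ", nyquist, " Hz")
  freqs <- (seq_len(n %/% 2)) / (n * tr)   # one-sided, DC excluded
  in_band <- freqs >= band[1] & freqs <= band[2]
  if (!any(in_band)) {
    min_len <- ceiling(1 / (band[2] - band[1]) / tr)
    stop("no frequency bins in [", band[1], ", ", band[2], "] Hz; ",
         "need a series of at least ~", min_len, " points at tr = ", tr)
  }
  x <- detrend_linear(series)
  amp <- 2 * Mod(stats::fft(x))[1L + seq_len(n %/% 2)] / n
  mean(amp[in_band])
}

#' Regional ALFF, standardized by the subject's global mean
#'
#' Voxelwise ALFF is divided by the subject's global mean ALFF over all voxels
#' of all ROIs, then averaged within each ROI. The all-voxel mean of the
#' normalized voxel values is exactly 1 for every subject.
#'
#' @inheritParams voxel_alff
#' @param subject A `subject_raw`.
#' @return Named numeric vector, one value per ROI.
#' @export
roi_alff <- function(subject, tr, band = c(0.01, 0.08)) {
  n_t <- ncol(subject$timeseries[[1]])
  # vectorized equivalent of voxel_alff() applied to every voxel: shared
  # detrending design, one multivariate FFT per ROI
  if (n_t < 32L) stop("series too short for spectral estimation (need >= 32 points)")
  nyquist <- 1 / (2 * tr)
  if (band[2] >= nyquist)
    stop("band upper limit must be below the Nyquist frequency ", nyquist, " Hz")
  freqs <- seq_len(n_t %/% 2) / (n_t * tr)
  in_band <- freqs >= band[1] & freqs <= band[2]
  if (!any(in_band)) stop("no frequency bins inside the band at this length/tr")
  design <- cbind(1, seq_len(n_t))
  per_roi <- lapply(subject$timeseries, function(ts) {
    resid <- stats::lm.fit(design, t(ts))$residuals
    amp <- 2 * Mod(stats::mvfft(resid))[1L + seq_len(n_t %/% 2), , drop = FALSE] / n_t
    colMeans(amp[in_band, , drop = FALSE])
  })
  global_mean <- mean(unlist(per_roi))
  if (global_mean <= 0) stop("global mean ALFF is zero: degenerate subject")
  vapply(per_roi, function(v) mean(v / global_mean), numeric(1))
}

#' Kendall's coefficient of concordance
#'
#' Concordance of K time series of common length n:
#' `W = 12 S / (K^2 (n^3 - n))` where `R_t` is the sum over series of the
#' within-series rank at time t and `S = sum_t (R_t - mean(R))^2`. Ranks are
#' computed independently per series with average ranks for ties.
#'
#' @param series_set K x n matrix, one series per row (K >= 2, n >= 2).
#' @param constant `"error"` (default) to reject constant series, `"zero"` to
#'   return 0 when any series is constant.
#' @return Scalar in \[0, 1\].
#' @export
kendall_w <- function(series_set, constant = c("error", "zero")) {
  constant <- match.arg(constant)
  series_set <- as.matrix(series_set)
  k <- nrow(series_set)
  n <- ncol(series_set)
  if (k < 2L || n < 2L) stop("need at least 2 series of length >= 2")
  is_const <- apply(series_set, 1L, function(x) max(x) == min(x))
  if (any(is_const)) {
    if (constant == "zero") return(0)
    stop("constant series in concordance computation (rows ",
         paste(which(is_const), collapse = ", "), ")")
  }
  ranks <- t(apply(series_set, 1L, rank))
  r_t <- colSums(ranks)
  s <- sum((r_t - mean(r_t))^2)
  12 * s / (k^2 * (n^3 - n))
}

# Indices (within the ROI block) of each voxel's 26-connected neighbours,
# truncated at the block boundary. Computed once per atlas.
block_neighbors <- function(atlas) {
  coords <- atlas$voxel_coords
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  lut <- stats::setNames(seq_len(nrow(coords)), key(coords))
  lapply(seq_len(nrow(coords)), function(i) {
    nb <- sweep(atlas$neighbor_offsets, 2L, coords[i, ], `+`)
    idx <- lut[key(nb)]
    as.integer(idx[!is.na(idx)])
  })
}

#' Regional homogeneity, standardized by the subject's global mean
#'
#' Each voxel's ReHo is Kendall's W over the voxel and its 26-connected
#' neighbours within the ROI block; voxel values are divided by the subject's
#' global mean over all voxels and averaged within each ROI, as for ALFF.
#'
#' @param subject A `subject_raw`.
#' @param atlas The `atlas_phantom` that defines the voxel lattice.
#' @param constant Passed to [kendall_w()]; how constant series are handled.
#' @return Named numeric vector, one value per ROI.
#' @export
roi_reho <- function(subject, atlas, constant = c("error", "zero")) {
  constant <- match.arg(constant)
  nbs <- block_neighbors(atlas)
  per_roi <- lapply(seq_along(subject$timeseries), function(r) {
    ts <- subject$timeseries[[r]]
    n_t <- ncol(ts)
    is_const <- apply(ts, 1L, function(x) max(x) == min(x))
    # within-series ranks are shared by every neighbourhood a voxel joins,
    # so compute them once per ROI; W then follows the rank-sum formula
    # exactly as in kendall_w()
    ranks <- t(apply(ts, 1L, rank))
    vapply(seq_len(nrow(ts)), function(v) {
      rows <- c(v, nbs[[v]])
      if (any(is_const[rows])) {
        if (constant == "zero") return(0)
        stop("ReHo failed at ROI ", r, ", voxel ", v,
             ": constant series in neighbourhood", call. = FALSE)
      }
      k <- length(rows)
      r_t <- colSums(ranks[rows, , drop = FALSE])
      12 * sum((r_t - mean(r_t))^2) / (k^2 * (n_t^3 - n_t))
    }, numeric(1))
  })
  global_mean <- mean(unlist(per_roi))
  if (global_mean <= 0) stop("global mean ReHo is zero: degenerate subject")
  v <- vapply(per_roi, function(x) mean(x / global_mean), numeric(1))
  names(v) <- names(subject$timeseries)
  v
}

#' Weighted degree centrality
#'
#' The degree centrality of a ROI is the sum of its connectivity weights to all
#' other ROIs, computed on the weighted (pre-binarization) matrix. Applied to
#' the gray-matter similarity matrix it yields sDC; to the functional
#' correlation matrix, fDC.
#'
#' @param matrix Symmetric weighted connectivity matrix with zero diagonal
#'   (a `connectivity_matrix` or plain matrix).
#' @return Numeric vector of row sums.
#' @export
degree_centrality <- function(matrix) {
  m <- connectivity_values(matrix)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("connectivity matrix must be symmetric")
  diag(m) <- 0
  rowSums(m)
}

#' Assemble the per-ROI node-feature table
#'
#' Combines the six regional measures into the node-feature matrix of a brain
#' graph. Column order is fixed: structural features `(GMV, WMV, sDC)`,
#' functional features `(ReHo, ALFF, fDC)`, or their concatenation (6 columns).
#' Degree centralities are computed from the weighted (not binarized)
#' connectivity matrices.
#'
#' @param subject A `subject_raw`.
#' @param gmm Weighted gray-matter similarity matrix (for sDC).
#' @param fbm Weighted functional correlation matrix (for fDC).
#' @param selection `"sMRI"`, `"fMRI"` or `"sMRI+fMRI"`.
#' @param tr,band Spectral parameters passed to [roi_alff()].
#' @param atlas Atlas (needed for ReHo neighbourhoods).
#' @param constant ReHo handling of constant series, see [kendall_w()].
#' @return N x F numeric matrix (F = 3 or 6) with named columns.
#' @export
assemble_node_features <- function(subject, gmm = NULL, fbm = NULL,
                                   selection = c("sMRI", "fMRI", "sMRI+fMRI"),
                                   tr = 2, band = c(0.01, 0.08),
                                   atlas = NULL,
                                   constant = c("error", "zero")) {
  selection <- match.arg(selection)
  smri <- NULL
  fmri <- NULL
  if (selection %in% c("sMRI", "sMRI+fMRI")) {
    if (is.null(gmm)) stop("structural features need the weighted GMM matrix")
    smri <- cbind(GMV = roi_mean_volume(subject, "gm"),
                  WMV = roi_mean_volume(subject, "wm"),
                  sDC = degree_centrality(gmm))
  }
  if (selection %in% c("fMRI", "sMRI+fMRI")) {
    if (is.null(fbm)) stop("functional features need the weighted FBM matrix")
    if (is.null(atlas)) stop("functional features need the atlas (for ReHo)")
    fmri <- cbind(ReHo = roi_reho(subject, atlas, constant = match.arg(constant)),
                  ALFF = roi_alff(subject, tr = tr, band = band),
                  fDC = degree_centrality(fbm))
  }
  out <- switch(selection, "sMRI" = smri, "fMRI" = fmri,
                "sMRI+fMRI" = cbind(smri, fmri))
  if (anyNA(out) || any(!is.finite(out))) stop("non-finite node features")
  out
}
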