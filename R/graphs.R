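#' Enumerate the brain-graph type grid
#'
#' For each atlas size, the 3 edge kinds (GMM, FBM, GMM-FBM) crossed with the
#' 3 node-feature kinds (sMRI, fMRI, sMRI+fMRI) give 9 graph types, in the
#' fixed order GMM & sMRI, GMM & fMRI, GMM & sMRI+fMRI, FBM & sMRI, ...,
#' GMM-FBM & sMRI+fMRI. Two atlases give 18 types.
#'
#' @param atlas_ns Non-empty vector of atlas sizes (e.g. `c(90, 246)`).
#' @param sparsity Optional retained-edge fraction shared by all specs; when
#'   NULL the default is 0.05 for 246-ROI atlases and 0.10 otherwise,
#'   mirroring the Erdős–Rényi floor `2 ln(N)/N`.
#' @return A data.frame with columns `atlas_n`, `edge_kind`, `node_kind`,
#'   `sparsity` and a human-readable `label`.
#' @export
enumerate_graph_types <- function(atlas_ns, sparsity = NULL) {
  if (length(atlas_ns) == 0L) stop("atlas_ns must be non-empty")
  edge_kinds <- c("GMM", "FBM", "GMM-FBM")
  node_kinds <- c("sMRI", "fMRI", "sMRI+fMRI")
  out <- do.call(rbind, lapply(atlas_ns, function(n) {
    grid <- expand.grid(node_kind = node_kinds, edge_kind = edge_kinds,
                        stringsAsFactors = FALSE)[, c(2, 1)]
    sp <- if (is.null(sparsity)) { if (n == 246) 0.05 else 0.10 } else sparsity
    data.frame(atlas_n = n, grid, sparsity = sp,
               label = paste0("N", n, ": ", grid$edge_kind, " & ", grid$node_kind),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

graph_type_spec <- function(atlas_n, edge_kind, node_kind, sparsity) {
  stopifnot(edge_kind %in% c("GMM", "FBM", "GMM-FBM"),
            node_kind %in% c("sMRI", "fMRI", "sMRI+fMRI"),
            sparsity > 0, sparsity < 1)
  list(atlas_n = atlas_n, edge_kind = edge_kind, node_kind = node_kind,
       sparsity = sparsity)
}

#' Precompute a subject's weighted matrices and full feature table
#'
#' The expensive per-subject quantities (GMM, FBM, GMM-FBM weighted matrices
#' and all six node features) are computed once and reused across graph types
#' and sparsities.
#'
#' @param subject A `subject_raw`.
#' @param atlas The `atlas_phantom`.
#' @param tr,band Spectral parameters for ALFF.
#' @param constant ReHo handling of constant series.
#' @return A list with `gmm`, `fbm`, `gmm_fbm` (weighted matrices) and
#'   `features` (N x 6 matrix, columns GMV, WMV, sDC, ReHo, ALFF, fDC).
#' @export
subject_derived <- function(subject, atlas, tr = 2, band = c(0.01, 0.08),
                            constant = "error") {
  gmm <- gmm_matrix(subject)
  fbm <- fbm_matrix(subject)
  feats <- assemble_node_features(subject, gmm = gmm, fbm = fbm,
                                  selection = "sMRI+fMRI", tr = tr,
                                  band = band, atlas = atlas,
                                  constant = constant)
  list(gmm = gmm, fbm = fbm, gmm_fbm = gmm_fbm_matrix(gmm, fbm),
       features = feats, subject_id = subject$subject_id)
}

#' Build one brain-graph sample
#'
#' Combines a subject's binarized adjacency (edge kind and sparsity from the
#' spec) with the selected node-feature columns into the unit fed to the
#' classifier. Degree-centrality columns always come from the weighted (not
#' binarized) matrices.
#'
#' @param derived Output of [subject_derived()].
#' @param spec One row of [enumerate_graph_types()] (or an equivalent list
#'   with `edge_kind`, `node_kind`, `sparsity`).
#' @param label Class label, 0 = control, 1 = patient.
#' @return A list of class `brain_graph` with `adjacency` (binary N x N),
#'   `features` (N x F), `label`, `subject_id`, `spec`.
#' @export
build_graph <- function(derived, spec, label) {
  edge <- switch(spec$edge_kind,
                 "GMM" = derived$gmm, "FBM" = derived$fbm,
                 "GMM-FBM" = derived$gmm_fbm,
                 stop("unknown edge kind: ", spec$edge_kind))
  cols <- switch(spec$node_kind,
                 "sMRI" = c("GMV", "WMV", "sDC"),
                 "fMRI" = c("ReHo", "ALFF", "fDC"),
                 "sMRI+fMRI" = c("GMV", "WMV", "sDC", "ReHo", "ALFF", "fDC"),
                 stop("unknown node kind: ", spec$node_kind))
  adj <- proportional_binarize(edge, spec$sparsity)
  structure(list(
    adjacency = connectivity_values(adj),
    features = derived$features[, cols, drop = FALSE],
    label = as.integer(label),
    subject_id = derived$subject_id,
    spec = spec
  ), class = "brain_graph")
}

#' Build a brain-graph dataset for one graph type
#'
#' @param derived_list List of [subject_derived()] outputs, one per subject.
#' @param labels Integer labels aligned with `derived_list`.
#' @param spec Graph-type spec (row of [enumerate_graph_types()]).
#' @return List of `brain_graph` samples.
#' @export
build_graph_dataset <- function(derived_list, labels, spec) {
  stopifnot(length(derived_list) == length(labels))
  lapply(seq_along(derived_list), function(i)
    build_graph(derived_list[[i]], spec, labels[i]))
}

#' Standardize node features with train-set statistics
#'
#' Each feature column is z-scored with the mean and SD pooled over all nodes
#' of the training subjects; the identical transform is applied to every
#' subject, so no information from test subjects reaches the scaler.
#'
#' @param dataset List of `brain_graph` samples.
#' @param train_ids Indices of the training subjects within `dataset`.
#' @param scaler Optional previously fitted scaler (a list with `mean`, `sd`);
#'   when supplied it is applied as-is.
#' @return A list with `dataset` (standardized) and `scaler` (fitted, with a
#'   `fitted` flag guarding against double application).
#' @export
zscore_features <- function(dataset, train_ids, scaler = NULL) {
  if (is.null(scaler)) {
    if (length(train_ids) == 0L) stop("train set is empty")
    train_mat <- do.call(rbind, lapply(dataset[train_ids], `[[`, "features"))
    mu <- colMeans(train_mat)
    sd_ <- apply(train_mat, 2L, stats::sd)
    if (any(sd_ == 0))
      stop("zero-variance feature column(s): ",
           paste(colnames(train_mat)[sd_ == 0], collapse = ", "))
    scaler <- list(mean = mu, sd = sd_, fitted = TRUE)
  } else if (!isTRUE(scaler$fitted)) {
    stop("scaler has not been fitted")
  }
  out <- lapply(dataset, function(g) {
    g$features <- sweep(sweep(g$features, 2L, scaler$mean, `-`),
                        2L, scaler$sd, `/`)
    g
  })
  list(dataset = out, scaler = scaler)
}
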