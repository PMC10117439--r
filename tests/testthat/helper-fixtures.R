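# Small builders shared across the suite; everything is generated in code.

tiny_atlas <- function(n_rois = 10L, block = c(2L, 2L, 2L)) {
  make_atlas_phantom(n_rois, block)
}

tiny_config <- function(..., n_control = 4L, n_patient = 4L, seed = 11L,
                        n_timepoints = 40L) {
  cohort_config(n_control = n_control, n_patient = n_patient, seed = seed,
                n_timepoints = n_timepoints, ...)
}

tiny_subject <- function(seed = 5L, atlas = tiny_atlas(),
                         config = tiny_config(), group = "control") {
  simulate_subject(atlas, group, config, subject_seed = seed)
}

# A hand-assembled subject_raw: ROI voxel series given explicitly.
manual_subject <- function(ts_list, gm = NULL, wm = NULL, id = "manual") {
  v <- nrow(ts_list[[1]])
  n <- length(ts_list)
  if (is.null(gm)) gm <- matrix(stats::runif(n * v, 0.4, 0.8), n, v)
  if (is.null(wm)) wm <- matrix(stats::runif(n * v, 0.4, 0.8), n, v)
  structure(list(subject_id = id, group = "control", gm_values = gm,
                 wm_values = wm, timeseries = ts_list),
            class = "subject_raw")
}

random_sym_matrix <- function(n, zero_diag = TRUE) {
  m <- matrix(stats::runif(n * n), n)
  m <- (m + t(m)) / 2
  if (zero_diag) diag(m) <- 0
  m
}

random_graph <- function(n, f, p_edge = 0.4, label = NULL) {
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  a[ut] <- stats::rbinom(sum(ut), 1L, p_edge)
  a <- a + t(a)
  structure(list(adjacency = a,
                 features = matrix(stats::rnorm(n * f), n, f),
                 label = if (is.null(label)) sample(0:1, 1L) else label,
                 subject_id = "toy", spec = NULL),
            class = "brain_graph")
}

random_graph_dataset <- function(n_graphs, n, f, seed = 1L) {
  set.seed(seed)
  labels <- rep(0:1, length.out = n_graphs)
  lapply(seq_len(n_graphs), function(i) {
    g <- random_graph(n, f, label = labels[i])
    # weak label signal keeps optimization non-degenerate
    g$features[, 1] <- g$features[, 1] + 0.5 * labels[i]
    g
  })
}

# Independent dense evaluation of the graph-convolution propagation rule,
# written long-hand (explicit loops) as the oracle.
dense_gcn_oracle <- function(h, a, w) {
  n <- nrow(a)
  at <- a + diag(n)
  d <- rowSums(at)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    s[i, j] <- at[i, j] / sqrt(d[i] * d[j])
  z <- s %*% h %*% w
  pmax(z, 0)
}

# Brute-force TopK pooling: score, sort, slice, gate, induce subgraph.
topk_oracle <- function(h, a, p, ratio) {
  u <- p / sqrt(sum(p^2))
  y <- drop(h %*% u)
  k <- ceiling(ratio * nrow(h))
  ord <- order(-y, seq_along(y))[seq_len(k)]
  list(features = h[ord, , drop = FALSE] * tanh(y[ord]),
       adjacency = a[ord, ord, drop = FALSE], indices = ord,
       scores = y[ord])
}

# Brute-force Kendall concordance via the definitional rank sums.
kendall_oracle <- function(m) {
  k <- nrow(m); n <- ncol(m)
  ranks <- matrix(0, k, n)
  for (i in seq_len(k)) ranks[i, ] <- rank(m[i, ])
  r_t <- numeric(n)
  for (t in seq_len(n)) r_t[t] <- sum(ranks[, t])
  s <- sum((r_t - mean(r_t))^2)
  12 * s / (k^2 * (n^3 - n))
}

# Exhaustive pairwise AUC: P(score_pos > score_neg) + 0.5 P(tie).
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
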