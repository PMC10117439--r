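#' Node-selection-frequency saliency from the last pooling layer
#'
#' For every training subject one inference-mode forward pass is run with the
#' final weights; the 20 survivors of the third pooling layer with the highest
#' pooling scores (ties broken by ascending node index) are recorded, and each
#' ROI's selection frequency is accumulated. The significance score is the
#' ROI's frequency divided by the total number of selections
#' (`20 * n_train`; e.g. 300 training subjects give a denominator of 6,000).
#' Scores therefore sum to 1 and each lies in \[0, 1/20\].
#'
#' @param model A `trained_gcn`.
#' @param train_graphs List of `brain_graph` samples (the training subjects).
#' @param roi_names Optional ROI labels.
#' @param n_top Number of top-scored survivors counted per subject
#'   (default 20).
#' @return A data.frame of class `saliency_table` with columns `roi_index`,
#'   `roi_name`, `frequency`, `score`, `rank`, sorted by score descending
#'   (ties by ascending `roi_index`).
#' @export
saliency_scores <- function(model, train_graphs, roi_names = NULL,
                            n_top = 20L) {
  n <- nrow(train_graphs[[1]]$adjacency)
  counts <- integer(n)
  for (g in train_graphs) {
    fw <- forward_blocks(model$params, g$adjacency, g$features,
                         model$model_cfg)
    last <- fw$blocks[[model$model_cfg$n_blocks]]
    if (length(last$orig) < n_top)
      stop("last pooling layer retains ", length(last$orig), " < ", n_top,
           " nodes; increase pool_ratio (need ceil(N * ratio^3) >= ", n_top, ")")
    # survivors arrive in descending-score order with index tie-break;
    # re-sort defensively on (score desc, original index asc)
    ord <- order(-last$scores, last$orig)
    sel <- last$orig[ord][seq_len(n_top)]
    counts[sel] <- counts[sel] + 1L
  }
  denom <- n_top * length(train_graphs)
  if (is.null(roi_names)) roi_names <- sprintf("ROI_%03d", seq_len(n))
  tab <- data.frame(roi_index = seq_len(n), roi_name = roi_names,
                    frequency = counts, score = counts / denom,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$score, tab$roi_index), ]
  tab$rank <- seq_len(n)
  rownames(tab) <- NULL
  class(tab) <- c("saliency_table", "data.frame")
  tab
}

#' Truncate a saliency table to its top k regions
#'
#' @param table A `saliency_table`.
#' @param k Number of rows to keep (at most N); ties at the boundary are
#'   already resolved by ascending ROI index in the table's ordering.
#' @return The first `k` rows.
#' @export
top_k_table <- function(table, k) {
  if (k > nrow(table)) stop("k exceeds the number of ROIs")
  table[seq_len(k), ]
}
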