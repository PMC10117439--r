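#' Model configuration for the hierarchical GCN classifier
#'
#' Three blocks of (graph convolution -> TopK pooling -> readout), readouts
#' summed, then a fully connected head `2h -> h -> n_classes` with batch
#' normalization and dropout on the hidden layer.
#'
#' @param hidden_dim Width h of the convolution layers (default 64).
#' @param pool_ratio TopK retention ratio per pooling layer (default 0.8;
#'   `ceil(N * ratio^3)` must stay >= 20 so the last pooling layer can supply
#'   the 20 nodes the saliency analysis counts).
#' @param dropout Dropout rate on the fully connected hidden layer.
#' @param n_classes Number of classes (default 2).
#' @return A list of class `model_config`.
#' @export
model_config <- function(hidden_dim = 64L, pool_ratio = 0.8,
                         dropout = 0.5, n_classes = 2L) {
  stopifnot(hidden_dim >= 1, pool_ratio > 0, pool_ratio <= 1,
            dropout >= 0, dropout < 1, n_classes >= 2)
  structure(list(hidden_dim = as.integer(hidden_dim), pool_ratio = pool_ratio,
                 n_blocks = 3L, dropout = dropout,
                 n_classes = as.integer(n_classes)),
            class = "model_config")
}

#' Training configuration
#'
#' Defaults follow the standard protocol: Adam, cross-entropy loss, learning
#' rate 1e-4, batch size 30, dropout 0.5 (in [model_config()]), at most 1000
#' epochs with early-stopping patience 500 on the loss of an internal
#' stratified validation split (15% of the training subjects).
#'
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement tolerated before stopping).
#' @param val_fraction Fraction of the training subjects held out, stratified
#'   by class, to monitor validation loss.
#' @param seed Seed for initialization, shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 30L,
                         max_epochs = 1000L, patience = 500L,
                         val_fraction = 0.15, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 0, val_fraction > 0, val_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

# Symmetrically normalized propagation matrix D^-1/2 (A + I) D^-1/2.
norm_adj <- function(a) {
  at <- a + diag(nrow(a))
  dinv <- 1 / sqrt(rowSums(at))
  at * outer(dinv, dinv)
}

relu <- function(x) (x > 0) * x

#' Graph convolution layer
#'
#' `ReLU(D^-1/2 (A + I) D^-1/2 H W)`: self-loops are added to the binary
#' adjacency, the result is symmetrically degree-normalized, multiplied with
#' the node features and the weights, and rectified.
#'
#' @param h N x D node-feature matrix.
#' @param a N x N symmetric binary adjacency with zero diagonal.
#' @param w D x D' weight matrix.
#' @return N x D' matrix.
#' @export
graph_conv <- function(h, a, w) {
  if (ncol(h) != nrow(w)) stop("feature/weight shape mismatch")
  if (nrow(h) != nrow(a)) stop("adjacency/feature shape mismatch")
  relu(norm_adj(a) %*% h %*% w)
}

#' TopK pooling layer
#'
#' Scores every node by projecting its feature vector onto the unit-normalized
#' projection vector (`y = H p / ||p||_2`), keeps the `k = ceil(ratio * N)`
#' highest-scoring nodes in descending-score order (ties broken by ascending
#' node index), gates the retained features by `tanh(y)`, and induces the
#' subgraph adjacency.
#'
#' @param h N x D feature matrix.
#' @param a N x N adjacency.
#' @param p Length-D projection vector (non-zero).
#' @param ratio Retention ratio in (0, 1].
#' @return List with `features` (k x D), `adjacency` (k x k), `indices`
#'   (original node indices of the survivors, in descending-score order) and
#'   `scores` (their raw scores y).
#' @export
topk_pool <- function(h, a, p, ratio) {
  pn <- sqrt(sum(p^2))
  if (pn == 0) stop("projection vector must be non-zero")
  n <- nrow(h)
  k <- ceiling(ratio * n)
  y <- as.numeric(h %*% (p / pn))
  ord <- order(-y, seq_len(n))
  idx <- ord[seq_len(k)]
  list(features = h[idx, , drop = FALSE] * tanh(y[idx]),
       adjacency = a[idx, idx, drop = FALSE],
       indices = idx, scores = y[idx])
}

#' Readout layer
#'
#' Fixed-size graph summary: concatenation of the columnwise maximum and the
#' columnwise mean of the surviving node features.
#'
#' @param h k x D feature matrix with k >= 1.
#' @return Numeric vector of length 2D.
#' @export
readout <- function(h) {
  if (nrow(h) < 1L) stop("readout of an empty graph")
  c(apply(h, 2L, max), colMeans(h))
}

# Uniform fan-in initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
init_mat <- function(nr, nc) {
  lim <- 1 / sqrt(nr)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

gcn_init_params <- function(n_features, cfg) {
  h <- cfg$hidden_dim
  dims <- c(n_features, rep(h, cfg$n_blocks))
  list(
    W = lapply(seq_len(cfg$n_blocks), function(l) init_mat(dims[l], dims[l + 1])),
    p = lapply(seq_len(cfg$n_blocks), function(l) stats::runif(h, -1, 1)),
    fc1 = init_mat(2L * h, h), b1 = rep(0, h),
    gamma = rep(1, h), beta = rep(0, h),
    fc2 = init_mat(h, cfg$n_classes), b2 = rep(0, cfg$n_classes)
  )
}

# Forward pass through the three conv/pool/readout blocks of one graph.
# Returns the summed readout vector and, when keep_cache, everything the
# backward pass (or the saliency analysis) needs.
forward_blocks <- function(params, a, h0, cfg, keep_cache = FALSE) {
  n_min <- nrow(a)
  for (l in seq_len(cfg$n_blocks)) n_min <- ceiling(cfg$pool_ratio * n_min)
  if (n_min < 1L) stop("graph too small for the cumulative pooling floor")
  a_cur <- a
  h_cur <- h0
  orig <- seq_len(nrow(a))
  blocks <- vector("list", cfg$n_blocks)
  r_sum <- 0
  for (l in seq_len(cfg$n_blocks)) {
    s <- norm_adj(a_cur)
    sh <- s %*% h_cur
    z <- sh %*% params$W[[l]]
    hc <- relu(z)
    p <- params$p[[l]]
    pn <- sqrt(sum(p^2))
    if (pn == 0) stop("zero projection vector in block ", l)
    u <- p / pn
    y <- as.numeric(hc %*% u)
    k <- ceiling(cfg$pool_ratio * nrow(hc))
    ord <- order(-y, seq_len(length(y)))
    idx <- ord[seq_len(k)]
    gate <- tanh(y[idx])
    hp <- hc[idx, , drop = FALSE] * gate
    amax <- max.col(t(hp), ties.method = "first")
    r_l <- c(hp[cbind(amax, seq_len(ncol(hp)))], colMeans(hp))
    r_sum <- r_sum + r_l
    blocks[[l]] <- if (keep_cache) list(
      s = s, sh = sh, z = z, hc = hc, u = u, pn = pn, y = y,
      idx = idx, gate = gate, hp = hp, amax = amax,
      h_in = h_cur, orig = orig[idx], scores = y[idx]
    ) else list(orig = orig[idx], scores = y[idx])
    orig <- orig[idx]
    a_cur <- a_cur[idx, idx, drop = FALSE]
    h_cur <- hp
  }
  list(r = r_sum, blocks = blocks)
}

# Backward pass through the blocks of one graph given the gradient of the
# loss with respect to the summed readout vector. Accumulates into `grads`.
# The pooled features of block l feed both the readout (max/mean) and block
# l + 1, so gradients from the deeper block are added before gating.
backward_blocks <- function(params, cache, dr, cfg, grads) {
  h <- cfg$hidden_dim
  d_next <- NULL   # gradient w.r.t. this block's pooled output, from block l+1
  for (l in rev(seq_len(cfg$n_blocks))) {
    bl <- cache$blocks[[l]]
    k <- length(bl$idx)
    d_hp <- matrix(0, k, ncol(bl$hp))
    # readout: max routes to the argmax row, mean spreads uniformly
    d_hp[cbind(bl$amax, seq_len(ncol(bl$hp)))] <- dr[seq_len(h)]
    d_hp <- d_hp + matrix(dr[h + seq_len(h)] / k, k, h, byrow = TRUE)
    if (!is.null(d_next)) d_hp <- d_hp + d_next
    hc_sel <- bl$hc[bl$idx, , drop = FALSE]
    d_hc <- matrix(0, nrow(bl$hc), ncol(bl$hc))
    d_hc[bl$idx, ] <- d_hp * bl$gate
    d_y <- numeric(length(bl$y))
    d_y[bl$idx] <- rowSums(d_hp * hc_sel) * (1 - bl$gate^2)
    d_hc <- d_hc + d_y %o% bl$u
    # y = Hc (p / ||p||): gradient w.r.t. p via the normalized projection
    g <- as.numeric(crossprod(bl$hc, d_y))
    grads$p[[l]] <- grads$p[[l]] + (g - bl$u * sum(bl$u * g)) / bl$pn
    d_z <- d_hc * (bl$z > 0)
    grads$W[[l]] <- grads$W[[l]] + crossprod(bl$sh, d_z)
    # gradient w.r.t. this block's input (= previous block's pooled output)
    d_next <- if (l > 1L) bl$s %*% d_z %*% t(params$W[[l]]) else NULL
  }
  grads
}

zero_grads <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Fully connected head: 2h -> h (batch norm, ReLU, dropout) -> n_classes.
forward_head <- function(params, r_mat, cfg, training, bn_state,
                         momentum = 0.1, eps = 1e-5) {
  z1 <- sweep(r_mat %*% params$fc1, 2L, params$b1, `+`)
  if (training) {
    mu <- colMeans(z1)
    va <- colMeans(sweep(z1, 2L, mu, `-`)^2)
    bn_state$mean <- (1 - momentum) * bn_state$mean + momentum * mu
    bn_state$var <- (1 - momentum) * bn_state$var + momentum * va
  } else {
    mu <- bn_state$mean
    va <- bn_state$var
  }
  z1hat <- sweep(sweep(z1, 2L, mu, `-`), 2L, sqrt(va + eps), `/`)
  uact <- sweep(sweep(z1hat, 2L, params$gamma, `*`), 2L, params$beta, `+`)
  act <- relu(uact)
  if (training && cfg$dropout > 0) {
    mask <- matrix(stats::rbinom(length(act), 1L, 1 - cfg$dropout),
                   nrow(act)) / (1 - cfg$dropout)
    dropped <- act * mask
  } else {
    mask <- NULL
    dropped <- act
  }
  logits <- sweep(dropped %*% params$fc2, 2L, params$b2, `+`)
  list(logits = logits, bn_state = bn_state,
       cache = list(r_mat = r_mat, z1 = z1, z1hat = z1hat, uact = uact,
                    act = act, mask = mask, dropped = dropped,
                    mu = mu, va = va, eps = eps))
}

backward_head <- function(params, head_cache, d_logits, grads) {
  hc <- head_cache
  grads$fc2 <- grads$fc2 + crossprod(hc$dropped, d_logits)
  grads$b2 <- grads$b2 + colSums(d_logits)
  d_drop <- d_logits %*% t(params$fc2)
  d_act <- if (is.null(hc$mask)) d_drop else d_drop * hc$mask
  d_u <- d_act * (hc$uact > 0)
  grads$gamma <- grads$gamma + colSums(d_u * hc$z1hat)
  grads$beta <- grads$beta + colSums(d_u)
  d_z1hat <- sweep(d_u, 2L, params$gamma, `*`)
  b <- nrow(d_z1hat)
  inv_std <- 1 / sqrt(hc$va + hc$eps)
  s1 <- colSums(d_z1hat)
  s2 <- colSums(d_z1hat * hc$z1hat)
  d_z1 <- sweep(
    d_z1hat * b - matrix(s1, b, length(s1), byrow = TRUE) -
      sweep(hc$z1hat, 2L, s2, `*`),
    2L, inv_std / b, `*`)
  grads$fc1 <- grads$fc1 + crossprod(hc$r_mat, d_z1)
  grads$b1 <- grads$b1 + colSums(d_z1)
  list(grads = grads, d_r = d_z1 %*% t(params$fc1))
}

# Loss and gradients for one minibatch of graphs (training mode).
batch_loss_grads <- function(params, graphs, labels, cfg, bn_state) {
  b <- length(graphs)
  caches <- vector("list", b)
  r_mat <- matrix(0, b, 2L * cfg$hidden_dim)
  for (i in seq_len(b)) {
    fw <- forward_blocks(params, graphs[[i]]$adjacency, graphs[[i]]$features,
                         cfg, keep_cache = TRUE)
    caches[[i]] <- fw
    r_mat[i, ] <- fw$r
  }
  head <- forward_head(params, r_mat, cfg, training = TRUE, bn_state)
  probs <- softmax_rows(head$logits)
  y1 <- labels + 1L
  loss <- -mean(log(pmax(probs[cbind(seq_len(b), y1)], 1e-12)))
  d_logits <- probs
  d_logits[cbind(seq_len(b), y1)] <- d_logits[cbind(seq_len(b), y1)] - 1
  d_logits <- d_logits / b
  grads <- zero_grads(params)
  bh <- backward_head(params, head$cache, d_logits, grads)
  grads <- bh$grads
  for (i in seq_len(b))
    grads <- backward_blocks(params, caches[[i]], bh$d_r[i, ], cfg, grads)
  list(loss = loss, grads = grads, bn_state = head$bn_state)
}

# Evaluation-mode cross-entropy loss (running BN statistics, no dropout).
eval_loss <- function(params, graphs, labels, cfg, bn_state) {
  r_mat <- t(vapply(graphs, function(g)
    forward_blocks(params, g$adjacency, g$features, cfg)$r,
    numeric(2L * cfg$hidden_dim)))
  head <- forward_head(params, r_mat, cfg, training = FALSE, bn_state)
  probs <- softmax_rows(head$logits)
  y1 <- labels + 1L
  list(loss = -mean(log(pmax(probs[cbind(seq_along(graphs), y1)], 1e-12))),
       probs = probs)
}

adam_init <- function(params) {
  list(m = zero_grads(params), v = zero_grads(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  walk <- function(p, g, m, v) {
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g^2
    mhat <- m2 / (1 - beta1^state$t)
    vhat <- v2 / (1 - beta2^state$t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
  }
  upd <- function(path) {
    if (is.list(params[[path]])) {
      for (i in seq_along(params[[path]])) {
        r <- walk(params[[path]][[i]], grads[[path]][[i]],
                  state$m[[path]][[i]], state$v[[path]][[i]])
        params[[path]][[i]] <<- r$p
        state$m[[path]][[i]] <<- r$m
        state$v[[path]][[i]] <<- r$v
      }
    } else {
      r <- walk(params[[path]], grads[[path]],
                state$m[[path]], state$v[[path]])
      params[[path]] <<- r$p
      state$m[[path]] <<- r$m
      state$v[[path]] <<- r$v
    }
  }
  for (nm in names(params)) upd(nm)
  list(params = params, state = state)
}

# Stratified index sample: draws `fraction` of each class (at least 1 when the
# class has >= 2 members).
stratified_holdout <- function(labels, fraction) {
  out <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_take <- max(1L, round(fraction * length(idx)))
    if (length(idx) < 2L) n_take <- 0L
    if (n_take > 0L) out <- c(out, sample(idx, n_take))
  }
  sort(out)
}

#' Train the hierarchical GCN classifier
#'
#' Minimizes cross-entropy with Adam under the supplied training
#' configuration. A stratified internal validation subset (`val_fraction` of
#' the training subjects) monitors the evaluation-mode loss after every epoch;
#' training stops at `max_epochs` or once the validation loss has not improved
#' for `patience` epochs, and the best-validation-loss weights (with their
#' batch-normalization statistics) are returned.
#'
#' @param dataset List of `brain_graph` samples (already standardized).
#' @param train_ids Indices of the training subjects within `dataset`.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @return A list of class `trained_gcn` with `params`, `bn_state`,
#'   `model_cfg`, `train_cfg`, `log` (per-epoch train/validation losses),
#'   `best_epoch`, `val_ids`.
#' @export
train_gcn <- function(dataset, train_ids, model_cfg = model_config(),
                      train_cfg = train_config()) {
  labels <- vapply(dataset, `[[`, integer(1), "label")
  if (length(unique(labels[train_ids])) < 2L ||
      min(table(labels[train_ids])) < 2L)
    stop("need at least 2 training subjects per class")
  set.seed(train_cfg$seed)
  val_local <- stratified_holdout(labels[train_ids], train_cfg$val_fraction)
  val_ids <- train_ids[val_local]
  fit_ids <- setdiff(train_ids, val_ids)
  n_features <- ncol(dataset[[fit_ids[1]]]$features)
  cfg <- model_cfg
  params <- gcn_init_params(n_features, cfg)
  bn_state <- list(mean = rep(0, cfg$hidden_dim), var = rep(1, cfg$hidden_dim))
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, bn_state = bn_state, epoch = 0L)
  wait <- 0L
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  val_graphs <- dataset[val_ids]
  val_labels <- labels[val_ids]
  for (epoch in seq_len(train_cfg$max_epochs)) {
    ord <- sample(fit_ids)
    batch_starts <- seq(1L, length(ord), by = train_cfg$batch_size)
    ep_loss <- 0
    for (s in batch_starts) {
      ids <- ord[s:min(s + train_cfg$batch_size - 1L, length(ord))]
      bl <- batch_loss_grads(params, dataset[ids], labels[ids], cfg, bn_state)
      bn_state <- bl$bn_state
      step <- adam_step(params, bl$grads, opt, train_cfg$learning_rate)
      params <- step$params
      opt <- step$state
      ep_loss <- ep_loss + bl$loss * length(ids)
    }
    ep_loss <- ep_loss / length(fit_ids)
    vl <- eval_loss(params, val_graphs, val_labels, cfg, bn_state)$loss
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss,
                                 val_loss = vl))
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, params = params, bn_state = bn_state,
                   epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > train_cfg$patience) break
    }
  }
  structure(list(params = best$params, bn_state = best$bn_state,
                 model_cfg = cfg, train_cfg = train_cfg, log = log,
                 best_epoch = best$epoch, val_ids = val_ids,
                 n_features = n_features),
            class = "trained_gcn")
}

#' Class scores for one graph
#'
#' Deterministic inference-mode forward pass: three conv/pool/readout blocks,
#' summed readouts, fully connected head with running batch-norm statistics
#' and no dropout.
#'
#' @param model A `trained_gcn`.
#' @param graph A `brain_graph`.
#' @return Numeric vector of length `n_classes` (pre-softmax logits).
#' @export
forward <- function(model, graph) {
  r <- forward_blocks(model$params, graph$adjacency, graph$features,
                      model$model_cfg)$r
  head <- forward_head(model$params, matrix(r, 1L), model$model_cfg,
                       training = FALSE, model$bn_state)
  as.numeric(head$logits)
}

#' Predicted patient-class probabilities
#'
#' @param model A `trained_gcn`.
#' @param graphs List of `brain_graph` samples.
#' @return Numeric vector of class-1 (patient) probabilities.
#' @export
predict_proba <- function(model, graphs) {
  r_mat <- t(vapply(graphs, function(g)
    forward_blocks(model$params, g$adjacency, g$features, model$model_cfg)$r,
    numeric(2L * model$model_cfg$hidden_dim)))
  head <- forward_head(model$params, r_mat, model$model_cfg,
                       training = FALSE, model$bn_state)
  softmax_rows(head$logits)[, 2L]
}
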