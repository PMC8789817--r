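#' A labeled bank of unit embeddings for kNN readout
#'
#' @param embeddings `n_items x dim` matrix of unit row vectors.
#' @param labels per-item class ids (integer or factor).
#' @return An object of class `memory_bank`.
#' @export
memory_bank <- function(embeddings, labels) {
  embeddings <- rbind(embeddings)
  if (nrow(embeddings) == 0L) input_error("memory bank is empty")
  assert_unit_rows(embeddings, what = "bank")
  if (length(labels) != nrow(embeddings)) input_error("labels must match embeddings rows")
  levels <- sort(unique(labels))
  structure(list(embeddings = embeddings, labels = labels,
                 class_levels = levels,
                 codes = match(labels, levels),
                 n_classes = length(levels)),
            class = "memory_bank")
}

#' Readout configuration
#'
#' @param k neighbours used by the kNN readout (default 200; clamped to the
#'   bank size).
#' @param knn_temperature temperature of the exponential similarity weighting
#'   `exp(similarity / knn_temperature)` (default 0.07).
#' @param probe_epochs gradient-descent epochs of the linear probe.
#' @param probe_lr probe learning rate.
#' @return An object of class `readout_config`.
#' @export
readout_config <- function(k = 200L, knn_temperature = 0.07,
                           probe_epochs = 200L, probe_lr = 0.5) {
  if (!is_count(k)) config_error("k must be >= 1")
  if (knn_temperature <= 0) config_error("knn_temperature must be > 0")
  structure(list(k = as.integer(k), knn_temperature = knn_temperature,
                 probe_epochs = as.integer(probe_epochs), probe_lr = probe_lr),
            class = "readout_config")
}

#' Similarity-weighted k-nearest-neighbour prediction
#'
#' Finds the top-`k` bank items by cosine similarity, gives each class a score
#' equal to the sum of `exp(similarity / temperature)` over its neighbours,
#' and predicts the top-scoring class.  Score ties are broken toward the
#' lowest class index (pinned for reproducibility).
#'
#' @param query unit vector (length = bank dim).
#' @param bank a [memory_bank()].
#' @param config a [readout_config()].
#' @return List with `scores` (named by class) and `label` (the predicted
#'   class, in the bank's original label space).
#' @export
knn_predict <- function(query, bank, config = readout_config()) {
  if (!inherits(bank, "memory_bank")) input_error("bank must be a memory_bank")
  sims <- as.vector(bank$embeddings %*% query)
  k <- min(config$k, length(sims))
  nn <- order(sims, decreasing = TRUE)[seq_len(k)]
  w <- exp(sims[nn] / config$knn_temperature)
  scores <- stats::setNames(numeric(bank$n_classes), bank$class_levels)
  agg <- rowsum(w, group = bank$codes[nn])
  scores[as.integer(rownames(agg))] <- agg[, 1]
  list(scores = scores, label = bank$class_levels[which.max(scores)])
}

#' Top-1 weighted kNN accuracy
#'
#' @param queries a [memory_bank()]-like labeled set of unit embeddings.
#' @param bank the neighbour store, a [memory_bank()].
#' @param config a [readout_config()].
#' @param exclude_self when queries and bank are the same items (aligned by
#'   index), drop each query's self-match before voting.
#' @return Top-1 accuracy as a percentage in \[0, 100\].
#' @export
knn_accuracy <- function(queries, bank, config = readout_config(),
                         exclude_self = FALSE) {
  if (!inherits(queries, "memory_bank")) input_error("queries must be a memory_bank")
  if (!inherits(bank, "memory_bank")) input_error("bank must be a memory_bank")
  nq <- nrow(queries$embeddings)
  if (nq == 0L) input_error("zero queries")
  if (exclude_self && nq != nrow(bank$embeddings)) {
    input_error("exclude_self requires queries aligned with the bank")
  }
  S <- queries$embeddings %*% t(bank$embeddings)
  if (exclude_self) S[cbind(seq_len(nq), seq_len(nq))] <- -Inf
  k <- min(config$k, ncol(S) - as.integer(exclude_self))
  correct <- 0L
  for (i in seq_len(nq)) {
    sims <- S[i, ]
    nn <- order(sims, decreasing = TRUE)[seq_len(k)]
    w <- exp(sims[nn] / config$knn_temperature)
    scores <- numeric(bank$n_classes)
    agg <- rowsum(w, group = bank$codes[nn])
    scores[as.integer(rownames(agg))] <- agg[, 1]
    if (bank$class_levels[which.max(scores)] == queries$labels[i]) {
      correct <- correct + 1L
    }
  }
  100 * correct / nq
}

#' Linear evaluation protocol (softmax probe over frozen features)
#'
#' Trains a multinomial logistic classification layer over frozen features by
#' full-batch gradient descent and reports held-out top-1 accuracy.  Features
#' are standardized with training-set statistics.  With zero epochs the
#' weights stay at zero, all class scores tie, and the argmax policy (lowest
#' class index) determines the prediction.
#'
#' @param train_features,test_features `n x units` matrices (or
#'   `layer_activations`).
#' @param train_labels,test_labels class ids.
#' @param config a [readout_config()] supplying `probe_epochs` and `probe_lr`.
#' @return Held-out top-1 accuracy as a percentage.
#' @export
linear_probe <- function(train_features, train_labels, test_features,
                         test_labels, config = readout_config()) {
  Xtr <- if (inherits(train_features, "layer_activations")) train_features$matrix else as.matrix(train_features)
  Xte <- if (inherits(test_features, "layer_activations")) test_features$matrix else as.matrix(test_features)
  if (ncol(Xtr) != ncol(Xte)) input_error("train/test feature dimensions differ")
  lev <- sort(unique(c(train_labels, test_labels)))
  ytr <- as.integer(factor(train_labels, levels = lev))
  yte <- as.integer(factor(test_labels, levels = lev))
  C <- length(lev)
  if (length(unique(ytr)) < 2L) input_error("training labels cover a single class")

  mu <- colMeans(Xtr)
  sd_ <- apply(Xtr, 2, stats::sd)
  sd_[sd_ < 1e-12] <- 1
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sd_, "/")
  Xte <- sweep(sweep(Xte, 2, mu), 2, sd_, "/")

  n <- nrow(Xtr)
  W <- matrix(0, ncol(Xtr), C)
  b <- numeric(C)
  Y <- matrix(0, n, C); Y[cbind(seq_len(n), ytr)] <- 1
  for (e in seq_len(config$probe_epochs)) {
    logits <- Xtr %*% W + matrix(b, n, C, byrow = TRUE)
    logits <- logits - apply(logits, 1, max)
    P <- exp(logits); P <- P / rowSums(P)
    G <- (P - Y) / n
    W <- W - config$probe_lr * (t(Xtr) %*% G)
    b <- b - config$probe_lr * colSums(G)
  }
  logits_te <- Xte %*% W + matrix(b, nrow(Xte), C, byrow = TRUE)
  pred <- apply(logits_te, 1, which.max)   # ties -> lowest class index
  100 * mean(pred == yte)
}
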