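# Independent oracles: deliberately naive scalar-loop implementations used to
# freeze expected values for the vectorized/compiled paths.

# random unit row vectors
runit <- function(n, d) {
  m <- matrix(rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}

# scalar-loop IPCL loss: sums written element by element
oracle_ipcl_loss <- function(z, negatives, tau) {
  I <- dim(z)[1]; V <- dim(z)[2]
  total <- 0
  for (i in seq_len(I)) {
    m <- rep(0, dim(z)[3])
    for (v in seq_len(V)) m <- m + z[i, v, ]
    m <- m / V
    p <- m / sqrt(sum(m^2))
    for (v in seq_len(V)) {
      e <- z[i, v, ]
      num <- exp(sum(e * p) / tau)
      den <- num
      if (nrow(negatives) > 0) {
        for (q in seq_len(nrow(negatives))) {
          den <- den + exp(sum(e * negatives[q, ]) / tau)
        }
      }
      total <- total + (-log(num / den))
    }
  }
  total / (I * V)
}

# per-pair scalar Pearson-distance RDM
oracle_rdm <- function(responses) {
  n <- nrow(responses)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) m[i, j] <- 1 - cor(responses[i, ], responses[j, ])
  }
  m
}

# closed-form ridge refit per leave-one-out fold, with the same
# standardization contract as the package implementation
oracle_ridge_loo <- function(X, Y, lambda) {
  n <- nrow(X)
  pred <- matrix(NA_real_, n, ncol(Y))
  for (c_idx in seq_len(n)) {
    tr <- setdiff(seq_len(n), c_idx)
    Xtr <- X[tr, , drop = FALSE]
    mu <- colMeans(Xtr)
    sd_ <- apply(Xtr, 2, sd); sd_[sd_ < 1e-12] <- 1
    Xs <- sweep(sweep(Xtr, 2, mu), 2, sd_, "/")
    xc <- (X[c_idx, ] - mu) / sd_
    ybar <- colMeans(Y[tr, , drop = FALSE])
    Yc <- sweep(Y[tr, , drop = FALSE], 2, ybar)
    beta <- solve(crossprod(Xs) + lambda * diag(ncol(X)), crossprod(Xs, Yc))
    pred[c_idx, ] <- as.vector(xc %*% beta) + ybar
  }
  pred
}

# exhaustive weighted-kNN oracle: sort all similarities, sum per-class weights
oracle_knn <- function(query, bank_emb, bank_lab, k, tau) {
  sims <- as.vector(bank_emb %*% query)
  ord <- order(sims, decreasing = TRUE)[seq_len(min(k, length(sims)))]
  classes <- sort(unique(bank_lab))
  scores <- sapply(classes, function(cl) {
    sum(exp(sims[ord][bank_lab[ord] == cl] / tau))
  })
  list(scores = scores, label = classes[which.max(scores)])
}

# small standard fixtures
tiny_backbone <- function(seed = 1L, dim = 8L) {
  build_backbone(backbone_config("tiny_gn", embedding_dim = dim), seed = seed)
}

small_world <- function(n_per_class = 4L, seed = 3L, noise = 0.05) {
  generate_shape_world(shape_world_spec(
    n_classes = 4L, n_instances_per_class = n_per_class,
    background_noise_sd = noise, seed = seed))
}

aug32 <- function(...) augment_config(output_size = 32L, ...)

# feature matrices with distinct geometries, standing in for model layers
fake_layers <- function(n_cond, units = c(6L, 8L, 10L), seed = 1) {
  withr::with_seed(seed, {
    ls <- lapply(units, function(u) matrix(rnorm(n_cond * u), n_cond, u))
    names(ls) <- paste0("layer", seq_along(ls))
    ls
  })
}
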