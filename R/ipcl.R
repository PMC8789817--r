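#' Construct an embedding set
#'
#' Houses the per-view unit embeddings of a batch: an
#' `n_images x n_views x dim` array plus per-image instance ids.
#'
#' @param vectors `n_images x n_views x dim` array of unit vectors.
#' @param instance_ids per-image identifiers.
#' @return An object of class `embedding_set`.
#' @export
embedding_set <- function(vectors, instance_ids = NULL) {
  if (length(dim(vectors)) != 3L) {
    input_error("vectors must be an n_images x n_views x dim array")
  }
  flat <- matrix(vectors, dim(vectors)[1] * dim(vectors)[2], dim(vectors)[3])
  assert_unit_rows(flat)
  if (is.null(instance_ids)) instance_ids <- seq_len(dim(vectors)[1])
  structure(list(vectors = vectors, instance_ids = instance_ids),
            class = "embedding_set")
}

#' Compute the instance prototype of a set of views
#'
#' The prototype is the mean of the view embeddings, re-projected onto the
#' unit hypersphere.
#'
#' @param views `n_views x dim` matrix of unit vectors (>= 1 view).
#' @param instance_id optional identifier carried on the result.
#' @return An `instance_prototype`: list with unit `vector` and `instance_id`.
#' @export
compute_prototype <- function(views, instance_id = NULL) {
  views <- rbind(views)
  if (nrow(views) < 1L) input_error("need at least one view")
  assert_unit_rows(views, what = "view")
  m <- colMeans(views)
  nrm <- sqrt(sum(m^2))
  if (nrm < 1e-8) {
    ipcl_error("views cancel: prototype mean has (near-)zero norm",
               "ipclversa_degenerate_prototype_error")
  }
  structure(list(vector = m / nrm, instance_id = instance_id),
            class = "instance_prototype")
}

#' Create a FIFO memory queue of unit vectors
#'
#' The queue stores the most recently encountered instance prototypes and
#' serves as the negative set of the contrastive loss.  Eviction is strictly
#' oldest-first.
#'
#' @param capacity maximum number of stored vectors (default 4096).
#' @param dim embedding dimensionality (fixed on first push when `NULL`).
#' @return An object of class `memory_queue`.
#' @export
memory_queue <- function(capacity = 4096L, dim = NULL) {
  if (!is_count(capacity)) config_error("capacity must be a positive count")
  structure(list(capacity = as.integer(capacity), dim = dim,
                 buffer = NULL, current_size = 0L),
            class = "memory_queue")
}

#' Push unit vectors onto a memory queue
#'
#' Vectors are appended newest-last; when capacity is exceeded the oldest
#' entries are evicted.  One slot per image: the training loop pushes each
#' image's prototype, not its individual views.
#'
#' @param queue a [memory_queue()].
#' @param embeddings matrix of unit row vectors (or a single vector).
#' @return The updated queue.
#' @export
queue_push <- function(queue, embeddings) {
  if (!inherits(queue, "memory_queue")) input_error("queue must be a memory_queue")
  embeddings <- rbind(embeddings)
  assert_unit_rows(embeddings, what = "queued")
  if (is.null(queue$dim)) queue$dim <- ncol(embeddings)
  if (ncol(embeddings) != queue$dim) input_error("dimension mismatch on queue push")
  buf <- rbind(queue$buffer, embeddings)
  if (nrow(buf) > queue$capacity) {
    buf <- buf[(nrow(buf) - queue$capacity + 1L):nrow(buf), , drop = FALSE]
  }
  queue$buffer <- buf
  queue$current_size <- nrow(buf)
  queue
}

#' Queue contents, oldest first
#' @param queue a [memory_queue()].
#' @return A `current_size x dim` matrix (0-row matrix when empty).
#' @export
queue_vectors <- function(queue) {
  if (queue$current_size == 0L) {
    return(matrix(numeric(0), 0L, queue$dim %||% 0L))
  }
  queue$buffer
}

# Core loss/gradient. z: I x V x D array (need not be exactly unit for the
# finite-difference path); negatives: Q x D matrix (constants).  Prototypes
# are recomputed from z, so the returned gradient includes the prototype
# chain (mean + renormalization) unless stop_prototype_gradient.
ipcl_loss_core <- function(z, negatives, temperature,
                           with_grad = FALSE, stop_prototype_gradient = FALSE) {
  dz <- dim(z)
  I <- dz[1]; V <- dz[2]; D <- dz[3]
  Zm <- matrix(aperm(z, c(2, 1, 3)), I * V, D)   # rows: view-fastest
  inst <- rep(seq_len(I), each = V)
  M <- matrix(0, I, D)
  for (v in seq_len(V)) M <- M + matrix(z[, v, ], I, D)
  M <- M / V
  nrm <- sqrt(rowSums(M * M))
  if (any(nrm < 1e-8)) {
    ipcl_error("views cancel: prototype mean has (near-)zero norm",
               "ipclversa_degenerate_prototype_error")
  }
  P <- M / nrm
  pos <- rowSums(Zm * P[inst, , drop = FALSE])
  nQ <- nrow(negatives)
  if (nQ == 0L) {
    out <- list(loss = 0, prototypes = P)
    if (with_grad) out$grad <- array(0, dim = dz)
    return(out)
  }
  # all |dot| <= ~1 for unit inputs; shift logits by -1/tau for safety
  l0 <- (pos - 1) / temperature
  S <- (Zm %*% t(negatives) - 1) / temperature
  Eq <- exp(S)
  e0 <- exp(l0)
  denom <- e0 + rowSums(Eq)
  losses <- -l0 + log(denom)
  loss <- mean(losses)
  out <- list(loss = loss, prototypes = P)
  if (!with_grad) return(out)

  pi0 <- e0 / denom
  Pi <- Eq / denom                                   # (I*V) x Q
  scale <- 1 / (temperature * I * V)
  Gz <- scale * ((pi0 - 1) * P[inst, , drop = FALSE] + Pi %*% negatives)
  if (!stop_prototype_gradient) {
    # accumulate d(loss)/d(prototype) per instance, then chain through the
    # renormalized mean: dM = (Gp - P * <Gp, P>) / ||M||, dz_iv += dM_i / V
    Gp <- rowsum(scale * (pi0 - 1) * Zm, group = inst)
    dM <- (Gp - P * rowSums(Gp * P)) / nrm
    Gz <- Gz + dM[inst, , drop = FALSE] / V
  }
  grad <- aperm(array(Gz, dim = c(V, I, D)), c(2, 1, 3))
  out$grad <- grad
  out
}

#' The instance-prototype contrastive loss
#'
#' For each view `v` of instance `i` with prototype `p_i` and queue negatives
#' `q`, the per-view loss is
#' `-log( exp(v.p_i/tau) / (exp(v.p_i/tau) + sum_q exp(v.q/tau)) )`;
#' the returned loss is the mean over all views and instances.  With an empty
#' queue the positive-only ratio is 1 and the loss is exactly 0.
#'
#' @param embeddings an [embedding_set()] or an `n_images x n_views x dim`
#'   array of unit vectors.
#' @param prototypes optional list of [compute_prototype()] results or an
#'   `n_images x dim` matrix aligned with `embeddings`; recomputed from the
#'   views when `NULL`.
#' @param queue a [memory_queue()] (or a matrix of unit row negatives).
#' @param temperature softmax temperature tau > 0 (default 0.07).
#' @return Scalar loss (>= 0).
#' @export
ipcl_loss <- function(embeddings, prototypes = NULL, queue = memory_queue(),
                      temperature = 0.07) {
  if (!is.numeric(temperature) || temperature <= 0) {
    config_error("temperature must be > 0")
  }
  z <- if (inherits(embeddings, "embedding_set")) embeddings$vectors else embeddings
  if (length(dim(z)) != 3L) input_error("embeddings must be I x V x D")
  assert_unit_rows(matrix(z, dim(z)[1] * dim(z)[2], dim(z)[3]))
  negatives <- if (inherits(queue, "memory_queue")) queue_vectors(queue) else rbind(queue)
  if (nrow(negatives) > 0L) assert_unit_rows(negatives, what = "negative")
  if (!is.null(prototypes)) {
    P <- if (is.list(prototypes) && inherits(prototypes[[1]], "instance_prototype")) {
      do.call(rbind, lapply(prototypes, `[[`, "vector"))
    } else rbind(prototypes)
    if (nrow(P) != dim(z)[1]) input_error("prototypes must align with embeddings")
    assert_unit_rows(P, what = "prototype")
    I <- dim(z)[1]; V <- dim(z)[2]
    Zm <- matrix(aperm(z, c(2, 1, 3)), I * V, dim(z)[3])
    inst <- rep(seq_len(I), each = V)
    pos <- rowSums(Zm * P[inst, , drop = FALSE])
    if (nrow(negatives) == 0L) return(0)
    l0 <- (pos - 1) / temperature
    S <- (Zm %*% t(negatives) - 1) / temperature
    return(mean(-l0 + log(exp(l0) + rowSums(exp(S)))))
  }
  ipcl_loss_core(z, negatives, temperature)$loss
}

#' IPCL training configuration
#'
#' @param temperature softmax temperature tau (default 0.07, the convention of
#'   the instance-discrimination lineage this objective builds on).
#' @param n_views augmented views per image per step (default 5).
#' @param queue_capacity memory-queue capacity (default 4096 images).
#' @param batch_instances images per optimization step.
#' @param epochs passes over the dataset.
#' @param lr initial SGD learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty on conv/fc weight matrices.
#' @param lr_schedule `"cosine"` decay to zero over training, or `"constant"`.
#' @param stop_prototype_gradient ablation flag: block gradients through the
#'   prototype (it is otherwise a function of the same batch).
#' @param within_batch_negatives ablation flag: add the other instances'
#'   prototypes in the batch as extra negatives (default off; negatives are
#'   queue entries only).
#' @param seed integer seed controlling initialization, shuffling and
#'   augmentation.
#' @return An object of class `ipcl_config`.
#' @export
ipcl_config <- function(temperature = 0.07, n_views = 5L,
                        queue_capacity = 4096L, batch_instances = 32L,
                        epochs = 30L, lr = 0.03, momentum = 0.9,
                        weight_decay = 1e-4,
                        lr_schedule = c("cosine", "constant"),
                        stop_prototype_gradient = FALSE,
                        within_batch_negatives = FALSE,
                        seed = 1L) {
  if (temperature <= 0) config_error("temperature must be > 0")
  if (!is_count(n_views)) config_error("n_views must be >= 1")
  if (!is_count(queue_capacity)) config_error("queue_capacity must be >= 1")
  if (!is_count(batch_instances)) config_error("batch_instances must be >= 1")
  if (!is.numeric(epochs) || epochs < 0 || epochs != round(epochs)) {
    config_error("epochs must be a nonnegative integer")
  }
  structure(list(temperature = temperature, n_views = as.integer(n_views),
                 queue_capacity = as.integer(queue_capacity),
                 batch_instances = as.integer(batch_instances),
                 epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 weight_decay = weight_decay,
                 lr_schedule = match.arg(lr_schedule),
                 stop_prototype_gradient = isTRUE(stop_prototype_gradient),
                 within_batch_negatives = isTRUE(within_batch_negatives),
                 seed = as.integer(seed)),
            class = "ipcl_config")
}

#' Train a backbone with instance-prototype contrastive learning
#'
#' Per step: sample `n_views` augmented views per image, embed them on the
#' unit hypersphere, form instance prototypes, evaluate the contrastive loss
#' against the memory queue, take an SGD-with-momentum step, and push the
#' (detached) prototypes onto the queue.  Class labels in `dataset` are
#' ignored: the objective is fully self-supervised.
#'
#' @param dataset a `labeled_image_set` (labels unused).
#' @param backbone_cfg a [backbone_config()].
#' @param config an [ipcl_config()].
#' @param augment_cfg an [augment_config()]; its `output_size` must match the
#'   backbone `input_size` and `n_views` is taken from `config`.
#' @return List of class `ipcl_trained` with elements `model`, `history`
#'   (data.frame: step, epoch, loss, queue_size), `config`, `augment_cfg`.
#' @export
train_ipcl <- function(dataset, backbone_cfg, config = ipcl_config(),
                       augment_cfg = augment_config(output_size = backbone_cfg$input_size)) {
  if (!inherits(dataset, "labeled_image_set")) input_error("dataset must be a labeled_image_set")
  n <- length(dataset$images)
  if (n == 0L) input_error("dataset is empty")
  if (augment_cfg$output_size != backbone_cfg$input_size) {
    config_error("augment output_size must equal backbone input_size")
  }
  augment_cfg$n_views <- config$n_views

  with_seed(config$seed, {
    model <- build_backbone(backbone_cfg)
    queue <- memory_queue(config$queue_capacity)
    velocity <- lapply(model$params, function(p) p * 0)
    history <- list()
    step <- 0L
    n_steps_total <- max(1L, config$epochs * ceiling(n / config$batch_instances))
    V <- config$n_views

    for (epoch in seq_len(config$epochs)) {
      order <- sample.int(n)
      batches <- split(order, ceiling(seq_along(order) / config$batch_instances))
      for (batch in batches) {
        step <- step + 1L
        lr_t <- if (config$lr_schedule == "cosine") {
          config$lr * 0.5 * (1 + cos(pi * (step - 1) / n_steps_total))
        } else config$lr
        I <- length(batch)
        views <- vector("list", I * V)
        for (i in seq_along(batch)) {
          vb <- sample_views(dataset$images[[batch[i]]], augment_cfg)
          for (v in seq_len(V)) views[[(i - 1L) * V + v]] <- vb$views[[v]]
        }
        x <- stack_views(views)
        fw <- forward_backbone(model, x, train = TRUE)
        Zm <- t(fw$out)                               # (I*V) x D, view-fastest
        z <- aperm(array(Zm, dim = c(V, I, ncol(Zm))), c(2, 1, 3))
        negatives <- queue_vectors(queue)
        res <- ipcl_loss_core(z, negatives, config$temperature,
                              with_grad = TRUE,
                              stop_prototype_gradient = config$stop_prototype_gradient)
        if (config$within_batch_negatives && I > 1L) {
          # add other prototypes as negatives (loss/grad recomputed)
          res <- ipcl_loss_core(z, rbind(negatives, res$prototypes),
                                config$temperature, with_grad = TRUE,
                                stop_prototype_gradient = config$stop_prototype_gradient)
        }
        if (!is.finite(res$loss)) {
          ipcl_error(sprintf("non-finite loss at step %d", step),
                     "ipclversa_training_error")
        }
        Gm <- matrix(aperm(res$grad, c(2, 1, 3)), I * V, dim(res$grad)[3])
        grads <- backward_backbone(model, fw$caches, t(Gm))
        for (nm in names(grads)) {
          g <- grads[[nm]]
          if (config$weight_decay > 0 && grepl("\\.W$", nm)) {
            g <- g + config$weight_decay * model$params[[nm]]
          }
          velocity[[nm]] <- config$momentum * velocity[[nm]] + g
          model$params[[nm]] <- model$params[[nm]] - lr_t * velocity[[nm]]
        }
        queue <- queue_push(queue, res$prototypes)
        history[[step]] <- data.frame(step = step, epoch = epoch,
                                      loss = res$loss,
                                      queue_size = queue$current_size)
      }
    }
    history <- if (length(history)) do.call(rbind, history) else {
      data.frame(step = integer(0), epoch = integer(0), loss = numeric(0),
                 queue_size = integer(0))
    }
    structure(list(model = model, history = history, config = config,
                   augment_cfg = augment_cfg, queue = queue),
              class = "ipcl_trained")
  })
}

#' Embed every image of a set through its deterministic evaluation view
#'
#' @param model a `backbone_model` with an embedding head.
#' @param set a `labeled_image_set`.
#' @param augment_cfg augmentation config supplying resize/normalization.
#' @return An `n_images x dim` matrix of unit embeddings.
#' @export
embed_image_set <- function(model, set, augment_cfg) {
  views <- lapply(set$images, eval_view, config = augment_cfg)
  forward_embed(model, views)
}
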