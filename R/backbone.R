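#' Backbone configuration
#'
#' Two convolutional encoders sharing one layer-naming and extraction
#' contract: `alexnet_gn`, an AlexNet with group normalization after every
#' convolutional and fully-connected layer (32 groups by default), and
#' `tiny_gn`, a three-conv-block + two-fc encoder sized for desk-scale
#' training and testing.  Both project to an embedding that is L2-normed onto
#' the unit hypersphere; setting `classifier_classes` replaces the L2-normed
#' embedding head with a plain classification layer (the category-supervised
#' comparand).
#'
#' @param architecture `"alexnet_gn"` or `"tiny_gn"`.
#' @param norm_groups number of GroupNorm groups; default 32 for `alexnet_gn`
#'   and 4 for `tiny_gn`.  Must divide every normalized layer's channel count.
#' @param embedding_dim embedding dimensionality (default 128).
#' @param l2_norm_output project the embedding onto the unit hypersphere
#'   (default `TRUE`; ignored when `classifier_classes` is set).
#' @param classifier_classes optional count; when set, the head is a
#'   `classifier_classes`-way linear layer with no L2 norm.
#' @param input_size input image side; default 224 for `alexnet_gn`, 32 for
#'   `tiny_gn`.
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(architecture = c("tiny_gn", "alexnet_gn"),
                            norm_groups = NULL,
                            embedding_dim = 128L,
                            l2_norm_output = TRUE,
                            classifier_classes = NULL,
                            input_size = NULL) {
  architecture <- match.arg(architecture)
  if (is.null(norm_groups)) {
    norm_groups <- if (architecture == "alexnet_gn") 32L else 4L
  }
  if (is.null(input_size)) {
    input_size <- if (architecture == "alexnet_gn") 224L else 32L
  }
  if (!is_count(norm_groups)) config_error("norm_groups must be a positive count")
  if (!is_count(embedding_dim, 2L)) config_error("embedding_dim must be >= 2")
  if (!is.null(classifier_classes) && !is_count(classifier_classes, 2L)) {
    config_error("classifier_classes must be a count >= 2")
  }
  structure(list(architecture = architecture,
                 norm_groups = as.integer(norm_groups),
                 embedding_dim = as.integer(embedding_dim),
                 l2_norm_output = isTRUE(l2_norm_output),
                 classifier_classes = classifier_classes,
                 input_size = as.integer(input_size)),
            class = "backbone_config")
}

# Architecture plans: conv blocks are (out_ch, k, stride, pad, pool_k,
# pool_stride) with pool_k = 0 meaning no pooling; fc blocks are widths.
backbone_plan <- function(config) {
  if (config$architecture == "tiny_gn") {
    list(conv = list(conv1 = c(16L, 3L, 1L, 1L, 2L, 2L),
                     conv2 = c(32L, 3L, 1L, 1L, 2L, 2L),
                     conv3 = c(64L, 3L, 1L, 1L, 2L, 2L)),
         fc = c(fc4 = 128L))
  } else {
    list(conv = list(conv1 = c(96L, 11L, 4L, 2L, 3L, 2L),
                     conv2 = c(256L, 5L, 1L, 2L, 3L, 2L),
                     conv3 = c(384L, 3L, 1L, 1L, 0L, 0L),
                     conv4 = c(384L, 3L, 1L, 1L, 0L, 0L),
                     conv5 = c(256L, 3L, 1L, 1L, 3L, 2L)),
         fc = c(fc6 = 4096L, fc7 = 4096L))
  }
}

#' Build a backbone model
#'
#' Precomputes all layer geometry (im2col gather indices and their sparse
#' scatter counterparts) for the configured input size and initializes
#' parameters (He-normal weights, unit GroupNorm gains).
#'
#' @param config a [backbone_config()].
#' @param seed optional integer seed for the parameter initialization.
#' @return An object of class `backbone_model` with elements `config`,
#'   `layers`, `params`, `layer_names` (the valid extraction taps), and
#'   `head_name`.
#' @export
build_backbone <- function(config, seed = NULL) {
  if (!inherits(config, "backbone_config")) config_error("config must be a backbone_config")
  plan <- backbone_plan(config)
  widths <- c(vapply(plan$conv, function(p) p[1], integer(1)), plan$fc)
  bad <- widths[widths %% config$norm_groups != 0L]
  if (length(bad)) {
    config_error(sprintf(
      "norm_groups = %d does not divide channel counts: %s",
      config$norm_groups, paste(bad, collapse = ", ")))
  }

  layers <- list()
  params <- list()
  H <- config$input_size; W <- config$input_size; C <- 3L

  with_seed(seed, {
    add_param <- function(name, value) params[[name]] <<- value
    for (nm in names(plan$conv)) {
      p <- plan$conv[[nm]]
      out_ch <- p[1]; k <- p[2]; stride <- p[3]; pad <- p[4]
      hw <- conv_out_hw(H, W, k, stride, pad)
      fan_in <- k * k * C
      add_param(paste0(nm, ".W"),
                matrix(stats::rnorm(fan_in * out_ch, 0, sqrt(2 / fan_in)),
                       fan_in, out_ch))
      add_param(paste0(nm, ".b"), numeric(out_ch))
      add_param(paste0(nm, ".gamma"), rep(1, out_ch))
      add_param(paste0(nm, ".beta"), numeric(out_ch))
      layers[[length(layers) + 1L]] <- list(
        kind = "conv", name = nm, W = paste0(nm, ".W"), b = paste0(nm, ".b"),
        in_ch = C, out_ch = out_ch, k = k, stride = stride, pad = pad,
        inH = H, inW = W, outH = hw[1], outW = hw[2])
      H <- hw[1]; W <- hw[2]; C <- out_ch
      layers[[length(layers) + 1L]] <- list(
        kind = "gn", groups = config$norm_groups,
        gamma = paste0(nm, ".gamma"), beta = paste0(nm, ".beta"), owner = nm)
      layers[[length(layers) + 1L]] <- list(kind = "relu", owner = nm)
      if (p[5] > 0L) {
        phw <- conv_out_hw(H, W, p[5], p[6], 0L)
        layers[[length(layers) + 1L]] <- list(
          kind = "pool", k = p[5], stride = p[6], inH = H, inW = W, owner = nm)
        H <- phw[1]; W <- phw[2]
      }
      layers[[length(layers)]]$tap <- nm   # block output (post relu/pool)
    }
    layers[[length(layers) + 1L]] <- list(kind = "flatten")
    width <- H * W * C
    for (nm in names(plan$fc)) {
      out_w <- plan$fc[[nm]]
      add_param(paste0(nm, ".W"),
                matrix(stats::rnorm(width * out_w, 0, sqrt(2 / width)),
                       width, out_w))
      add_param(paste0(nm, ".b"), numeric(out_w))
      add_param(paste0(nm, ".gamma"), rep(1, out_w))
      add_param(paste0(nm, ".beta"), numeric(out_w))
      layers[[length(layers) + 1L]] <- list(
        kind = "fc", name = nm, W = paste0(nm, ".W"), b = paste0(nm, ".b"))
      layers[[length(layers) + 1L]] <- list(
        kind = "gn", groups = config$norm_groups,
        gamma = paste0(nm, ".gamma"), beta = paste0(nm, ".beta"), owner = nm)
      layers[[length(layers) + 1L]] <- list(kind = "relu", owner = nm, tap = nm)
      width <- out_w
    }
    head_dim <- if (!is.null(config$classifier_classes)) {
      as.integer(config$classifier_classes)
    } else config$embedding_dim
    head_name <- if (!is.null(config$classifier_classes)) "logits" else "embed"
    add_param("head.W", matrix(stats::rnorm(width * head_dim, 0, sqrt(2 / width)),
                               width, head_dim))
    add_param("head.b", numeric(head_dim))
    layers[[length(layers) + 1L]] <- list(
      kind = "fc", name = "head", W = "head.W", b = "head.b")
    if (is.null(config$classifier_classes) && config$l2_norm_output) {
      layers[[length(layers) + 1L]] <- list(kind = "l2norm")
    }
    layers[[length(layers)]]$tap <- head_name

    structure(list(
      config = config,
      layers = layers,
      params = params,
      layer_names = c(names(plan$conv), names(plan$fc), head_name),
      head_name = head_name
    ), class = "backbone_model")
  })
}

# Single forward pass.  x: (H, W, 3, N) array of preprocessed views.
# Returns out plus (optionally) per-tap activations and backward caches.
forward_backbone <- function(model, x, train = FALSE, taps = NULL) {
  cur <- x
  caches <- if (train) vector("list", length(model$layers)) else NULL
  acts <- if (!is.null(taps)) stats::setNames(vector("list", length(taps)), taps) else NULL
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    res <- switch(ly$kind,
      conv = conv_forward(cur, ly, model$params),
      gn = gn_forward(cur, ly, model$params),
      relu = relu_forward(cur),
      pool = pool_forward(cur, ly),
      flatten = flatten_forward(cur),
      fc = fc_forward(cur, ly, model$params),
      l2norm = l2norm_forward(cur))
    cur <- res$out
    if (train) caches[[i]] <- res$cache
    if (!is.null(ly$tap) && !is.null(acts) && ly$tap %in% taps) {
      if (anyNA(cur) || any(!is.finite(cur))) {
        numeric_error(sprintf("non-finite activations at layer '%s'", ly$tap))
      }
      acts[[ly$tap]] <- cur
    }
  }
  list(out = cur, caches = caches, acts = acts)
}

# Backward pass from d(loss)/d(output); returns gradient list keyed like params.
backward_backbone <- function(model, caches, dout) {
  grads <- list()
  cur <- dout
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    if (ly$kind %in% c("conv", "gn", "fc")) {
      res <- switch(ly$kind,
        conv = conv_backward(cur, ly, model$params, caches[[i]]),
        gn = gn_backward(cur, ly, model$params, caches[[i]]),
        fc = fc_backward(cur, ly, model$params, caches[[i]]))
      cur <- res$dx
      for (nm in names(res$grads)) grads[[nm]] <- res$grads[[nm]]
    } else {
      cur <- switch(ly$kind,
        relu = relu_backward(cur, caches[[i]]),
        pool = pool_backward(cur, ly, caches[[i]]),
        flatten = flatten_backward(cur, caches[[i]]),
        l2norm = l2norm_backward(cur, caches[[i]]))
    }
  }
  grads
}

# Stack a list of H x W x 3 arrays (or pass through a 4-d array) to (H,W,3,N).
stack_views <- function(views) {
  if (is.array(views) && length(dim(views)) == 4L) return(views)
  if (inherits(views, "view_batch")) views <- views$views
  if (!is.list(views) || length(views) == 0L) input_error("no views to stack")
  d <- dim(views[[1]])
  out <- array(0, dim = c(d[1], d[2], d[3], length(views)))
  for (i in seq_along(views)) out[, , , i] <- views[[i]]
  out
}

#' Embed preprocessed views on the unit hypersphere
#'
#' @param model a [build_backbone()] model built with `l2_norm_output`.
#' @param views a `view_batch`, a list of preprocessed `H x W x 3` arrays, or
#'   an `(H, W, 3, N)` array.
#' @return An `N x embedding_dim` matrix whose rows have Euclidean norm
#'   1 (to within 1e-5).
#' @export
forward_embed <- function(model, views) {
  if (!inherits(model, "backbone_model")) input_error("model must be a backbone_model")
  if (model$head_name != "embed") {
    config_error("forward_embed requires a model built with an L2-normed embedding head")
  }
  x <- stack_views(views)
  out <- forward_backbone(model, x)$out
  if (any(!is.finite(out))) numeric_error("non-finite activations at layer 'embed'")
  t(out)
}

#' Extract flattened layer activations
#'
#' Convolutional feature maps are flattened over channel and space (channel-
#' major, spatial row-major) into a conditions x units matrix; fully-connected
#' layers yield their width.  Extraction is purely observational.
#'
#' @param model a [build_backbone()] model.
#' @param images list of preprocessed `input_size x input_size x 3` arrays (or
#'   a 4-d array), one per condition, in condition order.
#' @param layer_names which taps to extract; see `model$layer_names`.
#' @param chunk_size images per forward pass.
#' @return A named list of `layer_activations` objects: each has
#'   `layer_name`, `matrix` (conditions x units), `unit_count`.
#' @export
extract_activations <- function(model, images, layer_names = model$layer_names,
                                chunk_size = 64L) {
  if (!inherits(model, "backbone_model")) input_error("model must be a backbone_model")
  unknown <- setdiff(layer_names, model$layer_names)
  if (length(unknown)) {
    config_error(sprintf("unknown layer name(s) %s; valid names: %s",
                         paste(unknown, collapse = ", "),
                         paste(model$layer_names, collapse = ", ")))
  }
  x <- stack_views(images)
  N <- dim(x)[4]
  pieces <- split(seq_len(N), ceiling(seq_len(N) / chunk_size))
  mats <- stats::setNames(vector("list", length(layer_names)), layer_names)
  for (idx in pieces) {
    fw <- forward_backbone(model, x[, , , idx, drop = FALSE], taps = layer_names)
    for (nm in layer_names) {
      a <- fw$acts[[nm]]
      m <- if (length(dim(a)) == 4L) {
        d <- dim(a)
        t(matrix(aperm(a, c(2, 1, 3, 4)), d[1] * d[2] * d[3], d[4]))
      } else t(a)
      mats[[nm]] <- rbind(mats[[nm]], m)
    }
  }
  lapply(layer_names, function(nm) {
    structure(list(layer_name = nm, matrix = mats[[nm]],
                   unit_count = ncol(mats[[nm]])),
              class = "layer_activations")
  }) |> stats::setNames(layer_names)
}

#' MD5 hash of a model's parameters
#'
#' Used by the activation cache to detect stale caches.
#' @param model a `backbone_model`.
#' @return A character hash.
#' @export
model_hash <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(model$params, f)
  unname(tools::md5sum(f))
}
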