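#' Augmentation configuration for instance-level view sampling
#'
#' Defines the stochastic views that carry the instance-level objective: each
#' image is sampled several times (default 5) with a random resized crop,
#' optional horizontal flip, random grayscale, and brightness / contrast /
#' saturation / hue jitter, then resized and channel-normalized.  Rotation is
#' deliberately not among the augmentations (the objective sees only crops,
#' rescaling and coloration variation); an optional rotation flag exists for
#' ablations but defaults off.
#'
#' @param n_views number of views sampled per image (default 5).
#' @param crop_scale_range range of the crop area as a fraction of the image
#'   area, within (0, 1].
#' @param allow_horizontal_flip flip each view left-right with probability 0.5.
#' @param grayscale_probability probability of converting a view to grayscale.
#' @param jitter_strengths named list with `brightness`, `contrast`,
#'   `saturation` (multiplicative half-ranges) and `hue` (additive hue
#'   half-range on the \[0, 1) hue circle).
#' @param rotation_degrees half-range of random in-plane rotation; 0 disables
#'   (the default; only right-angle multiples are supported when enabled).
#' @param output_size side length of the square output views.
#' @param normalization_mean per-channel means subtracted after jitter.
#' @param normalization_sd per-channel standard deviations divided out.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(n_views = 5L,
                           crop_scale_range = c(0.2, 1),
                           allow_horizontal_flip = TRUE,
                           grayscale_probability = 0.2,
                           jitter_strengths = list(brightness = 0.4,
                                                   contrast = 0.4,
                                                   saturation = 0.4,
                                                   hue = 0.4),
                           rotation_degrees = 0,
                           output_size = 224L,
                           normalization_mean = c(0.485, 0.456, 0.406),
                           normalization_sd = c(0.229, 0.224, 0.225)) {
  if (!is_count(n_views)) config_error("n_views must be a count >= 1")
  if (length(crop_scale_range) != 2L || crop_scale_range[1] <= 0 ||
      crop_scale_range[2] > 1 || crop_scale_range[1] > crop_scale_range[2]) {
    config_error("crop_scale_range must be an increasing range within (0, 1]")
  }
  if (grayscale_probability < 0 || grayscale_probability > 1) {
    config_error("grayscale_probability must be in [0, 1]")
  }
  for (nm in c("brightness", "contrast", "saturation", "hue")) {
    if (is.null(jitter_strengths[[nm]]) || jitter_strengths[[nm]] < 0) {
      config_error(sprintf("jitter_strengths$%s must be a nonnegative number", nm))
    }
  }
  if (!is_count(output_size, 1L)) config_error("output_size must be a count")
  structure(list(
    n_views = as.integer(n_views),
    crop_scale_range = crop_scale_range,
    allow_horizontal_flip = isTRUE(allow_horizontal_flip),
    grayscale_probability = grayscale_probability,
    jitter_strengths = jitter_strengths,
    rotation_degrees = rotation_degrees,
    output_size = as.integer(output_size),
    normalization_mean = normalization_mean,
    normalization_sd = normalization_sd
  ), class = "augment_config")
}

#' Bilinear resize of a crop region to a square output
#'
#' Maps output pixel centres to input coordinates (half-pixel convention) and
#' gathers the four neighbours with bilinear weights; vectorized over the
#' output grid.
#' @keywords internal
#' @noRd
resize_bilinear <- function(img, top, left, h, w, out_size) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ry <- top + ((seq_len(out_size) - 0.5) * h / out_size) - 0.5
  rx <- left + ((seq_len(out_size) - 0.5) * w / out_size) - 0.5
  ry <- pmin(pmax(ry, 1), H); rx <- pmin(pmax(rx, 1), W)
  y0 <- floor(ry); x0 <- floor(rx)
  y1 <- pmin(y0 + 1, H); x1 <- pmin(x0 + 1, W)
  wy <- ry - y0; wx <- rx - x0
  out <- array(0, dim = c(out_size, out_size, 3L))
  w00 <- outer(1 - wy, 1 - wx); w01 <- outer(1 - wy, wx)
  w10 <- outer(wy, 1 - wx);     w11 <- outer(wy, wx)
  for (ch in 1:3) {
    p <- img[, , ch]
    out[, , ch] <- w00 * p[y0, x0] + w01 * p[y0, x1] +
                   w10 * p[y1, x0] + w11 * p[y1, x1]
  }
  out
}

# Matches the common random-resized-crop procedure: sample a target area and
# log-uniform aspect ratio, retrying up to 10 times, else fall back to the
# largest centred crop.
sample_crop_box <- function(H, W, scale_range, ratio_range = c(3 / 4, 4 / 3)) {
  area <- H * W
  for (i in 1:10) {
    target <- stats::runif(1, scale_range[1], scale_range[2]) * area
    lr <- log(ratio_range)
    ratio <- exp(stats::runif(1, lr[1], lr[2]))
    w <- round(sqrt(target * ratio))
    h <- round(sqrt(target / ratio))
    if (w >= 1 && h >= 1 && w <= W && h <= H) {
      top <- sample.int(H - h + 1L, 1L)
      left <- sample.int(W - w + 1L, 1L)
      return(c(top = top, left = left, h = h, w = w))
    }
  }
  side <- min(H, W)
  c(top = floor((H - side) / 2) + 1L, left = floor((W - side) / 2) + 1L,
    h = side, w = side)
}

apply_color_jitter <- function(img, js) {
  # fixed application order (brightness, contrast, saturation, hue), each
  # clamped back into [0, 1]; normalization is applied last by the caller
  if (js$brightness > 0) {
    img <- img * stats::runif(1, 1 - js$brightness, 1 + js$brightness)
    img <- pmin(pmax(img, 0), 1)
  }
  if (js$contrast > 0) {
    f <- stats::runif(1, 1 - js$contrast, 1 + js$contrast)
    gray_mean <- mean(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    img <- pmin(pmax(gray_mean + (img - gray_mean) * f, 0), 1)
  }
  if (js$saturation > 0) {
    f <- stats::runif(1, 1 - js$saturation, 1 + js$saturation)
    gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    for (ch in 1:3) img[, , ch] <- gray + (img[, , ch] - gray) * f
    img <- pmin(pmax(img, 0), 1)
  }
  if (js$hue > 0) {
    shift <- stats::runif(1, -js$hue, js$hue)
    dm <- dim(img)
    rgb <- matrix(aperm(img, c(3, 1, 2)), nrow = 3)
    hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
    out <- hsv_to_rgb(hsv[1, ] + shift, hsv[2, ], hsv[3, ])
    img <- aperm(array(t(out), dim = c(3, dm[1], dm[2])), c(2, 3, 1))
    img <- pmin(pmax(img, 0), 1)
  }
  img
}

#' Sample stochastic augmented views of one image
#'
#' @param image an H x W x 3 array with values in \[0, 1\].
#' @param config an [augment_config()].
#' @param seed optional integer seed; `NULL` uses (and advances) the ambient
#'   RNG stream, which is how the training loop composes reproducibility from
#'   a single run seed.
#' @return A `view_batch`: list with `views` (list of normalized
#'   `output_size x output_size x 3` arrays) and the `config`.
#' @export
sample_views <- function(image, config, seed = NULL) {
  if (length(dim(image)) != 3L || dim(image)[3] < 3L) {
    input_error("image must be an H x W x 3 array")
  }
  if (dim(image)[1] < 1L || dim(image)[2] < 1L) input_error("degenerate image (zero area)")
  if (!inherits(config, "augment_config")) config_error("config must be an augment_config")
  image <- image[, , 1:3, drop = FALSE]
  H <- dim(image)[1]; W <- dim(image)[2]
  js <- config$jitter_strengths

  with_seed(seed, {
    views <- lapply(seq_len(config$n_views), function(v) {
      box <- sample_crop_box(H, W, config$crop_scale_range)
      view <- resize_bilinear(image, box["top"], box["left"], box["h"], box["w"],
                              config$output_size)
      if (config$allow_horizontal_flip && stats::runif(1) < 0.5) {
        view <- view[, rev(seq_len(config$output_size)), , drop = FALSE]
      }
      if (config$rotation_degrees > 0) {
        quarter <- sample(c(-1L, 0L, 1L), 1L)
        if (quarter != 0L) {
          rot <- aperm(view, c(2, 1, 3))
          view <- if (quarter == 1L) rot[rev(seq_len(config$output_size)), , , drop = FALSE]
                  else rot[, rev(seq_len(config$output_size)), , drop = FALSE]
        }
      }
      view <- apply_color_jitter(view, js)
      if (config$grayscale_probability > 0 &&
          stats::runif(1) < config$grayscale_probability) {
        gray <- 0.299 * view[, , 1] + 0.587 * view[, , 2] + 0.114 * view[, , 3]
        for (ch in 1:3) view[, , ch] <- gray
      }
      for (ch in 1:3) {
        view[, , ch] <- (view[, , ch] - config$normalization_mean[ch]) /
          config$normalization_sd[ch]
      }
      view
    })
    structure(list(views = views, config = config), class = "view_batch")
  })
}

#' Deterministic evaluation view of an image
#'
#' Full-image resize plus channel normalization, with no stochastic
#' augmentation; used when extracting activations or embeddings for analysis.
#'
#' @inheritParams sample_views
#' @return A normalized `output_size x output_size x 3` array.
#' @export
eval_view <- function(image, config) {
  view <- resize_bilinear(image[, , 1:3, drop = FALSE], 1, 1,
                          dim(image)[1], dim(image)[2], config$output_size)
  for (ch in 1:3) {
    view[, , ch] <- (view[, , ch] - config$normalization_mean[ch]) /
      config$normalization_sd[ch]
  }
  view
}
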