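#' Specification for a procedural shape-world image set
#'
#' Shape world is a small synthetic visual world in which category identity is
#' carried purely by shape geometry (disc, square, triangle, cross, ring,
#' diamond) while position, scale and hue vary freely within class and the
#' background is noise.  It exists so that instance-level contrastive training
#' can be exercised end to end on data whose statistical structure -- not any
#' label -- carries the category signal.
#'
#' @param n_classes number of shape categories (>= 2, up to 6 distinct shapes).
#' @param n_instances_per_class images per category.
#' @param image_size side length in pixels of the square images (>= 32).
#' @param background_noise_sd standard deviation of the Gaussian pixel noise
#'   added to the mid-gray background, on the \[0, 1\] intensity scale.
#' @param within_class_jitter list with elements `position` (maximum centre
#'   offset as a fraction of the image half-size), `scale` (length-2 range of
#'   the shape radius as a fraction of the image half-size) and `hue`
#'   (half-width of the uniform hue jitter around each instance's base hue;
#'   1 means fully random hue).
#' @param seed integer seed; generation is fully deterministic given the seed.
#' @return An object of class `shape_world_spec`.
#' @export
shape_world_spec <- function(n_classes = 4L,
                             n_instances_per_class = 100L,
                             image_size = 32L,
                             background_noise_sd = 0.05,
                             within_class_jitter = list(
                               position = 0.25,
                               scale = c(0.5, 0.9),
                               hue = 1
                             ),
                             seed = 1L) {
  if (!is_count(n_classes, 2L)) config_error("n_classes must be a count >= 2")
  if (n_classes > length(.shape_catalogue)) {
    config_error(sprintf("n_classes must be <= %d (distinct shapes available)",
                         length(.shape_catalogue)))
  }
  if (!is_count(n_instances_per_class)) {
    config_error("n_instances_per_class must be a positive count")
  }
  if (!is_count(image_size, 32L)) config_error("image_size must be >= 32")
  if (!is.numeric(background_noise_sd) || background_noise_sd < 0) {
    config_error("background_noise_sd must be nonnegative")
  }
  jit <- within_class_jitter
  if (!is.list(jit) || is.null(jit$position) || is.null(jit$scale) ||
      is.null(jit$hue)) {
    config_error("within_class_jitter needs elements position, scale, hue")
  }
  if (length(jit$scale) == 1L) jit$scale <- rep(jit$scale, 2L)
  if (jit$scale[1] > jit$scale[2] || jit$scale[1] <= 0 || jit$scale[2] > 1) {
    config_error("within_class_jitter$scale must be an increasing range in (0, 1]")
  }
  structure(list(
    n_classes = as.integer(n_classes),
    n_instances_per_class = as.integer(n_instances_per_class),
    image_size = as.integer(image_size),
    background_noise_sd = background_noise_sd,
    within_class_jitter = jit,
    seed = as.integer(seed)
  ), class = "shape_world_spec")
}

# Shape masks are pure functions of a pixel grid; each returns a logical mask.
# cx, cy in pixel coordinates, r = shape radius in pixels.
.shape_catalogue <- list(
  disc = function(x, y, cx, cy, r) (x - cx)^2 + (y - cy)^2 <= r^2,
  square = function(x, y, cx, cy, r) pmax(abs(x - cx), abs(y - cy)) <= r,
  triangle = function(x, y, cx, cy, r) {
    # upward-pointing isoceles triangle inscribed in the radius-r box
    dy <- (y - cy) / r
    dx <- abs(x - cx) / r
    (dy >= -1) & (dy <= 1) & (dx <= (1 - dy) / 2)
  },
  cross = function(x, y, cx, cy, r) {
    (abs(x - cx) <= r / 3 & abs(y - cy) <= r) |
      (abs(y - cy) <= r / 3 & abs(x - cx) <= r)
  },
  ring = function(x, y, cx, cy, r) {
    d2 <- (x - cx)^2 + (y - cy)^2
    d2 <= r^2 & d2 >= (0.55 * r)^2
  },
  diamond = function(x, y, cx, cy, r) abs(x - cx) + abs(y - cy) <= r
)

# Vectorized HSV -> RGB for h in [0,1), s,v in [0,1]; returns 3-col matrix.
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

#' Generate a procedural shape-world image set
#'
#' Deterministic given `spec$seed`.  Every image carries exactly one class
#' label and a unique instance id; class identity is encoded only in the shape
#' geometry, never in colour or position.
#'
#' @param spec a [shape_world_spec()].
#' @return A `labeled_image_set`: list with `images` (list of
#'   `image_size x image_size x 3` arrays in \[0, 1\]), integer `labels`,
#'   `class_names`, character `instance_ids`, and the `spec`.
#' @export
generate_shape_world <- function(spec) {
  if (!inherits(spec, "shape_world_spec")) {
    config_error("spec must be a shape_world_spec")
  }
  s <- spec$image_size
  half <- s / 2
  grid_x <- matrix(rep(seq_len(s), each = s), nrow = s)   # column index
  grid_y <- matrix(rep(seq_len(s), times = s), nrow = s)  # row index
  jit <- spec$within_class_jitter
  n_total <- spec$n_classes * spec$n_instances_per_class

  with_seed(spec$seed, {
    images <- vector("list", n_total)
    labels <- integer(n_total)
    idx <- 0L
    for (cls in seq_len(spec$n_classes)) {
      shape_fun <- .shape_catalogue[[cls]]
      base_hue <- (cls - 1) / spec$n_classes
      for (inst in seq_len(spec$n_instances_per_class)) {
        idx <- idx + 1L
        cx <- half + 0.5 + stats::runif(1, -1, 1) * jit$position * half
        cy <- half + 0.5 + stats::runif(1, -1, 1) * jit$position * half
        r <- stats::runif(1, jit$scale[1], jit$scale[2]) * half * 0.9
        hue <- base_hue + stats::runif(1, -1, 1) * jit$hue / 2
        col <- hsv_to_rgb(hue, 0.8, 0.9)
        bg <- 0.5
        img <- array(bg, dim = c(s, s, 3L))
        if (spec$background_noise_sd > 0) {
          img <- img + array(stats::rnorm(s * s * 3L, 0, spec$background_noise_sd),
                             dim = c(s, s, 3L))
        }
        mask <- shape_fun(grid_x, grid_y, cx, cy, r)
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[mask] <- col[ch]
          img[, , ch] <- plane
        }
        images[[idx]] <- pmin(pmax(img, 0), 1)
        labels[idx] <- cls
      }
    }
    structure(list(
      images = images,
      labels = labels,
      class_names = names(.shape_catalogue)[seq_len(spec$n_classes)],
      instance_ids = sprintf("img%05d", seq_len(n_total)),
      spec = spec
    ), class = "labeled_image_set")
  })
}

#' Write a labeled image set as a class-per-subdirectory PNG folder
#'
#' @param set a `labeled_image_set`.
#' @param dir output directory; one subdirectory per class is created.
#' @return Invisibly, the vector of files written.
#' @export
write_image_folder <- function(set, dir) {
  if (!inherits(set, "labeled_image_set")) input_error("set must be a labeled_image_set")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(set$images))
  for (i in seq_along(set$images)) {
    cls_dir <- file.path(dir, set$class_names[set$labels[i]])
    dir.create(cls_dir, showWarnings = FALSE)
    files[i] <- file.path(cls_dir, paste0(set$instance_ids[i], ".png"))
    png::writePNG(set$images[[i]], files[i])
  }
  invisible(files)
}

#' Read a class-per-subdirectory PNG folder into a labeled image set
#'
#' @param dir directory whose immediate subdirectories name the classes.
#' @return A `labeled_image_set` (spec slot is `NULL`).
#' @export
read_image_folder <- function(dir) {
  classes <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) input_error("no class subdirectories found")
  images <- list(); labels <- integer(0); ids <- character(0)
  for (ci in seq_along(classes)) {
    fs <- sort(list.files(file.path(dir, classes[ci]), pattern = "\\.png$",
                          full.names = TRUE))
    for (f in fs) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
      img <- img[, , 1:3, drop = FALSE]
      images[[length(images) + 1L]] <- img
      labels <- c(labels, ci)
      ids <- c(ids, sub("\\.png$", "", basename(f)))
    }
  }
  structure(list(images = images, labels = labels, class_names = classes,
                 instance_ids = ids, spec = NULL),
            class = "labeled_image_set")
}
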