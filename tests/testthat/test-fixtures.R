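test_that("shape world generation is deterministic and correctly labeled", {
  spec <- shape_world_spec(n_classes = 3L, n_instances_per_class = 5L, seed = 42L)
  a <- generate_shape_world(spec)
  b <- generate_shape_world(spec)
  expect_identical(a, b)
  expect_length(a$images, 15L)
  expect_equal(sort(unique(a$labels)), 1:3)
  expect_equal(anyDuplicated(a$instance_ids), 0L)
  expect_true(all(vapply(a$images, function(im) all(im >= 0 & im <= 1), TRUE)))
})

test_that("zero jitter and zero background noise give identical images within class", {
  spec <- shape_world_spec(
    n_classes = 2L, n_instances_per_class = 4L, background_noise_sd = 0,
    within_class_jitter = list(position = 0, scale = c(0.7, 0.7), hue = 0),
    seed = 1L)
  sw <- generate_shape_world(spec)
  for (cls in 1:2) {
    idx <- which(sw$labels == cls)
    for (i in idx[-1]) expect_identical(sw$images[[i]], sw$images[[idx[1]]])
  }
  # ... but classes still differ (geometry carries the signal)
  expect_false(identical(sw$images[[which(sw$labels == 1)[1]]],
                         sw$images[[which(sw$labels == 2)[1]]]))
})

test_that("invalid shape-world specs are rejected", {
  expect_error(shape_world_spec(n_classes = 1L), class = "ipclversa_config_error")
  expect_error(shape_world_spec(image_size = 16L), class = "ipclversa_config_error")
  expect_error(generate_shape_world(list()), class = "ipclversa_config_error")
})

test_that("image folder round-trips through PNG", {
  sw <- small_world(n_per_class = 2L)
  dir <- withr::local_tempdir()
  write_image_folder(sw, dir)
  back <- read_image_folder(dir)
  expect_length(back$images, length(sw$images))
  expect_equal(sort(back$class_names), sort(sw$class_names))
  # PNG stores 8-bit samples; round-trip is exact to 1/255
  # class indices re-sort alphabetically on read; match classes by name
  cls <- back$class_names[back$labels[1]]
  same_class <- sw$images[which(sw$class_names[sw$labels] == cls)]
  expect_lt(max(abs(back$images[[1]] - same_class[[1]])), 1 / 255 + 1e-8)
})

test_that("noise-free synthetic subjects share one RDM and a ceiling of 1", {
  feats <- matrix(rnorm(12 * 6), 12, 6)
  spec <- synthetic_subject_spec(feats, n_subjects = 4L,
                                 n_voxels_per_subject = 30L, noise_sd = 0,
                                 seed = 5L)
  world <- generate_synthetic_subjects(spec)
  rdms <- lapply(world$subjects, function(s) compute_rdm(s$responses))
  for (i in 2:4) expect_equal(rdms[[i]]$matrix, rdms[[1]]$matrix)
  nc <- noise_ceiling(world$subjects, enumerate_split_halves(4L))
  expect_equal(nc$mean_r, 1, tolerance = 1e-6)
})

test_that("orthonormal mixing plants the generating Pearson geometry exactly", {
  feats <- matrix(rnorm(10 * 6), 10, 6)
  spec <- synthetic_subject_spec(feats, n_subjects = 2L,
                                 n_voxels_per_subject = 40L,
                                 weight_distribution = "orthonormal",
                                 noise_sd = 0, seed = 2L)
  world <- generate_synthetic_subjects(spec)
  r <- rdm_correlation(compute_rdm(feats),
                       compute_rdm(world$subjects[[1]]$responses))
  expect_equal(r, 1, tolerance = 1e-10)
})

test_that("split-half consistency decreases monotonically with noise", {
  feats <- matrix(rnorm(10 * 5), 10, 5)
  scheme <- enumerate_split_halves(4L)
  mean_ceiling <- function(noise_sd) {
    rs <- vapply(1:20, function(rep) {
      spec <- synthetic_subject_spec(feats, n_subjects = 4L,
                                     n_voxels_per_subject = 40L,
                                     noise_sd = noise_sd,
                                     seed = 1000L + rep)
      noise_ceiling(generate_synthetic_subjects(spec)$subjects, scheme)$mean_r
    }, numeric(1))
    fisher_mean(rs)
  }
  grid <- c(0.5, 1, 2)
  ceilings <- vapply(grid, mean_ceiling, numeric(1))
  expect_true(all(diff(ceilings) < 0))
})

test_that("a supplied mixing matrix is used verbatim; noise calibration tracks the target", {
  withr::with_seed(6, {
    feats <- matrix(rnorm(10 * 4), 10, 4)
    W <- matrix(abs(rnorm(4 * 12)), 4, 12)
    spec <- synthetic_subject_spec(feats, n_subjects = 2L,
                                   n_voxels_per_subject = 12L, noise_sd = 0,
                                   seed = 1L, weights = W)
    world <- generate_synthetic_subjects(spec)
    expect_identical(world$weights, W)
    expect_equal(world$subjects[[1]]$responses, feats %*% W,
                 ignore_attr = TRUE)
    expect_error(synthetic_subject_spec(feats, n_voxels_per_subject = 12L,
                                        weights = matrix(0, 3, 12)),
                 class = "ipclversa_config_error")
    # calibration picks a larger noise_sd for a lower consistency target
    base <- synthetic_subject_spec(feats, n_subjects = 4L,
                                   n_voxels_per_subject = 30L, seed = 1L)
    hi <- calibrate_noise_sd(base, target_r = 0.9, grid = c(0.5, 4), n_rep = 3L)
    lo <- calibrate_noise_sd(base, target_r = 0.2, grid = c(0.5, 4), n_rep = 3L)
    expect_lt(hi$noise_sd, lo$noise_sd)
  })
})

test_that("ground-truth weights are returned and noise is subject-specific", {
  feats <- matrix(rnorm(8 * 4), 8, 4)
  spec <- synthetic_subject_spec(feats, n_subjects = 3L,
                                 n_voxels_per_subject = 10L, noise_sd = 0.5,
                                 seed = 9L)
  world <- generate_synthetic_subjects(spec)
  expect_equal(dim(world$weights), c(4L, 10L))
  expect_true(all(world$weights >= 0))  # half-normal default
  expect_false(identical(world$subjects[[1]]$responses,
                         world$subjects[[2]]$responses))
})

test_that("subject matrices round-trip through delimited text", {
  feats <- matrix(rnorm(9 * 4), 9, 4)
  spec <- synthetic_subject_spec(feats, n_subjects = 2L,
                                 n_voxels_per_subject = 6L, seed = 3L)
  world <- generate_synthetic_subjects(spec)
  dir <- withr::local_tempdir()
  write_subject_matrices(world$subjects, dir, world$weights)
  back <- read_subject_matrices(dir)
  expect_length(back, 2L)
  expect_equal(back[[1]]$responses, world$subjects[[1]]$responses,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(file.exists(file.path(dir, "ground_truth_weights.tsv")))
})
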