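test_that("split-half enumeration counts and sizes are exact", {
  expect_equal(enumerate_split_halves(2L)$J, 1L)
  s4 <- enumerate_split_halves(4L)
  expect_equal(s4$J, 3L)                      # C(4,2)/2
  s7 <- enumerate_split_halves(7L)
  expect_equal(s7$J, 35L)                     # C(7,3): 3|4 splits
  sizes <- vapply(s7$splits, function(h) sort(c(length(h[[1]]), length(h[[2]]))),
                  numeric(2))
  expect_true(all(sizes[1, ] == 3L & sizes[2, ] == 4L))
  expect_equal(s7$correction_ratio, 4 / 3)
  # every subject appears exactly once per split; no duplicate bipartitions
  keys <- vapply(s7$splits, function(h) paste(sort(h[[2]]), collapse = ","), "")
  expect_equal(anyDuplicated(keys), 0L)
  for (h in s7$splits) expect_equal(sort(c(h[[1]], h[[2]])), 1:7)
  # subsampling cap
  s10 <- enumerate_split_halves(10L, max_splits = 40L, seed = 2L)
  expect_equal(s10$J, 40L)
  expect_error(enumerate_split_halves(1L), class = "ipclversa_input_error")
})

test_that("noiseless single-unit voxel is reproduced as lambda -> 0", {
  withr::with_seed(10, {
    X <- matrix(rnorm(20 * 6), 20, 6)
    Y <- X[, 3, drop = FALSE] * 2 + 1
    sub <- subject_voxel_data("s1", Y)
    fit <- fit_voxel_encoding_loo(X, sub, lambda_grid = 1e-8)
    expect_equal(fit$predicted, sub$responses, tolerance = 1e-4)
  })
})

test_that("fixed-lambda predictions match the closed-form refit-per-fold oracle", {
  withr::with_seed(22, {
    for (lambda in c(0.5, 10)) {
      X <- matrix(rnorm(15 * 8), 15, 8)
      Y <- matrix(rnorm(15 * 5), 15, 5)
      sub <- subject_voxel_data("s1", Y)
      fit <- fit_voxel_encoding_loo(X, sub, lambda_grid = lambda)
      expect_equal(unname(fit$predicted), oracle_ridge_loo(X, Y, lambda),
                   tolerance = 1e-8)
      expect_true(all(fit$lambda == lambda))
    }
  })
})

test_that("pure-noise features and voxels yield no spurious positive predictivity", {
  # cross-validated prediction accuracy is negatively biased under the null
  # (the held-out condition pulls the training mean away from itself), so the
  # null lands at or below zero -- never spuriously above it
  withr::with_seed(33, {
    rs <- vapply(1:15, function(rep) {
      X <- matrix(rnorm(18 * 6), 18, 6)
      Y <- matrix(rnorm(18 * 8), 18, 8)
      fit <- fit_voxel_encoding_loo(X, subject_voxel_data("s", Y))
      mean(diag(cor(fit$predicted, Y)))
    }, numeric(1))
    expect_lt(mean(rs), 0.05)
    # and with real signal the same pipeline is strongly positive
    X <- matrix(rnorm(18 * 6), 18, 6)
    W <- matrix(abs(rnorm(6 * 8)), 6, 8)
    Y <- X %*% W + matrix(rnorm(18 * 8, 0, 0.2), 18, 8)
    fit <- fit_voxel_encoding_loo(X, subject_voxel_data("s", Y))
    expect_gt(mean(diag(cor(fit$predicted, Y))), 0.8)
  })
})

test_that("held-out predictions are independent of the held-out response (leakage guard)", {
  withr::with_seed(44, {
    X <- matrix(rnorm(12 * 5), 12, 5)
    Y <- matrix(rnorm(12 * 4), 12, 4)
    fit1 <- fit_voxel_encoding_loo(X, subject_voxel_data("s", Y))
    Y2 <- Y; Y2[7, ] <- 0   # mutate the held-out condition's response
    fit2 <- fit_voxel_encoding_loo(X, subject_voxel_data("s", Y2))
    expect_equal(fit1$predicted[7, ], fit2$predicted[7, ], tolerance = 1e-12,
                 ignore_attr = TRUE)
  })
})

test_that("model_predicted_rdm composes compute_rdm over the predictions", {
  withr::with_seed(3, {
    X <- matrix(rnorm(10 * 4), 10, 4)
    Y <- matrix(rnorm(10 * 6), 10, 6)
    fit <- fit_voxel_encoding_loo(X, subject_voxel_data("s", Y))
    rdm <- model_predicted_rdm(fit)
    expect_equal(rdm$matrix, compute_rdm(fit$predicted)$matrix)
    # perfect encoding: predicted geometry equals measured geometry
    fit$predicted <- Y
    rownames(fit$predicted) <- fit$condition_ids
    expect_equal(model_predicted_rdm(fit)$matrix,
                 compute_rdm(subject_voxel_data("s", Y)$responses)$matrix)
  })
})

test_that("noise-free planted layer reaches mean r = 1 in the veRSA curve", {
  withr::with_seed(55, {
    layers <- fake_layers(24, units = c(6L, 8L, 10L))
    spec <- synthetic_subject_spec(layers$layer2, n_subjects = 4L,
                                   n_voxels_per_subject = 30L, noise_sd = 0,
                                   seed = 5L)
    world <- generate_synthetic_subjects(spec)
    scheme <- enumerate_split_halves(4L)
    curve <- versa_curve(layers, world$subjects, scheme,
                         lambda_grid = c(1e-8, 1e-2, 1))
    expect_equal(curve$results$layer2$mean_r, 1, tolerance = 1e-6)
    expect_lt(curve$results$layer1$mean_r, 1 - 1e-4)
  })
})

test_that("permuting brain RDM condition pairs nulls the veRSA correlation", {
  withr::with_seed(66, {
    layers <- fake_layers(16, units = c(6L,  8L))
    spec <- synthetic_subject_spec(layers$layer1, n_subjects = 4L,
                                   n_voxels_per_subject = 25L, noise_sd = 0.5,
                                   seed = 6L)
    world <- generate_synthetic_subjects(spec)
    # shuffle conditions of every subject identically: destroys alignment with
    # the feature rows while preserving the RDM's internal structure
    perm_world <- lapply(world$subjects, function(s) {
      perm <- sample(nrow(s$responses))
      subject_voxel_data(s$subject_id, s$responses[perm, ], s$condition_ids)
    })
    scheme <- enumerate_split_halves(4L)
    r_null <- versa_curve(layers["layer1"], perm_world, scheme)$results$layer1$mean_r
    r_true <- versa_curve(layers["layer1"], world$subjects, scheme)$results$layer1$mean_r
    expect_gt(r_true, 0.5)
    expect_lt(abs(r_null), 0.35)
  })
})

test_that("veRSA is invariant to an invertible linear mixing of the generating features", {
  withr::with_seed(77, {
    feats <- matrix(rnorm(20 * 6), 20, 6)
    mix <- matrix(rnorm(36), 6, 6) + diag(6)
    spec <- synthetic_subject_spec(feats, n_subjects = 4L,
                                   n_voxels_per_subject = 30L, noise_sd = 0.3,
                                   seed = 7L)
    world <- generate_synthetic_subjects(spec)
    scheme <- enumerate_split_halves(4L)
    grid <- 10^seq(-6, 2, length.out = 5)
    r_raw <- versa_curve(list(L = feats), world$subjects, scheme,
                         lambda_grid = grid)$results$L$mean_r
    r_mixed <- versa_curve(list(L = feats %*% mix), world$subjects, scheme,
                           lambda_grid = grid)$results$L$mean_r
    expect_equal(r_raw, r_mixed, tolerance = 0.02)
  })
})

test_that("noise ceiling: identical subjects give 1, anti-correlated subjects go negative", {
  withr::with_seed(9, {
    resp <- matrix(rnorm(10 * 8), 10, 8)
    subs <- list(subject_voxel_data("a", resp), subject_voxel_data("b", resp))
    scheme <- enumerate_split_halves(2L)
    expect_equal(noise_ceiling(subs, scheme)$mean_r, 1, tolerance = 1e-6)
    # construct two subjects whose RDM lower triangles anti-correlate
    r1 <- compute_rdm(resp)
    resp2 <- matrix(rnorm(10 * 8), 10, 8)
    best <- NULL
    for (i in 1:50) {
      cand <- matrix(rnorm(10 * 8), 10, 8)
      r <- cor(lower_tri(r1), lower_tri(compute_rdm(cand)))
      if (is.null(best) || r < best$r) best <- list(m = cand, r = r)
    }
    subs2 <- list(subject_voxel_data("a", resp), subject_voxel_data("b", best$m))
    nc <- noise_ceiling(subs2, scheme)
    expect_equal(nc$mean_r, best$r, tolerance = 1e-10)   # reported unclipped
    expect_error(noise_ceiling(subs[1]), class = "ipclversa_input_error")
  })
})

test_that("cv max-layer: forced selection, pinned tie-break, and selection-bias direction", {
  scheme <- enumerate_split_halves(4L)        # J = 3
  # single layer: cv max-r equals that layer's mean r
  r1 <- matrix(seq(0.1, 0.6, length.out = 6), 1, 6,
               dimnames = list("only", NULL))
  cv1 <- cv_max_layer(r1, scheme)
  expect_equal(cv1$result$mean_r, fisher_mean(r1[1, ]))
  # constructed tie: equal selection-half correlations -> earlier layer wins
  r2 <- rbind(early = rep(0.5, 6), late = rep(0.5, 6))
  cv2 <- cv_max_layer(r2, scheme)
  expect_true(all(cv2$selected == "early"))
  # on exchangeable null data, cv max-r <= plain max of layer means (on average)
  withr::with_seed(123, {
    diffs <- vapply(1:100, function(rep) {
      rm_ <- matrix(rnorm(4 * 6, 0, 0.2), 4, 6)
      cv <- cv_max_layer(rm_, scheme)$result$mean_r
      plain <- max(apply(rm_, 1, fisher_mean))
      plain - cv
    }, numeric(1))
    expect_gt(mean(diffs), 0)
  })
  expect_error(cv_max_layer(matrix(0, 2, 4), scheme),
               class = "ipclversa_alignment_error")
})

test_that("explained proportion is the ratio of correlations", {
  expect_equal(explained_proportion(0.5, 0.5), 100)
  expect_equal(explained_proportion(0, 0.9), 0)
  expect_equal(explained_proportion(0.79, 0.90), 87.78, tolerance = 0.01)
  expect_equal(explained_proportion(0.45, 0.9, squared = TRUE), 25)
  expect_error(explained_proportion(0.5, -0.1), class = "ipclversa_input_error")
})
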