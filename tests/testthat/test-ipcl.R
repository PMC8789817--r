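test_that("prototype closed forms hold", {
  v <- c(1, 0, 0, 0)
  expect_equal(compute_prototype(rbind(v, v, v))$vector, v)
  e1 <- c(1, 0, 0, 0); e2 <- c(0, 1, 0, 0)
  expect_equal(compute_prototype(rbind(e1, e2))$vector, (e1 + e2) / sqrt(2))
  expect_error(compute_prototype(rbind(v, -v)),
               class = "ipclversa_degenerate_prototype_error")
})

test_that("loss is zero with an empty queue and ln 2 for a single equal-logit negative", {
  withr::with_seed(1, {
    z <- array(runit(6 * 5, 16), dim = c(6, 5, 16))
    for (i in 1:6) for (v in 1:5) z[i, v, ] <- z[i, v, ] / sqrt(sum(z[i, v, ]^2))
    expect_identical(ipcl_loss(z, queue = memory_queue()), 0)
    # one view = prototype = e1; negative with the same logit as the positive
    for (tau in c(0.05, 0.07, 0.2)) {
      e1 <- c(1, 0, 0); q <- c(1, 0, 0)
      z1 <- array(e1, dim = c(1, 1, 3))
      expect_equal(ipcl_loss(z1, queue = rbind(q), temperature = tau), log(2),
                   tolerance = 1e-12)
      # equal logits also when positive != negative: v.p == v.q
      v <- c(1, 1, 0) / sqrt(2)
      zv <- array(v, dim = c(1, 1, 3))
      expect_equal(ipcl_loss(zv, prototypes = rbind(c(1, 0, 0)),
                             queue = rbind(c(0, 1, 0)), temperature = tau),
                   log(2), tolerance = 1e-12)
    }
  })
})

test_that("vectorized loss matches the scalar-loop oracle on 100 random configurations", {
  withr::with_seed(99, {
    for (rep in 1:100) {
      I <- sample(1:8, 1); V <- sample(1:5, 1); D <- sample(c(4, 8, 16), 1)
      nq <- sample(0:64, 1)
      z <- array(0, dim = c(I, V, D))
      zm <- runit(I * V, D)
      for (i in 1:I) for (v in 1:V) z[i, v, ] <- zm[(i - 1) * V + v, ]
      q <- if (nq > 0) runit(nq, D) else matrix(numeric(0), 0, D)
      tau <- runif(1, 0.05, 0.3)
      expect_equal(ipcl_loss(z, queue = q, temperature = tau),
                   oracle_ipcl_loss(z, q, tau), tolerance = 1e-6)
    }
  })
})

test_that("analytic loss gradient matches finite differences", {
  withr::with_seed(5, {
    I <- 2; V <- 3; D <- 6
    z <- array(0, dim = c(I, V, D))
    zm <- runit(I * V, D)
    for (i in 1:I) for (v in 1:V) z[i, v, ] <- zm[(i - 1) * V + v, ]
    q <- runit(4, D)
    res <- ipclversa:::ipcl_loss_core(z, q, 0.07, with_grad = TRUE)
    h <- 1e-6
    for (i in 1:I) for (v in 1:V) for (d in 1:D) {
      zp <- z; zm2 <- z
      zp[i, v, d] <- zp[i, v, d] + h
      zm2[i, v, d] <- zm2[i, v, d] - h
      fd <- (ipclversa:::ipcl_loss_core(zp, q, 0.07)$loss -
             ipclversa:::ipcl_loss_core(zm2, q, 0.07)$loss) / (2 * h)
      expect_equal(res$grad[i, v, d], fd, tolerance = 1e-4)
    }
  })
})

test_that("queue semantics: FIFO order, strict capacity, oldest-first eviction", {
  q <- memory_queue(capacity = 4L)
  ids <- diag(6)[, 1:6]   # 6 orthonormal vectors
  q <- queue_push(q, ids[1, ])
  expect_equal(q$current_size, 1L)
  for (i in 2:5) q <- queue_push(q, ids[i, ])
  expect_equal(q$current_size, 4L)
  m <- queue_vectors(q)
  expect_equal(m[1, ], ids[2, ])   # oldest at head; first push evicted
  expect_equal(m[4, ], ids[5, ])   # newest at tail
  # bulk push past capacity
  q2 <- memory_queue(capacity = 3L)
  q2 <- queue_push(q2, runit(5, 4))
  expect_equal(q2$current_size, 3L)
})

test_that("a 4097th push evicts exactly the first vector at default capacity", {
  q <- memory_queue()   # 4096
  expect_equal(q$capacity, 4096L)
  first <- c(1, rep(0, 7))
  q <- queue_push(q, first)
  q <- queue_push(q, runit(4096, 8))
  expect_equal(q$current_size, 4096L)
  expect_false(any(apply(queue_vectors(q), 1, function(r) isTRUE(all.equal(r, first)))))
})

test_that("adding negatives increases the loss, most for a prototype-aligned negative", {
  withr::with_seed(3, {
    v <- runit(1, 8)[1, ]
    z <- array(v, dim = c(1, 1, 8))
    base <- ipcl_loss(z, queue = memory_queue())
    # orthogonal negative
    ortho <- runit(1, 8)[1, ]
    ortho <- ortho - sum(ortho * v) * v
    ortho <- ortho / sqrt(sum(ortho^2))
    l_ortho <- ipcl_loss(z, queue = rbind(ortho))
    l_self <- ipcl_loss(z, queue = rbind(v))   # negative identical to prototype
    expect_gt(l_ortho, base)
    expect_gt(l_self, l_ortho)
  })
})

test_that("temperature and norm validation reject bad inputs", {
  z <- array(c(1, 0), dim = c(1, 1, 2))
  expect_error(ipcl_loss(z, temperature = 0), class = "ipclversa_config_error")
  expect_error(ipcl_loss(array(c(2, 0), dim = c(1, 1, 2))),
               class = "ipclversa_input_error")
})

test_that("zero-epoch training returns the initialization unchanged", {
  sw <- small_world(n_per_class = 2L)
  cfg <- ipcl_config(epochs = 0L, seed = 21L)
  tr <- train_ipcl(sw, backbone_config("tiny_gn", embedding_dim = 8L), cfg,
                   aug32())
  ref <- withr::with_seed(21L, build_backbone(backbone_config("tiny_gn", embedding_dim = 8L)))
  expect_equal(tr$model$params, ref$params, tolerance = 1e-15)
  expect_equal(nrow(tr$history), 0L)
})

test_that("short training is reproducible and keeps the loss finite", {
  sw <- small_world(n_per_class = 6L)
  cfg <- ipcl_config(epochs = 4L, batch_instances = 8L, queue_capacity = 16L,
                     lr = 0.02, seed = 31L)
  tr1 <- train_ipcl(sw, backbone_config("tiny_gn", embedding_dim = 8L), cfg, aug32())
  tr2 <- train_ipcl(sw, backbone_config("tiny_gn", embedding_dim = 8L), cfg, aug32())
  expect_identical(tr1$history, tr2$history)
  expect_true(all(is.finite(tr1$history$loss)))
  expect_true(all(tr1$history$queue_size <= 16L))
  expect_equal(nrow(tr1$history), 4L * 3L)   # 24 images / 8 per batch
  # embeddings remain unit-norm after updates
  e <- embed_image_set(tr1$model, sw, aug32())
  expect_equal(sqrt(rowSums(e^2)), rep(1, nrow(e)), tolerance = 1e-6)
})

test_that("alignment rises over training while cross-instance similarity does not", {
  sw <- small_world(n_per_class = 6L)
  bbc <- backbone_config("tiny_gn", embedding_dim = 8L)
  aug <- aug32(crop_scale_range = c(0.6, 1), grayscale_probability = 0,
               jitter_strengths = list(brightness = 0.3, contrast = 0.3,
                                       saturation = 0.3, hue = 0.05))
  cfg <- ipcl_config(epochs = 8L, batch_instances = 8L, queue_capacity = 16L,
                     lr = 0.03, momentum = 0, lr_schedule = "constant",
                     seed = 13L)
  mean_sims <- function(model) {
    # within-instance: mean cosine among 3 views of each image;
    # cross-instance: mean cosine between different images' view means
    withr::with_seed(77, {
      es <- lapply(sw$images[1:12], function(im) {
        forward_embed(model, sample_views(im, aug, seed = NULL))
      })
    })
    within <- mean(vapply(es, function(e) mean((e %*% t(e))[upper.tri(diag(nrow(e)))]),
                          numeric(1)))
    protos <- t(vapply(es, colMeans, numeric(ncol(es[[1]]))))
    protos <- protos / sqrt(rowSums(protos^2))
    S <- protos %*% t(protos)
    c(within = within, cross = mean(S[upper.tri(S)]))
  }
  before <- mean_sims(build_backbone(bbc, seed = 13L))
  tr <- train_ipcl(sw, bbc, cfg, aug)
  after <- mean_sims(tr$model)
  expect_gt(after["within"], before["within"])
  # views of one image become more similar to each other than to other
  # images: the within-minus-cross gap widens, and any drift in cross
  # similarity stays below the gain in alignment
  expect_gt(after["within"] - after["cross"], before["within"] - before["cross"])
  expect_lt(after["cross"] - before["cross"], after["within"] - before["within"])
})
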