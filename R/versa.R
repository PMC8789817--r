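#' Enumerate subject split-halves
#'
#' All unordered bipartitions of the subjects into groups of sizes
#' floor(n/2) and ceiling(n/2).  When the number of bipartitions exceeds
#' `max_splits`, a uniform subsample without replacement is drawn (seeded).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param max_splits cap on the number of splits retained (default 126: full
#'   enumeration at n = 7 and n = 10).
#' @param seed seed for the subsampling, used only when the cap binds.
#' @return An object of class `split_scheme`: list with `n_subjects`,
#'   `splits` (each a list of two index vectors), `J`, `correction_ratio`
#'   (= ceiling(n/2) / floor(n/2)), `max_splits`, `seed`.
#' @export
enumerate_split_halves <- function(n_subjects, max_splits = 126L, seed = 1L) {
  if (!is_count(n_subjects, 2L)) input_error("n_subjects must be >= 2")
  n <- as.integer(n_subjects)
  k <- n %/% 2L
  total <- choose(n, k) / if (n %% 2L == 0L) 2 else 1
  if (total <= max_splits && n <= 24L) {
    combos <- utils::combn(n, k, simplify = FALSE)
    if (n %% 2L == 0L) {
      combos <- Filter(function(g) 1L %in% g, combos)  # unordered: fix subject 1
    }
    splits <- lapply(combos, function(g) list(setdiff(seq_len(n), g), g))
  } else {
    splits <- list()
    seen <- character(0)
    with_seed(seed, {
      while (length(splits) < max_splits) {
        g <- sort(sample.int(n, k))
        key <- paste(g, collapse = ",")
        if (n %% 2L == 0L && !(1L %in% g)) {
          g <- sort(setdiff(seq_len(n), g))
          key <- paste(g, collapse = ",")
        }
        if (!(key %in% seen)) {
          seen <- c(seen, key)
          splits[[length(splits) + 1L]] <- list(setdiff(seq_len(n), g), g)
        }
      }
    })
  }
  structure(list(n_subjects = n, splits = splits, J = length(splits),
                 correction_ratio = ceiling(n / 2) / floor(n / 2),
                 max_splits = as.integer(max_splits), seed = seed),
            class = "split_scheme")
}

#' Leave-one-condition-out voxel-wise ridge encoding fit
#'
#' For each condition c, a ridge regression from the layer's units to each
#' voxel's response is fit on the remaining conditions and used to predict
#' condition c; assembling the held-out predictions over all conditions gives
#' a cross-validated estimate of every voxel's response to every image.  The
#' regularization strength is selected per voxel by the efficient (hat-matrix)
#' leave-one-out error within the training conditions, over `lambda_grid`.
#' Features are standardized with statistics frozen from each training fold
#' (ridge penalties are scale-sensitive and unit scales vary wildly across
#' layers).
#'
#' @param features `conditions x units` matrix or a `layer_activations`.
#' @param subject a [subject_voxel_data()].
#' @param lambda_grid positive ridge penalties (default 9 points log-spaced
#'   from 1e-3 to 1e5); per-voxel ties go to the first (smallest) grid value.
#' @param keep_weights also return the fitted units x voxels weight matrix of
#'   each held-out fold (memory-heavy; default off).
#' @return An object of class `encoding_fit`: `predicted` (conditions x
#'   voxels, each row predicted from a fit that excluded it), `lambda`
#'   (conditions x voxels selected penalties), `lambda_grid`, `subject_id`,
#'   `condition_ids`, and optionally `weights` (list over folds).
#' @export
fit_voxel_encoding_loo <- function(features, subject,
                                   lambda_grid = 10^seq(-3, 5, length.out = 9),
                                   keep_weights = FALSE) {
  X <- if (inherits(features, "layer_activations")) features$matrix else as.matrix(features)
  if (!inherits(subject, "subject_voxel_data")) input_error("subject must be a subject_voxel_data")
  Y <- subject$responses
  n <- nrow(X)
  if (nrow(Y) != n) input_error("features and responses must share condition order")
  if (n < 3L) input_error("need >= 3 conditions for leave-one-out encoding")
  if (length(lambda_grid) == 0L || any(lambda_grid <= 0)) {
    config_error("lambda_grid must be nonempty and strictly positive")
  }
  lambda_grid <- as.numeric(lambda_grid)
  V <- ncol(Y)
  L <- length(lambda_grid)
  predicted <- matrix(NA_real_, n, V, dimnames = dimnames(Y))
  lambda_sel <- matrix(NA_real_, n, V)
  weights <- if (keep_weights) vector("list", n) else NULL

  for (c_idx in seq_len(n)) {
    tr <- setdiff(seq_len(n), c_idx)
    Xtr <- X[tr, , drop = FALSE]
    mu <- colMeans(Xtr)
    sd_ <- apply(Xtr, 2, stats::sd)
    sd_[sd_ < 1e-12] <- 1
    Xs <- sweep(sweep(Xtr, 2, mu), 2, sd_, "/")
    xc <- (X[c_idx, ] - mu) / sd_
    ybar <- colMeans(Y[tr, , drop = FALSE])
    Yc <- sweep(Y[tr, , drop = FALSE], 2, ybar)

    sv <- svd(Xs)
    d2 <- sv$d^2
    UtY <- crossprod(sv$u, Yc)                    # r x V
    a <- as.vector(crossprod(xc, sv$v))           # length r
    U2 <- sv$u^2
    press <- matrix(NA_real_, L, V)
    preds <- matrix(NA_real_, L, V)
    nt <- length(tr)
    for (li in seq_len(L)) {
      shrink <- d2 / (d2 + lambda_grid[li])
      fitted <- sv$u %*% (UtY * shrink)
      h <- as.vector(U2 %*% shrink)
      denom <- pmax(1 - h, 1e-12)
      rl <- (Yc - fitted) / denom
      press[li, ] <- colSums(rl * rl)
      preds[li, ] <- as.vector((a * (sv$d / (d2 + lambda_grid[li]))) %*% UtY) + ybar
    }
    sel <- max.col(t(-press), ties.method = "first")  # per-voxel argmin PRESS
    predicted[c_idx, ] <- preds[cbind(sel, seq_len(V))]
    lambda_sel[c_idx, ] <- lambda_grid[sel]
    if (keep_weights) {
      Wfold <- matrix(0, ncol(X), V)
      for (li in sort(unique(sel))) {
        cols <- which(sel == li)
        Wfold[, cols] <- sv$v %*% ((sv$d / (d2 + lambda_grid[li])) *
                                     UtY[, cols, drop = FALSE])
      }
      weights[[c_idx]] <- Wfold
    }
  }
  structure(list(predicted = predicted, lambda = lambda_sel,
                 lambda_grid = lambda_grid, subject_id = subject$subject_id,
                 condition_ids = subject$condition_ids, weights = weights),
            class = "encoding_fit")
}

#' Model-predicted RDM from an encoding fit
#'
#' The predicted representational geometry: the correlation-distance RDM of
#' the cross-validated predicted responses.
#'
#' @param fit an [fit_voxel_encoding_loo()] result.
#' @return An `rdm`.
#' @export
model_predicted_rdm <- function(fit) {
  if (!inherits(fit, "encoding_fit")) input_error("fit must be an encoding_fit")
  if (anyNA(fit$predicted)) input_error("predicted responses are incomplete")
  compute_rdm(fit$predicted, condition_ids = fit$condition_ids)
}

#' Voxel-wise-encoding RSA layer curve
#'
#' For every layer and subject, voxel-wise encoding models yield a
#' model-predicted RDM.  For each subject split-half, each group's predicted
#' RDMs are averaged and correlated with the same group's average measured
#' brain RDM; both halves of every split contribute a correlation, and each
#' layer's correlations are summarized by their Fisher-z mean with the
#' adjusted (non-independence-corrected) confidence interval.
#'
#' @inheritParams classic_rsa_curve
#' @param lambda_grid ridge penalties passed to [fit_voxel_encoding_loo()].
#' @param unit_subsample optional count: randomly subsample this many units
#'   per layer before fitting (seeded; default off).
#' @param subsample_seed seed for the unit subsampling.
#' @return A `layer_curve` (see [classic_rsa_curve()]) with the per-subject
#'   model-predicted RDMs attached as `model_rdms`.
#' @export
versa_curve <- function(layer_activations, subjects, scheme,
                        lambda_grid = 10^seq(-3, 5, length.out = 9),
                        unit_subsample = NULL, subsample_seed = 1L) {
  layer_names <- names(layer_activations) %||%
    paste0("layer", seq_along(layer_activations))
  brain_rdms <- lapply(subjects, function(s) compute_rdm(s$responses))
  model_rdms <- stats::setNames(vector("list", length(layer_activations)),
                                layer_names)
  for (l in seq_along(layer_activations)) {
    la <- layer_activations[[l]]
    Xl <- if (inherits(la, "layer_activations")) la$matrix else as.matrix(la)
    if (!is.null(unit_subsample) && unit_subsample < ncol(Xl)) {
      keep <- with_seed(subsample_seed + l,
                        sort(sample.int(ncol(Xl), unit_subsample)))
      Xl <- Xl[, keep, drop = FALSE]
    }
    model_rdms[[l]] <- lapply(subjects, function(s) {
      model_predicted_rdm(fit_voxel_encoding_loo(Xl, s, lambda_grid))
    })
  }
  r_matrix <- split_half_correlations(model_rdms, brain_rdms, scheme,
                                      per_subject_model = TRUE)
  rownames(r_matrix) <- layer_names
  curve <- make_layer_curve(r_matrix, scheme)
  curve$model_rdms <- model_rdms
  curve
}

#' Split-half noise ceiling of a subject set
#'
#' For every split, the two groups' average brain RDMs are correlated; the
#' ceiling is the Fisher-z mean over splits with the adjusted confidence
#' interval.  Negative ceilings are reported as such, never clipped.
#'
#' @param subjects list of [subject_voxel_data()] (>= 2).
#' @param scheme an [enumerate_split_halves()] scheme.
#' @return A [correlation_result()].
#' @export
noise_ceiling <- function(subjects, scheme = NULL) {
  if (length(subjects) < 2L) input_error("noise ceiling needs >= 2 subjects")
  if (is.null(scheme)) scheme <- enumerate_split_halves(length(subjects))
  brain_mats <- lapply(subjects, function(s) as_rdm_matrix(compute_rdm(s$responses)))
  rs <- vapply(scheme$splits, function(halves) {
    a <- Reduce(`+`, brain_mats[halves[[1]]]) / length(halves[[1]])
    b <- Reduce(`+`, brain_mats[halves[[2]]]) / length(halves[[2]])
    stats::cor(lower_tri(a), lower_tri(b))
  }, numeric(1))
  correlation_result(rs, correction_ratio = scheme$correction_ratio)
}

#' Cross-validated max-layer estimation
#'
#' Per split, the layer with the highest correlation on the selection half is
#' chosen and its correlation on the independent half (new subjects) is
#' recorded; both orientations of every split are used.  Selection ties break
#' toward the earlier layer index (pinned).
#'
#' @param curve a `layer_curve` (from [versa_curve()] or
#'   [classic_rsa_curve()]), or a `layers x (2 J)` matrix of paired
#'   half-correlations with a `scheme` supplied.
#' @param scheme required when `curve` is a bare matrix.
#' @return List of class `cv_max_result`: `result` (a
#'   [correlation_result()] of the 2J evaluation correlations), `selected`
#'   (layer name chosen per evaluation), `selection_table`.
#' @export
cv_max_layer <- function(curve, scheme = NULL) {
  if (inherits(curve, "layer_curve")) {
    r_matrix <- curve$r_matrix
    scheme <- curve$scheme
  } else {
    r_matrix <- as.matrix(curve)
    if (is.null(scheme)) input_error("scheme required with a bare correlation matrix")
  }
  J <- scheme$J
  if (ncol(r_matrix) != 2L * J) {
    ipcl_error("correlation matrix does not match the split scheme",
               "ipclversa_alignment_error")
  }
  layer_names <- rownames(r_matrix) %||% paste0("layer", seq_len(nrow(r_matrix)))
  eval_r <- numeric(2L * J)
  selected <- character(2L * J)
  for (j in seq_len(J)) {
    colA <- 2L * j - 1L; colB <- 2L * j
    sA <- which.max(r_matrix[, colA])   # ties -> earlier layer
    sB <- which.max(r_matrix[, colB])
    eval_r[colA] <- r_matrix[sA, colB]; selected[colA] <- layer_names[sA]
    eval_r[colB] <- r_matrix[sB, colA]; selected[colB] <- layer_names[sB]
  }
  structure(list(result = correlation_result(eval_r, scheme$correction_ratio),
                 selected = selected,
                 selection_table = table(factor(selected, levels = layer_names))),
            class = "cv_max_result")
}

#' @export
print.cv_max_result <- function(x, ...) {
  cat("cv max-r: "); print(x$result)
  cat("selected layers:\n"); print(x$selection_table)
  invisible(x)
}

#' Proportion of explainable variance
#'
#' The model correlation as a percentage of the noise ceiling.  The default
#' is the plain ratio of correlations (100 * r_model / r_ceiling); set
#' `squared = TRUE` for the squared-ratio reading.
#'
#' @param model_result a [correlation_result()] or scalar correlation.
#' @param ceiling a [correlation_result()] or scalar ceiling (> 0).
#' @param squared use (r_model / r_ceiling)^2.
#' @return Percentage.
#' @export
explained_proportion <- function(model_result, ceiling, squared = FALSE) {
  rm_ <- if (inherits(model_result, "correlation_result")) model_result$mean_r else model_result
  rc <- if (inherits(ceiling, "correlation_result")) ceiling$mean_r else ceiling
  if (!is.finite(rc) || rc <= 0) {
    ipcl_error("noise ceiling must be positive for an explainable-variance ratio",
               "ipclversa_input_error")
  }
  ratio <- rm_ / rc
  100 * if (squared) ratio^2 else ratio
}

#' Calibrate the generator noise to a target split-half consistency
#'
#' Simulates replicate subject sets over a grid of noise standard deviations
#' and returns the grid value whose Monte-Carlo mean noise ceiling is closest
#' to the target.
#'
#' @param spec a [synthetic_subject_spec()] template (its `noise_sd`/`seed`
#'   are overridden).
#' @param target_r target split-half group RDM correlation.
#' @param grid candidate noise standard deviations.
#' @param n_rep replicate worlds per grid value.
#' @param seed base seed.
#' @return List with `noise_sd` (selected), and `table` (grid, mean ceiling).
#' @export
calibrate_noise_sd <- function(spec, target_r, grid = c(0.25, 0.5, 1, 2, 4),
                               n_rep = 5L, seed = 100L) {
  scheme <- enumerate_split_halves(spec$n_subjects)
  means <- vapply(seq_along(grid), function(gi) {
    rs <- vapply(seq_len(n_rep), function(rep) {
      sp <- spec
      sp$noise_sd <- grid[gi]
      sp$seed <- as.integer(seed + gi * 1000L + rep)
      noise_ceiling(generate_synthetic_subjects(sp)$subjects, scheme)$mean_r
    }, numeric(1))
    fisher_mean(rs)
  }, numeric(1))
  best <- which.min(abs(means - target_r))
  list(noise_sd = grid[best], table = data.frame(noise_sd = grid, ceiling = means))
}
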