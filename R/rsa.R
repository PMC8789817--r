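#' Compute a representational dissimilarity matrix (RDM)
#'
#' Entry (i, j) is the correlation distance `1 - Pearson(row i, row j)`
#' between the response patterns of conditions i and j, giving a symmetric
#' matrix with zero diagonal and entries in \[0, 2\].
#'
#' @param responses `conditions x features` matrix (>= 3 conditions, >= 2
#'   features); no condition row may be constant.
#' @param condition_ids optional condition labels (default: rownames).
#' @return An object of class `rdm`: list with `matrix` and `condition_ids`.
#' @export
compute_rdm <- function(responses, condition_ids = NULL) {
  responses <- as.matrix(responses)
  if (nrow(responses) < 3L) input_error("need >= 3 conditions")
  if (ncol(responses) < 2L) input_error("need >= 2 features")
  sds <- apply(responses, 1, stats::sd)
  if (any(sds < 1e-14)) {
    bad <- which(sds < 1e-14)[1]
    nm <- (rownames(responses) %||% as.character(seq_len(nrow(responses))))[bad]
    ipcl_error(sprintf("condition '%s' has a constant response pattern; correlation undefined", nm),
               "ipclversa_undefined_correlation_error")
  }
  m <- 1 - stats::cor(t(responses))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  ids <- condition_ids %||% rownames(responses) %||%
    sprintf("cond%03d", seq_len(nrow(responses)))
  dimnames(m) <- list(ids, ids)
  structure(list(matrix = m, condition_ids = as.character(ids)), class = "rdm")
}

as_rdm_matrix <- function(x) {
  if (inherits(x, "rdm")) x$matrix else as.matrix(x)
}

#' Lower-triangle vectorization of an RDM
#'
#' Strictly-below-diagonal entries (i > j) in row-major order, i.e. (2,1),
#' (3,1), (3,2), (4,1), ...; length n(n-1)/2.  The order is pinned: permuting
#' conditions and then vectorizing is not the same as vectorizing and then
#' permuting.
#'
#' @param rdm an [compute_rdm()] result or a square matrix.
#' @return Numeric vector of length n(n-1)/2.
#' @export
lower_tri <- function(rdm) {
  m <- as_rdm_matrix(rdm)
  tm <- t(m)
  tm[upper.tri(tm)]
}

#' Correlate two RDMs over their lower triangles
#'
#' @param a,b RDMs with identical condition ids in identical order.
#' @return Pearson r of the lower-triangle vectors.
#' @export
rdm_correlation <- function(a, b) {
  if (inherits(a, "rdm") && inherits(b, "rdm") &&
      !identical(a$condition_ids, b$condition_ids)) {
    ipcl_error("RDM condition ids do not align", "ipclversa_alignment_error")
  }
  stats::cor(lower_tri(a), lower_tri(b))
}

#' Fisher-z mean of correlations
#'
#' `tanh(mean(atanh(r)))`; values with |r| >= 1 - 1e-7 are clipped before the
#' atanh so that legitimately perfect correlations (e.g. from noise-free
#' synthetic data) average cleanly.
#'
#' @param rs correlations with |r| <= 1.
#' @return The Fisher-z averaged correlation.
#' @export
fisher_mean <- function(rs) {
  if (length(rs) == 0L) input_error("empty correlation list")
  if (any(abs(rs) > 1 + 1e-12)) input_error("correlations must satisfy |r| <= 1")
  z <- atanh(pmin(pmax(rs, -(1 - 1e-7)), 1 - 1e-7))
  tanh(mean(z))
}

#' Summarize per-split correlations with an adjusted confidence interval
#'
#' @param per_split_r correlations collected over split-halves.
#' @param correction_ratio the non-independence correction ratio n2/n1 (test
#'   over train group size).
#' @param level confidence level.
#' @return An object of class `correlation_result` with `mean_r`,
#'   `per_split_r`, `ci_low`, `ci_high`, `n_splits`, `correction_ratio`.
#' @export
correlation_result <- function(per_split_r, correction_ratio = 1, level = 0.95) {
  mean_r <- fisher_mean(per_split_r)
  ci <- if (length(per_split_r) >= 2L) {
    adjusted_ci(per_split_r, correction_ratio, level)
  } else c(mean_r, mean_r)
  structure(list(mean_r = mean_r, per_split_r = per_split_r,
                 ci_low = ci[1], ci_high = ci[2],
                 n_splits = length(per_split_r),
                 correction_ratio = correction_ratio),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("mean r = %.4f  [%.4f, %.4f]  (J = %d splits, correction ratio %.3g)\n",
              x$mean_r, x$ci_low, x$ci_high, x$n_splits, x$correction_ratio))
  invisible(x)
}

#' Classic RSA layer curve
#'
#' RDMs are computed directly from the raw layer activations, with no
#' encoding model or feature weighting, and correlated against split-half
#' group-mean brain RDMs under the same split scheme as the encoding-based
#' pipeline (each half of each split contributes one correlation).
#'
#' @param layer_activations named list of `layer_activations` (or
#'   conditions x units matrices).
#' @param subjects list of [subject_voxel_data()].
#' @param scheme an [enumerate_split_halves()] scheme.
#' @return List of class `layer_curve`: per-layer [correlation_result()]s in
#'   `results`, plus the `layers x (2 J)` matrix `r_matrix` (columns paired
#'   (split 1 half A, split 1 half B, split 2 half A, ...)) and the `scheme`.
#' @export
classic_rsa_curve <- function(layer_activations, subjects, scheme) {
  brain_rdms <- lapply(subjects, function(s) compute_rdm(s$responses))
  layer_names <- names(layer_activations) %||%
    paste0("layer", seq_along(layer_activations))
  model_rdms <- lapply(layer_activations, function(la) {
    compute_rdm(if (inherits(la, "layer_activations")) la$matrix else la,
                condition_ids = brain_rdms[[1]]$condition_ids)
  })
  r_matrix <- split_half_correlations(model_rdms, brain_rdms, scheme,
                                      per_subject_model = FALSE)
  rownames(r_matrix) <- layer_names
  make_layer_curve(r_matrix, scheme)
}

# Shared split-half correlation engine.  model_rdms: either one RDM per layer
# (classic RSA; per_subject_model = FALSE) or, per layer, a list of
# per-subject model-predicted RDMs (veRSA).  Returns layers x (2J) matrix.
split_half_correlations <- function(model_rdms, brain_rdms, scheme,
                                    per_subject_model = TRUE) {
  J <- length(scheme$splits)
  L <- length(model_rdms)
  out <- matrix(NA_real_, L, 2L * J)
  brain_mats <- lapply(brain_rdms, as_rdm_matrix)
  for (j in seq_len(J)) {
    halves <- scheme$splits[[j]]
    for (h in 1:2) {
      grp <- halves[[h]]
      brain_mean <- Reduce(`+`, brain_mats[grp]) / length(grp)
      for (l in seq_len(L)) {
        model_mat <- if (per_subject_model) {
          Reduce(`+`, lapply(model_rdms[[l]][grp], as_rdm_matrix)) / length(grp)
        } else as_rdm_matrix(model_rdms[[l]])
        out[l, 2L * (j - 1L) + h] <-
          stats::cor(lower_tri(model_mat), lower_tri(brain_mean))
      }
    }
  }
  out
}

make_layer_curve <- function(r_matrix, scheme) {
  ratio <- scheme$correction_ratio
  results <- lapply(seq_len(nrow(r_matrix)), function(l) {
    correlation_result(r_matrix[l, ], correction_ratio = ratio)
  })
  names(results) <- rownames(r_matrix)
  structure(list(results = results, r_matrix = r_matrix, scheme = scheme),
            class = "layer_curve")
}

#' @export
print.layer_curve <- function(x, ...) {
  for (nm in names(x$results)) {
    cat(sprintf("%-8s ", nm)); print(x$results[[nm]])
  }
  invisible(x)
}

#' Per-layer summary table of a layer curve
#' @param curve a `layer_curve`.
#' @return data.frame with layer, mean_r, ci_low, ci_high, n_splits.
#' @export
layer_curve_table <- function(curve) {
  do.call(rbind, lapply(names(curve$results), function(nm) {
    r <- curve$results[[nm]]
    data.frame(layer = nm, mean_r = r$mean_r, ci_low = r$ci_low,
               ci_high = r$ci_high, n_splits = r$n_splits)
  }))
}

#' Write / read an RDM as delimited text with a condition-id header
#' @param rdm an `rdm`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_rdm <- function(rdm, path) {
  m <- as_rdm_matrix(rdm)
  df <- data.frame(condition_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  structure(list(matrix = m, condition_ids = as.character(df[[1]])), class = "rdm")
}
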