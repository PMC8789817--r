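#' Specification for synthetic multi-subject voxel data
#'
#' Emulates the voxel model underlying voxel-wise encoding RSA: each voxel is
#' a weighted combination of model units, plus independent Gaussian
#' measurement noise.  One ground-truth mixing matrix is shared by all
#' subjects, so the simulated study has a known shared representational
#' geometry and subject differences are pure noise; noise is drawn
#' independently per subject and per voxel.
#'
#' @param generating_features conditions x units numeric matrix whose geometry
#'   the voxels inherit (>= 3 conditions).
#' @param n_subjects number of simulated subjects (>= 2).
#' @param n_voxels_per_subject voxels per subject (>= 1).
#' @param weight_distribution `"halfnormal"` draws mixing weights from
#'   |N(0, 1)| (nonnegative, interpretable sign; the planted geometry is then
#'   recovered only asymptotically in voxel count).  `"orthonormal"` mixes
#'   row-centred features through a row-orthonormal, zero-sum matrix, which
#'   plants the Pearson representational geometry of the features exactly
#'   (requires `n_voxels_per_subject > units`).
#' @param noise_sd standard deviation of the additive response noise, in
#'   response units.
#' @param seed integer seed.
#' @param weights optional fixed units x voxels mixing matrix; when supplied
#'   it is used as-is (only the noise is drawn), so replicate noise
#'   realizations of one ground-truth geometry can be simulated.
#' @return An object of class `synthetic_subject_spec`.
#' @export
synthetic_subject_spec <- function(generating_features,
                                   n_subjects = 8L,
                                   n_voxels_per_subject = 100L,
                                   weight_distribution = c("halfnormal", "orthonormal"),
                                   noise_sd = 1,
                                   seed = 1L,
                                   weights = NULL) {
  generating_features <- as.matrix(generating_features)
  if (nrow(generating_features) < 3L) {
    input_error("generating_features must have >= 3 conditions (rows)")
  }
  if (!is_count(n_subjects, 2L)) config_error("n_subjects must be a count >= 2")
  if (!is_count(n_voxels_per_subject, 1L)) {
    config_error("n_voxels_per_subject must be a count >= 1")
  }
  weight_distribution <- match.arg(weight_distribution)
  if (weight_distribution == "orthonormal" &&
      n_voxels_per_subject <= ncol(generating_features)) {
    config_error("orthonormal weights require n_voxels_per_subject > number of units")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) config_error("noise_sd must be >= 0")
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (nrow(weights) != ncol(generating_features) ||
        ncol(weights) != n_voxels_per_subject) {
      config_error("weights must be a units x n_voxels_per_subject matrix")
    }
  }
  structure(list(
    generating_features = generating_features,
    n_subjects = as.integer(n_subjects),
    n_voxels_per_subject = as.integer(n_voxels_per_subject),
    weight_distribution = weight_distribution,
    noise_sd = noise_sd,
    seed = as.integer(seed),
    weights = weights
  ), class = "synthetic_subject_spec")
}

#' A condition-by-voxel response matrix for one subject
#'
#' @param subject_id identifier string.
#' @param responses conditions x voxels numeric matrix.
#' @param condition_ids optional condition labels (defaults to rownames or
#'   `cond001`, ...).
#' @return An object of class `subject_voxel_data`.
#' @export
subject_voxel_data <- function(subject_id, responses, condition_ids = NULL) {
  responses <- as.matrix(responses)
  if (nrow(responses) < 3L) input_error("subject data needs >= 3 conditions")
  if (is.null(condition_ids)) {
    condition_ids <- rownames(responses) %||% sprintf("cond%03d", seq_len(nrow(responses)))
  }
  if (length(condition_ids) != nrow(responses)) {
    input_error("condition_ids must match the number of rows of responses")
  }
  rownames(responses) <- condition_ids
  structure(list(subject_id = as.character(subject_id),
                 responses = responses,
                 condition_ids = as.character(condition_ids)),
            class = "subject_voxel_data")
}

#' Generate synthetic subjects with a known shared representational geometry
#'
#' Each voxel's response profile over conditions is a fixed linear mixture of
#' the generating features plus independent Gaussian noise.  The ground-truth
#' mixing weights are returned for recovery tests.
#'
#' @param spec a [synthetic_subject_spec()].
#' @return List with `subjects` (list of [subject_voxel_data()]), `weights`
#'   (units x voxels ground-truth mixing matrix), and the `spec`.
#' @export
generate_synthetic_subjects <- function(spec) {
  if (!inherits(spec, "synthetic_subject_spec")) {
    config_error("spec must be a synthetic_subject_spec")
  }
  feats <- spec$generating_features
  n_cond <- nrow(feats)
  n_units <- ncol(feats)
  n_vox <- spec$n_voxels_per_subject
  cond_ids <- rownames(feats) %||% sprintf("cond%03d", seq_len(n_cond))

  with_seed(spec$seed, {
    if (!is.null(spec$weights)) {
      weights <- spec$weights
      signal <- feats %*% weights
    } else if (spec$weight_distribution == "halfnormal") {
      weights <- matrix(abs(stats::rnorm(n_units * n_vox)), n_units, n_vox)
      signal <- feats %*% weights
    } else {
      # Row-orthonormal, zero-sum mixing of row-centred features: preserves
      # the conditions' Pearson geometry exactly at finite voxel count.
      g <- matrix(stats::rnorm(n_vox * n_units), n_vox, n_units)
      g <- g - matrix(colMeans(g), n_vox, n_units, byrow = TRUE)
      q <- qr.Q(qr(g))                      # n_vox x n_units, orthonormal cols
      weights <- t(q)                       # units x voxels
      centred <- feats - rowMeans(feats)    # centre each condition across units
      signal <- centred %*% weights
    }
    subjects <- lapply(seq_len(spec$n_subjects), function(s) {
      noise <- if (spec$noise_sd > 0) {
        matrix(stats::rnorm(n_cond * n_vox, 0, spec$noise_sd), n_cond, n_vox)
      } else 0
      resp <- signal + noise
      colnames(resp) <- sprintf("vox%04d", seq_len(n_vox))
      subject_voxel_data(sprintf("sub%02d", s), resp, cond_ids)
    })
    list(subjects = subjects, weights = weights, spec = spec)
  })
}

#' Write subject voxel matrices as delimited text
#'
#' One tab-separated file per subject (conditions x voxels, header row of
#' voxel ids, first column of condition ids), plus a sidecar ground-truth
#' weights file when `weights` is supplied.
#'
#' @param subjects list of [subject_voxel_data()].
#' @param dir output directory.
#' @param weights optional units x voxels ground-truth mixing matrix.
#' @return Invisibly, the files written.
#' @export
write_subject_matrices <- function(subjects, dir, weights = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(subjects, function(s) {
    f <- file.path(dir, paste0(s$subject_id, ".tsv"))
    df <- data.frame(condition_id = s$condition_ids, s$responses,
                     check.names = FALSE)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }, character(1))
  if (!is.null(weights)) {
    wf <- file.path(dir, "ground_truth_weights.tsv")
    utils::write.table(weights, wf, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    files <- c(files, wf)
  }
  invisible(files)
}

#' Read subject voxel matrices written by [write_subject_matrices()]
#'
#' @param dir directory containing `*.tsv` subject files.
#' @return List of [subject_voxel_data()].
#' @export
read_subject_matrices <- function(dir) {
  fs <- sort(list.files(dir, pattern = "^sub.*\\.tsv$", full.names = TRUE))
  if (length(fs) == 0L) input_error("no subject .tsv files found")
  lapply(fs, function(f) {
    df <- utils::read.delim(f, check.names = FALSE)
    subject_voxel_data(sub("\\.tsv$", "", basename(f)),
                       as.matrix(df[, -1, drop = FALSE]),
                       as.character(df[[1]]))
  })
}
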