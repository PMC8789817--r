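#' Default demo-pipeline configuration
#'
#' One nested list drives a full end-to-end run: shape-world generation, IPCL
#' training of a tiny backbone, activation extraction, synthetic-subject
#' generation from a designated (planted) layer, veRSA + classic RSA + noise
#' ceiling + cross-validated max-layer, and a corrected comparison against an
#' untrained control.  Every block can be overridden; the whole structure is
#' serializable to YAML.
#'
#' @param seed global seed; all stage seeds are derived from it.
#' @return Nested configuration list of class `run_config`.
#' @export
demo_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    fixtures = list(
      n_classes = 4L, n_instances_per_class = 12L, image_size = 32L,
      n_condition_instances_per_class = 6L,
      planted_layer = "conv1",
      n_subjects = 6L, n_voxels_per_subject = 80L,
      weight_distribution = "halfnormal", noise_sd = 1
    ),
    backbone = list(architecture = "tiny_gn", embedding_dim = 16L),
    ipcl = list(epochs = 3L, batch_instances = 8L, lr = 0.02,
                momentum = 0, lr_schedule = "constant",
                queue_capacity = 40L),
    readout = list(k = 20L),
    versa = list(unit_subsample = 256L, max_splits = 126L),
    stats = list(alpha = 0.05, m = 1L)
  ), class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile(); on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Load / save a run configuration as YAML
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- demo_config(seed = cfg$seed %||% 1L)
  for (block in names(cfg)) {
    if (is.list(cfg[[block]])) {
      for (nm in names(cfg[[block]])) base[[block]][[nm]] <- cfg[[block]][[nm]]
    } else base[[block]] <- cfg[[block]]
  }
  base
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the end-to-end demo pipeline
#'
#' Generates a shape world, trains a tiny IPCL model, evaluates emergent
#' category structure (weighted kNN, trained vs untrained control), extracts
#' layerwise activations on a held-out condition set, synthesizes subjects
#' whose voxels mix a designated layer's units, and scores every layer with
#' veRSA and classic RSA against the synthetic brain data, with noise
#' ceiling, cross-validated max-layer, explained proportion, and a corrected
#' paired comparison of trained vs untrained cv-max correlations.
#'
#' @param config a [demo_config()]-style `run_config`.
#' @param out_dir optional directory; when given, CSV/JSON reports and a run
#'   manifest are written there.
#' @return A `report_bundle` list; see its names.
#' @export
run_demo_pipeline <- function(config = demo_config(), out_dir = NULL) {
  stage <- "configure"
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   completed = character(0))
  persist_manifest <- function() {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
  }
  on_fail <- function(e) {
    persist_manifest()
    ipcl_error(sprintf("demo pipeline failed at stage '%s': %s",
                       stage, conditionMessage(e)),
               "ipclversa_pipeline_error")
  }
  tryCatch({
    fx <- config$fixtures
    stage <- "simulate-images"
    train_set <- generate_shape_world(shape_world_spec(
      n_classes = fx$n_classes,
      n_instances_per_class = fx$n_instances_per_class,
      image_size = fx$image_size, seed = config$seed))
    cond_set <- generate_shape_world(shape_world_spec(
      n_classes = fx$n_classes,
      n_instances_per_class = fx$n_condition_instances_per_class,
      image_size = fx$image_size, seed = config$seed + 1L))
    manifest$completed <- c(manifest$completed, stage)

    stage <- "train-ipcl"
    bb_cfg <- do.call(backbone_config, config$backbone)
    ip_cfg <- do.call(ipcl_config, c(config$ipcl, list(seed = config$seed)))
    aug_cfg <- augment_config(output_size = bb_cfg$input_size)
    trained <- train_ipcl(train_set, bb_cfg, ip_cfg, aug_cfg)
    # matched control: same architecture at the trained model's initialization
    untrained <- with_seed(ip_cfg$seed, build_backbone(bb_cfg))
    manifest$completed <- c(manifest$completed, stage)

    stage <- "eval-knn"
    ro_cfg <- do.call(readout_config, config$readout)
    knn <- vapply(list(trained = trained$model, untrained = untrained),
                  function(m) {
      emb <- embed_image_set(m, train_set, aug_cfg)
      bank <- memory_bank(emb, train_set$labels)
      knn_accuracy(bank, bank, ro_cfg, exclude_self = TRUE)
    }, numeric(1))
    manifest$completed <- c(manifest$completed, stage)

    stage <- "extract-activations"
    cond_views <- lapply(cond_set$images, eval_view, config = aug_cfg)
    acts_trained <- extract_activations(trained$model, cond_views)
    acts_untrained <- extract_activations(untrained, cond_views)
    manifest$completed <- c(manifest$completed, stage)

    stage <- "simulate-subjects"
    gen_feats <- acts_trained[[fx$planted_layer]]
    if (is.null(gen_feats)) config_error("planted_layer not among extracted layers")
    subj_spec <- synthetic_subject_spec(
      gen_feats$matrix, n_subjects = fx$n_subjects,
      n_voxels_per_subject = fx$n_voxels_per_subject,
      weight_distribution = fx$weight_distribution,
      noise_sd = fx$noise_sd, seed = config$seed + 3L)
    world <- generate_synthetic_subjects(subj_spec)
    manifest$completed <- c(manifest$completed, stage)

    stage <- "versa"
    scheme <- enumerate_split_halves(fx$n_subjects,
                                     max_splits = config$versa$max_splits,
                                     seed = config$seed + 4L)
    versa_tr <- versa_curve(acts_trained, world$subjects, scheme,
                            unit_subsample = config$versa$unit_subsample,
                            subsample_seed = config$seed + 5L)
    versa_un <- versa_curve(acts_untrained, world$subjects, scheme,
                            unit_subsample = config$versa$unit_subsample,
                            subsample_seed = config$seed + 5L)
    classic_tr <- classic_rsa_curve(acts_trained, world$subjects, scheme)
    ceiling <- noise_ceiling(world$subjects, scheme)
    cvmax_tr <- cv_max_layer(versa_tr)
    cvmax_un <- cv_max_layer(versa_un)
    manifest$completed <- c(manifest$completed, stage)

    stage <- "compare"
    cmp <- corrected_paired_ttest(cvmax_tr$result$per_split_r,
                                  cvmax_un$result$per_split_r,
                                  correction_ratio = scheme$correction_ratio)
    explained <- explained_proportion(cvmax_tr$result, ceiling)
    manifest$completed <- c(manifest$completed, stage)

    bundle <- structure(list(
      config = config,
      history = trained$history,
      knn_top1 = knn,
      versa_trained = layer_curve_table(versa_tr),
      versa_untrained = layer_curve_table(versa_un),
      classic_trained = layer_curve_table(classic_tr),
      noise_ceiling = ceiling,
      cv_max_trained = cvmax_tr,
      cv_max_untrained = cvmax_un,
      comparison = cmp,
      explained_pct = explained
    ), class = "report_bundle")

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(bundle$history, file.path(out_dir, "history.csv"),
                       row.names = FALSE)
      utils::write.csv(bundle$versa_trained, file.path(out_dir, "versa_trained.csv"),
                       row.names = FALSE)
      utils::write.csv(bundle$versa_untrained,
                       file.path(out_dir, "versa_untrained.csv"), row.names = FALSE)
      utils::write.csv(bundle$classic_trained,
                       file.path(out_dir, "classic_trained.csv"), row.names = FALSE)
      ceil_df <- data.frame(mean_r = ceiling$mean_r, ci_low = ceiling$ci_low,
                            ci_high = ceiling$ci_high, n_splits = ceiling$n_splits)
      utils::write.csv(ceil_df, file.path(out_dir, "noise_ceiling.csv"),
                       row.names = FALSE)
      cv_df <- data.frame(
        model = c("trained", "untrained"),
        cv_max_r = c(cvmax_tr$result$mean_r, cvmax_un$result$mean_r),
        ci_low = c(cvmax_tr$result$ci_low, cvmax_un$result$ci_low),
        ci_high = c(cvmax_tr$result$ci_high, cvmax_un$result$ci_high),
        top_layer = c(names(which.max(cvmax_tr$selection_table)),
                      names(which.max(cvmax_un$selection_table))))
      utils::write.csv(cv_df, file.path(out_dir, "cv_max.csv"), row.names = FALSE)
      knn_df <- data.frame(model = names(knn), top1_percent = unname(knn))
      utils::write.csv(knn_df, file.path(out_dir, "knn.csv"), row.names = FALSE)
      cmp_df <- data.frame(t = cmp$t_statistic, p = cmp$p_value, J = cmp$J,
                           bonferroni_alpha = bonferroni_threshold(
                             config$stats$alpha, config$stats$m),
                           explained_pct = explained)
      utils::write.csv(cmp_df, file.path(out_dir, "comparison.csv"),
                       row.names = FALSE)
      persist_manifest()
    }
    bundle
  }, error = function(e) {
    if (inherits(e, "ipclversa_pipeline_error")) stop(e)
    on_fail(e)
  })
}

#' Write layer activations to a chunked binary cache
#'
#' One little-endian double binary per layer plus a JSON manifest recording
#' the model hash, image list and layer shapes.  Round-trips bit-exactly.
#'
#' @param path cache directory (created).
#' @param activations named list of `layer_activations`.
#' @param model_hash hash of the producing model ([model_hash()]).
#' @param image_ids condition/image identifiers, in row order.
#' @return Invisibly, `path`.
#' @export
write_activation_cache <- function(path, activations, model_hash = "",
                                   image_ids = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  image_ids <- image_ids %||% sprintf("img%05d", seq_len(nrow(activations[[1]]$matrix)))
  layers <- lapply(activations, function(a) {
    con <- file(file.path(path, paste0("layer_", a$layer_name, ".bin")), "wb")
    writeBin(as.vector(a$matrix), con, size = 8L, endian = "little")
    close(con)
    list(shape = dim(a$matrix))
  })
  names(layers) <- vapply(activations, `[[`, "", "layer_name")
  jsonlite::write_json(list(model_hash = model_hash, image_ids = image_ids,
                            endian = "little", layers = layers),
                       file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read layer activations back from a cache
#'
#' Validates the manifest against the expected model hash and image list;
#' a mismatch or a missing requested layer raises a cache-invalid error.
#'
#' @param path cache directory.
#' @param model_hash expected model hash (`NULL` skips the check).
#' @param image_ids expected image ids (`NULL` skips the check).
#' @param layers layer names to read (default: all in the manifest).
#' @return Named list of `layer_activations`.
#' @export
read_activation_cache <- function(path, model_hash = NULL, image_ids = NULL,
                                  layers = NULL) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) {
    ipcl_error("no cache manifest found", "ipclversa_cache_invalid_error")
  }
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!is.null(model_hash) && !identical(unname(mf$model_hash), unname(model_hash))) {
    ipcl_error("cache invalid: model hash mismatch", "ipclversa_cache_invalid_error")
  }
  if (!is.null(image_ids) && !identical(as.character(mf$image_ids),
                                        as.character(image_ids))) {
    ipcl_error("cache invalid: image list mismatch", "ipclversa_cache_invalid_error")
  }
  layers <- layers %||% names(mf$layers)
  missing <- setdiff(layers, names(mf$layers))
  if (length(missing)) {
    ipcl_error(sprintf("cache is missing layer(s): %s", paste(missing, collapse = ", ")),
               "ipclversa_cache_invalid_error")
  }
  out <- lapply(layers, function(nm) {
    shape <- unlist(mf$layers[[nm]]$shape)
    f <- file.path(path, paste0("layer_", nm, ".bin"))
    if (!file.exists(f)) {
      ipcl_error(sprintf("cache is missing layer(s): %s", nm),
                 "ipclversa_cache_invalid_error")
    }
    con <- file(f, "rb")
    v <- readBin(con, "double", n = prod(shape), size = 8L, endian = "little")
    close(con)
    structure(list(layer_name = nm, matrix = matrix(v, shape[1], shape[2]),
                   unit_count = shape[2]),
              class = "layer_activations")
  })
  stats::setNames(out, layers)
}
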