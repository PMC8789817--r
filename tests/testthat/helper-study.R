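# The shape-world study configuration shared by the emergent-category
# analyses in the test suite and by scripts/acceptance.R (which inlines the
# same settings; it cannot read test helpers).  Study-scale adaptations of
# the large-scale defaults (queue < dataset, milder crops/jitter, small
# momentum-free batches) are motivated in the methods vignette.

study_world_spec <- function(seed = 101L) {
  shape_world_spec(n_classes = 4L, n_instances_per_class = 100L,
                   image_size = 32L, seed = seed)
}

study_augment_config <- function() {
  augment_config(output_size = 32L, crop_scale_range = c(0.6, 1),
                 grayscale_probability = 0,
                 jitter_strengths = list(brightness = 0.3, contrast = 0.3,
                                         saturation = 0.3, hue = 0.05))
}

study_backbone_config <- function() {
  backbone_config("tiny_gn", embedding_dim = 64L)
}

study_ipcl_config <- function(seed = 7L) {
  ipcl_config(epochs = 30L, batch_instances = 8L, queue_capacity = 256L,
              lr = 0.03, momentum = 0, weight_decay = 1e-4,
              lr_schedule = "constant", seed = seed)
}
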