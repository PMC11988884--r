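# Shared toy-scale fixtures, built in code at test time.

toy_backbone_config <- function(...) {
  defaults <- list(image_size = 32L, patch_size = 16L, channels = 1L,
                   embed_dim = 8L, depth = 2L, n_heads = 2L,
                   feature_dim = 10L)
  do.call(backbone_config, utils::modifyList(defaults, list(...)))
}

# Small synthetic-feet experiment: toy backbone features for a grouped CV.
toy_feet_features <- function(seed = 7, n_patients = 60,
                              class_angle_means = c(pes_planus = 10,
                                                    not_pes_planus = 26)) {
  scfg <- synthetic_config(n_patients = n_patients, image_size = 32L,
                           class_angle_means = class_angle_means, seed = seed)
  data <- gen_dataset(scfg)
  bcfg <- backbone_config(image_size = 32L, patch_size = 8L, channels = 1L,
                          embed_dim = 32L, depth = 2L, n_heads = 4L,
                          feature_dim = 64L, seed = seed)
  extract_features(data, init_backbone(bcfg, seed = seed), bcfg)
}

# The five per-fold test-set confusion matrices reported for the real
# radiograph experiment, and the pooled matrix.
reported_fold_counts <- function() {
  tibble::tribble(
    ~fold, ~tp, ~fn, ~fp, ~tn,
    1L, 39L, 2L, 1L, 40L,
    2L, 41L, 0L, 1L, 40L,
    3L, 41L, 0L, 1L, 40L,
    4L, 40L, 1L, 1L, 40L,
    5L, 40L, 1L, 0L, 41L
  )
}

reported_table1 <- function() {
  tibble::tribble(
    ~fold, ~accuracy, ~sensitivity, ~specificity, ~precision, ~f1,
    1L, 96.34, 95.12, 97.56, 97.50, 96.29,
    2L, 98.78, 100, 98.78, 97.61, 98.79,
    3L, 98.78, 100, 98.78, 97.61, 98.79,
    4L, 97.56, 97.56, 97.56, 97.56, 97.55,
    5L, 98.78, 97.56, 100, 100, 98.76
  )
}

expect_vitelm_error <- function(expr, class) {
  expect_error(expr, class = paste0("vitelm_", class))
}
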