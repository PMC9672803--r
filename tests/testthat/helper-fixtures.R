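# Fixtures built in code: small synthetic datasets and rigged networks.

# High-contrast, low-noise study conditions used for desk-scale learning
# checks: 10 cases of 48^3 voxels at 1 mm with three 2.5-4.5 mm new lesions.
easy_sim_params <- function(seed = 123L) {
  sim_params(volume_shape = c(48L, 48L, 48L), voxel_size_mm = 1,
             n_stable_lesions = 2L, n_new_lesions = 3L,
             new_lesion_radius_range_mm = c(2.5, 4.5),
             lesion_contrast = 8, noise_sd = 0.02, seed = seed)
}

easy_cases <- function(n = 10L, seed = 123L) {
  p <- easy_sim_params(seed)
  lapply(seq_len(n) - 1L, function(i) generate_case(p, i))
}

# Reduced network used for CPU-scale training runs: tiny filter counts, a
# 16-voxel patch, the output bias at the positive-class prior log-odds, and
# a learning-rate schedule scaled up to compensate for the short run.
reduced_spec <- function() {
  unet_spec(base_filters = c(2L, 4L, 8L), groups_per_norm = 2L,
            patch_size = 16L, head_bias = -3)
}

reduced_train_config <- function(strategy, iters = 500L, seed = 7L, ...) {
  train_config(strategy, total_iterations = iters, patch_size = 16L,
               lr_values = c(3e-2, 3e-3, 3e-4), val_every = 100L,
               seed = seed, ...)
}

tiny_spec <- function(patch = 8L) {
  unet_spec(base_filters = c(2L, 4L, 8L), groups_per_norm = 2L,
            patch_size = patch)
}

# A network whose every parameter is zero emits logit 0 (probability 1/2)
# for any input.
constant_logit_net <- function(spec = unet_spec()) {
  net <- build_unet(spec, seed = 0L)
  net$params <- lapply(net$params, function(p) p * 0)
  net
}

# Small cases for sampler/training unit tests: 24^3 with one or two lesions.
tiny_cases <- function(n = 3L, seed = 5L, n_new = 1L) {
  p <- sim_params(volume_shape = c(24L, 24L, 24L), voxel_size_mm = 1,
                  n_stable_lesions = 0L, n_new_lesions = n_new,
                  new_lesion_radius_range_mm = c(2, 3),
                  lesion_contrast = 8, noise_sd = 0.02, seed = seed)
  lapply(seq_len(n) - 1L, function(i) generate_case(p, i))
}

smooth_volume <- function(shape = c(20L, 20L, 20L), voxel = 1, seed = 3L) {
  set.seed(seed)
  g <- lesionminer:::smooth_field(shape, sigma = 3)
  volume3d(1 + 0.2 * g, voxel_size_mm = voxel)
}
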