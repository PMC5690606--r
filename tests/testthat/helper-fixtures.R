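# Shared fixtures for the test suite. Everything is generated in code; the
# default ground truth mirrors the developmental hierarchy the generator is
# meant to emulate (V1 maturing before extrastriate areas, null form signal).

default_truth <- function(sr_dmax = 0) {
  ground_truth(
    voi_params = list("V1"    = list(dmax = 6, a_half = 12, n = 2),
                      "V4"    = list(dmax = 6, a_half = 28, n = 2),
                      "MT-V5" = list(dmax = 6, a_half = 28, n = 2)),
    contrast_params = list(
      structured_vs_random = list(dmax = sr_dmax, a_half = 20, n = 2)))
}

glass_conditions <- c("concentric_static", "radial_static", "random_static",
                      "concentric_dynamic", "radial_dynamic", "random_dynamic")

# A small fast session (few cycles, few voxels) for unit tests.
tiny_session <- function(age = 30, seed = 1, n_cycles = 4, n_voxels = 20,
                         noise_sd = 1, truth = default_truth()) {
  sched <- build_palindromic_schedule(glass_conditions, 36, 24, n_cycles)
  cfg <- session_config(age = age, n_voxels = n_voxels, noise_sd = noise_sd,
                        seed = seed)
  glass <- simulate_run(cfg, truth, sched)
  pin_cfg <- cfg
  pin_cfg$seed <- seed + 1000
  pin <- simulate_run(pin_cfg, truth, build_pinwheel_schedule(576))
  list(age = age, glass = glass, pinwheel = pin)
}

# Synthetic pattern matrix with a controllable class separation.
make_patterns <- function(n_pairs = 16, n_vox = 20, sep = 0, seed = 1,
                          contrast = "test") {
  set.seed(seed)
  xa <- matrix(rnorm(n_pairs * n_vox), n_pairs, n_vox)
  xb <- matrix(rnorm(n_pairs * n_vox), n_pairs, n_vox)
  xa[, 1:max(1, floor(n_vox / 2))] <- xa[, 1:max(1, floor(n_vox / 2))] + sep
  structure(list(x = rbind(xa, xb), y = rep(c("a", "b"), each = n_pairs),
                 pair = rep(seq_len(n_pairs), 2), n = 2 * n_pairs,
                 contrast = contrast),
            class = "pattern_matrix")
}
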