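# shared small fixtures, built in code

# compact fMRI-like session: n blocks per text, one run
small_fmri_design <- function(n_blocks_per_text = 3, seed = 5) {
  build_fmri_design(
    design_params("fmri", n_blocks_per_text = n_blocks_per_text,
                  n_runs = 1L),
    seed = seed
  )
}

small_geometry <- function(nr = 12, nc = 12, spacing = 2) {
  make_roi_geometry(c(nr, nc), spacing_mm = spacing)
}

# standard mask layout on the 12 x 12 grid: decoding ROI in the first
# 100 vertices with a sparse planted pattern, seed and PPI target outside
small_masks <- function() {
  list(roi = 1:100, pattern = seq(5, 95, by = 5), seed = 101:110,
       target = 120:130)
}

# a single-subject noise-free percept-patterned dataset plus its betas
make_noiseless_subject <- function(design, geometry, masks,
                                   effect_amplitude = 1, noise_sd = 0,
                                   ppi_gain = 0, hrf_peak = 3.7,
                                   seed = 3, behavior_seed = 2,
                                   ar1 = 0) {
  bp <- behavior_gen_params(
    reference_fixed_effects("scanner"),
    random_sd = c("(Intercept)" = 0.5, "E" = 0.5, "S" = 0.5),
    n_subjects = 1
  )
  beh <- simulate_behavior(design, bp, seed = behavior_seed)
  prm <- bold_gen_params(
    geometry, masks$roi, masks$seed, masks$target, masks$pattern,
    effect_amplitude = effect_amplitude, noise_sd = noise_sd,
    ar1_coef = ar1, hrf_peak = hrf_peak, ppi_coupling_gain = ppi_gain
  )
  ds <- simulate_bold(design, beh, prm, seed = seed)
  list(behavior = beh, params = prm, dataset = ds)
}

# light decoding configuration for fast tests
fast_decode_config <- function(...) {
  decode_config(n_balanced_datasets = 2L, k_folds = 2L, rfe_levels = 3L,
                rfe_splits = 6L, splits_per_level = 2L, smoothing_sd = 4,
                n_permutations = 5L, ...)
}
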