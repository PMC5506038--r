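test_that("double-gamma kernel is peak-normalized with an undershoot", {
  spec <- hrf_spec()
  h <- double_gamma_hrf(spec)
  expect_equal(max(h), 1)
  expect_lt(min(h), 0) # negative undershoot lobe
  expect_gt(attr(h, "times")[which.min(h)], attr(h, "times")[which.max(h)])
  # time-to-peak adjustment places the argmax on the requested latency
  for (tp in c(3.2, 3.7, 4.2)) {
    ha <- double_gamma_hrf(spec, t_peak = tp)
    expect_equal(attr(ha, "times")[which.max(ha)], tp, tolerance = 0.1)
  }
  expect_error(double_gamma_hrf(spec, t_peak = 5), "search range")
  expect_length(peak_search_grid(spec), 11)
})

test_that("design matrix has block, single-trial and constant columns", {
  d <- build_fmri_design(design_params("fmri"), seed = 1)
  n_tp <- ceiling(d$duration / 2)
  X <- build_design_matrix(d, hrf_spec(), n_tp, 2)
  expect_equal(ncol(X), 2 + 144 + 1)
  expect_equal(colnames(X)[1:2], c("exposure_aba", "exposure_ada"))
  expect_true(all(X[, "constant"] == 1))
  # empty design -> intercept only
  d0 <- build_psychophysical_design(
    design_params("psychophysical", n_blocks_per_text = 0), seed = 1)
  expect_equal(ncol(build_design_matrix(d0, hrf_spec(), 10, 2)), 1)
  # onset beyond the scan is rejected
  expect_error(build_design_matrix(d, hrf_spec(), 10, 2), "beyond the scan")
})

test_that("well-separated trials give nearly orthogonal trial columns", {
  d <- small_fmri_design(n_blocks_per_text = 2)
  n_tp <- ceiling(d$duration / 2)
  X <- build_design_matrix(d, hrf_spec(), n_tp, 2)
  tc <- grep("^trial_", colnames(X))[1:2]
  expect_lt(abs(cor(X[, tc[1]], X[, tc[2]])), 0.2)
})

test_that("trial betas and time-to-peak recover noiseless generating values", {
  d <- small_fmri_design()
  g <- small_geometry()
  m <- small_masks()
  s <- make_noiseless_subject(d, g, m, hrf_peak = 3.7)
  tb <- estimate_trial_betas(s$dataset, d)
  expect_true(all(tb$fitted_peak[m$pattern] == 3.7))
  sign_pc <- ifelse(s$behavior$response == 1, 1, -1)
  expected <- outer(sign_pc, s$params$pattern_weights)
  expect_equal(tb$beta[, m$pattern], expected, tolerance = 1e-6,
               ignore_attr = TRUE)
  # per-vertex random latencies are recovered too
  s2 <- make_noiseless_subject(d, g, m, hrf_peak = NULL, seed = 12)
  tb2 <- estimate_trial_betas(s2$dataset, d)
  expect_equal(tb2$fitted_peak[m$pattern],
               s2$dataset$hrf_peak[m$pattern])
})

test_that("all-zero data give all-zero betas and scaling is equivariant", {
  d <- small_fmri_design(n_blocks_per_text = 2)
  g <- make_roi_geometry(c(4, 4))
  n_tp <- ceiling(d$duration / 2)
  Y0 <- matrix(0, g$n_vertices, n_tp)
  attr(Y0, "tr") <- 2
  tb0 <- estimate_trial_betas(Y0, d)
  expect_true(all(tb0$beta == 0))
  m <- small_masks()
  s <- make_noiseless_subject(d, small_geometry(), m)
  Y <- s$dataset$data
  attr(Y, "tr") <- 2
  tb1 <- estimate_trial_betas(Y, d)
  Y3 <- Y * 3
  attr(Y3, "tr") <- 2
  tb3 <- estimate_trial_betas(Y3, d)
  expect_equal(tb3$beta, 3 * tb1$beta, tolerance = 1e-8)
})

test_that("noise-only betas have zero mean within sampling error", {
  d <- small_fmri_design(n_blocks_per_text = 2)
  g <- make_roi_geometry(c(3, 3))
  m <- list(roi = 1:4, pattern = 1:2, seed = 5:6, target = 7:8)
  bp <- bold_gen_params(g, m$roi, m$seed, m$target, m$pattern,
                        effect_amplitude = 0, exposure_amplitude = 0,
                        noise_sd = 1, ar1_coef = 0.3, hrf_peak = 3.7)
  beh <- simulate_behavior(
    d, behavior_gen_params(c("(Intercept)" = 0), n_subjects = 1), seed = 1)
  ds <- simulate_bold(d, beh, bp, seed = 2)
  tb <- estimate_trial_betas(ds, d)
  mb <- colMeans(tb$beta)
  se <- apply(tb$beta, 2, sd) / sqrt(nrow(tb$beta))
  expect_true(all(abs(mb) < 3.5 * se))
})

test_that("RFX t map matches hand computation and flags zero variance", {
  maps <- matrix(rep(1:6, 3), nrow = 6) # map value = subject index
  r <- rfx_ttest_map(maps)
  expect_equal(r$t, rep(mean(1:6) / (sd(1:6) / sqrt(6)), 3))
  same <- matrix(2, nrow = 4, ncol = 2)
  rz <- rfx_ttest_map(same)
  expect_true(all(rz$zero_variance))
  expect_equal(rz$p, c(0, 0))
  zero <- matrix(0, nrow = 4, ncol = 2)
  expect_equal(rfx_ttest_map(zero)$p, c(1, 1))
  # null calibration: ~5% of vertices below p = .05
  withr::with_seed(1, {
    null_maps <- matrix(rnorm(15 * 4000), nrow = 15)
  })
  pr <- mean(rfx_ttest_map(null_maps)$p < 0.05)
  expect_lt(abs(pr - 0.05), 0.015)
})

test_that("smoothness estimator inverts Gaussian smoothing", {
  g <- make_roi_geometry(c(80, 80), spacing_mm = 2)
  withr::with_seed(3, {
    maps <- t(replicate(4, smooth_vertex_map(rnorm(g$n_vertices), g, 4)))
  })
  fwhm <- estimate_smoothness_fwhm(maps, g)
  expect_equal(fwhm, 4 * 2 * sqrt(2 * log(2)), tolerance = 0.15)
})

test_that("cluster correction finds planted effects and respects thresholds", {
  g <- make_roi_geometry(c(30, 30), spacing_mm = 2)
  cfg <- cluster_config(p_vertex = 0.005, n_iterations = 400,
                        smoothness_fwhm = 6)
  # sub-threshold map everywhere -> no clusters
  r0 <- cluster_size_correct(rep(0.5, g$n_vertices), g, cfg, seed = 1)
  expect_equal(nrow(r0$clusters), 0)
  expect_gt(r0$min_cluster_size, 1)
  # planted 10 x 10 vertex block (400 mm^2) of tiny p values survives
  p_map <- rep(0.5, g$n_vertices)
  block <- as.vector(outer(5:14, (10:19 - 1) * 30, "+"))
  p_map[block] <- 1e-6
  r1 <- cluster_size_correct(p_map, g, cfg, seed = 1)
  expect_equal(nrow(r1$clusters), 1)
  expect_equal(r1$clusters$area_mm2, 400)
  # stricter primary threshold -> smaller minimum cluster size
  cfg2 <- cluster_config(p_vertex = 0.001, n_iterations = 400,
                         smoothness_fwhm = 6)
  r2 <- cluster_size_correct(rep(0.5, g$n_vertices), g, cfg2, seed = 1)
  expect_lte(r2$min_cluster_size, r0$min_cluster_size)
})

test_that("connected components follow 4-neighbor lattice adjacency", {
  g <- make_roi_geometry(c(5, 5))
  # vertices 1,2 adjacent (same column), 1 and 6 adjacent (same row);
  # 13 isolated; 21:23 a column-run in the last column? indices column-major
  comp <- connected_components(c(1, 2, 6, 13, 21, 22, 23), g)
  expect_equal(length(unique(comp)), 3)
  expect_equal(comp[1], comp[2])
  expect_equal(comp[1], comp[3])
  expect_equal(length(unique(comp[5:7])), 1)
})
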