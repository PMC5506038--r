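test_that("seed time course extraction z-scores and handles degeneracy", {
  Y <- rbind(sin(1:50), -sin(1:50), cos(1:50))
  stc <- extract_seed_timecourse(Y, 3)
  expect_equal(mean(stc), 0)
  expect_equal(sd(stc), 1)
  # cancellation: opposite series average to a constant -> flagged zeros
  z <- extract_seed_timecourse(Y, 1:2)
  expect_true(all(z == 0))
  expect_true(attr(z, "constant"))
  expect_error(extract_seed_timecourse(Y, integer(0)), "mask error")
  expect_error(extract_seed_timecourse(Y, 99), "mask error")
})

test_that("PPI regressor is the elementwise product of z-scored factors", {
  base <- cbind(constant = rep(1, 4))
  seed_tc <- c(1, -1, 1, -1)
  task <- c(1, 1, -1, -1)
  X <- build_ppi_design(base, seed_tc, task)
  zs <- (seed_tc - mean(seed_tc)) / sd(seed_tc)
  zt <- (task - mean(task)) / sd(task)
  expect_equal(unname(X[, "ppi"]), zs * zt)
  expect_equal(mean(X[, "seed"]), 0)
  expect_equal(sd(X[, "seed"]), 1)
  expect_equal(attr(X, "ppi_column"), ncol(X))
  # all-zero task -> all-zero interaction
  X0 <- build_ppi_design(base, seed_tc, rep(0, 4))
  expect_true(all(X0[, "ppi"] == 0))
  expect_error(build_ppi_design(base, seed_tc[1:2], task), "design error")
})

test_that("PPI beta recovers a noiseless planted coupling gain exactly", {
  d <- small_fmri_design()
  g <- small_geometry()
  m <- small_masks()
  s <- make_noiseless_subject(d, g, m, ppi_gain = 0.8)
  ds <- s$dataset
  n_tp <- ncol(ds$data)
  X <- build_design_matrix(d, hrf_spec(), n_tp, ds$tr)
  task <- exposure_task_regressor(d, hrf_spec(), n_tp, ds$tr)
  Xp <- build_ppi_design(X, extract_seed_timecourse(ds, m$seed), task)
  fit <- fit_ppi_glm(ds, Xp)
  expect_equal(fit$ppi_beta[m$target], rep(0.8, length(m$target)),
               tolerance = 1e-6)
  # invariance to rescaling the raw seed series
  ds2 <- ds
  ds2$data[m$seed, ] <- ds2$data[m$seed, ] * 7
  Xp2 <- build_ppi_design(X, extract_seed_timecourse(ds2, m$seed), task)
  fit2 <- fit_ppi_glm(ds2, Xp2)
  expect_equal(fit2$ppi_beta[m$target], fit$ppi_beta[m$target],
               tolerance = 1e-8)
})

test_that("zero coupling gain keeps target PPI t statistics at null levels", {
  d <- small_fmri_design(n_blocks_per_text = 2)
  g <- make_roi_geometry(c(6, 6))
  m <- list(roi = 1:10, pattern = 1:4, seed = 11:14, target = 20:24)
  bp <- behavior_gen_params(c("(Intercept)" = 0), n_subjects = 1)
  beh <- simulate_behavior(d, bp, seed = 1)
  tvals <- vapply(1:25, function(r) {
    prm <- bold_gen_params(g, m$roi, m$seed, m$target, m$pattern,
                           effect_amplitude = 0.5, noise_sd = 0.7,
                           ar1_coef = 0.3, hrf_peak = 3.7,
                           ppi_coupling_gain = 0)
    ds <- simulate_bold(d, beh, prm, seed = 100 + r)
    n_tp <- ncol(ds$data)
    X <- build_design_matrix(d, hrf_spec(), n_tp, ds$tr)
    task <- exposure_task_regressor(d, hrf_spec(), n_tp, ds$tr)
    Xp <- build_ppi_design(X, extract_seed_timecourse(ds, m$seed), task)
    mean(abs(fit_ppi_glm(ds, Xp)$ppi_t[m$target]))
  }, numeric(1))
  expect_gte(mean(tvals < 3), 0.95)
})

test_that("dropping the seed main effect inflates the PPI beta", {
  d <- small_fmri_design(n_blocks_per_text = 2)
  g <- make_roi_geometry(c(6, 6))
  m <- list(roi = 1:10, pattern = 1:4, seed = 11:14, target = 20:24)
  bp <- behavior_gen_params(c("(Intercept)" = 0), n_subjects = 1)
  beh <- simulate_behavior(d, bp, seed = 1)
  prm <- bold_gen_params(g, m$roi, m$seed, m$target, m$pattern,
                         effect_amplitude = 0.5, noise_sd = 0.05,
                         ar1_coef = 0.2, hrf_peak = 3.7,
                         ppi_coupling_gain = 0.5)
  ds <- simulate_bold(d, beh, prm, seed = 9)
  # make the target track the seed outside exposure too (correlated mains)
  ds$data[m$target, ] <- ds$data[m$target, ] +
    rep(2 * scale(colMeans(ds$data[m$seed, ]))[, 1],
        each = length(m$target))
  n_tp <- ncol(ds$data)
  X <- build_design_matrix(d, hrf_spec(), n_tp, ds$tr)
  task <- exposure_task_regressor(d, hrf_spec(), n_tp, ds$tr)
  stc <- extract_seed_timecourse(ds, m$seed)
  X_full <- build_ppi_design(X, stc, task)
  X_nomain <- X_full[, colnames(X_full) != "seed", drop = FALSE]
  attr(X_nomain, "ppi_column") <- ncol(X_nomain)
  b_full <- mean(fit_ppi_glm(ds, X_full)$ppi_beta[m$target])
  b_nomain <- mean(fit_ppi_glm(ds, X_nomain)$ppi_beta[m$target])
  expect_gt(abs(b_nomain - 0.5), abs(b_full - 0.5))
})

test_that("group PPI analysis detects a planted gain across subjects", {
  d <- small_fmri_design(n_blocks_per_text = 2)
  g <- make_roi_geometry(c(10, 10))
  m <- list(roi = 1:10, pattern = 1:4, seed = 31:34, target = 61:70)
  bp <- behavior_gen_params(c("(Intercept)" = 0), n_subjects = 1)
  beh <- simulate_behavior(d, bp, seed = 1)
  betas <- t(vapply(1:8, function(s) {
    prm <- bold_gen_params(g, m$roi, m$seed, m$target, m$pattern,
                           effect_amplitude = 0.5, noise_sd = 0.4,
                           ar1_coef = 0.2, hrf_peak = 3.7,
                           ppi_coupling_gain = 0.6)
    ds <- simulate_bold(d, beh, prm, seed = 500 + s)
    n_tp <- ncol(ds$data)
    X <- build_design_matrix(d, hrf_spec(), n_tp, ds$tr)
    task <- exposure_task_regressor(d, hrf_spec(), n_tp, ds$tr)
    Xp <- build_ppi_design(X, extract_seed_timecourse(ds, m$seed), task)
    fit_ppi_glm(ds, Xp)$ppi_beta
  }, numeric(g$n_vertices)))
  res <- ppi_group_map(betas, g,
                       cluster_config(p_vertex = 0.005, n_iterations = 300,
                                      smoothness_fwhm = 4), seed = 2)
  surv <- unlist(lapply(seq_len(nrow(res$correction$clusters)), function(j) {
    which(res$rfx$p < 0.005)
  }))
  expect_gt(nrow(res$correction$clusters), 0)
  expect_true(any(m$target %in% surv))
})
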