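#' HRF-convolved audiovisual exposure task regressor
#'
#' The psychological variable of the PPI model: an indicator of the
#' audiovisual exposure trials (both text types) convolved with the
#' double-gamma kernel and sampled at the TR grid. The z-scoring order is
#' configurable: `"after_convolution"` (default) convolves the raw event
#' indicator, `"before_convolution"` z-scores the TR-sampled indicator
#' first; in both cases the regressor is z-scored again before entering
#' the interaction product.
#'
#' @param design a `session_design`.
#' @param spec an `hrf_spec`.
#' @param n_timepoints number of volumes.
#' @param tr repetition time (s).
#' @param zscore_order when to z-score relative to convolution.
#'
#' @return Numeric regressor of length `n_timepoints`.
#' @export
exposure_task_regressor <- function(design, spec, n_timepoints, tr,
                                    zscore_order = c("after_convolution",
                                                     "before_convolution")) {
  zscore_order <- match.arg(zscore_order)
  times <- (seq_len(n_timepoints) - 1L) * tr
  onsets <- design$exposures$onset
  if (zscore_order == "after_convolution") {
    col <- numeric(n_timepoints)
    for (o in onsets) col <- col + hrf_eval(spec, times - o)
    return(col)
  }
  ind <- numeric(n_timepoints)
  for (o in onsets) {
    ind[which.min(abs(times - o))] <- ind[which.min(abs(times - o))] + 1
  }
  ind <- zscore_vec(ind)
  kern <- hrf_eval(spec, seq(0, spec$duration, by = tr))
  as.numeric(stats::filter(c(ind, numeric(length(kern))), kern,
                           method = "convolution", sides = 1))[
                             seq_len(n_timepoints)]
}

#' Extract the z-scored seed time course
#'
#' Spatial mean over the seed vertices, z-scored over time. A constant
#' (zero-variance) mean series is degenerate for z-scoring and returns a
#' flagged zero vector.
#'
#' @param data a `bold_dataset` or vertex x time matrix.
#' @param seed_mask integer vertex indices of the seed region.
#'
#' @return Numeric z-scored vector over time, with attribute `constant`.
#' @export
extract_seed_timecourse <- function(data, seed_mask) {
  Y <- if (inherits(data, "bold_dataset")) data$data else as.matrix(data)
  if (length(seed_mask) == 0) stop("mask error: seed_mask is empty")
  if (any(seed_mask < 1 | seed_mask > nrow(Y))) {
    stop("mask error: seed_mask outside the data grid")
  }
  m <- colMeans(Y[seed_mask, , drop = FALSE])
  out <- zscore_vec(m)
  attr(out, "constant") <- sd(m) == 0
  out
}

#' Append seed and psychophysiological-interaction predictors
#'
#' Builds the PPI design: the base first-level design matrix plus a
#' z-scored seed time-course predictor and the interaction predictor
#' `z(seed) * z(task)`. Both factors have mean 0 and SD 1 before the
#' product, and the base task (exposure) predictors are retained so the
#' interaction explains variance beyond the exposure-block responses
#' themselves.
#'
#' @param base_design base design matrix (see [build_design_matrix()]).
#' @param seed_tc seed time course (z-scored or raw; re-z-scored here).
#' @param task_regressor HRF-convolved exposure indicator
#'   (see [exposure_task_regressor()]).
#'
#' @return The design matrix with columns `seed` and `ppi` appended
#'   (`ppi` last); attribute `ppi_column` holds its index.
#' @export
build_ppi_design <- function(base_design, seed_tc, task_regressor) {
  n <- nrow(base_design)
  if (length(seed_tc) != n || length(task_regressor) != n) {
    stop("design error: seed/task length does not match the design matrix")
  }
  zs <- zscore_vec(as.numeric(seed_tc))
  zt <- zscore_vec(as.numeric(task_regressor))
  X <- cbind(base_design, seed = zs, ppi = zs * zt)
  attr(X, "ppi_column") <- ncol(X)
  X
}

#' Fit the PPI GLM per vertex
#'
#' Least-squares fit of the PPI design to every vertex time course,
#' returning the interaction (PPI) beta per vertex. Group inference runs
#' the per-subject beta maps through [rfx_ttest_map()] and
#' [cluster_size_correct()].
#'
#' @param data a `bold_dataset` or vertex x time matrix.
#' @param ppi_design design matrix from [build_ppi_design()].
#' @param keep_residuals return the residual maps (for smoothness
#'   estimation)?
#'
#' @return List with `ppi_beta` (per vertex), `ppi_t`, `resid_var`, and
#'   optionally `residuals` (vertex x time).
#' @export
fit_ppi_glm <- function(data, ppi_design, keep_residuals = FALSE) {
  Y <- if (inherits(data, "bold_dataset")) data$data else as.matrix(data)
  X <- ppi_design
  if (ncol(Y) != nrow(X)) stop("design error: time axes do not match")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    cc <- cor(X)
    diag(cc) <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    stop("design error: PPI design is rank deficient; most collinear pair: ",
         colnames(X)[worst[1]], " and ", colnames(X)[worst[2]])
  }
  coefs <- qr.coef(qx, t(Y)) # p x vertex
  res <- t(Y) - X %*% coefs
  dfree <- nrow(X) - ncol(X)
  rvar <- colSums(res^2) / dfree
  j <- attr(X, "ppi_column")
  xtxinv_jj <- chol2inv(qr.R(qx))[j, j]
  ppi_beta <- coefs[j, ]
  ppi_se <- sqrt(rvar * xtxinv_jj)
  out <- list(ppi_beta = unname(ppi_beta),
              ppi_t = unname(ppi_beta / ppi_se),
              resid_var = unname(rvar))
  if (keep_residuals) out$residuals <- t(res)
  out
}

#' Group PPI map with cluster-size correction
#'
#' One-sample t test of per-subject PPI beta maps across subjects, followed
#' by Monte Carlo cluster-size correction at the configured primary
#' threshold.
#'
#' @param beta_maps subject x vertex matrix of PPI betas.
#' @param geometry an `roi_geometry`.
#' @param config a `cluster_config`.
#' @param resid_maps optional maps for smoothness estimation (defaults to
#'   the demeaned subject beta maps).
#' @param seed Monte Carlo seed.
#'
#' @return List with `rfx` (see [rfx_ttest_map()]) and `correction`
#'   (see [cluster_size_correct()]).
#' @export
ppi_group_map <- function(beta_maps, geometry, config = cluster_config(),
                          resid_maps = NULL, seed = 1L) {
  rfx <- rfx_ttest_map(beta_maps)
  if (is.null(config$smoothness_fwhm) && is.null(resid_maps)) {
    resid_maps <- sweep(as.matrix(beta_maps), 2, rfx$mean)
  }
  corr <- cluster_size_correct(rfx$p, geometry, config, stat_map = rfx$t,
                               resid_maps = resid_maps, seed = seed)
  list(rfx = rfx, correction = corr)
}
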