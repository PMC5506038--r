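#' First-level design matrix with single-trial post-test predictors
#'
#' Builds the design matrix of the first-level GLM: one predictor per
#' audiovisual exposure block type ('aba'/'ada' text; each exposure trial
#' contributes a unit impulse), one single-trial predictor per auditory
#' post-test trial, and a constant. All event predictors are the
#' double-gamma kernel evaluated at the volume acquisition times.
#'
#' @param design a `session_design`.
#' @param spec an `hrf_spec`.
#' @param n_timepoints number of volumes.
#' @param tr repetition time (s).
#' @param t_peak optional kernel time-to-peak (s); default canonical.
#'
#' @return Numeric matrix `n_timepoints x (2 + n_posttests + 1)` (block
#'   columns are dropped when a block type has no events) with column names
#'   `exposure_aba`, `exposure_ada`, `trial_0001`, ..., `constant`.
#' @export
build_design_matrix <- function(design, spec, n_timepoints, tr,
                                t_peak = NULL) {
  stopifnot(inherits(design, "session_design"), inherits(spec, "hrf_spec"))
  times <- (seq_len(n_timepoints) - 1L) * tr
  scan_end <- times[n_timepoints]
  onsets <- c(design$exposures$onset, design$posttests$onset)
  if (length(onsets) > 0 && max(onsets) > scan_end) {
    stop("design error: event onset ", max(onsets),
         " s lies beyond the scan end (", scan_end, " s)")
  }
  reg <- function(onset_vec) {
    col <- numeric(n_timepoints)
    for (o in onset_vec) {
      col <- col + hrf_eval(spec, times - o, t_peak)
    }
    col
  }
  cols <- list()
  for (text in c("aba", "ada")) {
    on <- design$exposures$onset[design$exposures$exposure_text == text]
    if (length(on) > 0) cols[[paste0("exposure_", text)]] <- reg(on)
  }
  pt <- design$posttests
  for (i in seq_len(nrow(pt))) {
    cols[[sprintf("trial_%04d", i)]] <- reg(pt$onset[i])
  }
  cols[["constant"]] <- rep(1, n_timepoints)
  do.call(cbind, cols)
}

#' Estimate single-trial response amplitudes with time-to-peak adjustment
#'
#' Per vertex, searches the time-to-peak grid of the double-gamma kernel
#' (default 3.2--4.2 s in 0.1 s steps): for each candidate peak the full
#' design matrix is refit by least squares, the latency minimizing the
#' residual sum of squares is selected, and the trial betas under that
#' kernel are returned. Betas are in the units of the data (percent signal
#' if the data are).
#'
#' @param data a `bold_dataset` (see [simulate_bold()]) or a vertex x time
#'   matrix with attribute `tr`.
#' @param design the `session_design` the data were acquired under.
#' @param spec an `hrf_spec`.
#'
#' @return An object of class `trial_betas`: list with `beta` (trial x
#'   vertex matrix, rows ordered as `design$posttests`), `fitted_peak`
#'   (seconds per vertex), `resid_var`, `peak_grid`.
#' @export
estimate_trial_betas <- function(data, design, spec = hrf_spec()) {
  if (inherits(data, "bold_dataset")) {
    Y <- data$data
    tr <- data$tr
  } else {
    Y <- data
    tr <- attr(data, "tr")
    if (is.null(tr)) stop("data must carry a tr attribute")
  }
  n_tp <- ncol(Y)
  n_vtx <- nrow(Y)
  grid <- peak_search_grid(spec)
  n_trials <- nrow(design$posttests)
  Yt <- t(Y) # time x vertex
  best_rss <- rep(Inf, n_vtx)
  best_peak <- rep(NA_real_, n_vtx)
  best_beta <- matrix(NA_real_, n_trials, n_vtx)
  trial_rows <- NULL
  for (p in grid) {
    X <- build_design_matrix(design, spec, n_tp, tr, t_peak = p)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      keep <- qx$pivot[seq_len(qx$rank)]
      bad <- setdiff(colnames(X), colnames(X)[keep])
      stop("estimation error: design matrix is rank deficient; collinear ",
           "column(s): ", paste(bad, collapse = ", "))
    }
    coefs <- qr.coef(qx, Yt) # p x vertex
    rss <- colSums((Yt - X %*% coefs)^2)
    if (is.null(trial_rows)) {
      trial_rows <- grep("^trial_", colnames(X))
    }
    upd <- rss < best_rss - 1e-12
    if (any(upd)) {
      best_rss[upd] <- rss[upd]
      best_peak[upd] <- p
      best_beta[, upd] <- coefs[trial_rows, upd, drop = FALSE]
    }
  }
  dfree <- n_tp - (if (n_trials > 0) max(trial_rows) else 1L)
  structure(
    list(
      beta = best_beta, fitted_peak = best_peak,
      resid_var = best_rss / max(dfree, 1L), peak_grid = grid
    ),
    class = "trial_betas"
  )
}

#' Random-effects one-sample t map across subjects
#'
#' Per vertex, tests the subject-level estimates against zero with a
#' one-sample t statistic (subjects as random effects). Vertices with zero
#' between-subject variance are flagged: the sentinel p is 0 when the
#' common value is nonzero and 1 when it is zero, and the t value is NA.
#'
#' @param per_subject_maps subject x vertex matrix.
#'
#' @return List with `t`, `p` (two-sided), `df`, `mean`, and logical
#'   `zero_variance`.
#' @export
rfx_ttest_map <- function(per_subject_maps) {
  m <- as.matrix(per_subject_maps)
  n <- nrow(m)
  if (n < 2) stop("rfx error: at least 2 subjects required")
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  zero_var <- s == 0
  tval <- mu / (s / sqrt(n))
  pval <- 2 * pt(-abs(tval), df = n - 1)
  tval[zero_var] <- NA_real_
  pval[zero_var] <- ifelse(mu[zero_var] == 0, 1, 0)
  list(t = tval, p = pval, df = n - 1, mean = mu, zero_variance = zero_var)
}

#' Cluster-size correction configuration
#'
#' @param p_vertex primary vertex-level threshold (e.g. 0.001 or 0.005).
#' @param p_corr cluster-level family-wise criterion (0.05).
#' @param n_iterations Monte Carlo iterations (5000).
#' @param smoothness_fwhm map smoothness as Gaussian FWHM in mm; when
#'   `NULL` it must be estimated from residual maps
#'   (see [estimate_smoothness_fwhm()]).
#'
#' @return An object of class `cluster_config`.
#' @export
cluster_config <- function(p_vertex = 0.001, p_corr = 0.05,
                           n_iterations = 5000L, smoothness_fwhm = NULL) {
  if (p_vertex <= 0 || p_vertex >= 1 || p_corr <= 0 || p_corr >= 1) {
    stop("cluster parameter error: thresholds must lie in (0, 1)")
  }
  if (n_iterations < 1) stop("cluster parameter error: n_iterations must be > 0")
  structure(
    list(p_vertex = p_vertex, p_corr = p_corr,
         n_iterations = as.integer(n_iterations),
         smoothness_fwhm = smoothness_fwhm),
    class = "cluster_config"
  )
}

#' Estimate map smoothness as Gaussian FWHM
#'
#' Estimates the spatial smoothness of (residual) maps from the lag-one
#' neighbor correlation, assuming a Gaussian spatial autocorrelation
#' `rho(d) = exp(-d^2 / (4 sigma^2))` as produced by Gaussian-filtered white
#' noise with kernel SD `sigma`; `FWHM = 2 sqrt(2 log 2) sigma`.
#'
#' @param maps matrix (maps x vertex) or vector over vertices.
#' @param geometry an `roi_geometry`.
#'
#' @return FWHM in mm (0 for non-positive neighbor correlation).
#' @export
estimate_smoothness_fwhm <- function(maps, geometry) {
  if (is.null(dim(maps))) maps <- matrix(maps, nrow = 1)
  rs <- apply(maps, 1, function(v) {
    m <- matrix(v, geometry$nrow, geometry$ncol)
    r <- c()
    if (geometry$nrow > 1) {
      r <- c(r, cor(as.vector(m[-1, ]), as.vector(m[-geometry$nrow, ])))
    }
    if (geometry$ncol > 1) {
      r <- c(r, cor(as.vector(m[, -1]), as.vector(m[, -geometry$ncol])))
    }
    mean(r)
  })
  r1 <- mean(rs)
  if (!is.finite(r1) || r1 <= 0) return(0)
  sigma <- geometry$spacing_mm / (2 * sqrt(-log(r1)))
  2 * sqrt(2 * log(2)) * sigma
}

#' Monte Carlo cluster-size correction
#'
#' Simulates `n_iterations` smooth Gaussian null maps at the map's
#' estimated smoothness, thresholds each at the primary vertex-level
#' threshold (two-sided), and records the maximal suprathreshold cluster
#' size (4-neighbor connectivity). The minimum cluster size is the smallest
#' size whose null exceedance frequency is at most `p_corr`; observed
#' clusters at least that large survive.
#'
#' @param p_map two-sided p values over all vertices.
#' @param geometry an `roi_geometry`.
#' @param config a `cluster_config`; if `smoothness_fwhm` is `NULL`,
#'   `resid_maps` is required.
#' @param stat_map optional statistic map used to report cluster peaks.
#' @param resid_maps optional residual maps for smoothness estimation.
#' @param seed integer seed for the Monte Carlo null.
#'
#' @return List with `clusters` (data frame `id`, `n_vertices`, `area_mm2`,
#'   `peak_vertex`, `peak_stat`), `min_cluster_size`, `smoothness_fwhm`,
#'   and `null_max_sizes`.
#' @export
cluster_size_correct <- function(p_map, geometry, config = cluster_config(),
                                 stat_map = NULL, resid_maps = NULL,
                                 seed = 1L) {
  stopifnot(inherits(geometry, "roi_geometry"),
            inherits(config, "cluster_config"))
  fwhm <- config$smoothness_fwhm
  if (is.null(fwhm)) {
    if (is.null(resid_maps)) {
      stop("cluster parameter error: smoothness estimate required ",
           "(set smoothness_fwhm or pass resid_maps)")
    }
    fwhm <- estimate_smoothness_fwhm(resid_maps, geometry)
  }
  sd_units <- fwhm / (2 * sqrt(2 * log(2))) / geometry$spacing_mm
  zthr <- qnorm(1 - config$p_vertex / 2)
  kr <- conv_band_matrix(geometry$nrow, sd_units)
  kc <- t(conv_band_matrix(geometry$ncol, sd_units))
  max_sizes <- withr::with_seed(seed, {
    vapply(seq_len(config$n_iterations), function(i) {
      z <- kr %*% matrix(rnorm(geometry$n_vertices), geometry$nrow) %*% kc
      z <- (z - mean(z)) / sd(z)
      supra <- which(abs(z) >= zthr)
      if (length(supra) == 0) return(0L)
      max(tabulate(connected_components(supra, geometry)))
    }, integer(1))
  })
  exceed <- function(k) mean(max_sizes >= k)
  k <- 1L
  while (exceed(k) > config$p_corr) k <- k + 1L
  min_cluster_size <- k

  supra_obs <- which(p_map < config$p_vertex)
  clusters <- data.frame(
    id = integer(0), n_vertices = integer(0), area_mm2 = numeric(0),
    peak_vertex = integer(0), peak_stat = numeric(0)
  )
  if (length(supra_obs) > 0) {
    comp <- connected_components(supra_obs, geometry)
    sizes <- tabulate(comp)
    keep <- which(sizes >= min_cluster_size)
    if (length(keep) > 0) {
      rows <- lapply(seq_along(keep), function(j) {
        vts <- supra_obs[comp == keep[j]]
        pk <- if (is.null(stat_map)) {
          vts[which.min(p_map[vts])]
        } else {
          vts[which.max(abs(stat_map[vts]))]
        }
        data.frame(
          id = j, n_vertices = length(vts),
          area_mm2 = length(vts) * geometry$spacing_mm^2,
          peak_vertex = pk,
          peak_stat = if (is.null(stat_map)) NA_real_ else stat_map[pk]
        )
      })
      clusters <- do.call(rbind, rows)
    }
  }
  list(clusters = clusters, min_cluster_size = min_cluster_size,
       smoothness_fwhm = fwhm, null_max_sizes = max_sizes)
}
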