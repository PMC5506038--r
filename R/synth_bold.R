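#' Generative parameters for multivoxel BOLD simulation
#'
#' Describes the synthetic vertex x time BOLD data on the cortical-sheet
#' surrogate. Post-test trials evoke percept-dependent multivoxel patterns:
#' on `pattern_mask` vertices the trial amplitude is
#' `effect_amplitude * pattern_weights * (+1 for an /aba/ response, -1 for
#' /ada/)`, so the planted information is perceptual, mirroring decoding
#' labels taken from behavior. Exposure blocks drive `seed_mask` vertices
#' with amplitude `exposure_amplitude` per audiovisual trial, and the
#' `ppi_target_mask` time course additionally gains
#' `ppi_coupling_gain * z(seed) * z(task)` (task = HRF-convolved exposure
#' indicator), i.e. coupling to the seed that increases during exposure
#' blocks. Noise is AR(1) Gaussian per vertex with marginal SD `noise_sd`.
#'
#' @param geometry an `roi_geometry`.
#' @param roi_mask,seed_mask,ppi_target_mask,pattern_mask integer vertex
#'   sets; `pattern_mask` must lie inside `roi_mask`.
#' @param pattern_weights signed weights over `pattern_mask` (default
#'   alternating +1/-1, giving a mean-free spatial pattern).
#' @param effect_amplitude percept effect amplitude (percent signal).
#' @param exposure_amplitude exposure response amplitude on the seed.
#' @param hrf_peak optional fixed time-to-peak (scalar or per vertex);
#'   default: per-vertex draw from the search grid in `hrf_peak_range`.
#' @param hrf_peak_range per-vertex time-to-peak range (s).
#' @param noise_sd marginal noise SD (percent signal).
#' @param ar1_coef AR(1) autocorrelation coefficient, |coef| < 1.
#' @param ppi_coupling_gain exposure-dependent seed-coupling gain of the
#'   PPI target.
#' @param baseline constant signal level.
#'
#' @return An object of class `bold_gen_params`.
#' @export
bold_gen_params <- function(geometry, roi_mask, seed_mask, ppi_target_mask,
                            pattern_mask, pattern_weights = NULL,
                            effect_amplitude = 1, exposure_amplitude = 1,
                            hrf_peak = NULL, hrf_peak_range = c(3.2, 4.2),
                            noise_sd = 0.5, ar1_coef = 0.3,
                            ppi_coupling_gain = 0, baseline = 100) {
  stopifnot(inherits(geometry, "roi_geometry"))
  roi_mask <- check_mask(roi_mask, geometry, "roi_mask")
  seed_mask <- check_mask(seed_mask, geometry, "seed_mask")
  ppi_target_mask <- check_mask(ppi_target_mask, geometry, "ppi_target_mask")
  pattern_mask <- check_mask(pattern_mask, geometry, "pattern_mask")
  if (!all(pattern_mask %in% roi_mask)) {
    stop("geometry error: pattern_mask must lie inside roi_mask")
  }
  if (abs(ar1_coef) >= 1) stop("ar1_coef must satisfy |coef| < 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(pattern_weights)) {
    pattern_weights <- rep_len(c(1, -1), length(pattern_mask))
  }
  if (length(pattern_weights) != length(pattern_mask)) {
    stop("pattern_weights must match pattern_mask in length")
  }
  structure(
    list(
      geometry = geometry, roi_mask = roi_mask, seed_mask = seed_mask,
      ppi_target_mask = ppi_target_mask, pattern_mask = pattern_mask,
      pattern_weights = pattern_weights,
      effect_amplitude = effect_amplitude,
      exposure_amplitude = exposure_amplitude, hrf_peak = hrf_peak,
      hrf_peak_range = hrf_peak_range, noise_sd = noise_sd,
      ar1_coef = ar1_coef, ppi_coupling_gain = ppi_coupling_gain,
      baseline = baseline
    ),
    class = "bold_gen_params"
  )
}

#' Simulate a subject's multivoxel BOLD dataset
#'
#' Generates vertex x time data for one subject under a session design and
#' the subject's simulated behavior (see [bold_gen_params()] for the signal
#' model). Every event contributes a peak-normalized double-gamma response
#' at the vertex's time-to-peak, sampled at the TR grid, so that the
#' single-trial estimator run on noiseless data recovers the generating
#' amplitudes and latencies exactly.
#'
#' @param design a `session_design` (fMRI timing).
#' @param behavior a `trial_table` containing the subject's post-test
#'   responses (rows matching `design$posttests` in order).
#' @param params a `bold_gen_params`.
#' @param seed integer seed.
#' @param subject subject id selected from `behavior` (default: first).
#' @param spec an `hrf_spec` used for kernel evaluation and the task
#'   regressor.
#'
#' @return An object of class `bold_dataset`: list with `data` (vertex x
#'   time), `tr`, `geometry`, `masks`, `hrf_peak`, `design`, `subject`.
#' @export
simulate_bold <- function(design, behavior, params, seed = 1L,
                          subject = NULL, spec = hrf_spec()) {
  stopifnot(inherits(design, "session_design"),
            inherits(params, "bold_gen_params"))
  geom <- params$geometry
  if (is.null(subject)) subject <- behavior$subject[1]
  beh <- behavior[behavior$subject == subject, , drop = FALSE]
  n_pt <- nrow(design$posttests)
  if (nrow(beh) != n_pt) {
    stop("behavior does not cover the design post-tests for subject ",
         subject, " (", nrow(beh), " vs ", n_pt, " trials)")
  }
  tr <- design$params$tr
  n_tp <- ceiling(design$duration / tr)
  times <- (seq_len(n_tp) - 1L) * tr

  grid_peaks <- seq(params$hrf_peak_range[1], params$hrf_peak_range[2],
                    by = spec$peak_search_step)
  withr::with_seed(seed, {
    peaks <- if (is.null(params$hrf_peak)) {
      grid_peaks[sample.int(length(grid_peaks), geom$n_vertices,
                            replace = TRUE)]
    } else {
      rep_len(params$hrf_peak, geom$n_vertices)
    }

    Y <- matrix(params$baseline, geom$n_vertices, n_tp)

    # one kernel column per event, per distinct vertex peak latency
    used_peaks <- sort(unique(peaks[c(params$pattern_mask, params$seed_mask,
                                      params$ppi_target_mask)]))
    for (p in used_peaks) {
      vsel_pat <- params$pattern_mask[peaks[params$pattern_mask] == p]
      vsel_seed <- params$seed_mask[peaks[params$seed_mask] == p]
      if (length(vsel_pat) > 0 && n_pt > 0) {
        trial_reg <- vapply(design$posttests$onset,
                            function(o) hrf_eval(spec, times - o, p),
                            numeric(n_tp)) # time x trial
        sign_pc <- ifelse(beh$response == 1L, 1, -1)
        w <- params$pattern_weights[match(vsel_pat, params$pattern_mask)]
        amp <- outer(w * params$effect_amplitude, sign_pc) # vertex x trial
        Y[vsel_pat, ] <- Y[vsel_pat, ] + amp %*% t(trial_reg)
      }
      if (length(vsel_seed) > 0 && nrow(design$exposures) > 0) {
        exp_reg <- rowSums(vapply(design$exposures$onset,
                                  function(o) hrf_eval(spec, times - o, p),
                                  numeric(n_tp)))
        Y[vsel_seed, ] <- Y[vsel_seed, ] +
          params$exposure_amplitude * rep(exp_reg, each = length(vsel_seed))
      }
    }

    # exposure-dependent coupling of the PPI target to the seed
    if (params$ppi_coupling_gain != 0) {
      seed_clean <- colMeans(Y[params$seed_mask, , drop = FALSE])
      task <- exposure_task_regressor(design, spec, n_tp, tr)
      mod <- params$ppi_coupling_gain * zscore_vec(seed_clean) *
        zscore_vec(task)
      Y[params$ppi_target_mask, ] <- Y[params$ppi_target_mask, ] +
        rep(mod, each = length(params$ppi_target_mask))
    }

    if (params$noise_sd > 0) {
      innov_sd <- params$noise_sd * sqrt(1 - params$ar1_coef^2)
      eps <- matrix(rnorm(geom$n_vertices * n_tp, 0, innov_sd),
                    geom$n_vertices, n_tp)
      noise <- t(apply(eps, 1, function(e) {
        as.numeric(stats::filter(e, params$ar1_coef, method = "recursive"))
      }))
      Y <- Y + noise
    }
  })
  structure(
    list(
      data = Y, tr = tr, geometry = geom,
      masks = list(roi = params$roi_mask, seed = params$seed_mask,
                   ppi_target = params$ppi_target_mask,
                   pattern = params$pattern_mask),
      hrf_peak = peaks, design = design, subject = subject
    ),
    class = "bold_dataset"
  )
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat("<bold_dataset> ", nrow(x$data), " vertices x ", ncol(x$data),
      " volumes (TR ", x$tr, " s), subject ", x$subject, "\n", sep = "")
  invisible(x)
}

zscore_vec <- function(v) {
  s <- sd(v)
  if (!is.finite(s) || s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}
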