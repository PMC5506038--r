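#' Double-gamma hemodynamic response specification
#'
#' Shape parameters of the canonical double-gamma HRF
#' \deqn{h_0(t) = \Gamma(t; a_1, d_1) - r\,\Gamma(t; a_2, d_2)}
#' with gamma-density lobes for the peak and the (negative) undershoot.
#' Defaults are the widely used canonical values: peak delay 6 s,
#' undershoot delay 16 s, unit dispersions, peak/undershoot ratio 1/6.
#' `peak_search_range` bounds the per-vertex positive time-to-peak
#' adjustment used during single-trial beta fitting (3.2--4.2 s in steps of
#' `peak_search_step`).
#'
#' @param peak_delay,undershoot_delay gamma shape delays (s).
#' @param peak_disp,undershoot_disp gamma dispersions.
#' @param ratio undershoot/peak amplitude ratio.
#' @param dt kernel sampling step (s).
#' @param duration kernel support (s).
#' @param peak_search_range inclusive time-to-peak range (s).
#' @param peak_search_step grid step of the time-to-peak search (s).
#'
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16, peak_disp = 1,
                     undershoot_disp = 1, ratio = 1 / 6, dt = 0.1,
                     duration = 30, peak_search_range = c(3.2, 4.2),
                     peak_search_step = 0.1) {
  if (peak_search_range[1] > peak_search_range[2] || peak_search_step <= 0) {
    stop("hrf parameter error: empty or invalid time-to-peak search range")
  }
  if (dt <= 0 || duration <= 0) stop("hrf parameter error: dt and duration must be > 0")
  structure(
    list(
      peak_delay = peak_delay, undershoot_delay = undershoot_delay,
      peak_disp = peak_disp, undershoot_disp = undershoot_disp,
      ratio = ratio, dt = dt, duration = duration,
      peak_search_range = peak_search_range,
      peak_search_step = peak_search_step
    ),
    class = "hrf_spec"
  )
}

# canonical (unscaled) kernel value at times t
hrf_canonical <- function(spec, t) {
  out <- dgamma(t, shape = spec$peak_delay / spec$peak_disp,
                scale = spec$peak_disp) -
    spec$ratio * dgamma(t, shape = spec$undershoot_delay / spec$undershoot_disp,
                        scale = spec$undershoot_disp)
  out[t < 0] <- 0
  out
}

# argmax of the canonical kernel, located once on a fine grid
hrf_canonical_peak <- function(spec) {
  tt <- seq(0, spec$duration, by = 0.01)
  tt[which.max(hrf_canonical(spec, tt))]
}

# kernel evaluator with the time axis rescaled so the peak falls at t_peak,
# peak-normalized to 1
hrf_eval <- function(spec, t, t_peak = NULL) {
  t0 <- hrf_canonical_peak(spec)
  scale <- if (is.null(t_peak)) 1 else t0 / t_peak
  v <- hrf_canonical(spec, t * scale)
  v / hrf_canonical(spec, t0)
}

#' Sample a double-gamma HRF kernel
#'
#' Returns the kernel sampled on `seq(0, duration, by = dt)`, peak-normalized
#' to 1. When `t_peak` is given, the time axis is rescaled so the kernel
#' maximum falls at `t_peak` seconds (the per-vertex time-to-peak adjustment
#' used in trial-beta fitting); `t_peak` must then lie inside the
#' specification's search range.
#'
#' @param spec an `hrf_spec`.
#' @param t_peak optional target time-to-peak (s).
#'
#' @return Numeric kernel vector with attribute `times`.
#' @export
#' @examples
#' h <- double_gamma_hrf(hrf_spec(), t_peak = 4.2)
#' attr(h, "times")[which.max(h)]  # 4.2
double_gamma_hrf <- function(spec = hrf_spec(), t_peak = NULL) {
  stopifnot(inherits(spec, "hrf_spec"))
  if (!is.null(t_peak)) {
    r <- spec$peak_search_range
    if (t_peak < r[1] - 1e-9 || t_peak > r[2] + 1e-9) {
      stop("hrf parameter error: t_peak ", t_peak,
           " outside the search range [", r[1], ", ", r[2], "]")
    }
  }
  tt <- seq(0, spec$duration, by = spec$dt)
  v <- hrf_eval(spec, tt, t_peak)
  attr(v, "times") <- tt
  v
}

#' Grid of candidate time-to-peak values
#'
#' @param spec an `hrf_spec`.
#' @return Numeric vector spanning the search range at the search step.
#' @export
peak_search_grid <- function(spec = hrf_spec()) {
  seq(spec$peak_search_range[1], spec$peak_search_range[2],
      by = spec$peak_search_step)
}
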