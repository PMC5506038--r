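#' Simulation-based fixed-effect recovery
#'
#' Repeatedly simulates categorization behavior on a session design under a
#' generative logistic mixed model and refits the analysis model to each
#' replicate, collecting the fixed-effect estimates. Averaging the
#' estimates over replicates measures the bias of the fitting procedure at
#' the design's sample size; the package's recovery checks require the mean
#' estimate of the effects of interest to fall within 15% of the generating
#' value.
#'
#' @param design a `session_design`.
#' @param gen_params a `behavior_gen_params` (generating model).
#' @param fixed fixed-effects formula right-hand side for the refit
#'   (see [fit_logistic_glmm()]).
#' @param random random-term specification for the refit.
#' @param n_replicates number of simulate-and-refit replicates.
#' @param seed integer seed; replicate r uses a sub-seed derived from
#'   `(seed, r)`.
#'
#' @return Data frame with one row per replicate and one column per fixed
#'   effect term, plus a logical `converged` column. The attribute
#'   `generating` holds the generating fixed effects.
#' @export
#' @examples
#' \donttest{
#' d <- build_psychophysical_design(
#'   design_params("psychophysical", n_blocks_per_text = 2), seed = 1)
#' p <- behavior_gen_params(reference_fixed_effects("psychophysical", 27),
#'                          n_subjects = 8)
#' r <- simulate_and_refit(d, p, n_replicates = 2, seed = 1)
#' colMeans(r[names(r) != "converged"])
#' }
simulate_and_refit <- function(design, gen_params, fixed = "C * E * S",
                               random = c("1", "C", "C:E"),
                               n_replicates = 50L, seed = 1L) {
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    tab <- simulate_behavior(design, gen_params, seed = sub_seed(seed, r))
    fit <- fit_logistic_glmm(tab, fixed = fixed, random = random)
    est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
    rows[[r]] <- c(as.list(est), converged = fit$converged)
  }
  out <- do.call(rbind, lapply(rows, function(x) as.data.frame(x, check.names = FALSE)))
  attr(out, "generating") <- gen_params$fixed_effects
  out
}
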