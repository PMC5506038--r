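#' Generative parameters for behavioral simulation
#'
#' Defines the logistic mixed model that generates binary /aba/(=1) vs
#' /ada/(=0) categorization responses. Fixed effects and per-subject random
#' effect standard deviations are given on the logit scale and named by the
#' coded model terms: `"(Intercept)"`, `"C"` (Condition), `"E"` (Exposure),
#' `"S"` (Sound) and their products `"C:E"`, `"C:S"`, `"E:S"`, `"C:E:S"`
#' (see [code_factors()] for the coding).
#'
#' @param fixed_effects named numeric vector of logit-scale fixed effects;
#'   unnamed terms default to 0.
#' @param random_sd named non-negative numeric vector of per-subject random
#'   effect SDs (uncorrelated, i.e. diagonal covariance). Default: SD 0.5
#'   for the intercept, Condition slope and Condition-by-Exposure slope.
#' @param n_subjects number of simulated subjects.
#'
#' @return An object of class `behavior_gen_params`.
#' @seealso [simulate_behavior()], [reference_fixed_effects()]
#' @export
behavior_gen_params <- function(fixed_effects,
                                random_sd = c("(Intercept)" = 0.5,
                                              "C" = 0.5, "C:E" = 0.5),
                                n_subjects = 15L) {
  all_terms <- c("(Intercept)", "C", "E", "S", "C:E", "C:S", "E:S", "C:E:S")
  if (is.null(names(fixed_effects)) ||
      !all(names(fixed_effects) %in% all_terms)) {
    stop("fixed_effects must be named by model terms: ",
         paste(all_terms, collapse = ", "))
  }
  if (length(random_sd) > 0 &&
      (is.null(names(random_sd)) || !all(names(random_sd) %in% all_terms))) {
    stop("random_sd must be named by model terms")
  }
  if (any(random_sd < 0)) stop("random_sd must be non-negative")
  if (n_subjects < 1) stop("n_subjects must be positive")
  structure(
    list(fixed_effects = fixed_effects, random_sd = random_sd,
         n_subjects = as.integer(n_subjects)),
    class = "behavior_gen_params"
  )
}

#' Reference fixed effects for the recalibration psychometric models
#'
#' Logit-scale group fixed-effect estimates from text-based recalibration
#' categorization experiments, used as default generating values in
#' simulation studies. `"psychophysical"` refers to the offline session
#' model `Response ~ 1 + Condition * Exposure * Sound` with diagonal random
#' intercept, Condition and Condition:Exposure terms, reported for groups of
#' 27 and 15 subjects. `"scanner"` refers to the in-scanner session model
#' `Response ~ 1 + Exposure * Sound` with diagonal random intercept,
#' Exposure and Sound terms (15 subjects).
#'
#' @param model `"psychophysical"` or `"scanner"`.
#' @param n group size of the psychophysical reference fit (27 or 15);
#'   ignored for `"scanner"`.
#'
#' @return Named numeric vector of logit-scale fixed effects.
#' @export
#' @examples
#' reference_fixed_effects("psychophysical", n = 27)["C:E"]  # 1.78
reference_fixed_effects <- function(model = c("psychophysical", "scanner"),
                                    n = 27) {
  model <- match.arg(model)
  if (model == "psychophysical") {
    if (n == 27) {
      c("(Intercept)" = 0.69, "C" = -0.40, "E" = 0.26, "S" = 1.43,
        "C:E" = 1.78, "C:S" = -0.17, "E:S" = -0.01, "C:E:S" = -0.14)
    } else if (n == 15) {
      c("(Intercept)" = 0.50, "C" = -0.79, "E" = 0.12, "S" = 1.41,
        "C:E" = 2.18, "C:S" = -0.14, "E:S" = -0.14, "C:E:S" = 0.18)
    } else {
      stop("psychophysical reference fits exist for n = 27 or n = 15")
    }
  } else {
    c("(Intercept)" = 0.01, "E" = 1.14, "S" = 1.86, "E:S" = 0.38)
  }
}

# coded term columns from a coded trial table, as a named list
term_columns <- function(tab) {
  list(
    "(Intercept)" = rep(1, nrow(tab)),
    "C" = tab$C, "E" = tab$E, "S" = tab$S,
    "C:E" = tab$C * tab$E, "C:S" = tab$C * tab$S, "E:S" = tab$E * tab$S,
    "C:E:S" = tab$C * tab$E * tab$S
  )
}

#' Simulate categorization behavior on a session design
#'
#' For every subject, draws each post-test response from
#' `Bernoulli(plogis(eta))`, where `eta` is the fixed-effect linear
#' predictor of the coded logistic model plus the subject's random terms.
#' Random effects are drawn independently per subject from zero-mean normals
#' with the SDs in `params$random_sd` (diagonal covariance). /aba/ responses
#' are coded 1, /ada/ responses 0.
#'
#' @param design a `session_design`.
#' @param params a `behavior_gen_params`.
#' @param seed integer seed; draws are reproducible per subject.
#'
#' @return A `trial_table`: data frame with columns `subject`, `block`,
#'   `onset`, `condition`, `exposure_text`, `sound_token`, `response`, plus
#'   coded columns `C`, `E`, `S`.
#' @export
#' @examples
#' d <- build_psychophysical_design(seed = 1)
#' p <- behavior_gen_params(reference_fixed_effects("psychophysical", 27),
#'                          n_subjects = 2)
#' tab <- simulate_behavior(d, p, seed = 1)
#' mean(tab$response)
simulate_behavior <- function(design, params, seed = 1L) {
  stopifnot(inherits(design, "session_design"),
            inherits(params, "behavior_gen_params"))
  pt <- design$posttests
  if (nrow(pt) == 0L) stop("design has no post-test trials to simulate")
  base <- code_factors(data.frame(
    block = pt$block, onset = pt$onset, condition = pt$condition,
    exposure_text = pt$exposure_text, sound_token = pt$sound_token
  ))
  cols <- term_columns(base)
  fe <- params$fixed_effects
  eta_fixed <- Reduce(`+`, Map(function(term, b) b * cols[[term]],
                               names(fe), fe))
  withr::with_seed(seed, {
    out <- vector("list", params$n_subjects)
    for (s in seq_len(params$n_subjects)) {
      eta <- eta_fixed
      for (term in names(params$random_sd)) {
        u <- rnorm(1L, 0, params$random_sd[[term]])
        eta <- eta + u * cols[[term]]
      }
      resp <- rbinom(nrow(base), 1L, plogis(eta))
      out[[s]] <- cbind(data.frame(subject = s), base, response = resp)
    }
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("trial_table", "data.frame")
  tab
}
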