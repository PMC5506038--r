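#' Append coded model covariates to a trial table
#'
#' Applies the difference coding of the categorization model:
#' Condition `C` (recalibration = +0.5, adaptation = -0.5), Exposure `E`
#' ('aba' text = +0.5, 'ada' text = -0.5) and Sound `S` (/a?a/-1 = +1,
#' /a?a/ = 0, /a?a/+1 = -1; i.e. `S = -sound_token`, so positive `S` marks
#' the more /b/-like end of the continuum). Interaction covariates are
#' products of these columns.
#'
#' @param table data frame with columns `condition`, `exposure_text`,
#'   `sound_token`.
#'
#' @return The table with numeric columns `C`, `E`, `S` appended.
#' @export
#' @examples
#' code_factors(data.frame(condition = "recalibration",
#'                         exposure_text = "aba", sound_token = -1L))
code_factors <- function(table) {
  req <- c("condition", "exposure_text", "sound_token")
  miss <- setdiff(req, names(table))
  if (length(miss) > 0) {
    stop("coding error: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(table$condition %in% c("recalibration", "adaptation"))) {
    stop("coding error: unknown condition level")
  }
  if (!all(table$exposure_text %in% c("aba", "ada"))) {
    stop("coding error: unknown exposure_text level")
  }
  if (!all(table$sound_token %in% c(-1L, 0L, 1L))) {
    stop("coding error: unknown sound_token level")
  }
  table$C <- ifelse(table$condition == "recalibration", +0.5, -0.5)
  table$E <- ifelse(table$exposure_text == "aba", +0.5, -0.5)
  table$S <- -as.numeric(table$sound_token)
  table
}

#' Fit the logistic mixed-effects categorization model
#'
#' Fits a logistic GLMM to binary /aba/ responses with the requested fixed
#' structure and uncorrelated (diagonal-covariance) per-subject random
#' terms, maximizing the Laplace-approximated marginal likelihood via
#' [lme4::glmer()]. With `random = character(0)` the model reduces to an
#' ordinary logistic regression ([stats::glm()]). Wald z statistics and
#' two-sided normal-reference p values are reported, matching the `z`/`p`
#' columns of the conventional summary table.
#'
#' @param table a trial table with `subject`, `response` and factor columns
#'   (coded columns are added if absent).
#' @param fixed character scalar giving the fixed-effects formula right-hand
#'   side in the coded covariates, e.g. `"C * E * S"` (psychophysical
#'   session) or `"E * S"` (scanner session).
#' @param random character vector of random slope terms (besides nothing),
#'   drawn from `"1"`, `"C"`, `"E"`, `"S"`, `"C:E"`, ...; each enters as an
#'   independent variance component. `character(0)` fits fixed effects only.
#'
#' @return An object of class `model_fit`: list with `coefficients` (data
#'   frame `term`, `estimate`, `se`, `z`, `p`), `ranef_sd` (named vector),
#'   `converged`, `n_subjects`, `n_obs`, `formula` and the underlying `fit`.
#' @export
#' @examples
#' d <- build_psychophysical_design(
#'   design_params("psychophysical", n_blocks_per_text = 2), seed = 1)
#' p <- behavior_gen_params(reference_fixed_effects("psychophysical", 27),
#'                          n_subjects = 6)
#' tab <- simulate_behavior(d, p, seed = 1)
#' fit <- fit_logistic_glmm(tab)
#' fit$coefficients
fit_logistic_glmm <- function(table, fixed = "C * E * S",
                              random = c("1", "C", "C:E")) {
  if (!all(c("C", "E", "S") %in% names(table))) table <- code_factors(table)
  if (!"response" %in% names(table)) {
    stop("model error: trial table lacks a response column")
  }
  if (!all(table$response %in% c(0L, 1L))) {
    stop("model error: response must be binary 0/1")
  }
  use_glmm <- length(random) > 0
  if (use_glmm) {
    if (!"subject" %in% names(table)) {
      stop("model error: subject column required for random effects")
    }
    if (length(unique(table$subject)) < 2L) {
      stop("model error: at least 2 subjects required for a mixed model; ",
           "use random = character(0) for a fixed-effects fit")
    }
  }
  dat <- table
  cols <- term_columns(dat)
  re_terms <- character(0)
  for (term in setdiff(random, "1")) {
    if (!term %in% names(cols)) stop("model error: unknown random term ", term)
    safe <- gsub(":", "_x_", term, fixed = TRUE)
    dat[[safe]] <- cols[[term]]
    re_terms <- c(re_terms, sprintf("(0 + %s | subject)", safe))
  }
  if ("1" %in% random) re_terms <- c("(1 | subject)", re_terms)

  if (use_glmm) {
    fml <- stats::as.formula(
      paste("response ~", fixed, "+", paste(re_terms, collapse = " + "))
    )
    converged <- TRUE
    fit <- withCallingHandlers(
      lme4::glmer(fml, data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
          converged <<- FALSE
          invokeRestart("muffleWarning")
        }
      }
    )
    ct <- coef(summary(fit))
    vc <- lme4::VarCorr(fit)
    ranef_sd <- vapply(vc, function(m) sqrt(m[1, 1]), numeric(1))
    names(ranef_sd) <- vapply(vc, function(m) rownames(m)[1], character(1))
  } else {
    fml <- stats::as.formula(paste("response ~", fixed))
    fit <- stats::glm(fml, data = dat, family = stats::binomial())
    converged <- fit$converged
    ct <- coef(summary(fit))
    ranef_sd <- numeric(0)
  }
  est <- ct[, 1]
  se <- ct[, 2]
  if (any(abs(est) > 10 & se > 50)) {
    stop("model error: complete or quasi-complete separation detected ",
         "(diverging estimate with exploding standard error)")
  }
  z <- est / se
  coefs <- data.frame(
    term = rownames(ct), estimate = unname(est), se = unname(se),
    z = unname(z), p = unname(2 * pnorm(-abs(z))),
    stringsAsFactors = FALSE
  )
  rownames(coefs) <- NULL
  structure(
    list(
      coefficients = coefs, ranef_sd = ranef_sd, converged = converged,
      n_subjects = if ("subject" %in% names(table))
        length(unique(table$subject)) else 1L,
      n_obs = nrow(table), formula = deparse(fml), fit = fit
    ),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, digits = 3, ...) {
  cat("<model_fit> ", x$formula, "\n", sep = "")
  cat("  subjects: ", x$n_subjects, "  trials: ", x$n_obs,
      if (!x$converged) "  [NOT CONVERGED]" else "", "\n", sep = "")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  if (length(x$ranef_sd) > 0) {
    cat("  random-effect SDs:",
        paste(sprintf("%s=%.*f", names(x$ranef_sd), digits, x$ranef_sd),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pull a fixed-effect estimate from a model fit
#'
#' @param fit a `model_fit`.
#' @param term coefficient name as reported by the fit (e.g. `"C:E"`).
#' @return The logit-scale estimate.
#' @export
fixed_effect <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop("term not in model: ", term)
  fit$coefficients$estimate[i]
}

#' Cell means and standard errors of /aba/ response proportions
#'
#' Computes the proportion of /aba/ responses per subject and design cell,
#' then averages over subjects; the standard error is the between-subject
#' SD of the cell means divided by `sqrt(n_subjects)`.
#'
#' @param table a trial table with `subject` and `response`.
#' @param by character vector of grouping columns (default condition,
#'   exposure text and sound token).
#'
#' @return Data frame with the grouping columns plus `mean`, `se` and
#'   `n_subjects`; cells with no trials for any subject are flagged with
#'   `NA` mean.
#' @export
summarize_proportions <- function(table,
                                  by = c("condition", "exposure_text",
                                         "sound_token")) {
  stopifnot(all(c("subject", "response") %in% names(table)))
  miss <- setdiff(by, names(table))
  if (length(miss) > 0) stop("unknown grouping column(s): ",
                             paste(miss, collapse = ", "))
  per_subj <- stats::aggregate(
    table$response,
    by = c(table[by], list(subject = table$subject)),
    FUN = mean
  )
  names(per_subj)[ncol(per_subj)] <- "p_aba"
  out <- stats::aggregate(
    per_subj$p_aba, by = per_subj[by],
    FUN = function(v) c(mean = mean(v), se = sd(v) / sqrt(length(v)),
                        n = length(v))
  )
  res <- data.frame(out[by], mean = out$x[, "mean"], se = out$x[, "se"],
                    n_subjects = out$x[, "n"])
  # single-subject cells have undefined between-subject SE
  res$se[res$n_subjects < 2] <- NA_real_
  # flag design cells no subject contributed to (NA mean, 0 subjects)
  grid <- expand.grid(lapply(table[by], function(v) sort(unique(v))),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- by
  res <- merge(grid, res, by = by, all.x = TRUE, sort = TRUE)
  res$n_subjects[is.na(res$n_subjects)] <- 0
  res
}
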