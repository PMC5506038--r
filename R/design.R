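#' Session design parameters
#'
#' Bundles the trial arithmetic and timing constants of a text-based
#' recalibration session. The fMRI session uses 12 exposure blocks per text
#' ('aba'/'ada', recalibration only), 8 audiovisual exposure trials per block
#' (one per TR), and 6 auditory post-test trials per block presented
#' slow event-related with a mean inter-trial interval of 14 s jittered over
#' 6--8 TR. The psychophysical session adds the adaptation condition, uses 8
#' blocks per text and condition (16 blocks per condition, 96 post-tests per
#' condition) and a 5 s mean post-test interval jittered continuously over
#' 4--6 s.
#'
#' @param session `"fmri"` or `"psychophysical"`.
#' @param ... named overrides of any default field.
#'
#' @return An object of class `design_params`: a list with fields
#'   `n_exposure_trials_per_block`, `n_posttest_per_block`,
#'   `n_blocks_per_text` (per condition for the psychophysical session),
#'   `tr`, `posttest_iti_mean`, `posttest_iti_jitter` (TR units for fMRI,
#'   seconds for psychophysics), `exposure_iti`, `sound_duration`,
#'   `text_duration`, `response_cue_delay`, `n_runs`.
#' @export
#' @examples
#' design_params("fmri")
#' design_params("psychophysical", n_blocks_per_text = 2)
design_params <- function(session = c("fmri", "psychophysical"), ...) {
  session <- match.arg(session)
  p <- if (session == "fmri") {
    list(
      session = "fmri",
      n_exposure_trials_per_block = 8L,
      n_posttest_per_block = 6L,
      n_blocks_per_text = 12L,
      tr = 2.0,
      posttest_iti_mean = 14.0,
      posttest_iti_jitter = c(6L, 8L), # TR units, inclusive
      exposure_iti = 2.0,
      sound_duration = 0.640,
      text_duration = 1.0,
      response_cue_delay = 1.0,
      n_runs = 3L
    )
  } else {
    list(
      session = "psychophysical",
      n_exposure_trials_per_block = 8L,
      n_posttest_per_block = 6L,
      n_blocks_per_text = 8L, # per condition; 16 blocks per condition
      tr = 2.0,
      posttest_iti_mean = 5.0,
      posttest_iti_jitter = c(4, 6), # seconds, continuous
      exposure_iti = 2.0,
      sound_duration = 0.640,
      text_duration = 1.0,
      response_cue_delay = 1.0,
      n_runs = 1L
    )
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0L) {
    stop("unknown design parameter(s): ", paste(unknown, collapse = ", "))
  }
  p[names(dots)] <- dots
  class(p) <- "design_params"
  validate_design_params(p)
  p
}

validate_design_params <- function(p) {
  stopifnot(inherits(p, "design_params"))
  counts <- c(
    p$n_exposure_trials_per_block, p$n_posttest_per_block,
    p$n_runs
  )
  if (any(counts <= 0) || p$n_blocks_per_text < 0) {
    stop("design parameter error: counts must be positive ",
         "(n_blocks_per_text may be 0 for an empty design)")
  }
  if (p$tr <= 0) stop("design parameter error: tr must be > 0")
  j <- p$posttest_iti_jitter
  if (length(j) != 2L || j[1] > j[2]) {
    stop("design parameter error: jitter must be an increasing range")
  }
  mean_in_units <- if (p$session == "fmri") p$posttest_iti_mean / p$tr else
    p$posttest_iti_mean
  if (mean_in_units < j[1] || mean_in_units > j[2]) {
    stop("design parameter error: jitter range must bracket the mean ITI")
  }
  invisible(p)
}

new_session_design <- function(session, params, blocks, exposures, posttests,
                               duration) {
  structure(
    list(
      session = session, params = params, blocks = blocks,
      exposures = exposures, posttests = posttests, duration = duration
    ),
    class = "session_design"
  )
}

#' @export
print.session_design <- function(x, ...) {
  cat("<session_design> (", x$session, ")\n", sep = "")
  cat("  blocks:    ", nrow(x$blocks), "\n")
  cat("  exposures: ", nrow(x$exposures), "\n")
  cat("  post-tests:", nrow(x$posttests), "\n")
  cat("  duration:  ", round(x$duration, 1), "s\n")
  invisible(x)
}

# one post-test token sequence: each of the three continuum tokens twice,
# in random order
sample_tokens <- function(n_posttest) {
  if (n_posttest %% 3L != 0L) {
    stop("design parameter error: post-tests per block must be a multiple ",
         "of 3 so each token appears equally often")
  }
  sample(rep(c(-1L, 0L, 1L), n_posttest / 3L))
}

#' Build the fMRI session design
#'
#' Lays out `n_runs` runs, each containing an equal number of 'aba' and 'ada'
#' recalibration exposure blocks in seeded random order. Each block holds
#' `n_exposure_trials_per_block` audiovisual trials spaced one TR apart,
#' followed by `n_posttest_per_block` auditory post-test trials. The gap
#' between the last exposure trial and the first post-test, between
#' consecutive post-tests, and before the next block is drawn uniformly from
#' the inclusive integer TR jitter range (default 6--8 TR, mean 14 s). All
#' onsets fall on the TR grid. Within each block the three continuum tokens
#' each appear twice, in random order.
#'
#' @param params a `design_params` object (session `"fmri"`).
#' @param seed integer seed; identical seeds give identical designs.
#'
#' @return A `session_design` with data frames `blocks`, `exposures` and
#'   `posttests` (columns `onset` (s), `duration`, `sound_token`, `block`,
#'   `run`, `condition`, `exposure_text`) and the total session `duration`.
#' @export
#' @examples
#' d <- build_fmri_design(design_params("fmri"), seed = 1)
#' table(d$posttests$exposure_text)  # 72 post-tests per exposure text
build_fmri_design <- function(params = design_params("fmri"), seed = 1L) {
  validate_design_params(params)
  if (params$session != "fmri") {
    stop("design parameter error: params must describe an fmri session")
  }
  if (params$n_blocks_per_text %% params$n_runs != 0L) {
    stop("design parameter error: n_blocks_per_text (",
         params$n_blocks_per_text, ") must divide evenly over n_runs (",
         params$n_runs, ")")
  }
  per_run <- params$n_blocks_per_text / params$n_runs
  jit <- function() sample(seq(params$posttest_iti_jitter[1],
                               params$posttest_iti_jitter[2]), 1L) * params$tr
  withr::with_seed(seed, {
    blocks <- exposures <- posttests <- list()
    t_cur <- 0
    b <- 0L
    for (run in seq_len(params$n_runs)) {
      if (per_run > 0) {
        texts <- sample(rep(c("aba", "ada"), each = per_run))
      } else {
        texts <- character(0)
      }
      t_cur <- t_cur + jit() # lead-in baseline
      for (text in texts) {
        b <- b + 1L
        exp_on <- t_cur +
          (seq_len(params$n_exposure_trials_per_block) - 1L) *
            params$exposure_iti
        tokens <- sample_tokens(params$n_posttest_per_block)
        pt_on <- numeric(params$n_posttest_per_block)
        t_pt <- exp_on[length(exp_on)]
        for (i in seq_along(pt_on)) {
          t_pt <- t_pt + jit()
          pt_on[i] <- t_pt
        }
        blocks[[b]] <- data.frame(
          block = b, run = run, condition = "recalibration",
          exposure_text = text
        )
        exposures[[b]] <- data.frame(
          onset = exp_on, duration = params$sound_duration, block = b,
          run = run, condition = "recalibration", exposure_text = text
        )
        posttests[[b]] <- data.frame(
          onset = pt_on, duration = params$sound_duration,
          sound_token = tokens, block = b, run = run,
          condition = "recalibration", exposure_text = text
        )
        t_cur <- t_pt + jit()
      }
    }
    duration <- t_cur + 16 * params$tr # tail baseline
    new_session_design(
      "fmri", params,
      blocks = do.call(rbind, blocks) %||%
        data.frame(block = integer(0), run = integer(0),
                   condition = character(0), exposure_text = character(0)),
      exposures = do.call(rbind, exposures) %||% empty_events(),
      posttests = do.call(rbind, posttests) %||% empty_posttests(),
      duration = duration
    )
  })
}

#' Build the psychophysical session design
#'
#' Generates the offline session containing both recalibration (text +
#' ambiguous sound) and adaptation (text + matching clear sound) exposure
#' blocks, `n_blocks_per_text` blocks per condition and text (defaults give
#' 16 blocks and 96 post-test trials per condition). Block order is a seeded
#' random permutation of all blocks; post-test inter-trial intervals are
#' drawn continuously from the jitter range in seconds (default 4--6 s,
#' mean 5 s).
#'
#' @param params a `design_params` object (session `"psychophysical"`).
#' @param seed integer seed.
#'
#' @return A `session_design`; see [build_fmri_design()].
#' @export
#' @examples
#' d <- build_psychophysical_design(design_params("psychophysical"), seed = 1)
#' table(d$posttests$condition)  # 96 post-tests per condition
build_psychophysical_design <- function(
    params = design_params("psychophysical"), seed = 1L) {
  validate_design_params(params)
  if (params$session != "psychophysical") {
    stop("design parameter error: params must describe a psychophysical ",
         "session")
  }
  jit <- function() runif(1L, params$posttest_iti_jitter[1],
                          params$posttest_iti_jitter[2])
  combos <- expand.grid(
    condition = c("recalibration", "adaptation"),
    exposure_text = c("aba", "ada"),
    rep = seq_len(params$n_blocks_per_text),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  withr::with_seed(seed, {
    if (nrow(combos) > 0) combos <- combos[sample(nrow(combos)), , drop = FALSE]
    blocks <- exposures <- posttests <- list()
    t_cur <- jit()
    for (b in seq_len(nrow(combos))) {
      cond <- combos$condition[b]
      text <- combos$exposure_text[b]
      exp_on <- t_cur +
        (seq_len(params$n_exposure_trials_per_block) - 1L) *
          params$exposure_iti
      tokens <- sample_tokens(params$n_posttest_per_block)
      pt_on <- numeric(params$n_posttest_per_block)
      t_pt <- exp_on[length(exp_on)]
      for (i in seq_along(pt_on)) {
        t_pt <- t_pt + jit()
        pt_on[i] <- t_pt
      }
      blocks[[b]] <- data.frame(
        block = b, run = 1L, condition = cond, exposure_text = text
      )
      exposures[[b]] <- data.frame(
        onset = exp_on, duration = params$sound_duration, block = b,
        run = 1L, condition = cond, exposure_text = text
      )
      posttests[[b]] <- data.frame(
        onset = pt_on, duration = params$sound_duration,
        sound_token = tokens, block = b, run = 1L, condition = cond,
        exposure_text = text
      )
      t_cur <- t_pt + jit()
    }
    new_session_design(
      "psychophysical", params,
      blocks = do.call(rbind, blocks) %||%
        data.frame(block = integer(0), run = integer(0),
                   condition = character(0), exposure_text = character(0)),
      exposures = do.call(rbind, exposures) %||% empty_events(),
      posttests = do.call(rbind, posttests) %||% empty_posttests(),
      duration = t_cur + 16
    )
  })
}

empty_events <- function() {
  data.frame(
    onset = numeric(0), duration = numeric(0), block = integer(0),
    run = integer(0), condition = character(0), exposure_text = character(0)
  )
}

empty_posttests <- function() {
  data.frame(
    onset = numeric(0), duration = numeric(0), sound_token = integer(0),
    block = integer(0), run = integer(0), condition = character(0),
    exposure_text = character(0)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
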