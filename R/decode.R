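#' Percept-decoding configuration
#'
#' Constants of the balanced-resampling RFE-SVM decoding pipeline: 10
#' class-balanced datasets, 4 cross-validation folds each (40 folds in
#' total), 10 recursive-feature-elimination levels with a 30% elimination
#' ratio, 50 pre-drawn inner splits of 90% of the training trials consumed
#' 5 per level, Gaussian smoothing of weight maps with SD 5 mm before
#' ranking, 200 label permutations for the chance distribution, and the top
#' 20% most discriminative vertices per subject for the group consistency
#' map.
#'
#' @param n_balanced_datasets number of class-balanced resampled datasets.
#' @param k_folds cross-validation folds per balanced dataset.
#' @param rfe_levels feature-selection levels.
#' @param elimination_ratio fraction of surviving features eliminated per
#'   level; survivors follow `ceiling((1 - ratio) * n)`.
#' @param rfe_splits pre-drawn inner training splits per fold.
#' @param splits_per_level inner splits consumed per RFE level.
#' @param split_fraction fraction of training trials per inner split.
#' @param smoothing_sd weight-map smoothing SD (mm).
#' @param n_permutations label permutations for the null distribution.
#' @param svm_cost soft-margin cost of the linear SVM.
#' @param consistency_fraction top fraction of discriminative vertices
#'   entering the consistency map.
#' @param report_level which RFE level's accuracy is the subject accuracy:
#'   `"final"` (fewest features; default) or `"best"` (level with highest
#'   inner-split accuracy, chosen within the training data).
#'
#' @return An object of class `decode_config`.
#' @export
decode_config <- function(n_balanced_datasets = 10L, k_folds = 4L,
                          rfe_levels = 10L, elimination_ratio = 0.30,
                          rfe_splits = 50L, splits_per_level = 5L,
                          split_fraction = 0.90, smoothing_sd = 5,
                          n_permutations = 200L, svm_cost = 1,
                          consistency_fraction = 0.20,
                          report_level = c("final", "best")) {
  report_level <- match.arg(report_level)
  fracs <- c(elimination_ratio, split_fraction)
  if (any(fracs <= 0) || any(fracs >= 1)) {
    stop("decode parameter error: ratios must lie in (0, 1)")
  }
  if (consistency_fraction <= 0 || consistency_fraction > 1) {
    stop("decode parameter error: consistency_fraction must lie in (0, 1]")
  }
  counts <- c(n_balanced_datasets, k_folds, rfe_levels, rfe_splits,
              splits_per_level, n_permutations)
  if (any(counts < 1)) stop("decode parameter error: counts must be positive")
  if (svm_cost <= 0) stop("decode parameter error: svm_cost must be > 0")
  structure(
    list(
      n_balanced_datasets = as.integer(n_balanced_datasets),
      k_folds = as.integer(k_folds), rfe_levels = as.integer(rfe_levels),
      elimination_ratio = elimination_ratio,
      rfe_splits = as.integer(rfe_splits),
      splits_per_level = as.integer(splits_per_level),
      split_fraction = split_fraction, smoothing_sd = smoothing_sd,
      n_permutations = as.integer(n_permutations), svm_cost = svm_cost,
      consistency_fraction = consistency_fraction,
      report_level = report_level
    ),
    class = "decode_config"
  )
}

# deterministic sub-seed fan-out (kept below 2^31)
sub_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + p + 1) %% 2147483647
  as.integer(s)
}

#' Build class-balanced trial datasets
#'
#' When the two percept classes are unbalanced, creates
#' `n_balanced_datasets` datasets each containing every minority-class
#' trial plus a with-replacement sample of majority-class trials of equal
#' count. When the classes are already balanced, the original trial set is
#' returned unchanged in each dataset.
#'
#' @param labels per-trial class labels (two levels).
#' @param config a `decode_config`.
#' @param seed integer seed.
#'
#' @return List of `n_balanced_datasets` integer index vectors (multisets)
#'   into the trial set.
#' @export
#' @examples
#' balance_datasets(rep(c(1, 0), c(6, 4)), decode_config())
balance_datasets <- function(labels, config = decode_config(), seed = 1L) {
  cls <- unique(labels)
  if (length(cls) != 2L) {
    stop("class error: exactly two classes required, got ", length(cls))
  }
  n_by <- table(match(labels, cls))
  if (n_by[1] == n_by[2]) {
    return(replicate(config$n_balanced_datasets, seq_along(labels),
                     simplify = FALSE))
  }
  minority <- cls[which.min(n_by)]
  min_idx <- which(labels == minority)
  maj_idx <- which(labels != minority)
  withr::with_seed(seed, {
    lapply(seq_len(config$n_balanced_datasets), function(d) {
      sort(c(min_idx,
             maj_idx[sample.int(length(maj_idx), length(min_idx),
                                replace = TRUE)]))
    })
  })
}

#' Class-stratified k-fold partition
#'
#' @param labels labels of the (balanced) dataset trials.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#'
#' @return List of `k` disjoint test-index vectors covering the dataset,
#'   each containing a near-equal share of every class.
#' @export
split_folds <- function(labels, k, seed = 1L) {
  n <- length(labels)
  if (k < 2) stop("partition error: k must be at least 2 (no held-out data)")
  if (n < k) stop("partition error: dataset size ", n, " is below k = ", k)
  withr::with_seed(seed, {
    folds <- vector("list", k)
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      assign_to <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], idx[assign_to == f])
      }
    }
  })
  lapply(folds, sort)
}

#' Normalize features by training-set statistics
#'
#' Columns of the training set are z-scored across trials; the training
#' mean and SD are then applied to the test set, so no test information
#' enters the normalization. Constant training columns are set to zero in
#' both sets and flagged.
#'
#' @param train,test trial x feature matrices.
#'
#' @return List with `train`, `test` and logical `constant` per column.
#' @export
zscore_train_test <- function(train, test) {
  if (nrow(train) < 2) stop("normalization error: need >= 2 training trials")
  mu <- colMeans(train)
  # population SD (denominator n), the usual MVPA z-score convention
  sdev <- sqrt(colMeans(sweep(train, 2, mu)^2))
  const <- !is.finite(sdev) | sdev == 0
  sdev[const] <- 1
  tr <- sweep(sweep(train, 2, mu), 2, sdev, "/")
  te <- sweep(sweep(test, 2, mu), 2, sdev, "/")
  tr[, const] <- 0
  te[, const] <- 0
  list(train = tr, test = te, constant = const)
}

#' Train a soft-margin linear support vector machine
#'
#' Thin wrapper around [e1071::svm()] (libsvm SMO) exposing the primal
#' weight vector and bias of the decision function `sign(w . x + b)`.
#' Deterministic given the input order and cost.
#'
#' @param x trial x feature matrix (finite values).
#' @param y two-class labels.
#' @param cost soft-margin cost.
#'
#' @return An object of class `linear_svm` with `w`, `b`, `positive_class`
#'   (predicted when `w . x + b > 0`), `negative_class`, `levels`.
#' @export
train_linear_svm <- function(x, y, cost = 1) {
  if (!all(is.finite(x))) stop("input error: non-finite feature values")
  yf <- factor(y)
  if (nlevels(yf) != 2L) stop("class error: exactly two classes required")
  m <- e1071::svm(x = x, y = yf, kernel = "linear", cost = cost,
                  scale = FALSE)
  w <- drop(t(m$coefs) %*% m$SV)
  structure(
    list(
      w = w, b = -m$rho,
      positive_class = m$levels[m$labels[1]],
      negative_class = m$levels[m$labels[2]],
      levels = levels(yf)
    ),
    class = "linear_svm"
  )
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  score <- drop(as.matrix(newdata) %*% object$w + object$b)
  ifelse(score > 0, object$positive_class, object$negative_class)
}

svm_accuracy <- function(model, x, y) {
  mean(predict(model, x) == as.character(y))
}

#' Smooth, rectify and rank SVM weight maps
#'
#' Weight maps over the surviving features are smoothed with a Gaussian
#' filter (SD in mm) on the lattice geometry restricted to the surviving
#' feature set, converted to absolute values, and ranked in descending
#' order (rank 1 = most discriminative). Ties are broken by vertex index.
#' With `sd_mm = 0` the ranking equals the rank of the raw absolute
#' weights.
#'
#' @param weights numeric weights over `vertices`.
#' @param vertices vertex indices of the surviving features.
#' @param geometry an `roi_geometry`.
#' @param sd_mm smoothing SD (mm).
#'
#' @return Integer ranks aligned with `vertices`.
#' @export
smooth_rank_weights <- function(weights, vertices, geometry, sd_mm = 5) {
  score <- abs(smooth_vertex_map(weights, geometry, sd_mm, mask = vertices))
  ord <- order(-score, vertices)
  ranks <- integer(length(vertices))
  ranks[ord] <- seq_along(vertices)
  ranks
}

# stratified inner split of 90% of the training trials
draw_inner_splits <- function(labels, config) {
  lapply(seq_len(config$rfe_splits), function(s) {
    take <- integer(0)
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      n_take <- max(1L, round(config$split_fraction * length(idx)))
      n_take <- min(n_take, length(idx))
      take <- c(take, idx[sample.int(length(idx), n_take)])
    }
    sort(take)
  })
}

#' Recursive feature elimination with smoothed-weight ranking
#'
#' Runs `rfe_levels` elimination levels on a training set. At each level,
#' `splits_per_level` of the `rfe_splits` pre-drawn inner splits (90% of
#' the training trials, consumed in order) train linear SVMs on the
#' surviving features; their smoothed, rectified weight ranks are averaged,
#' the bottom `elimination_ratio` of features is eliminated (survivors =
#' `ceiling((1 - ratio) * n)`), and the level's accuracy is the mean
#' accuracy of those splits on their held-out 10%.
#'
#' @param x training trial x feature matrix (normalized).
#' @param y training labels.
#' @param vertices vertex indices of the feature columns.
#' @param geometry an `roi_geometry`.
#' @param config a `decode_config`.
#' @param seed integer seed for the inner splits.
#'
#' @return List with `survivors` (list of vertex-id vectors after each
#'   level), `level_accuracy`, `elimination_level` (aligned with
#'   `vertices`; survivors of the final level get `rfe_levels + 1`), and
#'   `exhausted` (TRUE when features ran out before the final level).
#' @export
run_rfe <- function(x, y, vertices, geometry, config = decode_config(),
                    seed = 1L) {
  if (ncol(x) < 2) stop("rfe error: at least 2 initial features required")
  stopifnot(ncol(x) == length(vertices))
  n <- nrow(x)
  splits <- withr::with_seed(seed, draw_inner_splits(y, config))
  surv <- seq_along(vertices) # column positions
  survivors <- vector("list", config$rfe_levels)
  level_acc <- rep(NA_real_, config$rfe_levels)
  elim_level <- rep(NA_integer_, length(vertices))
  exhausted <- FALSE
  for (L in seq_len(config$rfe_levels)) {
    s_idx <- ((L - 1L) * config$splits_per_level +
                seq_len(config$splits_per_level) - 1L) %%
      config$rfe_splits + 1L
    rank_sum <- numeric(length(surv))
    accs <- numeric(0)
    for (s in s_idx) {
      tr_i <- splits[[s]]
      te_i <- setdiff(seq_len(n), tr_i)
      fit <- train_linear_svm(x[tr_i, surv, drop = FALSE], y[tr_i],
                              cost = config$svm_cost)
      rank_sum <- rank_sum +
        smooth_rank_weights(fit$w, vertices[surv], geometry,
                            config$smoothing_sd)
      if (length(te_i) > 0) {
        accs <- c(accs, svm_accuracy(fit, x[te_i, surv, drop = FALSE],
                                     y[te_i]))
      }
    }
    level_acc[L] <- mean(accs)
    n_next <- ceiling((1 - config$elimination_ratio) * length(surv))
    if (n_next < 1) {
      elim_level[surv] <- L
      exhausted <- TRUE
      break
    }
    ord <- order(rank_sum / config$splits_per_level, vertices[surv])
    keep <- sort(surv[ord[seq_len(n_next)]])
    elim_level[setdiff(surv, keep)] <- L
    surv <- keep
    survivors[[L]] <- vertices[surv]
  }
  elim_level[surv] <- config$rfe_levels + 1L
  list(survivors = survivors, level_accuracy = level_acc,
       elimination_level = elim_level, exhausted = exhausted,
       final_survivors = vertices[surv])
}

# shared pipeline engine for decode_subject and permutation_null
decode_engine <- function(features, labels, roi_mask, geometry, config,
                          seed, shuffle_train = FALSE, perm = 0L,
                          compute_maps = TRUE) {
  labels <- as.character(labels)
  sets <- balance_datasets(labels, config, seed = sub_seed(seed, 1))
  n_folds_total <- config$n_balanced_datasets * config$k_folds
  fold_acc <- numeric(0)
  per_level <- matrix(NA_real_, config$rfe_levels, n_folds_total)
  elim_sum <- numeric(length(roi_mask))
  n_maps <- 0L
  fold_id <- 0L
  for (d in seq_along(sets)) {
    idx <- sets[[d]]
    y_d <- labels[idx]
    folds <- split_folds(y_d, config$k_folds, seed = sub_seed(seed, 2, d))
    for (f in seq_along(folds)) {
      fold_id <- fold_id + 1L
      te <- folds[[f]]
      tr <- setdiff(seq_along(idx), te)
      stopifnot(length(intersect(tr, te)) == 0L)
      x_tr <- features[idx[tr], , drop = FALSE]
      x_te <- features[idx[te], , drop = FALSE]
      y_tr <- y_d[tr]
      y_te <- y_d[te]
      if (shuffle_train) {
        y_tr <- withr::with_seed(sub_seed(seed, 3, d, f, perm),
                                 sample(y_tr))
      }
      if (length(unique(y_tr)) < 2L) next
      z <- zscore_train_test(x_tr, x_te)
      rfe <- run_rfe(z$train, y_tr, roi_mask, geometry, config,
                     seed = sub_seed(seed, 4, d, f, perm))
      # test accuracy at every level that produced a survivor set
      lvl_surv <- rfe$survivors
      for (L in seq_len(config$rfe_levels)) {
        vs <- lvl_surv[[L]]
        if (is.null(vs)) next
        cols <- match(vs, roi_mask)
        fit_l <- train_linear_svm(z$train[, cols, drop = FALSE], y_tr,
                                  cost = config$svm_cost)
        per_level[L, fold_id] <-
          svm_accuracy(fit_l, z$test[, cols, drop = FALSE], y_te)
      }
      report_L <- if (config$report_level == "final") {
        max(which(!vapply(lvl_surv, is.null, logical(1))))
      } else {
        which.max(rfe$level_accuracy)
      }
      fold_acc <- c(fold_acc, per_level[report_L, fold_id])
      if (compute_maps) {
        elim_sum <- elim_sum + rfe$elimination_level
        n_maps <- n_maps + 1L
      }
    }
  }
  list(
    fold_accuracies = fold_acc,
    mean_accuracy = mean(fold_acc),
    per_level_accuracies = per_level,
    discriminative_map = if (compute_maps && n_maps > 0) elim_sum / n_maps
      else NULL
  )
}

#' Decode percepts from single-trial response patterns
#'
#' Runs the full within-subject decoding pipeline on single-trial betas of
#' the ambiguous post-test trials, labelled by the subject's perceptual
#' responses: class balancing, stratified k-fold cross-validation,
#' train-statistics z-normalization, recursive feature elimination with
#' smoothed-weight ranking, and linear SVM evaluation on each fold's test
#' set at the reporting level. The discriminative map records, per ROI
#' vertex, the mean RFE level at which the vertex was eliminated (final
#' survivors count as `rfe_levels + 1`), averaged over the 40 folds.
#'
#' @param betas a `trial_betas` object or trial x vertex matrix over all
#'   grid vertices.
#' @param labels perceptual labels of the trials (two classes, e.g. 0/1).
#' @param roi_mask vertex indices of the decoding ROI.
#' @param geometry an `roi_geometry`.
#' @param config a `decode_config`.
#' @param seed integer seed.
#'
#' @return An object of class `decoding_result` with `fold_accuracies`,
#'   `mean_accuracy`, `per_level_accuracies` (levels x folds),
#'   `discriminative_map` (over `roi_mask`), `consistency_selection` (top
#'   `consistency_fraction` vertex ids), `roi_mask`, `config`.
#' @export
decode_subject <- function(betas, labels, roi_mask, geometry,
                           config = decode_config(), seed = 1L) {
  B <- if (inherits(betas, "trial_betas")) betas$beta else as.matrix(betas)
  roi_mask <- check_mask(roi_mask, geometry, "roi_mask")
  if (length(labels) != nrow(B)) {
    stop("labels must match the number of trials")
  }
  features <- B[, roi_mask, drop = FALSE]
  res <- decode_engine(features, labels, roi_mask, geometry, config, seed)
  n_sel <- max(1L, round(config$consistency_fraction * length(roi_mask)))
  ord <- order(-res$discriminative_map, roi_mask)
  res$consistency_selection <- sort(roi_mask[ord[seq_len(n_sel)]])
  res$roi_mask <- roi_mask
  res$config <- config
  class(res) <- "decoding_result"
  res
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result> mean accuracy ",
      sprintf("%.3f", x$mean_accuracy), " over ",
      length(x$fold_accuracies), " folds\n", sep = "")
  invisible(x)
}

#' Permutation null distribution of decoding accuracy
#'
#' Repeats the identical decoding pipeline with the training labels
#' randomly shuffled within each training set (test labels intact), giving
#' the chance distribution of the subject's mean accuracy.
#'
#' @inheritParams decode_subject
#'
#' @return Numeric vector of `n_permutations` mean accuracies.
#' @export
permutation_null <- function(betas, labels, roi_mask, geometry,
                             config = decode_config(), seed = 1L) {
  B <- if (inherits(betas, "trial_betas")) betas$beta else as.matrix(betas)
  roi_mask <- check_mask(roi_mask, geometry, "roi_mask")
  features <- B[, roi_mask, drop = FALSE]
  vapply(seq_len(config$n_permutations), function(p) {
    decode_engine(features, labels, roi_mask, geometry, config, seed,
                  shuffle_train = TRUE, perm = p,
                  compute_maps = FALSE)$mean_accuracy
  }, numeric(1))
}

#' Group-level Wilcoxon signed-rank test of decoding accuracy
#'
#' Compares single-subject accuracies with the mean of each subject's
#' permutation null using a two-sided Wilcoxon signed-rank test; the exact
#' distribution is used for n <= 25 when no ties or zero differences
#' occur.
#'
#' @param subject_accuracies per-subject mean accuracies.
#' @param subject_null_means per-subject mean permutation accuracies.
#'
#' @return List with `p_value`, `statistic` (V), `n`, `method`.
#' @export
group_wilcoxon <- function(subject_accuracies, subject_null_means) {
  stopifnot(length(subject_accuracies) == length(subject_null_means))
  n <- length(subject_accuracies)
  if (n < 5) stop("at least 5 paired subjects required")
  d <- subject_accuracies - subject_null_means
  if (all(d == 0)) {
    return(list(p_value = 1, statistic = NA_real_, n = n,
                method = "degenerate (all differences zero)"))
  }
  exact <- n <= 25 && !any(d == 0) && !any(duplicated(abs(d)))
  ht <- suppressWarnings(
    wilcox.test(subject_accuracies, subject_null_means, paired = TRUE,
                alternative = "two.sided", exact = exact)
  )
  list(p_value = ht$p.value, statistic = unname(ht$statistic), n = n,
       method = ht$method)
}

#' Inter-subject consistency map of discriminative vertices
#'
#' For each subject, selects the top `consistency_fraction` of ROI vertices
#' by discriminative value (ties broken by vertex index) and counts, per
#' vertex, the number of subjects whose top set contains it.
#'
#' @param per_subject_maps subject x vertex matrix of discriminative values
#'   over the shared ROI (e.g. `discriminative_map` of
#'   [decode_subject()]).
#' @param roi_mask vertex indices of the shared ROI.
#' @param config a `decode_config`.
#'
#' @return Integer counts aligned with `roi_mask`.
#' @export
consistency_map <- function(per_subject_maps, roi_mask,
                            config = decode_config()) {
  m <- as.matrix(per_subject_maps)
  if (ncol(m) != length(roi_mask)) {
    stop("maps must share the ROI (columns must match roi_mask)")
  }
  frac <- config$consistency_fraction
  if (frac <= 0 || frac > 1) {
    stop("decode parameter error: consistency_fraction must lie in (0, 1]")
  }
  n_sel <- max(1L, round(frac * length(roi_mask)))
  counts <- integer(length(roi_mask))
  for (s in seq_len(nrow(m))) {
    ord <- order(-m[s, ], roi_mask)
    counts[ord[seq_len(n_sel)]] <- counts[ord[seq_len(n_sel)]] + 1L
  }
  counts
}
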