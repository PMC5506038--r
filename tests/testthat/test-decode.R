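test_that("class balancing resamples the majority to the minority count", {
  labels <- rep(c(1, 0), c(6, 4))
  sets <- balance_datasets(labels, decode_config(), seed = 1)
  expect_length(sets, 10)
  for (s in sets) {
    expect_length(s, 8)
    expect_equal(as.integer(table(labels[s])), c(4L, 4L))
    expect_true(all(which(labels == 0) %in% s)) # all minority trials kept
  }
  # equal counts -> identity
  eq <- balance_datasets(rep(c(1, 0), each = 5), decode_config(), seed = 1)
  expect_true(all(vapply(eq, identical, logical(1), y = 1:10)))
  expect_error(balance_datasets(rep(1, 10), decode_config()), "class error")
})

test_that("stratified folds partition the dataset", {
  labels <- rep(c("a", "b"), each = 4)
  folds <- split_folds(labels, 4, seed = 2)
  expect_length(folds, 4)
  expect_setequal(unlist(folds), 1:8)
  expect_equal(sum(lengths(folds)), 8)
  for (f in folds) expect_equal(length(f), 2)
  expect_error(split_folds(labels, 1), "partition error")
  expect_error(split_folds(labels[1:3], 4), "partition error")
  # 10 balanced datasets x 4 folds = 40 cross-validation folds
  sets <- balance_datasets(rep(c(1, 0), c(7, 5)), decode_config(), seed = 1)
  total <- sum(vapply(sets, function(s)
    length(split_folds(rep(c(1, 0), c(5, 5)), 4, 1)), integer(1)))
  expect_equal(total, 40)
})

test_that("train statistics normalize the test set without leakage", {
  z <- zscore_train_test(matrix(c(1, 3), 2, 1), matrix(2, 1, 1))
  expect_equal(as.vector(z$train), c(-1, 1))
  expect_equal(as.vector(z$test), 0)
  # idempotent on standardized input
  withr::with_seed(1, x <- matrix(rnorm(20), 5, 4))
  x <- apply(x, 2, function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2)))
  z2 <- zscore_train_test(x, x)
  expect_equal(z2$train, x, tolerance = 1e-12, ignore_attr = TRUE)
  # constant column convention
  z3 <- zscore_train_test(matrix(5, 3, 1), matrix(7, 2, 1))
  expect_true(all(z3$train == 0) && all(z3$test == 0))
  expect_true(z3$constant)
})

test_that("linear SVM separates, fails on XOR, and recovers planted rules", {
  x <- rbind(c(1, 0), c(-1, 0))
  fit <- train_linear_svm(x, c("p", "n"), cost = 10)
  expect_equal(unname(predict(fit, rbind(c(2, 0)))), "p")
  # XOR is linearly inseparable
  xx <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  fx <- train_linear_svm(xx, c(1, 1, 0, 0), cost = 100)
  expect_lte(mean(predict(fx, xx) == as.character(c(1, 1, 0, 0))), 0.75)
  # planted weight direction
  withr::with_seed(7, {
    w_star <- c(2, -1, 0.5, 0, 0)
    X <- matrix(rnorm(400 * 5), 400, 5)
    y <- as.integer(X %*% w_star > 0)
    keep <- abs(X %*% w_star) > 0.5 # margin
    f <- train_linear_svm(X[keep, ], y[keep], cost = 10)
  })
  w <- f$w * if (f$positive_class == "1") 1 else -1
  ang <- acos(sum(w * w_star) / sqrt(sum(w^2) * sum(w_star^2))) * 180 / pi
  expect_lt(ang, 15)
  expect_error(train_linear_svm(matrix(c(NA, 1), 2, 1), c(0, 1)),
               "input error")
})

test_that("smoothed weight ranking is kernel-monotone with index tie-breaks", {
  g <- make_roi_geometry(c(10, 10), spacing_mm = 2)
  vts <- 1:100
  w <- numeric(100)
  w[45] <- 1
  r <- smooth_rank_weights(w, vts, g, sd_mm = 4)
  expect_equal(which(r == 1), 45)
  expect_lt(r[44], r[25]) # direct neighbor outranks a distant vertex
  # sd 0 reduces to raw |w| ranking
  w2 <- rnorm(100)
  r0 <- smooth_rank_weights(w2, vts, g, sd_mm = 0)
  expect_equal(order(-abs(w2)), order(r0))
  # all-equal weights -> vertex-index order
  re <- smooth_rank_weights(rep(1, 100), vts, g, sd_mm = 4)
  expect_true(all(diff(order(re)) >= 0) || all(re == seq_len(100)))
})

test_that("RFE survivor counts follow the ceiling recursion and limits", {
  g <- make_roi_geometry(c(8, 8))
  withr::with_seed(1, {
    x <- matrix(rnorm(20 * 64), 20, 64)
    y <- rep(c(0, 1), 10)
  })
  cfg <- decode_config(rfe_levels = 5, rfe_splits = 10, splits_per_level = 2,
                       smoothing_sd = 2)
  r <- run_rfe(x, y, 1:64, g, cfg, seed = 1)
  expected <- Reduce(function(n, .) ceiling(0.7 * n), 1:5, accumulate = TRUE,
                     init = 64)[-1]
  expect_equal(lengths(r$survivors), expected)
  expect_false(r$exhausted)
  # elimination levels partition the features
  expect_setequal(unique(r$elimination_level), c(1:5, 6))
  # near-zero elimination ratio keeps the survivor set constant
  cfg0 <- decode_config(rfe_levels = 3, rfe_splits = 6, splits_per_level = 2,
                        elimination_ratio = 1e-9, smoothing_sd = 2)
  r0 <- run_rfe(x, y, 1:64, g, cfg0, seed = 1)
  expect_true(all(lengths(r0$survivors) == 64))
})

test_that("RFE retains planted informative features", {
  g <- make_roi_geometry(c(10, 10))
  n_inf <- 10
  withr::with_seed(5, {
    keep_frac <- replicate(8, {
      y <- rep(c(0, 1), each = 15)
      x <- matrix(rnorm(30 * 100), 30, 100)
      x[, 1:n_inf] <- x[, 1:n_inf] + outer(ifelse(y == 1, 1, -1),
                                           rep(1.2, n_inf))
      cfg <- decode_config(rfe_levels = 5, rfe_splits = 10,
                           splits_per_level = 2, smoothing_sd = 0)
      r <- run_rfe(x, y, 1:100, g, cfg, seed = sample.int(1e6, 1))
      mean(1:n_inf %in% r$final_survivors)
    })
  })
  expect_gte(mean(keep_frac), 0.5)
})

test_that("subject decoding is deterministic and at chance for null data", {
  g <- small_geometry()
  cfg <- fast_decode_config()
  withr::with_seed(11, {
    feats <- matrix(rnorm(48 * 144), 48, 144)
    labels <- rep(c(0, 1), 24)
  })
  r1 <- decode_subject(feats, labels, 1:100, g, cfg, seed = 3)
  r2 <- decode_subject(feats, labels, 1:100, g, cfg, seed = 3)
  expect_identical(r1$fold_accuracies, r2$fold_accuracies)
  expect_identical(r1$discriminative_map, r2$discriminative_map)
  expect_lt(abs(r1$mean_accuracy - 0.5), 3 * sqrt(0.25 / 48))
  expect_true(all(r1$fold_accuracies >= 0 & r1$fold_accuracies <= 1))
  expect_length(r1$fold_accuracies,
                cfg$n_balanced_datasets * cfg$k_folds)
})

test_that("exact signed-rank p values match enumeration", {
  acc <- seq(0.55, 0.69, by = 0.01)
  null <- rep(0.5, 15)
  r <- group_wilcoxon(acc, null)
  expect_equal(r$p_value, 2 / 2^15)
  expect_equal(group_wilcoxon(null, null)$p_value, 1)
  withr::with_seed(2, {
    ps <- replicate(40, group_wilcoxon(0.5 + rnorm(8, 0, 0.03),
                                       rep(0.5, 8))$p_value)
  })
  expect_gt(mean(ps), 0.4) # symmetric differences are non-significant on average
})

test_that("consistency map counts subjects' top-fraction selections", {
  roi <- 1:10000
  cfg <- decode_config()
  one <- rep(seq(1, 11, length.out = 10000))
  maps <- matrix(one, nrow = 15, ncol = 10000, byrow = TRUE)
  cm <- consistency_map(maps, roi, cfg)
  expect_equal(sum(cm == 15), 2000) # top 20% of a 10,000-vertex ROI
  expect_true(all(cm %in% c(0L, 15L)))
  # disjoint top sets across subjects
  m2 <- matrix(0, 5, 100)
  for (s in 1:5) m2[s, ((s - 1) * 20 + 1):(s * 20)] <- 1
  cm2 <- consistency_map(m2, 1:100, cfg)
  expect_equal(max(cm2), 1)
  expect_error(consistency_map(maps, 1:50, cfg), "share the ROI")
})
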