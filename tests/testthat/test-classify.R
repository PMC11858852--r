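test_that("standardization has closed-form behaviour and is reusable", {
  out <- standardize(data.frame(a = c(1, 2, 3), b = c(10, 20, 60)))
  expect_equal(out$scaled$a, c(-1, 0, 1))
  expect_equal(mean(out$scaled$b), 0, tolerance = 1e-12)
  expect_equal(sd(out$scaled$b), 1, tolerance = 1e-12)
  # re-applying stored params reproduces the scaled table exactly
  again <- standardize_apply(data.frame(a = c(1, 2, 3), b = c(10, 20, 60)),
                             out$params)
  expect_equal(as.data.frame(again), as.data.frame(out$scaled), tolerance = 1e-15)
  expect_error(standardize(data.frame(a = c(1, 1, 1))), "zero-variance.*a")
  expect_error(standardize(data.frame(a = 1)), "at least 2 rows")
})

test_that("balanced class weights equal N / (K * n_c)", {
  y <- factor(rep(c("RF", "LF", "RH", "LH", "SOUND"),
                  times = c(92, 89, 39, 36, 31)),
              levels = c("RF", "LF", "RH", "LH", "SOUND"))
  w <- class_weights(y, "balanced")
  expect_equal(unname(w["RF"]), 287 / (5 * 92), tolerance = 1e-12)
  expect_equal(round(unname(w["RF"]), 4), 0.6239)
  expect_equal(unname(w["SOUND"]), 287 / (5 * 31), tolerance = 1e-12)

  balanced <- factor(rep(letters[1:5], each = 10))
  expect_equal(unname(class_weights(balanced, "balanced")), rep(1, 5))
  expect_equal(unname(class_weights(y, "none")), rep(1, 5))
  y_missing <- factor(c("RF", "RF"), levels = c("RF", "LF"))
  expect_error(class_weights(y_missing, "balanced"), "empty class")
})

test_that("well-separated classes are fit perfectly at every cost", {
  d <- separable_xy(n = 15)
  cfg <- svm_config(tune_reps = 5, bootstrap_reps = 5, seed = 3)
  m <- train_svm(d$x, d$y, cfg)
  expect_true(all(tidy(m)$mean_accuracy > 0.95))
  expect_equal(as.character(predict(m, d$x)), as.character(d$y))
  expect_true(m$cost %in% cfg$cost_grid)
})

test_that("grid search is deterministic and breaks ties toward small cost", {
  feats <- small_cohort_features(n_per_class = 6, seed = 21)
  cfg <- svm_config(tune_reps = 5, bootstrap_reps = 5, seed = 9)
  m1 <- fit_lameness_svm(feats, cfg)
  m2 <- fit_lameness_svm(feats, cfg)
  expect_identical(m1$cost, m2$cost)
  expect_equal(tidy(m1)$mean_accuracy, tidy(m2)$mean_accuracy, tolerance = 1e-15)
  # tie-break: constant accuracies select the smallest cost
  grid <- tidy(m1)
  best <- which(grid$mean_accuracy == max(grid$mean_accuracy))
  expect_equal(m1$cost, grid$cost[best[1]])
})

test_that("confusion matrices satisfy their accounting identities", {
  y <- as_lameness_label(c("RF", "RF", "LF", "RH", "LH", "SOUND", "SOUND"))
  p <- as_lameness_label(c("RF", "LF", "LF", "RH", "LH", "SOUND", "RF"))
  cm <- confusion_and_accuracy(y, p)
  expect_equal(sum(cm$counts), 7)
  expect_equal(unname(rowSums(cm$counts)),
               as.vector(table(y)[rownames(cm$counts)]))
  # overall accuracy equals the count-weighted mean of per-class accuracies
  pc <- cm$per_class
  expect_equal(cm$overall_pct,
               sum(pc$accuracy_pct * pc$n, na.rm = TRUE) / sum(pc$n),
               tolerance = 1e-12)
  # row percentages sum to 100 for non-empty rows
  sums <- rowSums(cm$row_percent)
  expect_true(all(abs(sums[!is.na(sums)] - 100) < 0.1))
  # identity predictions give 100 % everywhere
  ident <- confusion_and_accuracy(y, y)
  expect_true(all(ident$per_class$accuracy_pct[ident$per_class$n > 0] == 100))
  expect_error(confusion_and_accuracy(y, p[1:3]), "length mismatch")
  expect_error(confusion_and_accuracy(c("RF", "??"), c("RF", "RF")), "Unknown")
})

test_that("confusion counts are permutation-equivariant under relabeling", {
  set.seed(4)
  y <- sample(lameness_levels(), 60, replace = TRUE)
  p <- sample(lameness_levels(), 60, replace = TRUE)
  cm <- confusion_and_accuracy(y, p)
  swap <- function(v) ifelse(v == "RF", "LF", ifelse(v == "LF", "RF", v))
  cm2 <- confusion_and_accuracy(swap(y), swap(p))
  perm <- c("LF", "RF", "RH", "LH", "SOUND")
  expect_equal(unname(cm2$counts[perm, perm]), unname(cm$counts))
})

test_that("bootstrap validation is seeded, reproducible, and sane on separable data", {
  set.seed(1)
  y <- rep(c("RF", "LF"), each = 12)
  base <- matrix(rnorm(24 * 27, sd = 0.05), 24, 27)
  base[y == "LF", ] <- base[y == "LF", ] + 4
  colnames(base) <- feature_names()
  feats <- dplyr::bind_cols(tibble::tibble(label = y), as.data.frame(base))
  cfg <- svm_config(bootstrap_reps = 10, tune_reps = 3, seed = 5)
  v1 <- bootstrap_validate(feats, cfg, cost = 1)
  v2 <- bootstrap_validate(feats, cfg, cost = 1)
  expect_identical(v1$accuracy, v2$accuracy)
  expect_gte(v1$mean, 0.99)

  single <- bootstrap_validate(feats, svm_config(bootstrap_reps = 1, seed = 2),
                               cost = 1)
  expect_true(single$accuracy >= 0 && single$accuracy <= 1)
  expect_equal(single$B, 1L)
})

test_that("label-permuted features score at chance for balanced classes", {
  set.seed(13)
  n_per <- 12
  y <- factor(rep(lameness_levels(), each = n_per), levels = lameness_levels())
  X <- as.data.frame(matrix(rnorm(5 * n_per * 27), ncol = 27))
  names(X) <- feature_names()
  feats <- dplyr::bind_cols(tibble::tibble(label = as.character(y)), X)
  v <- bootstrap_validate(feats, svm_config(bootstrap_reps = 30, seed = 17),
                          cost = 1)
  # chance level 1/5 within Monte-Carlo error of the bootstrap distribution
  expect_lt(abs(v$mean - 0.2), max(3 * v$sd, 0.1))
})

test_that("variable importance identifies separators and ignores noise", {
  set.seed(6)
  n <- 40
  y <- as_lameness_label(rep(c("RF", "LF", "RH", "LH", "SOUND"), each = n / 5))
  feats <- tibble::tibble(
    AsI_up_H = as.numeric(y == "RF") + rnorm(n, sd = 1e-6),  # perfect separator
    ROM_H = rnorm(n),                                        # label-independent
    stride_frequency = rep(1.4, n))                          # constant
  imp <- variable_importance(feats, y)
  expect_true(all(as.matrix(imp[, -1]) >= 0 & as.matrix(imp[, -1]) <= 100))
  expect_equal(imp$RF[imp$feature == "AsI_up_H"], 100)
  expect_equal(imp$RF[imp$feature == "stride_frequency"], 0)
  # a label-independent feature scores near the folded-AUC floor
  auc <- attr(imp, "folded_auc")
  expect_lt(max(auc["ROM_H", ]), 0.75)
  # min-max scaling leaves at least one 0 and one 100
  vals <- as.matrix(imp[, -1])
  expect_equal(max(vals), 100)
  expect_equal(min(vals), 0)
})

test_that("importance AUCs agree with caret's filter importance", {
  skip_if_not_installed("caret")
  set.seed(8)
  n <- 30
  y <- factor(rep(c("pos", "neg"), each = n / 2))
  X <- data.frame(u = rnorm(n, mean = as.numeric(y == "pos")), v = rnorm(n))
  ours <- attr(variable_importance(X, ifelse(y == "pos", "RF", "LF")), "folded_auc")
  caret_imp <- caret::filterVarImp(X, y)
  expect_equal(unname(ours[, "RF"]), unname(caret_imp$pos), tolerance = 1e-9)
})

test_that("training rejects degenerate label sets", {
  d <- separable_xy(n = 5)
  expect_error(train_svm(d$x, factor(rep("a", 10)), svm_config()), "2 classes")
  expect_error(train_svm(d$x, d$y[1:3], svm_config()), "sizes differ")
  yy <- factor(c(rep("a", 9), "b"))
  expect_error(train_svm(d$x, yy, svm_config()), ">= 2 members")
})
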