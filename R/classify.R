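#' Configuration of the class-weighted RBF-SVM
#'
#' Kernel: `K(x, x') = exp(-sigma * ||x - x'||^2)` (so `sigma` equals the
#' `gamma` of libsvm-style parameterizations). The cost parameter is tuned
#' over a doubling grid of 10 values from 0.25 to 128 by out-of-bag
#' bootstrap accuracy; `sigma` is held fixed. Final validation uses
#' `bootstrap_reps` seeded repetitions.
#'
#' @param sigma RBF kernel width (fixed, not tuned).
#' @param cost_grid Strictly increasing positive cost values.
#' @param class_weight_mode `"balanced"` (`N / (K * n_c)`), `"none"`, or
#'   `"custom"` (supply `custom_weights`).
#' @param custom_weights Named weights, used when mode is `"custom"`.
#' @param bootstrap_reps Repetitions of the final bootstrap validation.
#' @param tune_reps Bootstrap repetitions used inside the cost grid search.
#' @param seed Integer seed controlling every resampling draw.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(sigma = 0.036,
                       cost_grid = c(0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, 128),
                       class_weight_mode = c("balanced", "none", "custom"),
                       custom_weights = NULL,
                       bootstrap_reps = 400,
                       tune_reps = 25,
                       seed = 1) {
  class_weight_mode <- match.arg(class_weight_mode)
  if (sigma <= 0) abort("svm_config: sigma must be > 0")
  if (any(cost_grid <= 0) || is.unsorted(cost_grid, strictly = TRUE)) {
    abort("svm_config: cost_grid must be strictly increasing and positive")
  }
  if (bootstrap_reps < 1 || tune_reps < 1) {
    abort("svm_config: bootstrap_reps and tune_reps must be >= 1")
  }
  structure(list(sigma = sigma, cost_grid = cost_grid,
                 class_weight_mode = class_weight_mode,
                 custom_weights = custom_weights,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 tune_reps = as.integer(tune_reps),
                 seed = as.integer(seed)),
            class = "svm_config")
}

#' Center and scale a feature table
#'
#' @param features Data frame or matrix of numeric features.
#' @return List with `scaled` (tibble, each column mean 0, sample SD 1) and
#'   `params` (tibble `feature`, `center`, `scale`) for reuse on new data.
#' @export
standardize <- function(features) {
  x <- as.data.frame(features)
  if (nrow(x) < 2) abort("standardize: need at least 2 rows")
  if (!all(vapply(x, is.numeric, logical(1)))) abort("standardize: non-numeric column")
  if (!all(vapply(x, function(v) all(is.finite(v)), logical(1)))) {
    abort("standardize: non-finite values")
  }
  center <- vapply(x, mean, numeric(1))
  scale_ <- vapply(x, sd, numeric(1))
  if (any(scale_ == 0)) {
    abort(paste0("standardize: zero-variance feature(s): ",
                 paste(names(x)[scale_ == 0], collapse = ", ")))
  }
  params <- tibble(feature = names(x), center = unname(center),
                   scale = unname(scale_))
  list(scaled = as_tibble(sweep(sweep(as.matrix(x), 2, center), 2, scale_, "/")),
       params = params)
}

#' @rdname standardize
#' @param params Standardization parameters from a previous [standardize()].
#' @export
standardize_apply <- function(features, params) {
  x <- as.matrix(as.data.frame(features)[, params$feature, drop = FALSE])
  as_tibble(sweep(sweep(x, 2, params$center), 2, params$scale, "/"))
}

#' Class weights for imbalanced cohorts
#'
#' Balanced mode gives class `c` the weight `N / (K * n_c)` with `N` the
#' total count, `K` the number of classes (the factor's levels) and `n_c`
#' the class count, so that every class contributes equally to the loss.
#'
#' @param y Factor of class labels.
#' @param mode `"balanced"`, `"none"`, or `"custom"`.
#' @param custom_weights Named numeric used in `"custom"` mode.
#' @return Named numeric vector of weights, one per level of `y`.
#' @export
class_weights <- function(y, mode = c("balanced", "none", "custom"),
                          custom_weights = NULL) {
  mode <- match.arg(mode)
  y <- as.factor(y)
  if (length(y) == 0) abort("class_weights: empty labels")
  lev <- levels(y)
  if (mode == "none") return(setNames(rep(1, length(lev)), lev))
  if (mode == "custom") {
    if (is.null(custom_weights) || !all(lev %in% names(custom_weights))) {
      abort("class_weights: custom mode needs a named weight per level")
    }
    return(custom_weights[lev])
  }
  n_c <- table(y)
  if (any(n_c == 0)) {
    abort(paste0("class_weights: empty class in balanced mode: ",
                 paste(lev[n_c == 0], collapse = ", ")))
  }
  setNames(as.numeric(length(y) / (length(lev) * n_c)), lev)
}

# One kernlab fit at a given cost, with class weights recomputed on the
# training labels (one-vs-one multiclass, the kernlab default).
fit_ksvm <- function(X, y, cost, config) {
  w <- class_weights(y, config$class_weight_mode, config$custom_weights)
  kernlab::ksvm(as.matrix(X), y, type = "C-svc", kernel = "rbfdot",
                kpar = list(sigma = config$sigma), C = cost,
                class.weights = w, scaled = FALSE)
}

# Bootstrap index draw that guarantees every class present; counts redraws.
draw_bootstrap <- function(y, counter_env = NULL) {
  n <- length(y)
  repeat {
    idx <- sample.int(n, n, replace = TRUE)
    if (nlevels(droplevels(y[idx])) == nlevels(droplevels(y))) return(idx)
    if (!is.null(counter_env)) counter_env$redraws <- counter_env$redraws + 1L
  }
}

#' Train the cost-tuned, class-weighted RBF-SVM
#'
#' For each cost on the grid, accuracy is estimated by bootstrap
#' resampling: the SVM is fitted on a resample and evaluated on its
#' out-of-bag rows, averaged over `config$tune_reps` repetitions (the same
#' resamples are reused across costs). The cost with the highest mean
#' out-of-bag accuracy is selected (ties go to the smallest cost, favouring
#' regularization) and the model is refitted on all rows.
#'
#' @param x Standardized feature table (rows = horses).
#' @param y Factor of class labels, one per row.
#' @param config An [svm_config()].
#' @return Object of class `lameness_svm`: the kernlab fit, `cost`,
#'   `sigma`, `grid` (tibble `cost`, `mean_accuracy`), `weights`, `levels`,
#'   `seed`, and optionally `standardization` when fitted through
#'   [fit_lameness_svm()].
#' @export
train_svm <- function(x, y, config = svm_config()) {
  X <- as.matrix(as.data.frame(x))
  y <- droplevels(as.factor(y))
  if (nrow(X) != length(y)) abort("train_svm: x and y sizes differ")
  if (nlevels(y) < 2) abort("train_svm: need at least 2 classes")
  if (any(table(droplevels(y)) < 2)) {
    abort("train_svm: every present class needs >= 2 members")
  }
  set.seed(config$seed)
  env <- new.env(); env$redraws <- 0L
  resamples <- replicate(config$tune_reps, draw_bootstrap(y, env),
                         simplify = FALSE)
  acc <- matrix(NA_real_, config$tune_reps, length(config$cost_grid))
  for (j in seq_along(config$cost_grid)) {
    for (r in seq_along(resamples)) {
      idx <- resamples[[r]]
      oob <- setdiff(seq_along(y), unique(idx))
      fit <- fit_ksvm(X[idx, , drop = FALSE], droplevels(y[idx]),
                      config$cost_grid[j], config)
      pred <- kernlab::predict(fit, X[oob, , drop = FALSE])
      acc[r, j] <- mean(as.character(pred) == as.character(y[oob]))
    }
  }
  grid <- tibble(cost = config$cost_grid, mean_accuracy = colMeans(acc))
  best <- which(grid$mean_accuracy == max(grid$mean_accuracy))[1]
  final <- fit_ksvm(X, y, grid$cost[best], config)
  structure(list(fit = final,
                 cost = grid$cost[best],
                 sigma = config$sigma,
                 grid = grid,
                 weights = class_weights(y, config$class_weight_mode,
                                         config$custom_weights),
                 levels = levels(y),
                 config = config,
                 seed = config$seed,
                 tuning_redraws = env$redraws,
                 standardization = NULL),
            class = "lameness_svm")
}

#' Fit the full pipeline on a raw feature table
#'
#' Convenience wrapper: standardizes the 27 feature columns, trains the
#' cost-tuned SVM, and stores the standardization parameters in the model so
#' that [predict.lameness_svm()] can be applied to raw features.
#'
#' @param features Feature tibble from [extract_features()] (needs `label`
#'   plus the [feature_names()] columns).
#' @param config An [svm_config()].
#' @return A `lameness_svm` with embedded standardization parameters.
#' @export
fit_lameness_svm <- function(features, config = svm_config()) {
  y <- as_lameness_label(features$label)
  std <- standardize(features[, FEATURE_NAMES])
  model <- train_svm(std$scaled, y, config)
  model$standardization <- std$params
  model
}

#' @export
print.lameness_svm <- function(x, ...) {
  cat("<lameness_svm> RBF sigma =", x$sigma, ", selected cost =", x$cost,
      "\n  classes:", paste(x$levels, collapse = ", "),
      "\n  class weights:", paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Predict lameness classes
#'
#' @param object A `lameness_svm`.
#' @param newdata Feature table; standardized internally when the model was
#'   fitted with [fit_lameness_svm()], used as-is otherwise.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.lameness_svm <- function(object, newdata, ...) {
  X <- if (!is.null(object$standardization)) {
    as.matrix(standardize_apply(newdata, object$standardization))
  } else {
    as.matrix(as.data.frame(newdata)[, , drop = FALSE])
  }
  factor(as.character(kernlab::predict(object$fit, X)), levels = object$levels)
}

#' Bootstrap out-of-bag validation of the full pipeline
#'
#' For each of `config$bootstrap_reps` repetitions: draw `n` rows with
#' replacement (redrawing when a class is absent), refit the whole pipeline
#' on the resample (standardize, class weights, SVM at `cost`), and predict
#' the out-of-bag rows. Reports the distribution of out-of-bag accuracy,
#' per-class accuracies, and the out-of-bag predictions pooled over all
#' repetitions as a confusion matrix.
#'
#' @param features Raw feature tibble (`label` + [feature_names()] columns).
#' @param config An [svm_config()]; `config$seed` drives all draws.
#' @param cost Cost parameter to use; typically the one selected by
#'   [train_svm()]. If `NULL`, the grid search is run first.
#' @return Object of class `bootstrap_validation`: `accuracy` (length-B
#'   numeric), `mean`, `sd`, `per_class` (tibble rep x class), pooled
#'   `oob_confusion` (a `confusion_matrix`), `cost`, `B`, `seed`,
#'   `redraws`.
#' @export
bootstrap_validate <- function(features, config = svm_config(), cost = NULL) {
  y <- as_lameness_label(features$label)
  X <- features[, FEATURE_NAMES]
  if (is.null(cost)) {
    cost <- fit_lameness_svm(features, config)$cost
  }
  set.seed(config$seed + 1L)
  B <- config$bootstrap_reps
  env <- new.env(); env$redraws <- 0L
  accuracy <- numeric(B)
  per_class <- matrix(NA_real_, B, length(levels(y)),
                      dimnames = list(NULL, levels(y)))
  pooled_true <- character(0)
  pooled_pred <- character(0)
  for (b in seq_len(B)) {
    idx <- draw_bootstrap(y, env)
    oob <- setdiff(seq_along(y), unique(idx))
    if (length(oob) == 0) next
    std <- standardize(X[idx, ])
    fit <- fit_ksvm(as.matrix(std$scaled), droplevels(y[idx]), cost, config)
    pred <- kernlab::predict(fit, as.matrix(standardize_apply(X[oob, ], std$params)))
    truth <- as.character(y[oob]); pred <- as.character(pred)
    accuracy[b] <- mean(pred == truth)
    for (lev in levels(y)) {
      sel <- truth == lev
      per_class[b, lev] <- if (any(sel)) mean(pred[sel] == lev) else NA_real_
    }
    pooled_true <- c(pooled_true, truth)
    pooled_pred <- c(pooled_pred, pred)
  }
  structure(list(accuracy = accuracy,
                 mean = mean(accuracy),
                 sd = sd(accuracy),
                 per_class = as_tibble(per_class),
                 oob_confusion = confusion_and_accuracy(
                   as_lameness_label(pooled_true), as_lameness_label(pooled_pred)),
                 cost = cost, B = B, seed = config$seed,
                 redraws = env$redraws),
            class = "bootstrap_validation")
}

#' @export
print.bootstrap_validation <- function(x, ...) {
  cat(sprintf("<bootstrap_validation> B = %d, OOB accuracy %.3f +/- %.3f (cost %.3g)\n",
              x$B, x$mean, x$sd, x$cost))
  invisible(x)
}

#' Confusion matrix and accuracies
#'
#' Counts with rows = actual and columns = predicted in the fixed class
#' order `RF, LF, RH, LH, SOUND`, row percentages, per-class accuracy
#' (diagonal over row total) and overall accuracy (trace over total), as
#' percentages.
#'
#' @param y_true,y_pred Vectors of labels (coerced with
#'   [as_lameness_label()]).
#' @return Object of class `confusion_matrix`: `counts` (5x5 integer),
#'   `row_percent`, `per_class` (tibble `class`, `n`, `accuracy_pct`),
#'   `overall_pct`.
#' @export
confusion_and_accuracy <- function(y_true, y_pred) {
  y_true <- as_lameness_label(y_true)
  y_pred <- as_lameness_label(y_pred)
  if (length(y_true) != length(y_pred)) {
    abort("confusion_and_accuracy: length mismatch")
  }
  counts <- table(actual = y_true, predicted = y_pred)
  counts <- unclass(counts)[LAMENESS_LEVELS, LAMENESS_LEVELS]
  confusion_from_counts(counts)
}

#' @rdname confusion_and_accuracy
#' @param counts A 5x5 (or square) count matrix, rows = actual classes.
#' @export
confusion_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) abort("confusion_from_counts: non-square input")
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion_from_counts: counts must be nonnegative integers")
  }
  rs <- rowSums(counts)
  row_percent <- counts / ifelse(rs == 0, NA, rs) * 100
  per_class <- tibble(class = rownames(counts),
                      n = as.integer(rs),
                      accuracy_pct = as.numeric(diag(row_percent)))
  structure(list(counts = counts,
                 row_percent = row_percent,
                 per_class = per_class,
                 overall_pct = 100 * sum(diag(counts)) / sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(format_confusion(x), sep = "\n")
  invisible(x)
}

#' ROC-based per-class variable importance
#'
#' Model-agnostic filter importance: for every feature and class, the area
#' under the ROC curve of the raw feature separating that class from all
#' others, folded as `max(AUC, 1 - AUC)` so that direction does not matter,
#' then linearly rescaled so the global maximum is 100 and the global
#' minimum 0. A constant feature has no ROC curve and is reported at 0.
#'
#' @param features Feature table (the [feature_names()] columns are used if
#'   present, otherwise all numeric columns).
#' @param y Class labels.
#' @return Object of class `importance_table`: tibble with `feature` and one
#'   0--100 column per class, plus attribute `folded_auc` (the unscaled
#'   matrix).
#' @export
variable_importance <- function(features, y) {
  y <- as_lameness_label(y)
  if (nlevels(droplevels(y)) < 2) abort("variable_importance: need >= 2 classes")
  cols <- intersect(FEATURE_NAMES, names(features))
  if (length(cols) == 0) cols <- names(features)[vapply(features, is.numeric, logical(1))]
  classes <- levels(droplevels(y))
  auc <- matrix(NA_real_, length(cols), length(classes),
                dimnames = list(cols, classes))
  for (f in cols) {
    v <- features[[f]]
    constant <- sd(v) == 0
    for (cl in classes) {
      if (constant) next
      r <- pROC::roc(response = y == cl, predictor = v, quiet = TRUE,
                     levels = c(FALSE, TRUE), direction = "<")
      a <- as.numeric(r$auc)
      auc[f, cl] <- max(a, 1 - a)
    }
  }
  valid <- is.finite(auc)
  if (!any(valid)) abort("variable_importance: all features constant")
  rng <- range(auc[valid])
  scaled <- auc
  scaled[valid] <- if (diff(rng) == 0) 100 else {
    100 * (auc[valid] - rng[1]) / diff(rng)
  }
  scaled[!valid] <- 0
  out <- as_tibble(as.data.frame(scaled))
  out <- dplyr::bind_cols(tibble(feature = cols), out)
  structure(out, class = c("importance_table", class(out)), folded_auc = auc)
}

#' @export
print.importance_table <- function(x, ...) {
  cat("<importance_table> per-class importance, 0-100 scale\n")
  NextMethod()
}

#' Structure of the misclassifications in a confusion matrix
#'
#' Splits the off-diagonal mass into clinically distinct error types:
#' lateralization errors (right/left swapped within the fore or hind pair),
#' fore--hind errors (lame limb attributed to the wrong girdle), and
#' sound-related errors (lame predicted sound or vice versa).
#'
#' @param cm A `confusion_matrix`.
#' @return One-row tibble with `lateralization`, `fore_hind`,
#'   `sound_related` counts.
#' @export
confusion_structure <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ct <- cm$counts
  fore <- c("RF", "LF"); hind <- c("RH", "LH")
  tibble(
    lateralization = ct["RF", "LF"] + ct["LF", "RF"] +
      ct["RH", "LH"] + ct["LH", "RH"],
    fore_hind = sum(ct[fore, hind]) + sum(ct[hind, fore]),
    sound_related = sum(ct[c(fore, hind), "SOUND"]) +
      sum(ct["SOUND", c(fore, hind)]))
}
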