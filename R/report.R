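#' Pipeline configuration
#'
#' Gathers everything needed for one end-to-end run: cohort composition,
#' simulation parameters, asymmetry-index dialect, SVM configuration, output
#' directory and master seed. Serializes losslessly to a YAML file.
#'
#' @param class_counts Named horse counts per class.
#' @param params A [sim_params()].
#' @param dialect Asymmetry-index dialect (`"caption"` or
#'   `"rom_normalized"`).
#' @param svm An [svm_config()].
#' @param out_dir Output directory for report artifacts.
#' @param seed Master seed for the whole run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(class_counts = c(RF = 92, LF = 89, RH = 39,
                                             LH = 36, SOUND = 31),
                            params = sim_params(),
                            dialect = c("caption", "rom_normalized"),
                            svm = svm_config(),
                            out_dir = "equigait_out",
                            seed = 1) {
  dialect <- match.arg(dialect)
  structure(list(class_counts = class_counts, params = params,
                 dialect = dialect, svm = svm, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` to serialize.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$class_counts <- as.list(x$class_counts)
  x$params <- unclass(x$params)
  x$params$base_amplitude <- as.list(x$params$base_amplitude)
  x$params$physio_asymmetry <- as.list(x$params$physio_asymmetry)
  if (length(x$params$retraction_amplitude) > 1) {
    x$params$retraction_amplitude <- as.list(x$params$retraction_amplitude)
  }
  x$params$compensation_matrix <- list(
    rows = rownames(x$params$compensation_matrix),
    cols = colnames(x$params$compensation_matrix),
    values = as.vector(t(x$params$compensation_matrix)))
  x$svm <- unclass(x$svm)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  cm <- matrix(as.numeric(x$params$compensation_matrix$values),
               nrow = length(x$params$compensation_matrix$rows), byrow = TRUE,
               dimnames = list(x$params$compensation_matrix$rows,
                               x$params$compensation_matrix$cols))
  p <- x$params
  p$compensation_matrix <- cm
  p$base_amplitude <- unlist(p$base_amplitude)
  p$physio_asymmetry <- unlist(p$physio_asymmetry)
  if (length(p$retraction_amplitude) > 1) {
    p$retraction_amplitude <- unlist(p$retraction_amplitude)
  }
  params <- do.call(sim_params, p)
  sv <- do.call(svm_config, x$svm)
  pipeline_config(class_counts = unlist(x$class_counts), params = params,
                  dialect = x$dialect, svm = sv, out_dir = x$out_dir,
                  seed = x$seed)
}

#' Count-weighted grade summary per lameness class
#'
#' Computes, per class, the total number of horses, the count-weighted mean
#' lameness grade and its sample standard deviation from a grade-count
#' table (grades 2--7).
#'
#' @param counts Tibble like [reference_grade_counts()]: a `class` column
#'   plus count columns `g2`..`g7`.
#' @return Tibble: `class`, `total`, `mean`, `sd` (full precision), and
#'   display-rounded `mean_1dp`, `sd_1dp`.
#' @export
grade_summary <- function(counts = reference_grade_counts()) {
  grade_cols <- grep("^g[0-9]+$", names(counts), value = TRUE)
  grades <- as.numeric(sub("^g", "", grade_cols))
  m <- as.matrix(counts[, grade_cols])
  if (any(m < 0) || any(m != round(m))) {
    abort("grade_summary: counts must be nonnegative integers")
  }
  if (any(rowSums(m) == 0)) abort("grade_summary: all-zero count row")
  total <- rowSums(m)
  mean_g <- as.numeric(m %*% grades) / total
  var_g <- vapply(seq_len(nrow(m)), function(i) {
    if (total[i] < 2) return(0)  # a single horse has no spread
    sum(m[i, ] * (grades - mean_g[i])^2) / (total[i] - 1)
  }, numeric(1))
  tibble(class = counts$class, total = as.integer(total),
         mean = mean_g, sd = sqrt(var_g),
         mean_1dp = round(mean_g, 1), sd_1dp = round(sqrt(var_g), 1))
}

#' Render a confusion matrix with row percentages and accuracies
#'
#' @param counts 5x5 count matrix (rows = actual) or a `confusion_matrix`.
#' @return The `confusion_matrix` object, invisibly printable through
#'   [format_confusion()]; its `per_class` and `overall_pct` carry the
#'   accuracy metrics.
#' @export
matrix_report <- function(counts) {
  cm <- if (inherits(counts, "confusion_matrix")) counts else confusion_from_counts(counts)
  cm
}

#' @rdname matrix_report
#' @param cm A `confusion_matrix`.
#' @export
format_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  lev <- rownames(cm$counts)
  header <- paste0(format("actual\\predicted", width = 16),
                   paste(format(lev, width = 12), collapse = ""))
  rows <- vapply(seq_along(lev), function(i) {
    cells <- sprintf("%d (%.1f%%)", cm$counts[i, ],
                     ifelse(is.na(cm$row_percent[i, ]), 0, cm$row_percent[i, ]))
    paste0(format(lev[i], width = 16), paste(format(cells, width = 12), collapse = ""))
  }, character(1))
  c(header, rows,
    sprintf("overall accuracy: %.1f%% (%d/%d)", cm$overall_pct,
            sum(diag(cm$counts)), sum(cm$counts)))
}

#' Run the whole pipeline end-to-end
#'
#' simulate -> extract features -> tune & fit the SVM -> bootstrap-validate
#' -> variable importance -> write artifacts. Two confusion reports are
#' written: the resubstitution matrix (model refitted on all data, applied
#' to the same data) and the bootstrap out-of-bag matrix pooled over
#' repetitions; they answer different questions and are labelled as such.
#'
#' @param config A [pipeline_config()].
#' @param write Write artifacts to `config$out_dir` (features.csv,
#'   confusion_resubstitution.json, confusion_oob.json, validation.json,
#'   importance.csv, config.yaml)?
#' @return List of class `gait_report`: `cohort`, `features`, `model`,
#'   `validation`, `confusion_resub`, `confusion_oob`, `importance`,
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), write = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  p <- config$params
  p$seed <- config$seed
  cohort <- stage("simulate", simulate_cohort(config$class_counts, params = p,
                                              seed = config$seed))
  features <- stage("extract", extract_features(cohort, dialect = config$dialect))
  sv <- config$svm
  sv$seed <- config$seed
  model <- stage("train", fit_lameness_svm(features, sv))
  validation <- stage("validate", bootstrap_validate(features, sv, cost = model$cost))
  resub <- confusion_and_accuracy(features$label, predict(model, features))
  importance <- stage("importance",
                      variable_importance(features[, FEATURE_NAMES], features$label))
  report <- structure(list(cohort = cohort, features = features, model = model,
                           validation = validation,
                           confusion_resub = resub,
                           confusion_oob = validation$oob_confusion,
                           importance = importance,
                           config = config),
                      class = "gait_report")
  if (write) write_report(report)
  report
}

#' @export
print.gait_report <- function(x, ...) {
  cat("<gait_report>", nrow(x$features), "horses; selected cost", x$model$cost, "\n")
  cat(sprintf("  bootstrap OOB accuracy %.3f +/- %.3f (B = %d)\n",
              x$validation$mean, x$validation$sd, x$validation$B))
  cat(sprintf("  resubstitution overall accuracy %.1f%%\n",
              x$confusion_resub$overall_pct))
  invisible(x)
}

write_report <- function(report) {
  dir <- report$config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list(package_version = as.character(utils::packageVersion("equigait")),
               seed = report$config$seed, dialect = report$config$dialect)
  write_features(report$features, file.path(dir, "features.csv"),
                 dialect = report$config$dialect)
  conf_json <- function(cm) {
    c(meta, list(classes = rownames(cm$counts),
                 counts = unname(apply(cm$counts, 1, as.integer, simplify = FALSE)),
                 row_percent = unname(apply(round(cm$row_percent, 1), 1,
                                            as.numeric, simplify = FALSE)),
                 per_class_accuracy_pct = report_round(cm$per_class$accuracy_pct),
                 overall_accuracy_pct = cm$overall_pct))
  }
  jsonlite::write_json(conf_json(report$confusion_resub),
                       file.path(dir, "confusion_resubstitution.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(conf_json(report$confusion_oob),
                       file.path(dir, "confusion_oob.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(c(meta, list(B = report$validation$B,
                                    cost = report$validation$cost,
                                    mean_oob_accuracy = report$validation$mean,
                                    sd_oob_accuracy = report$validation$sd)),
                       file.path(dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(as.data.frame(report$importance),
             file.path(dir, "importance.csv"), row.names = FALSE)
  write_pipeline_config(report$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

report_round <- function(x) as.numeric(round(x, 1))
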