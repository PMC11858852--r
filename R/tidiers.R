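#' Broom-style tidiers
#'
#' `tidy()` returns a per-component table, `glance()` a one-row model
#' summary, for the fitted SVM, confusion matrices, bootstrap validations
#' and importance tables.
#'
#' @param x The object to tidy.
#' @param ... Unused.
#' @name equigait-tidiers
NULL

#' @rdname equigait-tidiers
#' @method tidy lameness_svm
#' @export
tidy.lameness_svm <- function(x, ...) x$grid

#' @rdname equigait-tidiers
#' @method glance lameness_svm
#' @export
glance.lameness_svm <- function(x, ...) {
  tibble(cost = x$cost, sigma = x$sigma,
         n_classes = length(x$levels),
         n_support_vectors = kernlab::nSV(x$fit),
         tune_mean_accuracy = max(x$grid$mean_accuracy),
         seed = x$seed)
}

#' @rdname equigait-tidiers
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  counts <- as.data.frame(as.table(x$counts), stringsAsFactors = FALSE)
  names(counts) <- c("actual", "predicted", "n")
  pct <- as.data.frame(as.table(x$row_percent), stringsAsFactors = FALSE)
  counts$row_pct <- pct$Freq
  as_tibble(counts)
}

#' @rdname equigait-tidiers
#' @method glance confusion_matrix
#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble(n = sum(x$counts),
         overall_accuracy_pct = x$overall_pct,
         macro_accuracy_pct = mean(x$per_class$accuracy_pct, na.rm = TRUE))
}

#' @rdname equigait-tidiers
#' @method tidy bootstrap_validation
#' @export
tidy.bootstrap_validation <- function(x, ...) {
  tibble(rep = seq_len(x$B), accuracy = x$accuracy)
}

#' @rdname equigait-tidiers
#' @method glance bootstrap_validation
#' @export
glance.bootstrap_validation <- function(x, ...) {
  tibble(B = x$B, mean_accuracy = x$mean, sd_accuracy = x$sd,
         cost = x$cost, seed = x$seed, redraws = x$redraws)
}

#' @rdname equigait-tidiers
#' @method tidy importance_table
#' @export
tidy.importance_table <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(as.data.frame(x)), -"feature",
                      names_to = "class", values_to = "importance")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
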