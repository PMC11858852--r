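#' Plot methods
#'
#' `autoplot()` methods for the package's result objects: raw trial signals,
#' normalized stride curves, confusion matrices, bootstrap accuracy
#' distributions and importance heatmaps. All return ggplot objects.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @name equigait-plots
NULL

#' @rdname equigait-plots
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_text
#'   geom_histogram facet_wrap labs scale_fill_gradient2 scale_fill_gradient
#'   theme_minimal
#' @method autoplot gait_trial
#' @export
autoplot.gait_trial <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$time_s, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~channel, scales = "free_y", ncol = 1) +
    labs(x = "time (s)", y = "displacement (cm) / angle (deg)",
         title = sprintf("Trial: %s grade %d", object$label, object$grade)) +
    theme_minimal()
}

#' @rdname equigait-plots
#' @method autoplot stride_series
#' @export
autoplot.stride_series <- function(object, ...) {
  per_sensor <- purrr::imap(object$normalized_curves, function(mat, s) {
    strides <- purrr::imap(seq_len(nrow(mat)), function(k, .) {
      tibble(sensor = s, stride = k,
             pct = seq(0, 100, length.out = ncol(mat)), value = mat[k, ])
    })
    dplyr::bind_rows(strides)
  })
  df <- dplyr::bind_rows(per_sensor)
  mean_df <- purrr::imap(object$mean_curve, function(v, s) {
    tibble(sensor = s, pct = seq(0, 100, length.out = length(v)), value = v)
  })
  mean_df <- dplyr::bind_rows(mean_df)
  ggplot(df, aes(x = .data$pct, y = .data$value, group = .data$stride)) +
    geom_line(alpha = 0.25, linewidth = 0.3) +
    geom_line(data = mean_df, aes(group = NULL), linewidth = 0.9,
              colour = "firebrick") +
    facet_wrap(~sensor, ncol = 1, scales = "free_y") +
    labs(x = "stride (%)", y = "vertical displacement (cm)") +
    theme_minimal()
}

#' @rdname equigait-plots
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy(object)
  df$actual <- factor(df$actual, levels = rev(rownames(object$counts)))
  df$predicted <- factor(df$predicted, levels = colnames(object$counts))
  ggplot(df, aes(x = .data$predicted, y = .data$actual, fill = .data$row_pct)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%d\n(%.1f%%)", .data$n, .data$row_pct)),
              size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 100),
                        name = "row %") +
    labs(x = "predicted", y = "actual",
         title = sprintf("Overall accuracy %.1f%%", object$overall_pct)) +
    theme_minimal()
}

#' @rdname equigait-plots
#' @method autoplot bootstrap_validation
#' @export
autoplot.bootstrap_validation <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$accuracy)) +
    geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    labs(x = "out-of-bag accuracy", y = "bootstrap repetitions",
         title = sprintf("B = %d, mean %.3f +/- %.3f", object$B,
                         object$mean, object$sd)) +
    theme_minimal()
}

#' @rdname equigait-plots
#' @method autoplot importance_table
#' @export
autoplot.importance_table <- function(object, ...) {
  df <- tidy(object)
  df$feature <- factor(df$feature, levels = rev(object$feature))
  ggplot(df, aes(x = .data$class, y = .data$feature, fill = .data$importance)) +
    geom_tile() +
    scale_fill_gradient2(low = "firebrick", mid = "white", high = "forestgreen",
                         midpoint = 60, limits = c(0, 100), name = "importance") +
    labs(x = NULL, y = NULL, title = "Per-class variable importance (0-100)") +
    theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
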