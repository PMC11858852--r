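#' Reference clinical tables for worked-example statistics
#'
#' Published summary tables from a clinical validation cohort of 287 horses
#' trotting in a straight line (92 right-fore, 89 left-fore, 39 right-hind,
#' 36 left-hind lame, 31 sound). `reference_confusion()` returns the 5x5
#' confusion matrix of the cohort's class-weighted RBF-SVM (rows = actual,
#' columns = predicted, fixed order `RF, LF, RH, LH, SOUND`);
#' `reference_grade_counts()` returns the number of lame horses per class at
#' each lameness grade 2--7 of the 0--10 scale. These count tables are the
#' inputs of the package's worked examples ([matrix_report()],
#' [grade_summary()]); the raw recordings behind them are not public.
#'
#' @return `reference_confusion()`: 5x5 integer matrix.
#' @export
reference_confusion <- function() {
  m <- rbind(RF    = c(86, 0, 0, 2, 4),
             LF    = c(0, 81, 1, 1, 6),
             RH    = c(5, 4, 30, 0, 0),
             LH    = c(1, 2, 0, 33, 0),
             SOUND = c(6, 6, 1, 1, 17))
  colnames(m) <- LAMENESS_LEVELS
  m
}

#' @rdname reference_confusion
#' @return `reference_grade_counts()`: tibble with `class` and count columns
#'   `g2`..`g7`.
#' @export
reference_grade_counts <- function() {
  tibble(class = c("LF", "RF", "LH", "RH"),
         g2 = c(53, 51, 13, 18),
         g3 = c(13, 12, 8, 4),
         g4 = c(13, 23, 8, 14),
         g5 = c(5, 4, 1, 1),
         g6 = c(3, 2, 6, 2),
         g7 = c(2, 0, 0, 0))
}
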