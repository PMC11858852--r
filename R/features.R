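# The 27 model features, in fixed table order.
FEATURE_NAMES <- c(
  "AsI_up_H", "AsI_up_W", "AsI_up_P",
  "AsI_down_H", "AsI_down_W", "AsI_down_P",
  "AsI_max_H", "AsI_max_W", "AsI_max_P",
  "AsI_min_H", "AsI_min_W", "AsI_min_P",
  "AsI_retraction_fore", "AsI_retraction_hind",
  "AsI_Tmax_H", "AsI_Tmax_W", "AsI_Tmax_P",
  "ERz_H", "ERz_W", "ERz_P",
  "dphi_H", "dphi_W", "dphi_P",
  "stride_frequency",
  "ROM_H", "ROM_W", "ROM_P")

#' Names of the 27 movement-asymmetry features
#'
#' Per upper-body sensor (`_H` head, `_W` withers, `_P` pelvis): five
#' asymmetry indices (`AsI_up`, `AsI_down`, `AsI_max`, `AsI_min`,
#' `AsI_Tmax`, %), the second-to-first harmonic energy ratio (`ERz`, %),
#' the first-minus-second harmonic phase difference (`dphi`, degrees), and
#' the stride range of motion (`ROM`, cm); plus the fore and hind limb-pair
#' retraction asymmetry (`AsI_retraction_fore`/`_hind`, %) and the stride
#' frequency (Hz). Order is fixed.
#'
#' @return Character vector of length 27.
#' @export
feature_names <- function() FEATURE_NAMES

#' Left--right asymmetry indices from half-stride landmarks
#'
#' Computes the five asymmetry indices of a sensor's mean stride curve, as
#' percentages. Two normalization dialects are supported. The `"caption"`
#' dialect uses the classic contralateral-amplitude denominators:
#' \deqn{AsI_{min} = 100 (min_R - min_L)/up_L,\quad
#'       AsI_{max} = 100 (max_L - max_R)/up_L,\quad
#'       AsI_{up} = 100 (up_L - up_R)/up_L,}
#' \deqn{AsI_{down} = 100 (down_L - down_R)/down_L,\quad
#'       AsI_{Tmax} = 100 (diffTmax_L - diffTmax_R)/diffTmax_L.}
#' The `"rom_normalized"` dialect divides the same numerators by the stride
#' range of motion instead, which makes every index exactly antisymmetric
#' under a left--right mirror. Positive values indicate the right-side half
#' has the smaller landmark.
#'
#' @param lm A `stride_landmarks`.
#' @param dialect `"caption"` (default) or `"rom_normalized"`.
#' @return Named numeric of length 5: `AsI_up`, `AsI_down`, `AsI_max`,
#'   `AsI_min`, `AsI_Tmax` (percent).
#' @export
asymmetry_indices <- function(lm, dialect = c("caption", "rom_normalized")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(lm, "stride_landmarks"))
  num <- c(AsI_up = lm$up_L - lm$up_R,
           AsI_down = lm$down_L - lm$down_R,
           AsI_max = lm$max_L - lm$max_R,
           AsI_min = lm$min_R - lm$min_L,
           AsI_Tmax = lm$diffTmax_L - lm$diffTmax_R)
  if (dialect == "caption") {
    den <- c(AsI_up = lm$up_L, AsI_down = lm$down_L, AsI_max = lm$up_L,
             AsI_min = lm$up_L, AsI_Tmax = lm$diffTmax_L)
  } else {
    if (lm$ROM <= 0) abort("asymmetry_indices: ROM must be > 0 for the rom_normalized dialect")
    den <- c(AsI_up = lm$ROM, AsI_down = lm$ROM, AsI_max = lm$ROM,
             AsI_min = lm$ROM, AsI_Tmax = lm$ROM)
  }
  zero <- den == 0
  if (any(zero)) {
    abort(paste0("asymmetry_indices: zero denominator for ",
                 paste(names(den)[zero], collapse = ", ")))
  }
  out <- 100 * num / den
  out[c("AsI_up", "AsI_down", "AsI_max", "AsI_min", "AsI_Tmax")]
}

#' Two-harmonic Fourier fit of a stride curve
#'
#' Least-squares fit of
#' `c0 + c1 cos(2*pi*u) + s1 sin(2*pi*u) + c2 cos(4*pi*u) + s2 sin(4*pi*u)`
#' over normalized stride phase `u` in `[0, 1]`. The first harmonic (one
#' cycle per stride) carries the left--right asymmetric component; the
#' second (two cycles per stride) the symmetric trot oscillation.
#'
#' @param mean_curve Numeric stride curve sampled on an even phase grid.
#' @param stride_frequency Optional Hz, stored for reference.
#' @return Object of class `harmonic_fit`: `amplitude_1`, `amplitude_2`
#'   (cm), `phase_1`, `phase_2` (degrees in (-180, 180], 0 by convention for
#'   a vanishing amplitude), `residual_rms` (cm).
#' @export
harmonic_fit <- function(mean_curve, stride_frequency = NULL) {
  y <- as.numeric(mean_curve)
  if (length(y) < 5) abort("harmonic_fit: need at least 5 points")
  if (!all(is.finite(y))) abort("harmonic_fit: non-finite curve")
  u <- seq(0, 1, length.out = length(y))
  X <- cbind(1, cos(2 * pi * u), sin(2 * pi * u),
             cos(4 * pi * u), sin(4 * pi * u))
  beta <- lm.fit(X, y)$coefficients
  amp <- function(c_, s_) sqrt(c_^2 + s_^2)
  ph <- function(c_, s_, a) {
    if (a < 1e-12) 0 else unname(wrap_degrees(atan2(s_, c_) * 180 / pi))
  }
  a1 <- amp(beta[2], beta[3]); a2 <- amp(beta[4], beta[5])
  res <- y - X %*% beta
  structure(list(amplitude_1 = unname(a1), amplitude_2 = unname(a2),
                 phase_1 = ph(beta[2], beta[3], a1),
                 phase_2 = ph(beta[4], beta[5], a2),
                 residual_rms = sqrt(mean(res^2)),
                 stride_frequency = stride_frequency),
            class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf("<harmonic_fit> A1 = %.4g cm @ %.1f deg, A2 = %.4g cm @ %.1f deg, rms %.3g\n",
              x$amplitude_1, x$phase_1, x$amplitude_2, x$phase_2, x$residual_rms))
  invisible(x)
}

#' Harmonic symmetry features: energy ratio and phase difference
#'
#' `ERz` is the energy of the second harmonic over the energy of the first,
#' in percent (`100 * amplitude_2^2 / amplitude_1^2`); large values indicate
#' a symmetric gait. `dphi` is `phase_1 - phase_2` wrapped into
#' `(-180, 180]`. A perfectly symmetric signal has no first harmonic; its
#' `ERz` is then reported at the configurable ceiling and flagged degenerate.
#'
#' @param fit A [harmonic_fit()].
#' @param ceiling Cap applied to `ERz` when the first harmonic vanishes.
#' @return Tibble with one row: `ERz` (%), `dphi` (degrees), `degenerate`.
#' @export
fourier_features <- function(fit, ceiling = 1e6) {
  stopifnot(inherits(fit, "harmonic_fit"))
  degenerate <- fit$amplitude_1 < 1e-9 ||
    100 * (fit$amplitude_2 / max(fit$amplitude_1, 1e-300))^2 > ceiling
  erz <- if (degenerate) ceiling else 100 * fit$amplitude_2^2 / fit$amplitude_1^2
  tibble(ERz = erz,
         dphi = wrap_degrees(fit$phase_1 - fit$phase_2),
         degenerate = degenerate)
}

#' Limb retraction asymmetry at lift-off
#'
#' For each limb of the pair, the retraction angle is the mean over strides
#' of the absolute cannon angle at the lift-off instant; the index is the
#' left--right difference as a percentage of the pair mean:
#' `100 * (left - right) / ((left + right)/2)`. Positive values mean the
#' left limb retracts further (e.g. a right-limb retraction deficit).
#'
#' @param trial A `gait_trial`.
#' @param pair `"fore"` (LF vs RF) or `"hind"` (LH vs RH).
#' @return Scalar percentage.
#' @export
retraction_asymmetry <- function(trial, pair = c("fore", "hind")) {
  pair <- match.arg(pair)
  stopifnot(inherits(trial, "gait_trial"))
  limbs <- if (pair == "fore") c(L = "LF", R = "RF") else c(L = "LH", R = "RH")
  angle_at_liftoff <- function(l) {
    ev <- trial$stance_events
    lo <- ev$liftoff[ev$limb == l]
    if (length(lo) < 3) {
      abort(sprintf("retraction_asymmetry: need >= 3 lift-off events for %s, found %d",
                    l, length(lo)))
    }
    mean(abs(trial$limb_angle[[l]][lo]))
  }
  left <- angle_at_liftoff(limbs[["L"]])
  right <- angle_at_liftoff(limbs[["R"]])
  100 * (left - right) / ((left + right) / 2)
}

#' Build the 27-feature vector for one trial
#'
#' Runs the full per-trial pipeline: stride segmentation, per-sensor
#' landmark extraction and asymmetry indices, two-harmonic Fourier features,
#' limb-pair retraction asymmetry, stride frequency and range of motion.
#'
#' @param trial A `gait_trial`.
#' @param dialect Asymmetry-index normalization, see [asymmetry_indices()].
#' @param reference_limb Stride-delimiting limb, see [segment_strides()].
#' @return One-row tibble with the 27 columns of [feature_names()] plus a
#'   logical `ERz_degenerate` marker (TRUE when any sensor's first harmonic
#'   vanished and its ERz was capped).
#' @export
build_feature_vector <- function(trial, dialect = c("caption", "rom_normalized"),
                                 reference_limb = "RH") {
  dialect <- match.arg(dialect)
  series <- segment_strides(trial, reference_limb = reference_limb)
  out <- list()
  degenerate <- FALSE
  for (s in GAIT_SENSORS) {
    lm <- extract_landmarks(series, sensor = s)
    asi <- asymmetry_indices(lm, dialect = dialect)
    for (nm in names(asi)) out[[paste0(nm, "_", s)]] <- unname(asi[[nm]])
    ff <- fourier_features(harmonic_fit(series$mean_curve[[s]],
                                        series$stride_frequency))
    out[[paste0("ERz_", s)]] <- ff$ERz
    out[[paste0("dphi_", s)]] <- ff$dphi
    out[[paste0("ROM_", s)]] <- lm$ROM
    degenerate <- degenerate || ff$degenerate
  }
  out$AsI_retraction_fore <- retraction_asymmetry(trial, "fore")
  out$AsI_retraction_hind <- retraction_asymmetry(trial, "hind")
  out$stride_frequency <- series$stride_frequency
  vec <- as_tibble(out)[, FEATURE_NAMES]
  vec$ERz_degenerate <- degenerate
  vec
}

#' Extract the feature table for a whole cohort
#'
#' @param cohort Cohort tibble from [simulate_cohort()] (columns `trial_id`,
#'   `label`, `grade`, list-column `trial`).
#' @inheritParams build_feature_vector
#' @return Tibble: `trial_id`, `label`, `grade`, the 27 feature columns and
#'   `ERz_degenerate`. Errors in individual trials are rethrown with the
#'   trial id attached.
#' @export
extract_features <- function(cohort, dialect = c("caption", "rom_normalized"),
                             reference_limb = "RH") {
  dialect <- match.arg(dialect)
  rows <- purrr::map2(cohort$trial, cohort$trial_id, function(tr, id) {
    tryCatch(build_feature_vector(tr, dialect, reference_limb),
             error = function(e) {
               abort(sprintf("extract_features: trial %s: %s", id, conditionMessage(e)))
             })
  })
  dplyr::bind_cols(dplyr::select(cohort, "trial_id", "label", "grade"),
                   dplyr::bind_rows(rows))
}

#' Write / read a feature table CSV
#'
#' One row per trial: `trial_id`, `label`, `grade`, the 27 feature columns.
#' The asymmetry-index dialect is recorded in a comment header line and
#' restored (as an attribute) on read; the round trip is lossless.
#'
#' @param features Feature tibble from [extract_features()].
#' @param path CSV path.
#' @param dialect Dialect string recorded in the file header.
#' @export
write_features <- function(features, path, dialect = "caption") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# equigait features; dialect=%s", dialect), con)
  write.csv(features, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  header <- readLines(path, n = 1)
  dialect <- sub(".*dialect=", "", header)
  df <- as_tibble(read.csv(path, comment.char = "#", stringsAsFactors = FALSE))
  df$label <- as_lameness_label(df$label)
  attr(df, "dialect") <- dialect
  df
}
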