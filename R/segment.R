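#' Segment a trial into time-normalized strides
#'
#' Cuts each upper-body displacement series into strides delimited by
#' successive stance onsets of a reference limb (default: right hind),
#' linearly resamples every stride to 101 points on a 0--100 % stride-phase
#' grid, removes each stride's mean level, and averages pointwise into a mean
#' stride curve per sensor. Stance events are taken from the trial when
#' present; otherwise onsets are detected as maxima of the reference limb's
#' protraction angle.
#'
#' @param trial A `gait_trial`.
#' @param reference_limb Limb whose stance onsets delimit strides.
#' @param n_points Points on the normalized stride grid (odd keeps the 50 %
#'   midpoint exact).
#' @return Object of class `stride_series`: list with `boundaries` (onset
#'   sample indices), `normalized_curves` (per sensor, strides x `n_points`
#'   matrix), `mean_curve` (per sensor), `stride_frequency` (Hz),
#'   `limb_phase` (mid-stance stride fraction per limb), `reference_limb`,
#'   `sampling_rate`.
#' @export
segment_strides <- function(trial, reference_limb = "RH", n_points = 101) {
  stopifnot(inherits(trial, "gait_trial"))
  reference_limb <- match.arg(reference_limb, GAIT_LIMBS)
  fs <- trial$params$sampling_rate
  ev <- trial$stance_events
  onsets <- if (!is.null(ev) && nrow(ev) > 0) {
    sort(ev$onset[ev$limb == reference_limb])
  } else {
    detect_angle_peaks(trial$limb_angle[[reference_limb]])
  }
  if (length(onsets) < 4) {
    abort(sprintf("segment_strides: need >= 3 complete strides, found %d",
                  max(0L, length(onsets) - 1L)))
  }
  check_periodicity(trial$displacement[[1]], diff(onsets))

  n_strides <- length(onsets) - 1
  u <- seq(0, 1, length.out = n_points)
  normalized <- list()
  mean_curve <- list()
  for (s in GAIT_SENSORS) {
    y <- trial$displacement[[s]]
    mat <- matrix(NA_real_, n_strides, n_points)
    for (k in seq_len(n_strides)) {
      idx <- onsets[k]:onsets[k + 1]
      cur <- stats::approx(x = seq(0, 1, length.out = length(idx)),
                           y = y[idx], xout = u)$y
      mat[k, ] <- cur - mean(cur)
    }
    normalized[[s]] <- mat
    mean_curve[[s]] <- colMeans(mat)
  }

  stride_frequency <- n_strides / ((onsets[n_strides + 1] - onsets[1]) / fs)
  limb_phase <- stance_phase_fractions(ev, onsets, reference_limb)

  structure(list(boundaries = onsets,
                 normalized_curves = normalized,
                 mean_curve = mean_curve,
                 stride_frequency = stride_frequency,
                 limb_phase = limb_phase,
                 reference_limb = reference_limb,
                 sampling_rate = fs),
            class = "stride_series")
}

# Fallback onset detection: local maxima of the protraction angle.
detect_angle_peaks <- function(theta) {
  n <- length(theta)
  i <- 2:(n - 1)
  which(theta[i] > theta[i - 1] & theta[i] >= theta[i + 1]) + 1L
}

# Guard against aperiodic input: stride durations must agree to 10 %.
check_periodicity <- function(y, stride_lengths) {
  if (length(stride_lengths) >= 2 &&
      diff(range(stride_lengths)) > 0.1 * mean(stride_lengths)) {
    abort("segment_strides: stride durations vary by more than 10% (non-periodic input?)")
  }
  invisible(TRUE)
}

# Mean mid-stance position of each limb as a fraction of the stride,
# averaged circularly over all complete strides.
stance_phase_fractions <- function(ev, onsets, reference_limb) {
  period <- mean(diff(onsets))
  out <- c()
  for (l in GAIT_LIMBS) {
    e <- ev[ev$limb == l, ]
    if (nrow(e) == 0) next
    mid <- (e$onset + e$liftoff) / 2
    frac <- ((mid - onsets[1]) / period) %% 1
    ang <- atan2(mean(sin(2 * pi * frac)), mean(cos(2 * pi * frac)))
    out[l] <- (ang / (2 * pi)) %% 1
  }
  out
}

#' @export
print.stride_series <- function(x, ...) {
  cat("<stride_series>", nrow(x$normalized_curves[[1]]), "strides,",
      ncol(x$normalized_curves[[1]]), "points; stride frequency",
      signif(x$stride_frequency, 4), "Hz; reference limb", x$reference_limb, "\n")
  invisible(x)
}

#' Extract half-stride landmarks from a mean stride curve
#'
#' Locates the two local minima and two local maxima of the trot-pattern mean
#' curve (treated circularly) and assigns each minimum to the half-stride in
#' which the sensor's reference limb is in stance: the right/left forelimb
#' for head and withers, the right/left hindlimb for the pelvis. For the half
#' assigned to side X: `up_X` is the following local maximum minus the
#' minimum, `down_X` the preceding local maximum minus the minimum,
#' `diffTmax_X` the following local maximum minus the curve's global minimum.
#' `ROM` is the global max minus global min.
#'
#' @param series A `stride_series`, or a bare numeric curve (then
#'   `half_assignment` is required).
#' @param sensor One of `"H"`, `"W"`, `"P"`.
#' @param half_assignment Optional named vector `c(R = fr, L = fl)` of
#'   mid-stance stride fractions overriding the assignment derived from the
#'   trial's stance events (swap them to swap the `_R`/`_L` fields).
#' @param prominence_tol Extrema with prominence below this fraction of the
#'   curve's range are treated as noise ripples and pruned.
#' @return Object of class `stride_landmarks`: named list with `min_R, min_L,
#'   max_R, max_L, up_R, up_L, down_R, down_L, diffTmax_R, diffTmax_L, ROM`
#'   (cm), plus `sensor` and `reference_side`.
#' @export
extract_landmarks <- function(series, sensor = "W", half_assignment = NULL,
                              prominence_tol = 0.02) {
  drop_endpoint <- NA
  if (inherits(series, "stride_series")) {
    curve <- series$mean_curve[[sensor]]
    drop_endpoint <- TRUE  # percent-stride grid: 100 % duplicates 0 %
    if (is.null(half_assignment)) {
      pair <- if (sensor %in% c("H", "W")) c(R = "RF", L = "LF") else c(R = "RH", L = "LH")
      half_assignment <- c(R = unname(series$limb_phase[[pair[["R"]]]]),
                           L = unname(series$limb_phase[[pair[["L"]]]]))
    }
  } else {
    curve <- as.numeric(series)
    if (is.null(half_assignment)) {
      abort("extract_landmarks: half_assignment is required for a bare curve")
    }
  }
  if (!all(is.finite(curve))) abort("extract_landmarks: non-finite curve")

  ex <- circular_extrema(curve, prominence_tol, drop_endpoint)
  if (length(ex$min_idx) != 2 || length(ex$max_idx) != 2) {
    abort(sprintf(
      "extract_landmarks (%s): expected 2 minima and 2 maxima per stride, found %d minima / %d maxima",
      sensor, length(ex$min_idx), length(ex$max_idx)))
  }

  m <- length(ex$circ)  # circular length (duplicate endpoint dropped)
  frac <- (ex$min_idx - 1) / m
  # assign each minimum to the nearer mid-stance fraction (circular distance)
  dist_to <- function(f, g) pmin(abs(f - g), 1 - abs(f - g))
  dR <- dist_to(frac, half_assignment[["R"]])
  dL <- dist_to(frac, half_assignment[["L"]])
  right_first <- dR[1] < dL[1]
  idx_R <- if (right_first) ex$min_idx[1] else ex$min_idx[2]
  idx_L <- if (right_first) ex$min_idx[2] else ex$min_idx[1]
  if (right_first == (dR[2] < dL[2])) {
    abort("extract_landmarks: ambiguous half assignment (both minima nearest the same side)")
  }

  half <- function(idx) {
    nxt <- next_extremum(idx, ex$max_idx, m, forward = TRUE)
    prv <- next_extremum(idx, ex$max_idx, m, forward = FALSE)
    list(min = ex$circ[idx],
         max_next = ex$circ[nxt],
         max_prev = ex$circ[prv])
  }
  hR <- half(idx_R); hL <- half(idx_L)
  gmin <- min(curve); gmax <- max(curve)

  structure(list(min_R = hR$min, min_L = hL$min,
                 max_R = hR$max_next, max_L = hL$max_next,
                 up_R = hR$max_next - hR$min, up_L = hL$max_next - hL$min,
                 down_R = hR$max_prev - hR$min, down_L = hL$max_prev - hL$min,
                 diffTmax_R = hR$max_next - gmin,
                 diffTmax_L = hL$max_next - gmin,
                 ROM = gmax - gmin,
                 sensor = sensor,
                 reference_side = if (sensor %in% c("H", "W")) "forelimb" else "hindlimb"),
            class = "stride_landmarks")
}

# Local extrema of a circular curve with prominence pruning. The duplicated
# 0 % / 100 % endpoint of percent-stride curves is dropped before wrapping.
circular_extrema <- function(curve, prominence_tol, drop_endpoint = NA) {
  n <- length(curve)
  if (is.na(drop_endpoint)) {
    drop_endpoint <- n > 2 &&
      abs(curve[1] - curve[n]) < 1e-6 * max(1, diff(range(curve)))
  }
  circ <- if (drop_endpoint) curve[-n] else curve
  m <- length(circ)
  prv <- circ[c(m, 1:(m - 1))]
  nxt <- circ[c(2:m, 1)]
  max_idx <- which(circ > prv & circ >= nxt)
  min_idx <- which(circ < prv & circ <= nxt)
  # prune low-prominence ripple pairs (adjacent max/min too close in value)
  tol <- prominence_tol * diff(range(circ))
  repeat {
    ex <- sort(c(max_idx, min_idx))
    if (length(ex) <= 4) break
    vals <- circ[ex]
    nxt_ex <- c(ex[-1], ex[1])
    gaps <- abs(vals - circ[nxt_ex])
    worst <- which.min(gaps)
    if (gaps[worst] >= tol) break
    drop <- c(ex[worst], nxt_ex[worst])
    max_idx <- setdiff(max_idx, drop)
    min_idx <- setdiff(min_idx, drop)
  }
  list(circ = circ, max_idx = sort(min_idx_check(max_idx)), min_idx = sort(min_idx_check(min_idx)))
}

min_idx_check <- function(x) as.integer(x)

# Nearest extremum index after (or before) idx, circularly.
next_extremum <- function(idx, candidates, m, forward = TRUE) {
  d <- (candidates - idx) %% m
  d[d == 0] <- m
  if (!forward) d <- m - d
  candidates[which.min(d)]
}

#' @export
print.stride_landmarks <- function(x, ...) {
  cat("<stride_landmarks> sensor", x$sensor, sprintf("(%s reference)\n", x$reference_side))
  v <- unlist(x[c("min_R", "min_L", "max_R", "max_L", "up_R", "up_L",
                  "down_R", "down_L", "diffTmax_R", "diffTmax_L", "ROM")])
  print(round(v, 4))
  invisible(x)
}

#' Tidy landmarks into a long table
#' @param x A `stride_landmarks`.
#' @param ... Unused.
#' @method tidy stride_landmarks
#' @export
tidy.stride_landmarks <- function(x, ...) {
  fields <- c("min_R", "min_L", "max_R", "max_L", "up_R", "up_L",
              "down_R", "down_L", "diffTmax_R", "diffTmax_L", "ROM")
  tibble(sensor = x$sensor, field = fields,
         value = unlist(x[fields], use.names = FALSE))
}

#' Reconstruct vertical displacement from vertical acceleration
#'
#' Drift-rejecting double integration: a zero-phase high-pass Butterworth
#' filter (cut-off well below the stride frequency) is applied to the
#' acceleration, after each integration stage, and to the result. This is an
#' approximation suitable for stride-periodic signals; the core synthetic
#' pipeline works on displacement directly and does not use it.
#'
#' @param acc Vertical acceleration series, m/s^2.
#' @param sampling_rate Hz.
#' @param cutoff_hz High-pass cut-off, Hz; must sit below the stride
#'   frequency of the gait being processed.
#' @return Zero-mean vertical displacement in cm, same length as `acc`.
#' @export
displacement_from_acceleration <- function(acc, sampling_rate, cutoff_hz = 0.5) {
  if (!all(is.finite(acc))) abort("displacement_from_acceleration: non-finite samples")
  if (length(acc) < 10) abort("displacement_from_acceleration: series too short")
  bf <- signal::butter(2, cutoff_hz / (sampling_rate / 2), type = "high")
  hp <- function(x) signal::filtfilt(bf, x)
  integ <- function(x) as.numeric(pracma::cumtrapz(x)) / sampling_rate
  v <- integ(hp(acc))
  d <- integ(hp(v))
  d <- hp(d)
  100 * (d - mean(d))
}
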