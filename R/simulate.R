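#' Simulation parameters for synthetic trot recordings
#'
#' Bundles every knob of the trot signal generator. The displacement model for
#' an upper-body sensor (head `H`, withers `W`, pelvis `P`) is a two-harmonic
#' sinusoid: a dominant second harmonic (two oscillations per stride, the
#' symmetric component produced by the two diagonal stances of the trot) of
#' amplitude `base_amplitude`, plus a lameness-induced first harmonic (one per
#' stride, the asymmetric component) whose amplitude is
#' `asymmetry_gain * grade * compensation_matrix[label, sensor] *
#' base_amplitude`. Limb protraction--retraction angles are single sinusoids
#' with trot phasing (diagonal limbs in phase, contralaterals half a stride
#' apart); the lame limb's amplitude is reduced by
#' `retraction_deficit_per_grade * grade`.
#'
#' @param stride_frequency Stride frequency in Hz (strides per second).
#' @param sampling_rate Sampling rate in Hz; must exceed
#'   `4 * stride_frequency` (both modelled harmonics must be resolvable).
#' @param n_strides Number of complete strides to record (>= 3).
#' @param base_amplitude Named numeric, vertical half-amplitude in cm of the
#'   second-harmonic oscillation per sensor (`H`, `W`, `P`).
#' @param asymmetry_gain First-harmonic amplitude injected per grade unit,
#'   as a fraction of the sensor's `base_amplitude`.
#' @param compensation_matrix 4 x 3 signed matrix (rows `RF,LF,RH,LH`,
#'   columns `H,W,P`) of relative asymmetry weights: how strongly lameness of
#'   each limb expresses at each sensor, sign encoding the side. The default
#'   makes forelimb lameness dominate head/withers and hindlimb lameness
#'   dominate the pelvis with an ipsilateral head component (the classic
#'   compensatory pattern); it is a configurable modelling choice, not a
#'   clinical claim.
#' @param retraction_amplitude Protraction--retraction half-amplitude in
#'   degrees; either a scalar or a named vector per limb (`RF,LF,RH,LH`).
#' @param retraction_deficit_per_grade Fractional reduction of the lame
#'   limb's retraction amplitude per grade unit.
#' @param physio_asymmetry Named numeric (`H`, `W`, `P`), additional
#'   first-harmonic asymmetry in grade-equivalent units added regardless of
#'   label. Defaults to zero; cohort simulation uses it to give every horse
#'   (including sound ones) a small physiological asymmetry.
#' @param noise_sd Standard deviation (cm) of white Gaussian noise added to
#'   each displacement sample.
#' @param seed Integer seed for the trial's noise stream, or `NULL`.
#'
#' @return A list of class `sim_params`.
#' @seealso [simulate_trial()], [simulate_cohort()]
#' @export
sim_params <- function(stride_frequency = 1.4,
                       sampling_rate = 200,
                       n_strides = 15,
                       base_amplitude = c(H = 3.0, W = 2.5, P = 3.5),
                       asymmetry_gain = 0.05,
                       compensation_matrix = default_compensation_matrix(),
                       retraction_amplitude = 25,
                       retraction_deficit_per_grade = 0.03,
                       physio_asymmetry = c(H = 0, W = 0, P = 0),
                       noise_sd = 0.05,
                       seed = NULL) {
  p <- list(stride_frequency = stride_frequency,
            sampling_rate = sampling_rate,
            n_strides = n_strides,
            base_amplitude = base_amplitude,
            asymmetry_gain = asymmetry_gain,
            compensation_matrix = compensation_matrix,
            retraction_amplitude = retraction_amplitude,
            retraction_deficit_per_grade = retraction_deficit_per_grade,
            physio_asymmetry = physio_asymmetry,
            noise_sd = noise_sd,
            seed = seed)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

#' @rdname sim_params
#' @export
default_compensation_matrix <- function() {
  m <- rbind(RF = c(1.0, 0.6, 0.1),
             LF = c(-1.0, -0.6, -0.1),
             RH = c(0.4, 0.2, 1.0),
             LH = c(-0.4, -0.2, -1.0))
  colnames(m) <- GAIT_SENSORS
  m
}

validate_sim_params <- function(p) {
  num_fields <- c(p$stride_frequency, p$sampling_rate, p$n_strides,
                  p$base_amplitude, p$asymmetry_gain, p$compensation_matrix,
                  p$retraction_amplitude, p$retraction_deficit_per_grade,
                  p$physio_asymmetry, p$noise_sd)
  if (!all(is.finite(num_fields))) abort("sim_params: all fields must be finite")
  if (p$sampling_rate <= 4 * p$stride_frequency) {
    abort("sim_params: sampling_rate must exceed 4 * stride_frequency (aliasing guard)")
  }
  if (p$n_strides < 3) abort("sim_params: n_strides must be >= 3")
  if (!all(GAIT_SENSORS %in% names(p$base_amplitude)) ||
      any(p$base_amplitude[GAIT_SENSORS] <= 0)) {
    abort("sim_params: base_amplitude must be positive and named H, W, P")
  }
  if (p$noise_sd < 0) abort("sim_params: noise_sd must be >= 0")
  cm <- p$compensation_matrix
  if (!all(GAIT_LIMBS %in% rownames(cm)) || !all(GAIT_SENSORS %in% colnames(cm))) {
    abort("sim_params: compensation_matrix needs rows RF,LF,RH,LH and columns H,W,P")
  }
  invisible(p)
}

# Trot phasing: mid-stance of the LF+RH diagonal is placed at t = 0.
# A limb is in stance while its angle decreases from maximal protraction
# (stance onset) to maximal retraction (lift-off), i.e. for sine phase in
# [pi/2, 3*pi/2].
limb_phase_offsets <- function() {
  c(RF = 0, LF = pi, RH = pi, LH = 0)
}

# Phase of the injected first harmonic, per sensor: chosen so a
# positive-weight asymmetry gives a shallower displacement minimum during
# the stance of the sensor's RIGHT reference limb (right fore for head and
# withers, right hind for the pelvis), i.e. a positive asymmetry index.
asymmetry_phase <- function(sensor) if (sensor == "P") pi / 2 else -pi / 2

#' Simulate one straight-line trot recording
#'
#' Generates a labelled trial: vertical displacement of head, withers and
#' pelvis plus protraction--retraction angle of the four cannon sensors, with
#' analytic stance-onset / lift-off events. With `noise_sd = 0` and default
#' `physio_asymmetry`, a `SOUND` trial is exactly left--right symmetric by
#' construction; a lame trial carries a first-harmonic displacement
#' asymmetry scaled by `grade` and a retraction deficit on the lame limb.
#'
#' @param label Lameness class (one of [lameness_levels()]).
#' @param grade Lameness grade on the 0--10 scale (0 sound, 10
#'   non-weight-bearing). Ignored for the asymmetry injection when
#'   `label = "SOUND"`.
#' @param params A [sim_params()] object.
#'
#' @return An object of class `gait_trial`: a list with elements
#'   `displacement` (named list of numeric series, cm), `limb_angle` (named
#'   list, degrees, protraction positive), `stance_events` (tibble with
#'   `limb`, `onset`, `liftoff` sample indices), `time_s`, `label`, `grade`,
#'   `params`.
#' @export
#' @examples
#' tr <- simulate_trial("RF", grade = 3, sim_params(seed = 1))
#' str(tr$displacement$H)
simulate_trial <- function(label, grade, params = sim_params()) {
  validate_sim_params(params)
  label <- as_lameness_label(label)
  if (length(label) != 1) abort("simulate_trial: one label at a time")
  if (!is.finite(grade) || grade < 0 || grade > 10) {
    abort("simulate_trial: grade must be in [0, 10]")
  }
  f <- params$stride_frequency
  fs <- params$sampling_rate
  n <- ceiling(fs * (params$n_strides + 1.5) / f)
  t <- (seq_len(n) - 1) / fs

  if (!is.null(params$seed)) set.seed(params$seed)

  lab <- as.character(label)
  weights <- if (lab == "SOUND") {
    setNames(numeric(3), GAIT_SENSORS)
  } else {
    params$compensation_matrix[lab, GAIT_SENSORS]
  }

  displacement <- list()
  for (s in GAIT_SENSORS) {
    A <- params$base_amplitude[[s]]
    a <- params$asymmetry_gain *
      (grade * weights[[s]] + params$physio_asymmetry[[s]]) * A
    y <- -A * cos(4 * pi * f * t) + a * sin(2 * pi * f * t + asymmetry_phase(s))
    if (params$noise_sd > 0) y <- y + rnorm(n, sd = params$noise_sd)
    displacement[[s]] <- y
  }

  phases <- limb_phase_offsets()
  theta0 <- params$retraction_amplitude
  if (length(theta0) == 1) theta0 <- setNames(rep(theta0, 4), GAIT_LIMBS)
  limb_angle <- list()
  for (l in GAIT_LIMBS) {
    amp <- theta0[[l]]
    if (l == lab) amp <- amp * (1 - params$retraction_deficit_per_grade * grade)
    limb_angle[[l]] <- amp * sin(2 * pi * f * t + phases[[l]])
  }

  stance_events <- stance_events_from_phase(phases, f, fs, n)

  structure(list(displacement = displacement,
                 limb_angle = limb_angle,
                 stance_events = stance_events,
                 time_s = t,
                 label = label,
                 grade = grade,
                 params = params),
            class = "gait_trial")
}

# Analytic gait events: stance onset where the angle sine passes its maximum
# (phase pi/2), lift-off at the retraction extremum (phase 3*pi/2).
stance_events_from_phase <- function(phases, f, fs, n) {
  res <- list()
  for (l in names(phases)) {
    k <- -3:ceiling(f * n / fs + 3)
    onset_t <- (pi / 2 - phases[[l]] + 2 * pi * k) / (2 * pi * f)
    liftoff_t <- onset_t + 1 / (2 * f)
    onset <- round(onset_t * fs) + 1
    liftoff <- round(liftoff_t * fs) + 1
    keep <- onset >= 1 & liftoff <= n
    res[[l]] <- tibble(limb = l, onset = as.integer(onset[keep]),
                       liftoff = as.integer(liftoff[keep]))
  }
  dplyr::bind_rows(res)
}

#' @export
print.gait_trial <- function(x, ...) {
  cat("<gait_trial> label:", as.character(x$label), " grade:", x$grade,
      "\n  ", length(x$time_s), "samples @", x$params$sampling_rate, "Hz, ",
      "stride frequency", x$params$stride_frequency, "Hz\n")
  invisible(x)
}

#' Tidy a gait trial into a long signal table
#'
#' @param x A `gait_trial`.
#' @param ... Unused.
#' @return Tibble with `time_s`, `channel`
#'   (`disp_H, disp_W, disp_P, ang_RF, ang_LF, ang_RH, ang_LH`) and `value`.
#' @method tidy gait_trial
#' @export
tidy.gait_trial <- function(x, ...) {
  disp <- purrr::imap(x$displacement, function(v, s) {
    tibble(time_s = x$time_s, channel = paste0("disp_", s), value = v)
  })
  ang <- purrr::imap(x$limb_angle, function(v, l) {
    tibble(time_s = x$time_s, channel = paste0("ang_", l), value = v)
  })
  dplyr::bind_rows(c(disp, ang))
}

#' Simulate a labelled cohort of trot recordings
#'
#' Draws one trial per horse with deterministic per-trial seeds derived from
#' `seed`, class labels in the given counts, lameness grades from
#' `grade_sampler`, and per-horse biological variability: base amplitudes are
#' jittered log-normally (`amplitude_cv`), the lame limb's compensation
#' weights receive additive Gaussian jitter (`compensation_jitter_sd`), every
#' horse gets a small random physiological asymmetry
#' (`physio_asymmetry_sd`, grade-equivalent units) and a small left--right
#' retraction amplitude imbalance (`retraction_jitter_cv`). Set the four
#' jitter parameters to zero for perfectly clean cohorts.
#'
#' @param class_counts Named integer vector of horses per class; default is
#'   the reference clinical cohort composition (92 RF, 89 LF, 39 RH, 36 LH,
#'   31 sound; 287 horses).
#' @param grade_sampler Function `n -> integer grades in 2..7` used for lame
#'   horses, or `NULL` for the default sampler that follows the reference
#'   cohort's empirical grade distribution. Sound horses draw grades from
#'   \{0, 1\}.
#' @param params Baseline [sim_params()] shared by all horses.
#' @param seed Master seed; the cohort is reproducible element-wise.
#' @param amplitude_cv,compensation_jitter_sd,physio_asymmetry_sd,retraction_jitter_cv,stride_frequency_cv
#'   Between-horse variability parameters (see Description);
#'   `stride_frequency_cv` is the log-normal coefficient of variation of the
#'   per-horse trot cadence around `params$stride_frequency`.
#'
#' @return Tibble with columns `trial_id`, `label`, `grade`, `seed` and a
#'   list-column `trial` of `gait_trial` objects.
#' @export
#' @examples
#' co <- simulate_cohort(c(RF = 2, SOUND = 1), seed = 1,
#'                       params = sim_params(n_strides = 5))
#' co$label
simulate_cohort <- function(class_counts = c(RF = 92, LF = 89, RH = 39,
                                             LH = 36, SOUND = 31),
                            grade_sampler = NULL,
                            params = sim_params(),
                            seed = 1,
                            amplitude_cv = 0.15,
                            compensation_jitter_sd = 0.25,
                            physio_asymmetry_sd = 0.3,
                            retraction_jitter_cv = 0.03,
                            stride_frequency_cv = 0.05) {
  validate_sim_params(params)
  class_counts <- class_counts[class_counts > 0]
  if (length(class_counts) == 0) abort("simulate_cohort: empty cohort")
  labels <- as_lameness_label(rep(names(class_counts), class_counts))
  n <- length(labels)
  if (is.null(grade_sampler)) grade_sampler <- default_grade_sampler
  set.seed(seed)
  grades <- integer(n)
  lame <- labels != "SOUND"
  grades[lame] <- grade_sampler(sum(lame))
  grades[!lame] <- sample(0:1, sum(!lame), replace = TRUE)

  trial_seeds <- derive_seed(seed, seq_len(n))
  trials <- vector("list", n)
  theta0 <- params$retraction_amplitude
  if (length(theta0) == 1) theta0 <- setNames(rep(theta0, 4), GAIT_LIMBS)
  for (i in seq_len(n)) {
    set.seed(trial_seeds[i])
    p <- params
    p$stride_frequency <- params$stride_frequency *
      exp(rnorm(1, sd = stride_frequency_cv))
    p$base_amplitude <- params$base_amplitude[GAIT_SENSORS] *
      exp(rnorm(3, sd = amplitude_cv))
    lab <- as.character(labels[i])
    if (lab != "SOUND" && compensation_jitter_sd > 0) {
      p$compensation_matrix[lab, ] <- p$compensation_matrix[lab, ] +
        rnorm(3, sd = compensation_jitter_sd)
    }
    p$physio_asymmetry <- params$physio_asymmetry[GAIT_SENSORS] +
      rnorm(3, sd = physio_asymmetry_sd)
    p$retraction_amplitude <- theta0 * exp(rnorm(4, sd = retraction_jitter_cv))
    p$seed <- trial_seeds[i]
    trials[[i]] <- simulate_trial(labels[i], grades[i], p)
  }
  tibble(trial_id = sprintf("trial_%03d", seq_len(n)),
         label = labels, grade = grades, seed = trial_seeds,
         trial = trials)
}

# Empirical grade distribution of the reference clinical cohort (grades 2..7
# pooled across the four lame classes).
default_grade_sampler <- function(n) {
  counts <- colSums(as.matrix(reference_grade_counts()[, -1]))
  sample(2:7, n, replace = TRUE, prob = counts / sum(counts))
}

#' Write / read cohort signal files
#'
#' Long-format CSV interchange: `signals.csv` with columns
#' `trial_id,time_s,channel,value`; `labels.csv` with
#' `trial_id,label,grade,seed`; `events.csv` with
#' `trial_id,limb,stance_onset_s,liftoff_s`.
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `write_gait_cohort()` returns the paths invisibly;
#'   `read_gait_signals()` returns the long signal tibble.
#' @export
write_gait_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  signals <- purrr::map2(cohort$trial, cohort$trial_id, function(tr, id) {
    dplyr::mutate(tidy(tr), trial_id = id, .before = 1)
  })
  signals <- dplyr::bind_rows(signals)
  events <- purrr::map2(cohort$trial, cohort$trial_id, function(tr, id) {
    fs <- tr$params$sampling_rate
    dplyr::transmute(tr$stance_events, trial_id = id, limb = .data$limb,
                     stance_onset_s = (.data$onset - 1) / fs,
                     liftoff_s = (.data$liftoff - 1) / fs)
  })
  events <- dplyr::bind_rows(events)
  labels <- dplyr::select(cohort, "trial_id", "label", "grade", "seed")
  paths <- file.path(dir, c("signals.csv", "labels.csv", "events.csv"))
  write.csv(signals, paths[1], row.names = FALSE)
  write.csv(labels, paths[2], row.names = FALSE)
  write.csv(events, paths[3], row.names = FALSE)
  invisible(paths)
}

#' @rdname write_gait_cohort
#' @param path Path to a `signals.csv` written by [write_gait_cohort()].
#' @export
read_gait_signals <- function(path) {
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname write_gait_cohort
#' @details `read_gait_cohort()` rebuilds trial objects from the three CSVs
#'   written by `write_gait_cohort()`; the sampling rate is inferred from the
#'   time stamps. Rebuilt trials carry only what downstream processing needs
#'   (series, events, label, grade, sampling rate), not the generator
#'   parameters.
#' @export
read_gait_cohort <- function(dir) {
  sig <- read_gait_signals(file.path(dir, "signals.csv"))
  labels <- read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  events <- read.csv(file.path(dir, "events.csv"), stringsAsFactors = FALSE)
  trials <- vector("list", nrow(labels))
  for (i in seq_len(nrow(labels))) {
    id <- labels$trial_id[i]
    s <- sig[sig$trial_id == id, ]
    t <- sort(unique(s$time_s))
    fs <- 1 / stats::median(diff(t))
    chan <- function(nm) s$value[s$channel == nm][order(s$time_s[s$channel == nm])]
    ev <- events[events$trial_id == id, ]
    trials[[i]] <- structure(list(
      displacement = list(H = chan("disp_H"), W = chan("disp_W"),
                          P = chan("disp_P")),
      limb_angle = list(RF = chan("ang_RF"), LF = chan("ang_LF"),
                        RH = chan("ang_RH"), LH = chan("ang_LH")),
      stance_events = tibble(limb = ev$limb,
                             onset = as.integer(round(ev$stance_onset_s * fs)) + 1L,
                             liftoff = as.integer(round(ev$liftoff_s * fs)) + 1L),
      time_s = t,
      label = as_lameness_label(labels$label[i]),
      grade = labels$grade[i],
      params = list(sampling_rate = fs)),
      class = "gait_trial")
  }
  tibble(trial_id = labels$trial_id,
         label = as_lameness_label(labels$label),
         grade = labels$grade, seed = labels$seed, trial = trials)
}
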