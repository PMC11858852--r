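# Shared fixtures and independent oracles for the test suite.

# Sampling commensurate with the stride: 200 Hz / 1.25 Hz = 160 samples per
# stride, 80 per half-stride, and every analytic gait event falls exactly on
# a sample. Under these conditions interpolation is exact and symmetry
# properties hold to machine precision.
commensurate_params <- function(noise_sd = 0, seed = 1, n_strides = 10, ...) {
  sim_params(stride_frequency = 1.25, sampling_rate = 200,
             n_strides = n_strides, noise_sd = noise_sd, seed = seed, ...)
}

# Analytic two-harmonic stride curve on a dense circular grid (no duplicated
# endpoint), in the stride frame used throughout: minima at 25 % and 75 %
# stride (the two diagonal-stance troughs), optional first harmonic `b` and
# circular shift.
analytic_curve <- function(n = 4000, A = 1, b = 0, shift = 0) {
  u <- (seq_len(n) - 1) / n
  A * cos(4 * pi * (u - shift)) + b * sin(2 * pi * (u - shift))
}

# Brute-force landmark oracle: dense scan over a circular curve. Local
# extrema found by direct neighbour comparison at every point; minima
# assigned to sides by circular distance to the given mid-stance fractions;
# following/preceding maxima by exhaustive circular walk. Independent of the
# package's extrema detection.
oracle_landmarks <- function(curve, mid_R, mid_L) {
  m <- length(curve)
  nxt <- c(2:m, 1)
  prv <- c(m, 1:(m - 1))
  is_max <- curve > curve[prv] & curve >= curve[nxt]
  is_min <- curve < curve[prv] & curve <= curve[nxt]
  min_idx <- which(is_min)
  stopifnot(length(min_idx) == 2, sum(is_max) == 2)
  circ_dist <- function(a, b) pmin(abs(a - b), 1 - abs(a - b))
  frac <- (min_idx - 1) / m
  ord <- order(circ_dist(frac, mid_R))
  idx_R <- min_idx[ord[1]]
  idx_L <- min_idx[ord[2]]
  walk <- function(start, dir) {
    i <- start
    repeat {
      i <- if (dir > 0) (i %% m) + 1 else ((i - 2) %% m) + 1
      if (is_max[i]) return(i)
    }
  }
  land <- function(idx) {
    list(min = curve[idx],
         max_next = curve[walk(idx, 1)],
         max_prev = curve[walk(idx, -1)])
  }
  r <- land(idx_R); l <- land(idx_L)
  list(min_R = r$min, min_L = l$min,
       max_R = r$max_next, max_L = l$max_next,
       up_R = r$max_next - r$min, up_L = l$max_next - l$min,
       down_R = r$max_prev - r$min, down_L = l$max_prev - l$min,
       diffTmax_R = r$max_next - min(curve),
       diffTmax_L = l$max_next - min(curve),
       ROM = max(curve) - min(curve))
}

# Small cohort for classifier tests: defaults scaled down.
small_cohort_features <- function(n_per_class = 8, seed = 42) {
  counts <- setNames(rep(n_per_class, 5), lameness_levels())
  co <- simulate_cohort(counts, params = sim_params(n_strides = 6), seed = seed)
  extract_features(co)
}

# Clearly separable 2-class toy features.
separable_xy <- function(n = 20, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * 2, mean = 0, sd = 0.1), ncol = 2),
             matrix(rnorm(n * 2, mean = 5, sd = 0.1), ncol = 2))
  colnames(x) <- c("f1", "f2")
  list(x = tibble::as_tibble(x),
       y = factor(rep(c("a", "b"), each = n)))
}
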