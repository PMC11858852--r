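test_that("asymmetry indices vanish on symmetric landmarks in both dialects", {
  curve <- analytic_curve(n = 2000, b = 0)
  lm <- extract_landmarks(curve, half_assignment = c(R = 0.75, L = 0.25))
  for (d in c("caption", "rom_normalized")) {
    asi <- asymmetry_indices(lm, dialect = d)
    expect_equal(unname(asi), rep(0, 5), tolerance = 1e-10)
    expect_named(asi, c("AsI_up", "AsI_down", "AsI_max", "AsI_min", "AsI_Tmax"))
  }
})

test_that("caption-dialect indices match hand-computed values from the oracle", {
  curve <- analytic_curve(n = 4000, b = 0.2)
  o <- oracle_landmarks(curve, mid_R = 0.75, mid_L = 0.25)
  lm <- extract_landmarks(curve, half_assignment = c(R = 0.75, L = 0.25))
  got <- asymmetry_indices(lm, dialect = "caption")
  # the five contralateral-denominator formulas, written out directly
  expect_equal(got[["AsI_min"]], 100 * (o$min_R - o$min_L) / o$up_L, tolerance = 1e-9)
  expect_equal(got[["AsI_max"]], 100 * (o$max_L - o$max_R) / o$up_L, tolerance = 1e-9)
  expect_equal(got[["AsI_up"]], 100 * (o$up_L - o$up_R) / o$up_L, tolerance = 1e-9)
  expect_equal(got[["AsI_down"]], 100 * (o$down_L - o$down_R) / o$down_L, tolerance = 1e-9)
  expect_equal(got[["AsI_Tmax"]], 100 * (o$diffTmax_L - o$diffTmax_R) / o$diffTmax_L,
               tolerance = 1e-9)
  rom <- asymmetry_indices(lm, dialect = "rom_normalized")
  expect_equal(rom[["AsI_min"]], 100 * (o$min_R - o$min_L) / o$ROM, tolerance = 1e-9)
})

test_that("rom-normalized indices negate exactly under a left-right mirror", {
  curve <- analytic_curve(n = 3000, b = 0.3)
  a <- extract_landmarks(curve, half_assignment = c(R = 0.75, L = 0.25))
  b <- extract_landmarks(curve, half_assignment = c(R = 0.25, L = 0.75))
  expect_equal(unname(asymmetry_indices(a, "rom_normalized")),
               -unname(asymmetry_indices(b, "rom_normalized")),
               tolerance = 1e-12)
})

test_that("zero denominators raise errors naming the index", {
  lm <- extract_landmarks(analytic_curve(n = 1000, b = 0.1),
                          half_assignment = c(R = 0.75, L = 0.25))
  lm$up_L <- 0
  expect_error(asymmetry_indices(lm, "caption"), "AsI_up")
  lm$ROM <- 0
  expect_error(asymmetry_indices(lm, "rom_normalized"), "ROM")
})

test_that("harmonic fit recovers planted amplitudes and phases", {
  u <- seq(0, 1, length.out = 101)
  fit <- harmonic_fit(2 * cos(4 * pi * u))
  expect_equal(fit$amplitude_2, 2, tolerance = 1e-9)
  expect_equal(fit$amplitude_1, 0, tolerance = 1e-9)

  fit2 <- harmonic_fit(1 * sin(2 * pi * u) + 2 * cos(4 * pi * u))
  expect_equal(fit2$amplitude_1, 1, tolerance = 1e-9)
  expect_equal(fit2$amplitude_2, 2, tolerance = 1e-9)
  expect_equal(fit2$phase_1, 90, tolerance = 1e-9)
  expect_equal(fit2$phase_2, 0, tolerance = 1e-9)

  # a constant offset is absorbed by the intercept
  fit3 <- harmonic_fit(1 * sin(2 * pi * u) + 2 * cos(4 * pi * u) + 7)
  expect_equal(fit3$amplitude_1, fit2$amplitude_1, tolerance = 1e-9)
  expect_equal(fit3$phase_2, fit2$phase_2, tolerance = 1e-9)

  # degenerate: constant curve
  fit4 <- harmonic_fit(rep(3, 50))
  expect_equal(fit4$amplitude_1, 0, tolerance = 1e-9)
  expect_equal(fit4$phase_1, 0)
  expect_error(harmonic_fit(c(1, 2, 3)), "at least 5 points")
})

test_that("energy ratio and phase difference follow their definitions", {
  u <- seq(0, 1, length.out = 101)
  eq <- fourier_features(harmonic_fit(sin(2 * pi * u) + sin(4 * pi * u)))
  expect_equal(eq$ERz, 100, tolerance = 1e-9)

  ff <- fourier_features(harmonic_fit(1 * sin(2 * pi * u) + 2 * cos(4 * pi * u)))
  expect_equal(ff$ERz, 400, tolerance = 1e-9)   # 100 * 2^2 / 1^2
  expect_equal(ff$dphi, 90, tolerance = 1e-9)   # 90 - 0
  expect_false(ff$degenerate)

  sym <- fourier_features(harmonic_fit(2 * cos(4 * pi * u)))
  expect_true(sym$degenerate)
  expect_equal(sym$ERz, 1e6)
  capped <- fourier_features(harmonic_fit(2 * cos(4 * pi * u)), ceiling = 500)
  expect_equal(capped$ERz, 500)
})

test_that("retraction asymmetry follows its arithmetic definition", {
  p <- commensurate_params()
  tr <- simulate_trial("SOUND", 0, p)
  expect_equal(retraction_asymmetry(tr, "fore"), 0, tolerance = 1e-9)
  expect_equal(retraction_asymmetry(tr, "hind"), 0, tolerance = 1e-9)

  # left 20 deg, right 16 deg -> 100 * 4 / 18 = 22.22...
  p2 <- commensurate_params()
  p2$retraction_amplitude <- c(RF = 16, LF = 20, RH = 25, LH = 25)
  tr2 <- simulate_trial("SOUND", 0, p2)
  expect_equal(retraction_asymmetry(tr2, "fore"), 100 * 4 / 18, tolerance = 1e-6)

  # right-fore-lame: right retraction reduced, left > right -> positive index
  tr3 <- simulate_trial("RF", 4, p)
  expect_gt(retraction_asymmetry(tr3, "fore"), 0)
  expect_equal(retraction_asymmetry(tr3, "hind"), 0, tolerance = 1e-9)

  tr4 <- tr3
  tr4$stance_events <- tr4$stance_events[1:2, ]
  expect_error(retraction_asymmetry(tr4, "fore"), "lift-off events")
})

test_that("the feature vector has 27 finite features in fixed order", {
  tr <- simulate_trial("LH", 3, commensurate_params(noise_sd = 0.05, seed = 11))
  fv <- build_feature_vector(tr)
  expect_equal(names(fv)[1:27], feature_names())
  expect_length(feature_names(), 27)
  expect_true(all(is.finite(unlist(fv[1:27]))))
  # determinism
  fv2 <- build_feature_vector(simulate_trial("LH", 3,
                                             commensurate_params(noise_sd = 0.05, seed = 11)))
  expect_identical(fv, fv2)
})

test_that("zero-noise sound trials yield exactly null asymmetry features", {
  fv <- build_feature_vector(simulate_trial("SOUND", 0, commensurate_params()))
  asym <- grep("^AsI_", feature_names(), value = TRUE)
  expect_equal(unname(unlist(fv[asym])), rep(0, length(asym)), tolerance = 1e-9)
  expect_true(fv$ERz_degenerate)
})

test_that("features scale correctly when displacement is scaled", {
  tr <- simulate_trial("RF", 3, commensurate_params(noise_sd = 0, seed = 2))
  tr_scaled <- tr
  tr_scaled$displacement <- lapply(tr$displacement, function(y) 3 * y)
  f1 <- build_feature_vector(tr)
  f2 <- build_feature_vector(tr_scaled)
  for (s in c("H", "W", "P")) {
    expect_equal(f2[[paste0("ROM_", s)]], 3 * f1[[paste0("ROM_", s)]], tolerance = 1e-9)
    expect_equal(f2[[paste0("ERz_", s)]], f1[[paste0("ERz_", s)]], tolerance = 1e-9)
    expect_equal(f2[[paste0("AsI_up_", s)]], f1[[paste0("AsI_up_", s)]], tolerance = 1e-9)
  }
})

test_that("mirroring the lame side negates asymmetry features only (rom dialect)", {
  p <- commensurate_params()
  for (pair in list(c("RF", "LF"), c("RH", "LH"))) {
    f1 <- build_feature_vector(simulate_trial(pair[1], 4, p), dialect = "rom_normalized")
    f2 <- build_feature_vector(simulate_trial(pair[2], 4, p), dialect = "rom_normalized")
    asym <- grep("^AsI_", feature_names(), value = TRUE)
    expect_equal(unname(unlist(f1[asym])), -unname(unlist(f2[asym])), tolerance = 1e-9)
    sym <- c("ERz_H", "ERz_W", "ERz_P", "ROM_H", "ROM_W", "ROM_P", "stride_frequency")
    expect_equal(unname(unlist(f1[sym])), unname(unlist(f2[sym])), tolerance = 1e-9)
    # the phase difference flips sign with the side of the first harmonic
    expect_equal(f1$dphi_H, -f2$dphi_H, tolerance = 1e-6)
  }
})

test_that("the feature table round-trips through CSV losslessly", {
  co <- simulate_cohort(c(RF = 2, SOUND = 2), params = sim_params(n_strides = 4),
                        seed = 8)
  feats <- extract_features(co)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(feats, path, dialect = "caption")
  back <- read_features(path)
  expect_equal(attr(back, "dialect"), "caption")
  expect_equal(as.character(back$label), as.character(feats$label))
  for (f in feature_names()) {
    expect_equal(back[[f]], feats[[f]], tolerance = 1e-12)
  }
})
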