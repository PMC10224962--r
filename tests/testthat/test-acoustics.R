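test_that("autocorrelation tracker pins pure tones and rejects noise", {
  con <- track_f0(make_tone(700, dur = 0.5), fs_default)
  expect_true(all(con$voiced))
  expect_true(all(abs(con$f0 - 700) <= 1))
  set.seed(31)
  noise <- track_f0(rnorm(fs_default / 2), fs_default)
  expect_gte(mean(!noise$voiced), 0.9)
  expect_error(track_f0(numeric(100), fs_default), "shorter")
})

test_that("f0 recovery error is below 1% across the species' range", {
  for (fr in seq(400, 1400, by = 100)) {
    call <- synthesize_call(flat_spec(fr, 0.3), seed = 1)
    f <- extract_features(call)
    expect_lt(abs(f$f0_mean - fr) / fr, 0.01, label = paste0(fr, " Hz"))
  }
})

test_that("contour statistics match closed forms", {
  const <- f0_contour(seq(0, 0.5, by = 0.01), rep(700, 51))
  s <- f0_statistics(const)
  expect_equal(s$f0_range, 0)
  expect_equal(s$f0_abs_slope, 0)
  expect_equal(s$f0_var, 0)
  expect_equal(s$f0_mean, 700)

  ramp <- f0_contour(seq(0, 1, by = 0.01), seq(600, 900, length.out = 101))
  r <- f0_statistics(ramp)
  expect_equal(r$f0_mean, 750)
  expect_equal(r$f0_abs_slope, 300, tolerance = 1e-6)
  expect_equal(r$f0_var, 300, tolerance = 1e-6)
  expect_equal(r$f0_start, 600)
  expect_equal(r$f0_end, 900)

  tri <- f0_contour(c(0, 0.1, 0.2), c(700, 800, 700))
  tr <- f0_statistics(tri)
  expect_equal(tr$f0_abs_slope, 1000)
  expect_equal(tr$f0_range, 100)
  expect_equal(tr$f0_var, 1000)

  expect_error(f0_statistics(f0_contour(c(0, 0.1), c(700, NA))),
               "fewer than 2")
})

test_that("spectral quartiles follow the energy distribution", {
  # uniform spectrum: all mass spread evenly to 24 kHz
  fr <- seq(0, 24000, by = 10)
  u <- quartiles_from_spectrum(fr, rep(1, length(fr)))
  expect_equal(u$q50, 12000, tolerance = 0.01)
  expect_equal(u$spectral_cog, 12000, tolerance = 0.01)
  # two equal-energy tones at 1 and 3 kHz
  two <- make_tone(1000, 0.5) + make_tone(3000, 0.5)
  q2 <- spectral_quartiles(two, fs_default)
  expect_equal(q2$spectral_cog, 2000, tolerance = 0.02)
  expect_lt(abs(q2$q25 - 1000), 60)
  expect_lt(abs(q2$q75 - 3000), 60)
  # single tone: all quartiles and the cog collapse onto it
  q1 <- spectral_quartiles(make_tone(700, 0.5), fs_default)
  expect_true(all(abs(unlist(q1) - 700) < 60))
  expect_lte(q1$q25, q1$q50)
  expect_lte(q1$q50, q1$q75)
  expect_error(spectral_quartiles(numeric(4800), fs_default), "zero-energy")
  expect_error(spectral_quartiles(numeric(4), fs_default), "too short")
})

test_that("modulation rates count envelope peaks and contour reversals", {
  t <- (seq_len(fs_default) - 0.5) / fs_default
  am10 <- sin(2 * pi * 700 * t) * (1 + 0.5 * sin(2 * pi * 10 * t))
  expect_equal(am_rate(am10, fs_default), 10, tolerance = 0.1)
  expect_equal(am_rate(make_tone(700, 1), fs_default), 0)

  vib <- sin(2 * pi * cumsum(750 + 50 * sin(2 * pi * 5 * t)) / fs_default)
  expect_equal(fm_rate(track_f0(vib, fs_default)), 10, tolerance = 0.15)
  chirp <- sin(2 * pi * cumsum(seq(600, 900, length.out = fs_default)) /
                 fs_default)
  expect_equal(fm_rate(track_f0(chirp, fs_default)), 0)
  expect_equal(fm_rate(track_f0(make_tone(700, 0.5), fs_default)), 0)
  expect_error(fm_rate(f0_contour(c(0, 0.01), c(700, 700))), "fewer than 3")
})

test_that("features are invariant to gain and to silence outside the span", {
  call <- synthesize_call(default_specs()$clucking, seed = 13)
  f0 <- extract_features(call)
  for (gain in c(10, 0.1)) {                       # +/- 20 dB
    scaled <- call
    scaled$waveform <- call$waveform * gain
    expect_equal(extract_features(scaled)[feature_names()],
                 f0[feature_names()], tolerance = 1e-8)
  }
  pad <- 0.3
  shifted <- call_record("shifted",
                         waveform = c(numeric(pad * call$sample_rate),
                                      call$waveform,
                                      numeric(pad * call$sample_rate)),
                         sample_rate = call$sample_rate,
                         call_type = call$call_type,
                         start_s = pad,
                         end_s = pad + length(call$waveform) / call$sample_rate)
  fs <- extract_features(shifted)
  expect_equal(fs[feature_names()], f0[feature_names()], tolerance = 1e-8)
})

test_that("feature-vector ordering invariants hold across random specs", {
  set.seed(41)
  shapes <- c("flat", "rise", "fall", "arch", "trill", "syllable_series")
  for (i in 1:8) {
    sp <- synthesis_spec("single",
                         f0_mean_dist = c(runif(1, 600, 1000), runif(1, 0, 60)),
                         f0_range_dist = c(runif(1, 30, 250), runif(1, 0, 40)),
                         duration_dist = c(runif(1, 0.08, 1.2), 0.02),
                         am_rate_dist = c(runif(1, 5, 45), 2),
                         fm_rate_dist = c(runif(1, 2, 9), 1),
                         contour_shape = sample(shapes, 1),
                         n_syllables = c(2L, 4L),
                         noise_snr = 25)
    f <- extract_features(synthesize_call(sp, seed = 500 + i))
    expect_lte(f$f0_min, f$f0_mean)
    expect_lte(f$f0_mean, f$f0_max)
    expect_equal(f$f0_range, f$f0_max - f$f0_min)
    expect_lte(f$q25, f$q50)
    expect_lte(f$q50, f$q75)
    expect_gt(f$duration, 0)
    expect_gte(f$am_rate, 0)
    expect_gte(f$fm_rate, 0)
    expect_gte(f$f0_abs_slope, 0)
    expect_gte(f$f0_var, 0)
  }
})

test_that("corpus extraction yields one complete row per call", {
  corp <- synthesize_corpus(default_specs()[c("clucking", "terror")],
                            n_per_type = 3, seed = 19)
  ft <- extract_corpus_features(corp)
  expect_equal(nrow(ft), 6)
  expect_false(anyNA(ft[feature_names()]))
  expect_equal(ft$call_id, corp$manifest$call_id)
})
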