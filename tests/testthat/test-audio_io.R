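test_that("WAV files round-trip through write and read", {
  x <- make_tone(700, dur = 0.05)
  p <- tempfile(fileext = ".wav")
  write_wav(x, fs_default, p)
  w <- read_wav(p)
  expect_equal(w$sample_rate, fs_default)
  expect_equal(ncol(w$samples), 1)
  expect_equal(nrow(w$samples), length(x))
  expect_lt(max(abs(w$samples[, 1] - x)), 1e-4)  # 16-bit quantisation + scale
  # stereo: downmix by channel mean, length preserved
  st <- cbind(x, -x / 2)
  p2 <- tempfile(fileext = ".wav")
  write_wav(st, fs_default, p2)
  rec <- read_call(p2, list(call_id = "c1", call_type = "clucking"))
  expect_s3_class(rec, "auk_record")
  expect_equal(rec$call_type, "clucking")
  expect_length(rec$waveform, length(x))
  expect_lt(max(abs(rec$waveform - x / 4)), 1 / 16000)
})

test_that("annotation labels outside the closed call-type set are rejected", {
  p <- tempfile(fileext = ".wav")
  write_wav(make_tone(700, 0.02), fs_default, p)
  expect_error(read_call(p, list(call_id = "c1", call_type = "cluck")),
               "unknown call_type")
  expect_error(call_record("x", call_type = "warble"), "unknown call_type")
})

test_that("spectrograms localise tones and track chirps", {
  sp <- spectrogram(make_tone(1000, dur = 1), fs_default)
  expect_equal(sp$fft_length, 715)
  peak_bin <- apply(sp$magnitude, 2, which.max)
  expect_true(all(abs(sp$frequencies[peak_bin] - 1000) < fs_default / 715))
  # silence: uniform floor after dB clamping
  sil <- spectrogram(numeric(4800), fs_default, fft_length = 512)
  expect_equal(max(sil$magnitude) - min(sil$magnitude), 0)
  # chirp: ridge frequency non-decreasing across frames (ideal-chirp oracle:
  # the per-frame argmax follows the instantaneous frequency)
  t <- (seq_len(fs_default) - 0.5) / fs_default
  chirp <- sin(2 * pi * cumsum(600 + 300 * t) / fs_default)
  sc <- spectrogram(chirp, fs_default)
  ridge <- sc$frequencies[apply(sc$magnitude, 2, which.max)]
  expect_true(all(diff(ridge) > -fs_default / 715))
  expect_gt(ridge[length(ridge)], ridge[1] + 200)
  expect_error(spectrogram(numeric(100), fs_default, fft_length = 715),
               "shorter")
})

test_that("linear spectrogram energy matches waveform energy without overlap", {
  x <- make_tone(1234, dur = 0.5) + 0.1 * sin(2 * pi * 333 * seq_len(24000) / 48000)
  L <- 600
  sp <- spectrogram(x, fs_default, window = "rectangle", fft_length = L,
                    hop = L)
  covered <- length(seq(1, length(x) - L + 1, by = L)) * L
  expect_lt(abs(sum(sp$power) - sum(x[seq_len(covered)]^2)) /
              sum(x[seq_len(covered)]^2), 0.01)
})

test_that("call selection fills the design and reuses individuals only when forced", {
  pool <- candidate_pool()
  sel <- select_calls(pool, n_per_type = 30)
  expect_equal(nrow(sel), 240)
  expect_equal(as.vector(table(sel$call_type)[call_types()]), rep(30L, 8))
  # handling: 21 individuals, 30 calls -> exactly 9 sampled twice
  h <- sel[sel$call_type == "handling", ]
  expect_equal(sum(table(h$individual) == 2), 9)
  expect_true(all(table(h$individual) <= 2))
  # non-handling types have enough distinct individuals: no reuse
  o <- sel[sel$call_type != "handling", ]
  expect_true(all(table(paste(o$call_type, o$individual)) == 1))
  # within each type the selected calls are the top-SNR qualifying ones
  cl <- pool[pool$call_type == "clucking", ]
  kept <- sel$call_id[sel$call_type == "clucking"]
  expect_setequal(kept,
                  cl$call_id[order(-cl$snr, cl$call_id)][1:30])
})

test_that("call selection is deterministic, flags shortfalls, honours n = 0", {
  pool <- candidate_pool()
  s1 <- select_calls(pool, 10)
  s2 <- select_calls(pool[sample.int(nrow(pool)), ], 10)
  expect_equal(s1$call_id, s2$call_id)
  expect_equal(nrow(select_calls(pool, 0)), 0)
  small <- pool[pool$call_type == "single", ][1:4, ]
  expect_warning(out <- select_calls(small, 30), "fewer than 30")
  expect_equal(nrow(out), 4)
  expect_equal(attr(out, "shortfall"), "single")
  # low-quality calls never qualify
  lowq <- pool[pool$call_type == "single", ]
  lowq$quality[1:35] <- "low"
  expect_warning(sel_low <- select_calls(lowq, 30))
  expect_true(all(sel_low$quality == "high"))
})

test_that("band SNR estimates rank embedded calls by their noise level", {
  set.seed(21)
  fs <- fs_default
  noise <- rnorm(fs, 0, 0.01)
  x <- noise
  idx <- (0.4 * fs):(0.6 * fs)
  x[idx] <- x[idx] + make_tone(800, dur = length(idx) / fs, amp = 0.5)
  snr_clean <- estimate_snr(x, fs, 0.4, 0.6)
  noisy <- x + rnorm(fs, 0, 0.05)
  snr_noisy <- estimate_snr(noisy, fs, 0.4, 0.6)
  expect_gt(snr_clean, snr_noisy)
  expect_gt(snr_clean, 20)
  # a call spanning the whole file has no flanking noise estimate
  expect_true(is.na(estimate_snr(make_tone(800, 0.5), fs, 0, 0.5)))
})
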