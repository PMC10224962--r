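# Praat-style acoustic parameter extraction: autocorrelation f0 tracking,
# contour statistics, spectral energy quartiles / centre of gravity, and
# amplitude/frequency modulation rates.
#
# Pitch floor/ceiling default to 300/1600 Hz, bracketing the species' observed
# fundamental (roughly 600-1210 Hz); frame 40 ms, hop 10 ms, voicing
# threshold 0.45. All thresholds are arguments.

#' Track the fundamental frequency by windowed autocorrelation
#'
#' Each frame is mean-subtracted, Hann-windowed, and its normalised
#' autocorrelation (taper-corrected by the window's own autocorrelation)
#' searched for peaks between `1/ceiling` and `1/floor` seconds, refined by
#' parabolic interpolation. A frame is voiced iff its best peak reaches
#' `voicing_threshold`. Octave jumps are smoothed by a lowest-cost path over
#' per-frame candidates with transition cost proportional to
#' `|log2(f0[i]/f0[i-1])|`; a small static octave cost penalises
#' lower-frequency candidates so subharmonic peaks (whose autocorrelation
#' is as high as the true period's) are not preferred.
#'
#' @param waveform Numeric samples.
#' @param sample_rate Hz.
#' @param floor,ceiling Pitch search range, Hz.
#' @param frame Analysis frame length, s.
#' @param hop Frame hop, s.
#' @param voicing_threshold Minimum normalised autocorrelation peak.
#' @param max_candidates Per-frame candidates entering the path search.
#' @param octave_cost Weight of the octave-jump transition cost.
#' @param octave_bias Static per-octave penalty favouring higher-frequency
#'   candidates of equal autocorrelation strength.
#' @return `auk_f0contour`: data frame `time` (frame centres, s), `f0` (Hz,
#'   `NA` when unvoiced), `voiced`, `strength`.
#' @export
track_f0 <- function(waveform, sample_rate = 48000, floor = 300,
                     ceiling = 1600, frame = 0.04, hop = 0.01,
                     voicing_threshold = 0.45, max_candidates = 4,
                     octave_cost = 0.35, octave_bias = 0.05) {
  n <- length(waveform)
  flen <- round(frame * sample_rate)
  hlen <- max(1L, round(hop * sample_rate))
  if (n < flen) stop("waveform shorter than one analysis frame")
  lag_min <- max(2L, base::floor(sample_rate / ceiling))
  lag_max <- base::ceiling(sample_rate / floor)
  if (lag_max >= flen) stop("frame too short for the pitch floor")
  starts <- seq(1L, n - flen + 1L, by = hlen)
  w <- hann_window(flen)
  nfft <- stats::nextn(2L * flen, 2)
  frames <- vapply(starts, function(s) {
    x <- waveform[s:(s + flen - 1L)]
    c((x - mean(x)) * w, numeric(nfft - flen))
  }, numeric(nfft))
  # autocorrelation via the Wiener-Khinchin theorem, all frames at once
  ac <- Re(stats::mvfft(Mod(stats::mvfft(frames))^2, inverse = TRUE)) / nfft
  r0 <- ac[1L, ]
  # de-bias by the window's own autocorrelation (taper correction)
  wac <- Re(stats::fft(Mod(stats::fft(c(w, numeric(nfft - flen))))^2,
                       inverse = TRUE)) / nfft
  wac <- wac / wac[1L]
  nfr <- length(starts)
  cand_f <- vector("list", nfr)
  cand_s <- vector("list", nfr)
  lags <- lag_min:lag_max
  for (j in seq_len(nfr)) {
    if (r0[j] <= 0) { cand_f[[j]] <- numeric(0); cand_s[[j]] <- numeric(0); next }
    r <- (ac[lags + 1L, j] / r0[j]) / wac[lags + 1L]
    k <- length(r)
    is_peak <- c(FALSE, r[2:(k - 1)] > r[1:(k - 2)] & r[2:(k - 1)] >= r[3:k],
                 FALSE)
    pk <- which(is_peak)
    if (!length(pk)) { cand_f[[j]] <- numeric(0); cand_s[[j]] <- numeric(0); next }
    pk <- pk[order(r[pk], decreasing = TRUE)][seq_len(min(max_candidates,
                                                          length(pk)))]
    # parabolic interpolation around each integer-lag peak
    lag_hat <- vapply(pk, function(i) {
      y0 <- r[i - 1]; y1 <- r[i]; y2 <- r[i + 1]
      den <- y0 - 2 * y1 + y2
      d <- if (abs(den) > 1e-12) 0.5 * (y0 - y2) / den else 0
      lags[i] + max(min(d, 0.5), -0.5)
    }, numeric(1))
    cand_f[[j]] <- sample_rate / lag_hat
    cand_s[[j]] <- pmin(r[pk], 1)
  }
  best <- vapply(seq_len(nfr),
                 function(j) if (length(cand_s[[j]])) max(cand_s[[j]]) else 0,
                 numeric(1))
  voiced <- best >= voicing_threshold
  f0 <- rep(NA_real_, nfr)
  # lowest-cost path per contiguous voiced run
  run_id <- cumsum(c(TRUE, diff(voiced) != 0))
  for (rid in unique(run_id[voiced])) {
    idx <- which(run_id == rid & voiced)
    fs_list <- cand_f[idx]
    ss_list <- cand_s[idx]
    # drop sub-threshold candidates but keep at least the best
    for (q in seq_along(idx)) {
      keep <- ss_list[[q]] >= voicing_threshold
      if (!any(keep)) keep <- which.max(ss_list[[q]])
      fs_list[[q]] <- fs_list[[q]][keep]
      ss_list[[q]] <- ss_list[[q]][keep]
    }
    m <- length(idx)
    local_cost <- lapply(seq_len(m), function(q)
      (1 - ss_list[[q]]) + octave_bias * log2(ceiling / fs_list[[q]]))
    cost <- local_cost
    back <- vector("list", m)
    if (m > 1) for (q in 2:m) {
      tc <- outer(fs_list[[q - 1]], fs_list[[q]],
                  function(a, b) octave_cost * abs(log2(b / a)))
      tot <- cost[[q - 1]] + tc
      back[[q]] <- apply(tot, 2, which.min)
      cost[[q]] <- local_cost[[q]] + apply(tot, 2, min)
    }
    sel <- integer(m)
    sel[m] <- which.min(cost[[m]])
    if (m > 1) for (q in m:2) sel[q - 1] <- back[[q]][sel[q]]
    f0[idx] <- vapply(seq_len(m), function(q) fs_list[[q]][sel[q]], numeric(1))
  }
  structure(data.frame(time = (starts - 1 + flen / 2) / sample_rate,
                       f0 = f0, voiced = voiced, strength = best),
            class = c("auk_f0contour", "data.frame"))
}

#' Construct an f0 contour from explicit values
#'
#' Mainly for building reference contours in tests and examples.
#'
#' @param time Frame centres, s (strictly increasing).
#' @param f0 Hz per frame (`NA` allowed on unvoiced frames).
#' @param voiced Logical per frame; default: wherever `f0` is finite.
#' @return `auk_f0contour` data frame.
#' @export
f0_contour <- function(time, f0, voiced = is.finite(f0)) {
  stopifnot(length(time) == length(f0), all(diff(time) > 0))
  f0[!voiced] <- NA_real_
  if (any(f0[voiced] <= 0, na.rm = TRUE)) stop("voiced f0 must be positive")
  structure(data.frame(time = time, f0 = f0, voiced = voiced,
                       strength = as.numeric(voiced)),
            class = c("auk_f0contour", "data.frame"))
}

#' Fundamental-frequency contour statistics
#'
#' Over voiced frames: min, max, mean, start (first voiced), end (last
#' voiced), range = max - min; `f0_abs_slope` is the mean absolute local
#' slope over consecutive voiced frame pairs (Hz/s) and `f0_var` the total
#' cumulative absolute f0 change divided by the voiced-span duration (Hz/s).
#'
#' @param contour An `auk_f0contour`.
#' @return Named list of the eight f0 statistics.
#' @export
f0_statistics <- function(contour) {
  v <- which(contour$voiced & is.finite(contour$f0))
  if (length(v) < 2) stop("f0 statistics undefined: fewer than 2 voiced frames")
  f <- contour$f0[v]
  t <- contour$time[v]
  # slopes only between consecutive voiced frames (no bridging across gaps)
  consec <- diff(v) == 1
  df <- diff(f)[consec]
  dt <- diff(t)[consec]
  span <- t[length(t)] - t[1]
  list(f0_min = min(f), f0_max = max(f), f0_mean = mean(f),
       f0_start = f[1], f0_end = f[length(f)],
       f0_range = max(f) - min(f),
       f0_abs_slope = if (length(df)) mean(abs(df / dt)) else 0,
       f0_var = if (length(df)) sum(abs(df)) / span else 0)
}

#' Spectral energy quartiles and centre of gravity
#'
#' Power spectrum of the whole call as a Hann-windowed mean periodogram
#' (Welch average); Q25/Q50/Q75 are the lowest frequencies at which the
#' cumulative power reaches 25/50/75% of the total (linear interpolation
#' within bins), and the centre of gravity is the power-weighted mean
#' frequency.
#'
#' @param waveform Numeric samples (>= 16).
#' @param sample_rate Hz.
#' @param seg_length Welch segment length; default `min(1024, n)` rounded
#'   down to a power of two.
#' @return Named list `q25`, `q50`, `q75`, `spectral_cog` (Hz).
#' @export
spectral_quartiles <- function(waveform, sample_rate = 48000,
                               seg_length = NULL) {
  n <- length(waveform)
  if (n < 16) stop("waveform too short for spectral analysis")
  if (sum(waveform^2) == 0) stop("zero-energy waveform")
  if (is.null(seg_length)) seg_length <- 2^floor(log2(min(1024, n)))
  sp <- spectrogram(waveform, sample_rate, window = "hann",
                    fft_length = seg_length, hop = max(1L, seg_length %/% 2))
  power <- rowMeans(sp$power)
  qs <- quartiles_from_spectrum(sp$frequencies, power)
  qs
}

#' Quartiles and centre of gravity of an explicit power spectrum
#'
#' @param frequencies Bin frequencies, Hz (ascending).
#' @param power Non-negative power per bin.
#' @return Named list `q25`, `q50`, `q75`, `spectral_cog`.
#' @export
quartiles_from_spectrum <- function(frequencies, power) {
  stopifnot(length(frequencies) == length(power), all(power >= 0))
  tot <- sum(power)
  if (tot == 0) stop("zero-energy spectrum")
  cum <- cumsum(power) / tot
  qx <- function(p) {
    i <- which(cum >= p)[1]
    lo <- if (i == 1) 0 else cum[i - 1]
    f_lo <- if (i == 1) frequencies[1] else frequencies[i - 1]
    if (cum[i] - lo < .Machine$double.eps) return(frequencies[i])
    f_lo + (frequencies[i] - f_lo) * (p - lo) / (cum[i] - lo)
  }
  list(q25 = qx(0.25), q50 = qx(0.5), q75 = qx(0.75),
       spectral_cog = sum(frequencies * power) / tot)
}

# amplitude envelope: magnitude of the analytic signal, low-pass smoothed
.envelope <- function(waveform, sample_rate, smooth_hz = 100) {
  n <- length(waveform)
  X <- stats::fft(waveform)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(stats::fft(X * h, inverse = TRUE) / n)
  # moving Hann-kernel average ~ low-pass at smooth_hz
  klen <- max(3L, round(sample_rate / smooth_hz))
  kern <- hann_window(klen); kern <- kern / sum(kern)
  padded <- c(rev(env[seq_len(klen)]), env, rev(env[(n - klen + 1L):n]))
  sm <- stats::filter(padded, kern, sides = 2)
  as.numeric(sm[(klen + 1L):(klen + n)])
}

# peak prominences by the standard left/right walk to the higher surrounding
# minima
.peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    left <- x[seq_len(p)]
    hi_l <- which(left[-length(left)] > x[p])
    lmin <- min(left[(if (length(hi_l)) max(hi_l) else 1):p])
    right <- x[p:length(x)]
    hi_r <- which(right[-1] > x[p])
    rmin <- min(right[1:(if (length(hi_r)) min(hi_r) + 1 else length(right))])
    x[p] - max(lmin, rmin)
  }, numeric(1))
}

#' Amplitude modulation rate
#'
#' Envelope peaks (magnitude of the analytic signal, smoothed at ~100 Hz)
#' with prominence above `prominence * max(envelope)` counted per second of
#' call duration. A flat envelope gives 0.
#'
#' @param waveform Numeric samples.
#' @param sample_rate Hz.
#' @param prominence Fraction of the envelope maximum a peak must rise above
#'   its surroundings.
#' @param smooth_hz Envelope smoothing cutoff, Hz.
#' @return Rate in s^-1.
#' @export
am_rate <- function(waveform, sample_rate = 48000, prominence = 0.1,
                    smooth_hz = 100) {
  n <- length(waveform)
  env <- .envelope(waveform, sample_rate, smooth_hz)
  # exclude the onset/offset ramps so an unmodulated tone yields no peak
  edge <- min(round(0.005 * sample_rate), (n - 3L) %/% 2)
  if (edge > 0) env <- env[(edge + 1L):(n - edge)]
  k <- length(env)
  if (k < 3 || max(env) <= 0) return(0)
  is_peak <- c(FALSE, env[2:(k - 1)] > env[1:(k - 2)] &
                 env[2:(k - 1)] >= env[3:k], FALSE)
  pk <- which(is_peak)
  if (!length(pk)) return(0)
  prom <- .peak_prominence(env, pk)
  sum(prom >= prominence * max(env)) / (n / sample_rate)
}

#' Frequency modulation rate
#'
#' Sign changes of the f0 derivative — contour direction reversals — per
#' second of voiced span. A reversal is only registered once the contour has
#' moved by at least `hysteresis` Hz in the new direction, so frame-level
#' tracking jitter on a near-constant contour does not count as modulation.
#'
#' @param contour An `auk_f0contour` with >= 3 voiced frames.
#' @param hysteresis Minimum excursion (Hz) confirming a direction change;
#'   default 1% of the mean voiced f0 (at least 2 Hz).
#' @return Rate in s^-1.
#' @export
fm_rate <- function(contour, hysteresis = NULL) {
  v <- which(contour$voiced & is.finite(contour$f0))
  if (length(v) < 3) stop("fm rate undefined: fewer than 3 voiced frames")
  f <- contour$f0[v]
  t <- contour$time[v]
  if (is.null(hysteresis)) hysteresis <- max(2, 0.01 * mean(f))
  dir <- 0L; extreme <- f[1]; n_rev <- 0L
  for (x in f[-1]) {
    if (dir == 0L) {
      if (x >= extreme + hysteresis) { dir <- 1L; extreme <- x }
      else if (x <= extreme - hysteresis) { dir <- -1L; extreme <- x }
    } else if (dir == 1L) {
      if (x > extreme) extreme <- x
      else if (x <= extreme - hysteresis) {
        n_rev <- n_rev + 1L; dir <- -1L; extreme <- x
      }
    } else {
      if (x < extreme) extreme <- x
      else if (x >= extreme + hysteresis) {
        n_rev <- n_rev + 1L; dir <- 1L; extreme <- x
      }
    }
  }
  span <- t[length(t)] - t[1]
  if (span <= 0) return(0)
  n_rev / span
}

#' Extract the full acoustic feature vector from a call record
#'
#' Composes [track_f0()], [f0_statistics()], [spectral_quartiles()],
#' [am_rate()] and [fm_rate()] over the annotated call span. For calls
#' shorter than five default frames the analysis frame is shortened to
#' `duration / 5` (never below 8 ms) so that very short calls still yield a
#' usable contour with frame centres covering most of the call; `duration`
#' is the annotated span itself.
#'
#' @param record An `auk_record` or `auk_call`.
#' @param floor,ceiling,frame,hop,voicing_threshold Passed to [track_f0()].
#' @return One-row data frame with `call_id`, `call_type` and
#'   [feature_names()].
#' @export
extract_features <- function(record, floor = 300, ceiling = 1600,
                             frame = 0.04, hop = 0.01,
                             voicing_threshold = 0.45) {
  call_id <- record$call_id %||% record$call_type %||% "call"
  res <- tryCatch({
    x <- record$waveform
    fs <- record$sample_rate
    if (is.null(x)) stop("record carries no waveform")
    start_s <- record$start_s; end_s <- record$end_s
    if (!is.null(start_s) && is.finite(start_s) &&
        !is.null(end_s) && is.finite(end_s)) {
      a <- max(1L, base::floor(start_s * fs) + 1L)
      b <- min(length(x), base::floor(end_s * fs))
      x <- x[a:b]
      duration <- end_s - start_s
    } else duration <- length(x) / fs
    frame_used <- max(min(frame, duration / 5), 0.008)
    # keep at least 4 frames even just above the 10 ms duration floor
    hop_used <- max(min(hop, frame_used / 4, (duration - frame_used) / 3),
                    1 / fs)
    con <- track_f0(x, fs, floor = floor, ceiling = ceiling,
                    frame = frame_used, hop = hop_used,
                    voicing_threshold = voicing_threshold)
    fstat <- f0_statistics(con)
    qs <- spectral_quartiles(x, fs)
    data.frame(call_id = call_id,
               call_type = record$call_type %||% NA_character_,
               as.data.frame(fstat), as.data.frame(qs),
               duration = duration,
               am_rate = am_rate(x, fs),
               fm_rate = fm_rate(con))
  }, error = function(e) {
    stop("feature extraction failed for call '", call_id, "': ",
         conditionMessage(e), call. = FALSE)
  })
  res[, c("call_id", "call_type", feature_names())]
}

#' Extract features for every call in a corpus
#'
#' @param corpus An `auk_corpus` (or list of `auk_record`/`auk_call`).
#' @param ... Passed to [extract_features()].
#' @return Data frame, one row per call.
#' @export
extract_corpus_features <- function(corpus, ...) {
  calls <- if (inherits(corpus, "auk_corpus")) corpus$calls else corpus
  ids <- if (inherits(corpus, "auk_corpus")) corpus$manifest$call_id
         else vapply(seq_along(calls),
                     function(i) calls[[i]]$call_id %||% paste0("call_", i),
                     character(1))
  rows <- lapply(seq_along(calls), function(i) {
    rec <- calls[[i]]
    rec$call_id <- ids[i]
    extract_features(rec, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
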