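# Call records, spectrograms, SNR estimation and the call-selection filter.

#' Read a call from a WAV file plus its annotation row
#'
#' Stereo files are downmixed to mono by channel mean; the native sample rate
#' is preserved. The annotation must supply a `call_type` from the closed
#' eight-label set.
#'
#' @param wav_path Path to the WAV file.
#' @param annotation Named list or one-row data frame with at least `call_id`
#'   and `call_type`; optional `start_s`, `end_s` (half-open \[start, end)
#'   seconds), `context`, `individual`, `quality`.
#' @return An object of class `auk_record`.
#' @export
read_call <- function(wav_path, annotation) {
  annotation <- as.list(annotation)
  ct <- as.character(annotation$call_type)
  if (!ct %in% call_types())
    stop("unknown call_type label: '", ct, "'")
  w <- read_wav(wav_path)
  x <- rowMeans(w$samples)
  call_record(
    call_id = as.character(annotation$call_id %||% basename(wav_path)),
    waveform = x, sample_rate = w$sample_rate, call_type = ct,
    start_s = annotation$start_s %||% NA_real_,
    end_s = annotation$end_s %||% NA_real_,
    context = annotation$context %||% NA_character_,
    individual = annotation$individual %||% NA_character_,
    quality = annotation$quality %||% "high")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Construct a call record
#'
#' @param call_id Unique identifier.
#' @param waveform Numeric sample vector (optional if features precomputed).
#' @param sample_rate Sample rate, Hz.
#' @param call_type One of [call_types()].
#' @param start_s,end_s Annotated call span, half-open `[start_s, end_s)`
#'   seconds; `NA` means the whole waveform.
#' @param context Free-text production context.
#' @param individual Optional source individual id.
#' @param quality `"high"` or `"low"`.
#' @return `auk_record` object.
#' @export
call_record <- function(call_id, waveform = NULL, sample_rate = 48000,
                        call_type, start_s = NA_real_, end_s = NA_real_,
                        context = NA_character_, individual = NA_character_,
                        quality = "high") {
  if (!call_type %in% call_types())
    stop("unknown call_type label: '", call_type, "'")
  structure(list(call_id = call_id, waveform = waveform,
                 sample_rate = sample_rate, call_type = call_type,
                 start_s = start_s, end_s = end_s, context = context,
                 individual = individual,
                 quality = match.arg(quality, c("high", "low"))),
            class = "auk_record")
}

#' Spectrogram (Hann window, half-window hop)
#'
#' The analysis window is `fft_length` samples (the reference setting is the
#' non-power-of-two 715); frames are zero-padded to the next power of two
#' internally, which refines the frequency grid without changing the
#' analysis bandwidth.
#'
#' @param waveform Numeric samples.
#' @param sample_rate Hz.
#' @param window Window name (`"hann"` or `"rectangle"`).
#' @param fft_length Analysis window length in samples (>= 16).
#' @param hop Hop in samples; default `fft_length / 2`.
#' @return `auk_spectrogram`: `times` (frame centres, s), `frequencies` (Hz),
#'   `magnitude` (dB re max, frequencies x frames), `power` (linear one-sided
#'   power, scaled so summing over frequency estimates the frame's mean
#'   squared amplitude times the window length), `window`, `fft_length`.
#' @export
spectrogram <- function(waveform, sample_rate = 48000, window = "hann",
                        fft_length = 715, hop = NULL) {
  window <- match.arg(window, c("hann", "rectangle"))
  if (fft_length < 16) stop("fft_length must be >= 16")
  n <- length(waveform)
  if (n < fft_length) stop("waveform shorter than one analysis window")
  if (is.null(hop)) hop <- floor(fft_length / 2)
  starts <- seq(1L, n - fft_length + 1L, by = hop)
  w <- if (window == "hann") hann_window(fft_length) else rep(1, fft_length)
  nfft <- stats::nextn(fft_length, 2)
  frames <- vapply(starts, function(s)
    c(waveform[s:(s + fft_length - 1L)] * w, numeric(nfft - fft_length)),
    numeric(nfft))
  X <- stats::mvfft(frames)
  nb <- nfft %/% 2 + 1L
  p2 <- Mod(X[seq_len(nb), , drop = FALSE])^2 / nfft
  # fold the negative frequencies onto the one-sided spectrum
  dbl <- rep(2, nb); dbl[1] <- 1; if (nfft %% 2 == 0) dbl[nb] <- 1
  power <- p2 * dbl / mean(w^2)
  mag <- 10 * log10(pmax(power, .Machine$double.xmin))
  mag <- mag - max(mag)
  mag <- pmax(mag, -120)
  structure(list(times = (starts - 1 + fft_length / 2) / sample_rate,
                 frequencies = (seq_len(nb) - 1) * sample_rate / nfft,
                 magnitude = mag, power = power,
                 window = window, fft_length = fft_length, hop = hop),
            class = "auk_spectrogram")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' Band-limited signal-to-noise estimate for an annotated call
#'
#' RMS of the call band (default 300-8000 Hz) over the annotated span,
#' divided by the same band's RMS over the flanking 100 ms on each side,
#' in dB. Calls without flanking audio get `NA`.
#'
#' @param waveform Samples containing the call and some flanking audio.
#' @param sample_rate Hz.
#' @param start_s,end_s Annotated call span (half-open, seconds).
#' @param band Passband `c(low, high)` Hz.
#' @param flank Flanking duration per side, s.
#' @return SNR in dB, or `NA` if no flanking audio exists.
#' @export
estimate_snr <- function(waveform, sample_rate, start_s, end_s,
                         band = c(300, 8000), flank = 0.1) {
  n <- length(waveform)
  a <- floor(start_s * sample_rate) + 1L
  b <- min(floor(end_s * sample_rate), n)
  if (a <= 1 && b >= n) return(NA_real_)
  # FFT brick-wall bandpass
  X <- stats::fft(waveform)
  f <- (seq_len(n) - 1) * sample_rate / n
  f <- pmin(f, sample_rate - f)
  X[f < band[1] | f > band[2]] <- 0
  xb <- Re(stats::fft(X, inverse = TRUE)) / n
  fl <- round(flank * sample_rate)
  noise_idx <- c(seq(max(1L, a - fl), max(1L, a - 1L)),
                 seq(min(n, b + 1L), min(n, b + fl)))
  noise_idx <- noise_idx[noise_idx < a | noise_idx > b]
  if (!length(noise_idx)) return(NA_real_)
  rms_call <- sqrt(mean(xb[a:b]^2))
  rms_noise <- sqrt(mean(xb[noise_idx]^2))
  20 * log10(rms_call / max(rms_noise, .Machine$double.xmin))
}

#' Select the analysis set of calls
#'
#' Per call type, keeps the `n_per_type` highest-SNR high-quality calls,
#' preferring distinct source individuals; an individual is reused (up to
#' `1 + max_repeat_per_individual` of its calls) only once distinct
#' individuals are exhausted — mirroring the reference design where 21
#' recorded individuals forced nine to be sampled twice for one call type.
#' Ties are broken by `call_id` lexicographic order, so selection is
#' deterministic.
#'
#' @param records Data frame with columns `call_id`, `call_type`, `quality`,
#'   `snr` (dB; `NA` ranks last), and optionally `individual` (`NA` = treated
#'   as distinct unknown individuals).
#' @param n_per_type Calls to keep per type.
#' @param max_repeat_per_individual Extra calls allowed per individual once
#'   distinct individuals run out.
#' @return The selected rows; attribute `shortfall` names types with fewer
#'   than `n_per_type` qualifying calls (also signalled as a warning).
#' @export
select_calls <- function(records, n_per_type = 30,
                         max_repeat_per_individual = 1) {
  stopifnot(is.data.frame(records))
  if (!"individual" %in% names(records)) records$individual <- NA_character_
  if (!"quality" %in% names(records)) records$quality <- "high"
  if (n_per_type == 0) {
    out <- records[0, ]
    attr(out, "shortfall") <- character(0)
    return(out)
  }
  shortfall <- character(0)
  picked <- lapply(split(records, records$call_type), function(cand) {
    cand <- cand[cand$quality == "high", , drop = FALSE]
    snr <- ifelse(is.na(cand$snr), -Inf, cand$snr)
    cand <- cand[order(-snr, cand$call_id), , drop = FALSE]
    # unknown individuals are all distinct
    ind <- ifelse(is.na(cand$individual),
                  paste0(".anon_", cand$call_id), cand$individual)
    first <- !duplicated(ind)
    sel <- which(first)[seq_len(min(n_per_type, sum(first)))]
    if (length(sel) < n_per_type) {
      used <- table(ind[sel])
      extra <- integer(0)
      for (i in setdiff(seq_len(nrow(cand)), sel)) {
        if (length(sel) + length(extra) >= n_per_type) break
        cnt <- sum(ind[c(sel, extra)] == ind[i])
        if (cnt <= max_repeat_per_individual) extra <- c(extra, i)
      }
      sel <- sort(c(sel, extra))
    }
    if (length(sel) < n_per_type)
      shortfall <<- c(shortfall, cand$call_type[1])
    cand[sel, , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  if (length(shortfall))
    warning("fewer than ", n_per_type, " qualifying calls for: ",
            paste(shortfall, collapse = ", "))
  attr(out, "shortfall") <- shortfall
  out
}
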