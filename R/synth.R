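# Synthetic little auk call generator.
#
# Calls are harmonic stacks whose fundamental-frequency contour, duration,
# amplitude modulation and additive noise are drawn from per-call-type
# Gaussian distributions matching the published summary statistics, so that
# every downstream stage (feature extraction, repertoire discrimination,
# valence models) is testable without field recordings.

#' Build a synthesis specification
#'
#' A `SynthesisSpec` holds the per-call-type generative distributions: each
#' `*_dist` is a `c(mean, sd)` pair on the natural scale of the parameter.
#'
#' @param call_type One of [call_types()].
#' @param f0_mean_dist,f0_range_dist Mean and range of the fundamental
#'   frequency contour, Hz.
#' @param f0_min_dist,f0_max_dist Marginal distributions of the per-call f0
#'   minimum/maximum, Hz (used by the feature-table fast path).
#' @param q25_dist,q50_dist,q75_dist Spectral energy quartiles, Hz.
#' @param duration_dist Call duration, s.
#' @param am_rate_dist,fm_rate_dist Amplitude/frequency modulation rates, s^-1.
#' @param n_harmonics Number of harmonic partials (1/k amplitude roll-off).
#' @param contour_shape One of `"flat"`, `"rise"`, `"fall"`, `"arch"`,
#'   `"trill"`, `"syllable_series"`.
#' @param n_syllables Integer `c(min, max)`; the syllable count is drawn
#'   uniformly from this range for `syllable_series` contours.
#' @param noise_snr Signal-to-noise ratio of the additive Gaussian noise, dB.
#' @param am_depth Fractional depth of the sinusoidal amplitude modulation.
#'
#' @return An object of class `auk_spec`.
#' @export
synthesis_spec <- function(call_type,
                           f0_mean_dist, f0_range_dist,
                           duration_dist, am_rate_dist, fm_rate_dist,
                           f0_min_dist = NULL, f0_max_dist = NULL,
                           q25_dist = NULL, q50_dist = NULL, q75_dist = NULL,
                           n_harmonics = 10L,
                           contour_shape = "arch",
                           n_syllables = c(1L, 1L),
                           noise_snr = 25,
                           am_depth = 0.5) {
  shapes <- c("flat", "rise", "fall", "arch", "trill", "syllable_series")
  contour_shape <- match.arg(contour_shape, shapes)
  stopifnot(length(f0_mean_dist) == 2, length(duration_dist) == 2,
            duration_dist[1] > 0, n_harmonics >= 1,
            all(n_syllables >= 1))
  dists <- list(f0_mean_dist, f0_range_dist, duration_dist, am_rate_dist,
                fm_rate_dist, f0_min_dist, f0_max_dist, q25_dist, q50_dist,
                q75_dist)
  sds <- vapply(Filter(Negate(is.null), dists), `[`, numeric(1), 2L)
  if (any(sds < 0)) stop("distribution SDs must be >= 0")
  structure(list(call_type = call_type,
                 f0_mean_dist = f0_mean_dist, f0_range_dist = f0_range_dist,
                 f0_min_dist = f0_min_dist, f0_max_dist = f0_max_dist,
                 q25_dist = q25_dist, q50_dist = q50_dist, q75_dist = q75_dist,
                 duration_dist = duration_dist,
                 am_rate_dist = am_rate_dist, fm_rate_dist = fm_rate_dist,
                 n_harmonics = as.integer(n_harmonics),
                 contour_shape = contour_shape,
                 n_syllables = as.integer(rep(n_syllables, length.out = 2)),
                 noise_snr = noise_snr, am_depth = am_depth),
            class = "auk_spec")
}

#' Default synthesis specifications for the eight call types
#'
#' Distributions are the published per-type means and SDs of the measured
#' acoustic parameters; the f0 *range* distribution is derived as
#' `mean(f0_max) - mean(f0_min)` with SD the average of the min/max SDs.
#'
#' @return Named list of eight [synthesis_spec()] objects.
#' @export
#' @examples
#' default_specs()[["clucking"]]$duration_dist  # c(0.09, 0.02)
default_specs <- function() {
  out <- lapply(call_types(), function(ct) {
    m <- .auk_table_means[, ct]
    s <- .auk_table_sds[, ct]
    synthesis_spec(
      call_type     = ct,
      f0_mean_dist  = c(m["f0_mean"], s["f0_mean"]),
      f0_range_dist = c(m["f0_max"] - m["f0_min"],
                        (s["f0_max"] + s["f0_min"]) / 2),
      f0_min_dist   = c(m["f0_min"], s["f0_min"]),
      f0_max_dist   = c(m["f0_max"], s["f0_max"]),
      q25_dist      = c(m["q25"], s["q25"]),
      q50_dist      = c(m["q50"], s["q50"]),
      q75_dist      = c(m["q75"], s["q75"]),
      duration_dist = c(m["duration"], s["duration"]),
      am_rate_dist  = c(m["am_rate"], s["am_rate"]),
      fm_rate_dist  = c(m["fm_rate"], s["fm_rate"]),
      contour_shape = .auk_contours[[ct]],
      n_syllables   = .auk_n_syllables[[ct]]
    )
  })
  names(out) <- call_types()
  out
}

# truncated-normal draw by redraw (not clipping), with a physical floor
rtrunc1 <- function(mean, sd, lower = 0, max_redraws = 100L) {
  if (sd == 0) {
    if (mean <= lower) stop("degenerate draw at or below physical floor")
    return(mean)
  }
  for (i in seq_len(max_redraws)) {
    x <- stats::rnorm(1, mean, sd)
    if (x > lower) return(x)
  }
  stop("no positive draw after ", max_redraws, " redraws")
}

# f0 contour (Hz per sample) and voiced mask over n samples of duration T.
# Shapes are parameterised so the voiced time-average equals `m` and the
# voiced excursion equals `r`.
.contour <- function(shape, n, fs, m, r, fm, n_syl) {
  t <- (seq_len(n) - 0.5) / fs
  T <- n / fs
  voiced <- rep(TRUE, n)
  f0 <- switch(shape,
    flat  = rep(m, n),
    rise  = m - r / 2 + r * t / T,
    fall  = m + r / 2 - r * t / T,
    arch  = (m - 2 * r / pi) + r * sin(pi * t / T),
    trill = m + (r / 2) * sin(2 * pi * (fm / 2) * t),
    syllable_series = {
      gap_frac <- if (n_syl > 1) 0.25 else 0
      syl_len <- floor(n * (1 - gap_frac) / n_syl)
      gap_len <- if (n_syl > 1) floor(n * gap_frac / (n_syl - 1)) else 0L
      f <- rep(m, n); voiced <- rep(FALSE, n)
      pos <- 1L
      for (k in seq_len(n_syl)) {
        idx <- pos:(pos + syl_len - 1L)
        idx <- idx[idx <= n]
        ts <- (seq_along(idx) - 0.5) / fs
        Ts <- length(idx) / fs
        f[idx] <- (m - 2 * r / pi) + r * sin(pi * ts / Ts)
        voiced[idx] <- TRUE
        pos <- pos + syl_len + gap_len
      }
      f0 <- f
      f
    })
  list(f0 = f0, voiced = voiced, t = t)
}

# ground-truth f0 statistics from the sampled contour
.contour_truth <- function(con, fs) {
  f0 <- con$f0[con$voiced]
  t  <- con$t[con$voiced]
  tv <- length(f0) / fs                       # voiced duration
  # derivatives only within contiguous voiced runs
  run <- cumsum(c(TRUE, diff(which(con$voiced)) > 1))
  d <- unlist(lapply(split(f0, run), diff), use.names = FALSE)
  slope <- if (length(d)) mean(abs(d)) * fs else 0
  fvar  <- if (length(d)) sum(abs(d)) / tv else 0
  sgn <- sign(d[abs(d) > 1e-9 / fs])
  sgn <- sgn[sgn != 0]
  n_inflect <- if (length(sgn) > 1) sum(diff(sgn) != 0) else 0
  list(f0_min = min(f0), f0_max = max(f0), f0_mean = mean(f0),
       f0_start = f0[1], f0_end = f0[length(f0)],
       f0_range = max(f0) - min(f0),
       f0_abs_slope = slope, f0_var = fvar,
       fm_rate = n_inflect / tv)
}

#' Synthesise one call
#'
#' Draws realised parameters from the spec distributions (redrawing negative
#' values, with a 10 ms duration floor), builds a harmonic stack with 1/k
#' amplitude roll-off following the contour, applies sinusoidal amplitude
#' modulation and additive Gaussian noise at the spec SNR.
#'
#' @param spec A [synthesis_spec()].
#' @param seed Integer seed; identical `(spec, seed)` give identical output.
#' @param fs Sample rate, Hz.
#' @return An object of class `auk_call`: `waveform`, `sample_rate`, `truth`
#'   (named list of realised generator values; spectral quartiles are `NA`
#'   since the generator does not fix them), `call_type`.
#' @export
synthesize_call <- function(spec, seed, fs = 48000) {
  stopifnot(inherits(spec, "auk_spec"))
  with_seed(seed, {
    dur <- rtrunc1(spec$duration_dist[1], spec$duration_dist[2], lower = 0.01)
    m   <- rtrunc1(spec$f0_mean_dist[1], spec$f0_mean_dist[2], lower = 1)
    r   <- if (spec$contour_shape == "flat") 0 else
             abs_or_zero(spec$f0_range_dist)
    am  <- abs_or_zero(spec$am_rate_dist)
    fm  <- abs_or_zero(spec$fm_rate_dist)
    n_syl <- if (spec$n_syllables[1] == spec$n_syllables[2]) spec$n_syllables[1]
             else sample(spec$n_syllables[1]:spec$n_syllables[2], 1)
    n <- max(round(dur * fs), 16L)
    con <- .contour(spec$contour_shape, n, fs, m, r, fm, n_syl)
    # keep every partial below Nyquist
    H <- max(1L, min(spec$n_harmonics, floor((fs / 2 - 1) / max(con$f0))))
    phase <- 2 * pi * cumsum(con$f0) / fs
    x <- numeric(n)
    for (k in seq_len(H)) x <- x + sin(k * phase) / k
    # sinusoidal AM with random phase
    am_phi <- stats::runif(1, 0, 2 * pi)
    env <- 1 + spec$am_depth * sin(2 * pi * am * con$t + am_phi)
    x <- x * env
    # voiced mask with 2.5 ms cosine ramps per voiced run
    mask <- .ramped_mask(con$voiced, fs, ramp = 0.0025)
    x <- x * mask
    if (is.finite(spec$noise_snr)) {
      rms <- sqrt(mean(x^2))
      x <- x + stats::rnorm(n, 0, rms * 10^(-spec$noise_snr / 20))
    }
    x <- 0.9 * x / max(abs(x))
    tr <- .contour_truth(con, fs)
    truth <- c(tr[c("f0_min", "f0_max", "f0_mean", "f0_start", "f0_end",
                    "f0_range", "f0_abs_slope", "f0_var")],
               list(q25 = NA_real_, q50 = NA_real_, q75 = NA_real_,
                    spectral_cog = NA_real_,
                    duration = n / fs, am_rate = am, fm_rate = tr$fm_rate))
    structure(list(waveform = x, sample_rate = fs, truth = truth,
                   call_type = spec$call_type),
              class = "auk_call")
  })
}

abs_or_zero <- function(dist) {
  if (dist[2] == 0) return(max(dist[1], 0))
  x <- stats::rnorm(1, dist[1], dist[2])
  for (i in seq_len(100L)) {
    if (x >= 0) return(x)
    x <- stats::rnorm(1, dist[1], dist[2])
  }
  0
}

.ramped_mask <- function(voiced, fs, ramp = 0.0025) {
  n <- length(voiced)
  mask <- as.numeric(voiced)
  nr <- max(2L, round(ramp * fs))
  runs <- rle(voiced)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  up <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
  for (i in which(runs$values)) {
    a <- starts[i]; b <- ends[i]
    len <- b - a + 1L
    k <- min(nr, floor(len / 2))
    if (k > 0) {
      mask[a:(a + k - 1L)] <- up[seq_len(k)]
      mask[(b - k + 1L):b] <- rev(up[seq_len(k)])
    }
  }
  mask
}

#' Synthesise a balanced corpus of calls
#'
#' Per-call seeds are derived deterministically from the master seed, so the
#' whole corpus is reproducible and calls can be regenerated independently.
#'
#' @param specs Named list of [synthesis_spec()] (default [default_specs()]).
#' @param n_per_type Calls per type (the reference design uses 30).
#' @param seed Master integer seed.
#' @param fs Sample rate, Hz.
#' @return `auk_corpus`: list with `calls` (list of `auk_call`) and
#'   `manifest` (data frame: call_id, call_type, seed + realised truth values).
#' @export
synthesize_corpus <- function(specs = default_specs(), n_per_type = 30,
                              seed = 1, fs = 48000) {
  stopifnot(n_per_type >= 1)
  n_total <- n_per_type * length(specs)
  seeds <- derive_seeds(seed, n_total)
  calls <- vector("list", n_total)
  rows <- vector("list", n_total)
  i <- 0L
  for (ct in names(specs)) {
    for (j in seq_len(n_per_type)) {
      i <- i + 1L
      calls[[i]] <- synthesize_call(specs[[ct]], seeds[i], fs = fs)
      rows[[i]] <- data.frame(call_id = sprintf("%s_%03d", ct, j),
                              call_type = ct, seed = seeds[i],
                              as.data.frame(calls[[i]]$truth))
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(calls = calls, manifest = manifest, sample_rate = fs,
                 seed = seed),
            class = "auk_corpus")
}

#' Draw a feature table directly from the spec distributions
#'
#' Fast path for the statistical stages: each measured parameter is drawn
#' independently from its per-type Gaussian (no waveform synthesis), with
#' redraw truncation at zero for physically non-negative quantities and a
#' 10 ms duration floor. Derived columns (`f0_range`, `f0_start`, `f0_end`,
#' `f0_abs_slope`, `f0_var`, `spectral_cog`) follow the contour-shape
#' closed forms; `f0_range = f0_max - f0_min` is left possibly negative since
#' the marginals are drawn independently.
#'
#' @inheritParams synthesize_corpus
#' @return Data frame: `call_id`, `call_type`, then [feature_names()].
#' @export
sample_feature_table <- function(specs = default_specs(), n_per_type = 30,
                                 seed = 1) {
  stopifnot(n_per_type >= 1)
  with_seed(seed, {
    rows <- lapply(names(specs), function(ct) {
      sp <- specs[[ct]]
      n <- n_per_type
      draw <- function(dist, lower = 0) {
        if (is.null(dist)) return(rep(NA_real_, n))
        vapply(seq_len(n), function(i) rtrunc1(dist[1], dist[2], lower),
               numeric(1))
      }
      f0_min  <- draw(sp$f0_min_dist)
      f0_max  <- draw(sp$f0_max_dist)
      f0_mean <- draw(sp$f0_mean_dist)
      q25 <- draw(sp$q25_dist); q50 <- draw(sp$q50_dist); q75 <- draw(sp$q75_dist)
      duration <- draw(sp$duration_dist, lower = 0.01)
      am_rate <- draw(sp$am_rate_dist)
      fm_rate <- draw(sp$fm_rate_dist)
      f0_range <- f0_max - f0_min
      rabs <- pmax(f0_range, 0)
      n_syl <- if (sp$n_syllables[1] == sp$n_syllables[2])
        rep(sp$n_syllables[1], n)
      else sample(sp$n_syllables[1]:sp$n_syllables[2], n, replace = TRUE)
      shp <- sp$contour_shape
      f0_start <- switch(shp, rise = f0_min, fall = f0_max,
                         flat = f0_mean, trill = f0_mean, f0_min)
      f0_end <- switch(shp, rise = f0_max, fall = f0_min,
                       flat = f0_mean, trill = f0_mean, f0_min)
      slope <- switch(shp,
                      flat = rep(0, n),
                      rise = rabs / duration,
                      fall = rabs / duration,
                      arch = 2 * rabs / duration,
                      trill = rabs * fm_rate,
                      syllable_series = 2 * rabs * n_syl /
                        (duration * ifelse(n_syl > 1, 0.75, 1)))
      data.frame(call_id = sprintf("%s_%03d", ct, seq_len(n)),
                 call_type = ct,
                 f0_min = f0_min, f0_max = f0_max, f0_mean = f0_mean,
                 f0_start = f0_start, f0_end = f0_end, f0_range = f0_range,
                 f0_abs_slope = slope, f0_var = slope,
                 q25 = q25, q50 = q50, q75 = q75,
                 spectral_cog = (q25 + q50 + q75) / 3,
                 duration = duration, am_rate = am_rate, fm_rate = fm_rate)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write a corpus to WAV files plus a CSV manifest
#'
#' @param corpus An [synthesize_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest with a `wav_path` column.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "auk_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(corpus$manifest$call_id, ".wav"))
  for (i in seq_along(corpus$calls)) {
    write_wav(corpus$calls[[i]]$waveform, corpus$sample_rate, paths[i])
  }
  manifest <- cbind(corpus$manifest, wav_path = paths)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
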