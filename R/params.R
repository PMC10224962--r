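# Published per-call-type acoustic statistics (mean, SD) for the eight adult
# little auk call types, mating + incubation repertoire. Units: Hz for
# frequencies, s for duration, s^-1 for modulation rates.

#' The eight little auk call-type labels
#'
#' Closed label set used throughout the package, in canonical order.
#'
#' @return Character vector of length 8.
#' @export
call_types <- function() {
  c("single", "clucking", "classic", "terror",
    "handling", "low_trill", "short", "short_trill")
}

# parameter x call-type matrices of means and SDs
.auk_param_names <- c("f0_min", "f0_max", "f0_mean", "q25", "q50", "q75",
                      "duration", "am_rate", "fm_rate")

.auk_table_means <- matrix(c(
  # single, clucking, classic, terror, handling, low_trill, short, short_trill
  657.15,  646.67,  632.45,  657.98,  685.62,  621.99,  657.49,  601.90,  # f0_min
  808.76,  809.65, 1209.48,  766.58,  749.48,  915.47,  815.05,  934.72,  # f0_max
  759.09,  751.51,  912.61,  721.23,  717.65,  808.71,  735.81,  808.49,  # f0_mean
  676.43, 1334.59, 1504.70,   74.84,  377.78,  802.11,  708.10,  769.52,  # q25
 1375.92, 2073.89, 2634.73,  794.57,  770.45, 1927.92, 1390.37, 1589.59,  # q50
 3939.74, 2718.37, 5278.29, 1535.94, 1457.16, 6989.95, 5473.14, 4417.26,  # q75
    0.11,    0.09,    2.74,    0.33,    0.11,    1.08,    0.23,    0.75,  # duration
   28.64,   26.28,   39.11,   42.21,   24.62,   47.98,   37.08,   45.40,  # am_rate
    4.78,    5.53,    5.65,    8.76,    5.13,    4.37,    2.77,    4.05), # fm_rate
  nrow = 9, byrow = TRUE,
  dimnames = list(.auk_param_names, call_types()))

.auk_table_sds <- matrix(c(
   97.87,   58.99,   60.50,   73.97,  108.49,   84.97,   72.74,   63.01,
  177.02,   95.53,  154.24,   72.57,  135.66,  133.68,   78.40,  104.98,
  150.86,   80.18,   63.60,   65.30,  118.14,  108.99,   65.08,   77.38,
  477.10,  498.92,  588.35,  271.09,  297.60,  344.17,  154.63,  286.84,
  846.78,  410.24, 1499.41, 2503.71,  385.00, 1508.20,  938.34, 1303.54,
 4299.23,  442.53, 4903.84, 4346.71,  451.01, 5834.44, 4549.35, 4727.89,
    0.05,    0.02,    0.44,    0.13,    0.10,    0.84,    0.15,    0.38,
   10.71,   12.44,    8.08,    9.40,   11.09,    4.90,   12.17,    4.87,
    3.67,    1.00,    0.76,    2.56,    4.18,    2.05,    2.51,    1.72),
  nrow = 9, byrow = TRUE,
  dimnames = list(.auk_param_names, call_types()))

# contour family per type, chosen from the qualitative call descriptions:
# short single-unit calls are arched pulses, the trilled types carry sinusoidal
# vibrato, the classic call is a fixed 3-syllable series and terror a series
# of 2-6 identical syllables.
.auk_contours <- c(single = "arch", clucking = "arch", classic = "syllable_series",
                   terror = "syllable_series", handling = "arch",
                   low_trill = "trill", short = "arch", short_trill = "trill")

.auk_n_syllables <- list(single = c(1L, 1L), clucking = c(1L, 1L),
                         classic = c(3L, 3L), terror = c(2L, 6L),
                         handling = c(1L, 1L), low_trill = c(1L, 1L),
                         short = c(1L, 1L), short_trill = c(1L, 1L))

#' Canonical acoustic feature names
#'
#' Column order of the per-call acoustic feature vector: fundamental-frequency
#' statistics, spectral energy quartiles and centre of gravity, duration, and
#' amplitude/frequency modulation rates.
#'
#' @return Character vector of length 15.
#' @export
feature_names <- function() {
  c("f0_min", "f0_max", "f0_mean", "f0_start", "f0_end", "f0_range",
    "f0_abs_slope", "f0_var", "q25", "q50", "q75", "spectral_cog",
    "duration", "am_rate", "fm_rate")
}

# run code under a fixed RNG seed without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic child seeds from a master seed, all < 2^31
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}
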