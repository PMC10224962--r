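# Shared fixtures, all built in code.

fs_default <- 48000

# plain sine tone
make_tone <- function(freq, dur = 0.5, fs = fs_default, amp = 0.8) {
  amp * sin(2 * pi * freq * (seq_len(round(dur * fs)) - 0.5) / fs)
}

# degenerate zero-variance synthesis spec
flat_spec <- function(f0 = 750, dur = 0.5, snr = Inf, n_harmonics = 10) {
  synthesis_spec("single", f0_mean_dist = c(f0, 0), f0_range_dist = c(0, 0),
                 duration_dist = c(dur, 0), am_rate_dist = c(0, 0),
                 fm_rate_dist = c(0, 0), contour_shape = "flat",
                 noise_snr = snr, n_harmonics = n_harmonics)
}

# feature table with k perfectly separated spherical clusters
separated_table <- function(k = 2, n_per = 10, p = 4, gap = 50, seed = 11) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(k), function(g)
    matrix(rnorm(n_per * p), n_per, p) + gap * g))
  colnames(X) <- paste0("f", seq_len(p))
  data.frame(call_id = sprintf("c%03d", seq_len(k * n_per)),
             call_type = rep(call_types()[seq_len(k)], each = n_per), X)
}

# one Gaussian cloud with arbitrary balanced labels (null structure)
null_table <- function(k = 8, n_per = 20, p = 5, seed = 12) {
  set.seed(seed)
  X <- matrix(rnorm(k * n_per * p), k * n_per, p)
  colnames(X) <- paste0("f", seq_len(p))
  data.frame(call_id = sprintf("c%03d", seq_len(k * n_per)),
             call_type = rep(call_types()[seq_len(k)], each = n_per), X)
}

# candidate metadata pool for the selection filter: n_cand high-quality calls
# per type, distinct individuals except handling (21 recorded individuals,
# two calls each)
candidate_pool <- function(n_cand = 40, seed = 7) {
  set.seed(seed)
  rows <- lapply(call_types(), function(ct) {
    if (ct == "handling") {
      ind <- rep(sprintf("hand_ind%02d", 1:21), each = 2)
      ids <- sprintf("%s_%03d", ct, seq_along(ind))
      data.frame(call_id = ids, call_type = ct, quality = "high",
                 snr = round(runif(length(ind), 5, 30), 3), individual = ind)
    } else {
      data.frame(call_id = sprintf("%s_%03d", ct, seq_len(n_cand)),
                 call_type = ct, quality = "high",
                 snr = round(runif(n_cand, 5, 30), 3),
                 individual = sprintf("%s_ind%02d", ct, seq_len(n_cand)))
    }
  })
  do.call(rbind, rows)
}
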