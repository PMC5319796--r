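# Shared fixture builders. Everything is generated in code; seeds are fixed
# so the suite is deterministic.

cfg41 <- function(seed, ...) sim_config(seed, frame_interval = 0.041, ...)

# a hand-built track_set from a frame/x/y table
make_track <- function(frame, x, y, id = 1L, dt = 0.041) {
  track_set(data.frame(track_id = id, frame = as.integer(frame),
                       x = x, y = y),
            frame_interval = dt)
}

# independent DP oracle: exact P(at least one run of >= m successes in k
# independent Bernoulli(p) trials), by tracking the trailing run length
bernoulli_run_prob_dp <- function(k, p, m = 3L) {
  if (k < m) return(0)
  s <- c(1, rep(0, m - 1L))
  for (i in seq_len(k)) s <- c((1 - p) * sum(s), p * s[seq_len(m - 1L)])
  1 - sum(s)
}

# brute-force oracle over all 2^n Bernoulli strings
bernoulli_run_prob_enum <- function(n, p, m = 3L) {
  total <- 0
  for (bits in 0:(2^n - 1)) {
    s <- as.integer(intToBits(bits))[seq_len(n)]
    r <- rle(s)
    if (any(r$values == 1L & r$lengths >= m))
      total <- total + p^sum(s) * (1 - p)^(n - sum(s))
  }
  total
}

# residence summary straight from a vector of durations (seconds), for
# tests that exercise the CDF/KS machinery independently of detection
summary_from_durations <- function(durations) {
  durs <- sort(durations)
  structure(list(intervals = data.frame(duration = durs),
                 mean_residence = mean(durs) * 1000,
                 n_intervals = length(durs),
                 cdf = data.frame(time = durs,
                                  cumulative_probability =
                                    seq_along(durs) / length(durs)),
                 units = "ms"),
            class = "residence_summary")
}
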