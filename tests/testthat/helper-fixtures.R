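# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately avoid the package's own code paths.

# Homogeneous Poisson train via exponential inter-spike intervals
# (independent of the package's uniform-order-statistics generator).
poisson_train <- function(rate, t0, t1, id = "cell", animal = "a1",
                          type = "unknown") {
  isi <- stats::rexp(ceiling(rate * (t1 - t0) * 1.5) + 50, rate)
  t <- t0 + cumsum(isi)
  spike_train(id, animal, type, t[t < t1])
}

# All-pairs brute-force CCG oracle: chunked outer difference, direct
# per-bin comparisons on lag = t_post - t_pre.
brute_ccg_counts <- function(a, b, centers = -50:50, chunk = 500L) {
  raw <- integer(length(centers))
  lo <- (centers - 0.5) / 1000; hi <- (centers + 0.5) / 1000
  for (i0 in seq(1L, length(a), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, length(a))
    d <- as.vector(outer(b, a[idx], "-"))
    d <- d[d >= min(lo) & d < max(hi)]
    for (k in seq_along(centers))
      raw[k] <- raw[k] + sum(d >= lo[k] & d < hi[k])
  }
  raw
}

# Brute-force pairing-event oracle over all pairs.
brute_pairing <- function(pyr, int_, w_s) {
  d <- as.vector(outer(int_, pyr, "-"))  # t_int - t_pyr
  list(plus = sum(d > 0 & d <= w_s), minus = sum(-d > 0 & -d <= w_s))
}

# Partial-correlation oracle via the precision matrix of (x, y, Z).
brute_partial_cor <- function(x, y, Z) {
  P <- solve(stats::cor(cbind(x, y, Z)))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# A bare CCG object with prescribed raw counts (for filter/chance tests).
make_ccg <- function(raw, n_ref, centers = -50:50) {
  structure(list(lag_ms = centers, raw = raw, n_ref = n_ref,
                 prob = raw / n_ref, pre_id = "pre", post_id = "post"),
            class = "ccg")
}

# One-session simulation of a single pyramidal/interneuron pair with an
# optional planted connection; returns trains plus the session interval.
sim_pair <- function(p_trans = 0, pyr_hz = 1, int_hz = 15, len_s = 1500,
                     seed = 1) {
  conns <- if (p_trans > 0)
    data.frame(animal = 1, pre = 1, post = 1, p_FAM1 = p_trans,
               p_NOV = 0, p_FAML = 0, p_FAM2 = 0, p_REST = 0)
  cfg <- sim_config(n_animals = 1, n_pyr = 1, n_int = 1,
                    pyr_rate_meanlog = log(pyr_hz), pyr_rate_sdlog = 0,
                    int_rate_meanlog = log(int_hz), int_rate_sdlog = 0,
                    connections = conns,
                    session_lengths_s = c(FAM1 = len_s),
                    animal_rate_sd = 0, seed = seed)
  sm <- simulate_dataset(cfg)
  list(pre = sm$trains$a01_pyr01, post = sm$trains$a01_int01,
       interval = session_interval(sm$sessions, "FAM1"))
}
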