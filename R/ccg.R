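#' Spike-time cross-correlogram on a fixed +/-50 ms, 1 ms lattice
#'
#' For every pair of spikes (one from the presynaptic/reference train, one
#' from the postsynaptic train) with both spikes inside `interval`, the lag
#' `t_post - t_pre` is histogrammed into 101 bins of 1 ms width centred on
#' the integer lags -50..+50 ms (bin edges at half-integer milliseconds, each
#' bin half-open `[centre - 0.5, centre + 0.5)` ms). Because reference spike
#' counts differ across cells and sessions, the histogram is normalised by
#' the number of reference spikes: `prob = raw / n_ref`, the probability of a
#' postsynaptic spike at each lag per presynaptic spike.
#'
#' With this lattice the monosynaptic 0.5-2.5 ms latency window is exactly
#' the two bins centred at +1 and +2 ms.
#'
#' When `pre` and `post` are the same cell (equal `cell_id`), each spike's
#' pairing with itself is excluded; two distinct cells that happen to share
#' spike times are counted in full.
#'
#' @param pre Reference (presynaptic, typically pyramidal) [spike_train()].
#' @param post Postsynaptic (typically interneuron) [spike_train()].
#' @param interval Analysis window: `c(start_s, end_s)` or a
#'   data.frame(start_s, end_s) of disjoint intervals whose pair counts are
#'   accumulated (spike pairs straddling two intervals are not counted).
#' @param half_ms Half-width of the lag axis in ms (default 50).
#' @param bin_ms Bin width in ms (default 1).
#'
#' @return An object of class `ccg`: list with `lag_ms` (bin centres),
#'   `raw` (pair counts), `n_ref`, `prob = raw/n_ref`, and the pair ids.
#'   Returns `NULL` (missing CCG) when the reference train has no spikes in
#'   the interval.
#' @export
compute_ccg <- function(pre, post, interval, half_ms = 50, bin_ms = 1) {
  iv <- as_intervals(interval)
  edges_ms <- seq(-half_ms - bin_ms / 2, half_ms + bin_ms / 2, by = bin_ms)
  centers <- seq(-half_ms, half_ms, by = bin_ms)
  n_bins <- length(centers)
  raw <- integer(n_bins)
  n_ref <- 0L
  same_cell <- identical(pre$cell_id, post$cell_id)
  for (i in seq_len(nrow(iv))) {
    a <- restrict_spikes(pre$spikes, iv[i, ])
    b <- restrict_spikes(post$spikes, iv[i, ])
    n_ref <- n_ref + length(a)
    if (!length(a) || !length(b)) next
    raw <- raw + ccg_counts(a, b, edges_ms / 1000, same_cell)
  }
  if (n_ref == 0L) return(NULL)
  structure(list(lag_ms = centers, raw = raw, n_ref = n_ref,
                 prob = raw / n_ref,
                 pre_id = pre$cell_id, post_id = post$cell_id),
            class = "ccg")
}

# Pair counts for sorted spike vectors a (reference) and b, with bin edges in
# seconds. Candidate b-spikes near each a-spike are located by bisection with
# a one-bin slack, then each lag t_b - t_a is assigned to its half-open bin
# [edge_k, edge_{k+1}) so edge placement never depends on how the candidate
# window was computed.
ccg_counts <- function(a, b, edges_s, same_cell = FALSE) {
  n_bins <- length(edges_s) - 1L
  slack <- edges_s[2] - edges_s[1]
  lo <- findInterval(a + edges_s[1] - slack, b)            # b[idx] <= bound
  hi <- findInterval(a + edges_s[n_bins + 1L] + slack, b)
  n_cand <- hi - lo
  if (sum(n_cand) == 0) return(integer(n_bins))
  pre_idx <- rep.int(seq_along(a), n_cand)
  post_idx <- sequence(n_cand, from = lo + 1L)
  if (same_cell) {
    keep <- pre_idx != post_idx
    pre_idx <- pre_idx[keep]; post_idx <- post_idx[keep]
  }
  lag <- b[post_idx] - a[pre_idx]
  k <- findInterval(lag, edges_s)                          # 0 or n_bins+1 = outside
  tabulate(k[k >= 1L & k <= n_bins], nbins = n_bins)
}

#' @exportS3Method base::print
print.ccg <- function(x, ...) {
  cat(sprintf("<ccg> %s -> %s: n_ref = %d, %d pair counts in [%d, %d] ms\n",
              x$pre_id, x$post_id, x$n_ref, sum(x$raw),
              min(x$lag_ms), max(x$lag_ms)))
  invisible(x)
}

#' Export a cross-correlogram as a data.frame
#'
#' @param x A [compute_ccg()] result.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return data.frame(lag_ms, raw, prob).
#' @export
as.data.frame.ccg <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(lag_ms = x$lag_ms, raw = x$raw, prob = x$prob)
}

flank_bins <- function(ccg, flank_ms = c(10, 50)) {
  abs(ccg$lag_ms) >= flank_ms[1] & abs(ccg$lag_ms) <= flank_ms[2]
}

peak_bins <- function(ccg, peak_ms = c(1, 2)) {
  ccg$lag_ms %in% peak_ms
}

#' Chance level of joint firing
#'
#' The chance probability that the pair fires together is estimated by
#' averaging the correlogram probabilities over the 10-50 ms bins on both
#' sides of the histogram (82 flank bins on the default lattice). For two
#' independently firing cells this equals the postsynaptic rate times the
#' bin width, whatever the two firing rates are, which is what makes the
#' chance-subtracted transmission statistic rate-compensated.
#'
#' @param ccg A [compute_ccg()] result.
#' @param flank_ms Absolute-lag range of the flanks in ms. Default `c(10, 50)`.
#' @return Mean per-bin probability over the flank bins.
#' @export
chance_level <- function(ccg, flank_ms = c(10, 50)) {
  if (is.null(ccg)) return(NA_real_)
  mean(ccg$prob[flank_bins(ccg, flank_ms)])
}

#' Detect a monosynaptic peak in a cross-correlogram
#'
#' A putative monosynaptic pyramidal-to-interneuron connection shows as a
#' large, sharp peak in the 0.5-2.5 ms bins after the reference pyramidal
#' spike (the bins centred at +1 and +2 ms). The peak statistic is
#' `(max raw count over the two peak bins - flank mean) / flank SD`,
#' computed on raw counts over the 82 flank bins (|lag| 10-50 ms); the peak
#' is significant when it reaches `z_threshold` (3 standard deviations from
#' baseline by default).
#'
#' @param ccg A [compute_ccg()] result (or `NULL` for a missing CCG).
#' @param z_threshold Significance threshold in flank SD units. Default 3.
#' @param peak_ms Peak bin centres in ms. Default `c(1, 2)`.
#' @param flank_ms Flank range in ms. Default `c(10, 50)`.
#' @return List with `significant` (logical), `peak_z`, and `defined`
#'   (FALSE when the CCG is missing or the flank SD is zero, in which case
#'   `significant` is FALSE and `peak_z` is NA).
#' @export
detect_monosynaptic <- function(ccg, z_threshold = 3, peak_ms = c(1, 2),
                                flank_ms = c(10, 50)) {
  if (is.null(ccg))
    return(list(significant = FALSE, peak_z = NA_real_, defined = FALSE))
  fl <- ccg$raw[flank_bins(ccg, flank_ms)]
  s <- stats::sd(fl)
  if (!is.finite(s) || s == 0)
    return(list(significant = FALSE, peak_z = NA_real_, defined = FALSE))
  z <- (max(ccg$raw[peak_bins(ccg, peak_ms)]) - mean(fl)) / s
  list(significant = z >= z_threshold, peak_z = z, defined = TRUE)
}

#' Spike-transmission probability
#'
#' The connection strength of a detected pair: the probability, in excess of
#' chance, that the presynaptic spike discharges the postsynaptic cell
#' within the monosynaptic 0.5-2.5 ms window. Computed as the sum over the
#' two peak bins of `(prob - chance)`, i.e. extra postsynaptic spikes per
#' presynaptic spike. Subtracting the flank-estimated chance level
#' compensates for firing-rate changes, so session-to-session differences
#' reflect the connection rather than joint rate drift. Values can be
#' slightly negative for unconnected pairs (sampling noise around zero);
#' they are deliberately not clamped.
#'
#' @inheritParams detect_monosynaptic
#' @return Numeric transmission probability, or NA for a missing CCG.
#' @export
transmission_probability <- function(ccg, peak_ms = c(1, 2), flank_ms = c(10, 50)) {
  if (is.null(ccg)) return(NA_real_)
  ch <- chance_level(ccg, flank_ms)
  sum(ccg$prob[peak_bins(ccg, peak_ms)] - ch)
}

#' Quality filters for sparse or irregular correlograms
#'
#' A candidate pair is retained only if at least one of the two baseline
#' familiar-environment sessions (FAM1 or FAM2) yields (a) at least
#' `min_counts` spike coincidence counts within the -50 to +50 ms interval
#' and (b) bin values regular enough that their SD is below
#' `dispersion_threshold` times their mean. The dispersion test is evaluated
#' on the flank bins by default so a genuine monosynaptic peak cannot fail
#' its own quality filter; set `dispersion_on = "all"` to evaluate it on all
#' 101 bins.
#'
#' @param ccg_fam1,ccg_fam2 Session CCGs from [compute_ccg()]; `NULL` for a
#'   missing CCG counts as failing the count test for that session.
#' @param min_counts Minimum total coincidence count. Default 1000.
#' @param dispersion_threshold Maximum SD/mean of bin values. Default 1/3.
#' @param dispersion_on `"flanks"` (default) or `"all"`.
#' @param flank_ms Flank range in ms. Default `c(10, 50)`.
#' @return List with `passes` (logical) and `reasons` (character vector,
#'   empty when passing; otherwise `"min_counts"` and/or `"dispersion"`).
#' @export
apply_quality_filters <- function(ccg_fam1, ccg_fam2, min_counts = 1000,
                                  dispersion_threshold = 1 / 3,
                                  dispersion_on = c("flanks", "all"),
                                  flank_ms = c(10, 50)) {
  dispersion_on <- match.arg(dispersion_on)
  ok_one <- function(ccg) {
    if (is.null(ccg)) return(c(counts = FALSE, disp = FALSE))
    counts_ok <- sum(ccg$raw) >= min_counts
    v <- if (dispersion_on == "flanks") ccg$raw[flank_bins(ccg, flank_ms)] else ccg$raw
    m <- mean(v)
    disp_ok <- m > 0 && stats::sd(v) / m < dispersion_threshold
    c(counts = counts_ok, disp = disp_ok)
  }
  q1 <- ok_one(ccg_fam1); q2 <- ok_one(ccg_fam2)
  passes <- (q1["counts"] && q1["disp"]) || (q2["counts"] && q2["disp"])
  reasons <- character()
  if (!passes) {
    if (!q1["counts"] && !q2["counts"]) reasons <- c(reasons, "min_counts")
    else reasons <- c(reasons, "dispersion")
  }
  list(passes = unname(passes), reasons = reasons)
}

#' Light-response PSTH and response class
#'
#' Peri-stimulus time histogram of one cell around light-pulse onsets:
#' spike probability per `bin_ms` bin (spike count across pulses divided by
#' the number of pulses), over `window_s` around pulse onset. The cell is
#' classified by comparing its mean in-pulse bin probability with the
#' pre-pulse baseline: suppressed if below `(1 - theta)` times baseline,
#' activated (e.g. disinhibited) if above `(1 + theta)` times baseline, else
#' unmodulated.
#'
#' @param train A [spike_train()].
#' @param pulses data.frame(start_s, end_s) of light pulses (>= 1 row).
#' @param bin_ms PSTH bin width in ms. Default 20.
#' @param window_s Window around pulse onset in seconds. Default
#'   `c(-0.1, 0.6)` for 500 ms pulses.
#' @param theta Relative modulation threshold. Default 0.5.
#' @return List with `bin_start_s` (left bin edges relative to onset),
#'   `prob`, `class`, and the baseline/in-pulse means.
#' @export
light_response_psth <- function(train, pulses, bin_ms = 20,
                                window_s = c(-0.1, 0.6), theta = 0.5) {
  pulses <- as_intervals(pulses)
  if (!nrow(pulses)) stop("light_response_psth requires at least one pulse")
  bw <- bin_ms / 1000
  edges <- seq(window_s[1], window_s[2], by = bw)
  n_bins <- length(edges) - 1L
  counts <- integer(n_bins)
  for (i in seq_len(nrow(pulses))) {
    rel <- train$spikes - pulses$start_s[i]
    rel <- rel[rel >= edges[1] & rel < edges[n_bins + 1L]]
    k <- findInterval(rel, edges)
    counts <- counts + tabulate(k[k >= 1L & k <= n_bins], nbins = n_bins)
  }
  prob <- counts / nrow(pulses)
  width <- stats::median(pulses$end_s - pulses$start_s)
  ctr <- edges[-length(edges)] + bw / 2
  pre <- prob[ctr < 0]
  inp <- prob[ctr > 0 & ctr < width]
  base_m <- mean(pre); in_m <- mean(inp)
  cls <- if (base_m == 0) {
    if (in_m > 0) "activated" else "unmodulated"
  } else if (in_m < (1 - theta) * base_m) "suppressed"
  else if (in_m > (1 + theta) * base_m) "activated"
  else "unmodulated"
  list(bin_start_s = edges[-length(edges)], prob = prob, class = cls,
       baseline_prob = base_m, in_pulse_prob = in_m)
}
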