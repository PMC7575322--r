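#' Mean firing rate within an interval
#'
#' @param train A [spike_train()].
#' @param interval `c(start_s, end_s)` or data.frame(start_s, end_s); with
#'   several intervals the rate is pooled (total spikes / total time).
#' @return Rate in Hz.
#' @export
session_rate <- function(train, interval) {
  iv <- as_intervals(interval)
  total <- sum(iv$end_s - iv$start_s)
  stopifnot(total > 0)
  length(restrict_spikes(train$spikes, iv)) / total
}

#' Relative change score
#'
#' The bounded, rate-normalised change between two sessions:
#' `c = (b - a) / (b + a)`, always in `[-1, 1]`. The extremes -1 and +1 mean
#' the quantity is non-zero in only one of the two sessions; 0 means no
#' change. The same score is applied to firing rates, spike-transmission
#' probabilities and pairing-event counts. Undefined (NA) when `a + b = 0`.
#'
#' @param a,b Non-negative values in the first and second session
#'   (vectorised).
#' @return `(b - a) / (b + a)`, NA where `a + b == 0` or either input is NA.
#' @export
relative_change <- function(a, b) {
  if (any(a < 0 | b < 0, na.rm = TRUE))
    stop("relative_change expects non-negative inputs")
  out <- (b - a) / (b + a)
  out[!is.na(a + b) & (a + b) == 0] <- NA_real_
  out
}

#' Split a session into alternating odd/even blocks
#'
#' Consecutive blocks of `block_s` seconds are numbered from 1 at the start
#' of the interval; odd-numbered and even-numbered blocks form two
#' interleaved half-sessions used as a within-session stability baseline.
#' A trailing partial block is dropped.
#'
#' @param interval `c(start_s, end_s)`.
#' @param block_s Block length in seconds. Default 5.
#' @return List with `odd` and `even`, each a data.frame(start_s, end_s).
#' @export
alternating_split <- function(interval, block_s = 5) {
  iv <- as_intervals(interval)
  stopifnot(nrow(iv) == 1L, block_s > 0)
  n_blocks <- floor((iv$end_s - iv$start_s) / block_s)
  if (n_blocks < 2L) stop("interval must contain at least two blocks")
  starts <- iv$start_s + (seq_len(n_blocks) - 1L) * block_s
  blocks <- data.frame(start_s = starts, end_s = starts + block_s)
  odd <- seq_len(n_blocks) %% 2L == 1L
  list(odd = blocks[odd, , drop = FALSE], even = blocks[!odd, , drop = FALSE])
}

#' Odd/even half-session firing rates
#'
#' @param train A [spike_train()].
#' @param interval `c(start_s, end_s)` of the session.
#' @param block_s Block length in seconds. Default 5.
#' @return Named numeric `c(odd = , even = )` rates in Hz.
#' @export
split_half_rates <- function(train, interval, block_s = 5) {
  sp <- alternating_split(interval, block_s)
  c(odd = session_rate(train, sp$odd), even = session_rate(train, sp$even))
}

#' Odd/even half-session spike-transmission probabilities
#'
#' CCG pair counts and reference-spike counts are accumulated over the odd
#' (resp. even) 5 s blocks, then the chance-subtracted transmission is
#' computed on each accumulated correlogram.
#'
#' @param pre,post [spike_train()]s of the pair.
#' @param interval `c(start_s, end_s)` of the session.
#' @param block_s Block length in seconds. Default 5.
#' @param ... Passed to [transmission_probability()].
#' @return Named numeric `c(odd = , even = )` transmission probabilities
#'   (NA where the half has no reference spikes).
#' @export
split_half_transmission <- function(pre, post, interval, block_s = 5, ...) {
  sp <- alternating_split(interval, block_s)
  c(odd = transmission_probability(compute_ccg(pre, post, sp$odd), ...),
    even = transmission_probability(compute_ccg(pre, post, sp$even), ...))
}

#' Within-session split-half stability baseline
#'
#' Correlation across pairs (or cells) of a metric measured in the odd- and
#' even-numbered 5 s blocks of the same session. Because the two halves are
#' interleaved samples of the same behavioural state, this correlation is
#' the stability ceiling against which cross-session correlations are
#' compared (via [fisher_z_compare()]).
#'
#' @param odd,even Numeric vectors of the metric in the two halves, one
#'   element per pair/cell.
#' @return Pearson correlation, or NA when fewer than 3 complete pairs.
#' @export
split_half_baseline <- function(odd, even) {
  ok <- stats::complete.cases(odd, even)
  if (sum(ok) < 3L) return(NA_real_)
  stats::cor(odd[ok], even[ok])
}

#' Spike pairing-event counts within a time window
#'
#' Counts spike pairs of a pyramidal cell and an interneuron whose lag falls
#' within `window_ms`, per direction: `count_dir_plus` counts pairs where
#' the pyramidal spike precedes the interneuron spike
#' (`0 < t_int - t_pyr <= W`), `count_dir_minus` pairs where it follows
#' (`0 < t_pyr - t_int <= W`), and `count_all` their sum. Exact zero-lag
#' coincidences are directionless and counted in neither. Every pair is
#' counted, so one spike may participate in several pairing events.
#'
#' @param pyr,int_ [spike_train()]s of the pyramidal cell and interneuron.
#' @param interval Analysis interval (`c(start_s, end_s)` or
#'   data.frame of intervals).
#' @param window_ms Window length in ms (10, 20, 50 and 100 are the
#'   standard choices).
#' @return List with `window_ms`, `count_dir_plus`, `count_dir_minus`,
#'   `count_all`.
#' @export
pairing_counts <- function(pyr, int_, interval, window_ms) {
  stopifnot(window_ms > 0)
  iv <- as_intervals(interval)
  w <- window_ms / 1000
  plus <- 0L; minus <- 0L
  for (i in seq_len(nrow(iv))) {
    a <- restrict_spikes(pyr$spikes, iv[i, ])
    b <- restrict_spikes(int_$spikes, iv[i, ])
    if (!length(a) || !length(b)) next
    # count in (t, t + w]: findInterval counts elements <= bound
    plus <- plus + sum(findInterval(a + w, b) - findInterval(a, b))
    minus <- minus + sum(findInterval(b + w, a) - findInterval(b, a))
  }
  list(window_ms = window_ms, count_dir_plus = plus, count_dir_minus = minus,
       count_all = plus + minus)
}
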