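#' Simulation configuration
#'
#' Defaults emulate the recording-day structure the analysis is designed
#' for: four 25 min exploration sessions (FAM1, NOV, FAML, FAM2) followed by
#' an 18 min rest session with 500 ms test light pulses; pyramidal cells
#' firing around 0.3-3 Hz and interneurons around 5-30 Hz (log-normal rate
#' distributions); probabilistic spike transmission at 0.5-2.5 ms latency
#' for planted connections; light-driven suppression of a subset of cells
#' and disinhibition of some pyramidal cells during FAML light epochs; and a
#' multiplicative animal-level random rate offset.
#'
#' @param n_animals Number of animals. Default 4.
#' @param n_pyr,n_int Pyramidal cells / interneurons per animal. Defaults
#'   15 and 5.
#' @param pyr_rate_meanlog,pyr_rate_sdlog Log-normal parameters of pyramidal
#'   base rates (Hz). Defaults `log(1)` and 0.5 (about 0.4-2.7 Hz central
#'   range).
#' @param int_rate_meanlog,int_rate_sdlog Same for interneurons. Defaults
#'   `log(12)` and 0.4 (about 5-27 Hz).
#' @param connections data.frame with columns `animal` (1-based index),
#'   `pre` (pyramidal index within animal), `post` (interneuron index within
#'   animal), `p_FAM1`, `p_NOV`, `p_FAML`, `p_FAM2`, `p_REST` (per-session
#'   transmission probabilities in `[0, 1]`), and optionally
#'   `latency_mean_ms`, `latency_sd_ms`. May be empty (no planted
#'   connections).
#' @param session_lengths_s Named lengths of FAM1/NOV/FAML/FAM2/REST in
#'   seconds. Defaults 1500 for the explorations, 1080 for REST.
#' @param faml_light List: `fraction_suppressed_pyr`,
#'   `fraction_suppressed_int`, `fraction_disinhibited_pyr`,
#'   `suppression_factor` (in-light rate multiplier for suppressed cells),
#'   `enhancement_factor` (for disinhibited cells), `epoch_s` (length of
#'   alternating light/no-light epochs), `duty` (fraction of FAML under
#'   light; light epochs tile the session as every other `epoch_s` block
#'   scaled to the duty cycle).
#' @param rest_pulse List: `width_s` (default 0.5) and `period_s`
#'   (default 3) of the rest-session test pulses.
#' @param latency_mean_ms,latency_sd_ms Default transmission latency
#'   distribution (truncated normal on 0.5-2.5 ms). Defaults 1.4 and 0.3.
#' @param animal_rate_sd SD of the animal-level log-rate offset
#'   (multiplicative). Default 0.1.
#' @param seed Integer seed; the generator is deterministic given the full
#'   config including the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_animals = 4, n_pyr = 15, n_int = 5,
                       pyr_rate_meanlog = log(1), pyr_rate_sdlog = 0.5,
                       int_rate_meanlog = log(12), int_rate_sdlog = 0.4,
                       connections = NULL,
                       session_lengths_s = c(FAM1 = 1500, NOV = 1500,
                                             FAML = 1500, FAM2 = 1500,
                                             REST = 1080),
                       faml_light = list(fraction_suppressed_pyr = 0.25,
                                         fraction_suppressed_int = 0.6,
                                         fraction_disinhibited_pyr = 0.15,
                                         suppression_factor = 0.3,
                                         enhancement_factor = 2,
                                         epoch_s = 10, duty = 0.4),
                       rest_pulse = list(width_s = 0.5, period_s = 3),
                       latency_mean_ms = 1.4, latency_sd_ms = 0.3,
                       animal_rate_sd = 0.1, seed = 1L) {
  if (is.null(connections))
    connections <- data.frame(animal = integer(), pre = integer(),
                              post = integer(), p_FAM1 = numeric(),
                              p_NOV = numeric(), p_FAML = numeric(),
                              p_FAM2 = numeric(), p_REST = numeric())
  stopifnot(all(session_lengths_s > 0),
            faml_light$suppression_factor > 0,
            faml_light$enhancement_factor > 0,
            faml_light$duty > 0, faml_light$duty < 1)
  pcols <- paste0("p_", SESSION_LABELS)
  miss <- setdiff(pcols, names(connections))
  for (m in miss) connections[[m]] <- 0
  if (nrow(connections)) {
    p <- as.matrix(connections[, pcols])
    stopifnot(all(p >= 0 & p <= 1))
  }
  if (!"latency_mean_ms" %in% names(connections))
    connections$latency_mean_ms <- rep(latency_mean_ms, nrow(connections))
  if (!"latency_sd_ms" %in% names(connections))
    connections$latency_sd_ms <- rep(latency_sd_ms, nrow(connections))
  structure(list(n_animals = n_animals, n_pyr = n_pyr, n_int = n_int,
                 pyr_rate_meanlog = pyr_rate_meanlog,
                 pyr_rate_sdlog = pyr_rate_sdlog,
                 int_rate_meanlog = int_rate_meanlog,
                 int_rate_sdlog = int_rate_sdlog,
                 connections = connections,
                 session_lengths_s = session_lengths_s,
                 faml_light = faml_light, rest_pulse = rest_pulse,
                 animal_rate_sd = animal_rate_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Rest-session light pulses
#'
#' Pulses of `width_s` are placed every `period_s` from the start of the
#' rest interval; the last pulse that would not fit entirely is dropped.
#'
#' @param rest_interval `c(start_s, end_s)` of the rest session.
#' @param width_s Pulse width in seconds (default 0.5).
#' @param period_s Pulse period in seconds (default 3).
#' @return data.frame(start_s, end_s), one row per pulse.
#' @export
make_rest_pulses <- function(rest_interval, width_s = 0.5, period_s = 3) {
  if (width_s <= 0 || period_s <= 0) stop("width_s and period_s must be positive")
  if (width_s >= period_s) stop("width_s must be smaller than period_s")
  iv <- as_intervals(rest_interval)
  n <- floor((iv$end_s - iv$start_s) / period_s)
  if (n < 1L) return(data.frame(start_s = numeric(), end_s = numeric()))
  onsets <- iv$start_s + (seq_len(n) - 1L) * period_s
  data.frame(start_s = onsets, end_s = onsets + width_s)
}

# Alternating light epochs tiling a session: within each period of
# epoch_s / duty seconds, the first epoch_s seconds are lit. A trailing
# partial light epoch is clipped to the session end.
make_faml_epochs <- function(interval, epoch_s, duty) {
  iv <- as_intervals(interval)
  period <- epoch_s / duty
  onsets <- seq(iv$start_s, iv$end_s, by = period)
  onsets <- onsets[onsets < iv$end_s]
  data.frame(start_s = onsets, end_s = pmin(onsets + epoch_s, iv$end_s))
}

# Homogeneous Poisson spikes on [start, end) at `rate` Hz. Exact duplicate
# times (an artifact of the RNG's finite granularity at large n) are dropped.
gen_poisson <- function(rate, start_s, end_s) {
  if (rate <= 0 || end_s <= start_s) return(numeric())
  n <- stats::rpois(1L, rate * (end_s - start_s))
  unique(sort(stats::runif(n, start_s, end_s)))
}

# Piecewise Poisson: base rate outside `light`, base * factor inside.
gen_modulated_poisson <- function(rate, interval, light, factor) {
  iv <- as_intervals(interval)
  if (!nrow(light) || factor == 1)
    return(gen_poisson(rate, iv$start_s, iv$end_s))
  spikes <- numeric()
  cursor <- iv$start_s
  for (i in seq_len(nrow(light))) {
    spikes <- c(spikes, gen_poisson(rate, cursor, light$start_s[i]),
                gen_poisson(rate * factor, light$start_s[i], light$end_s[i]))
    cursor <- light$end_s[i]
  }
  sort(c(spikes, gen_poisson(rate, cursor, iv$end_s)))
}

# Truncated-normal draws on [lo, hi] via inverse CDF.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# Merge near-coincident spikes (< tol seconds apart), keeping the earlier.
merge_coincident <- function(spikes, tol = 1e-4) {
  if (length(spikes) < 2L) return(spikes)
  spikes <- sort(spikes)
  spikes[c(TRUE, diff(spikes) >= tol)]
}

#' Simulate a multi-session recording with planted connections
#'
#' Background activity is homogeneous Poisson per cell per session, at the
#' cell's base rate times its animal offset, times a light factor when the
#' spike falls inside a light interval and the cell is light-responsive
#' (suppressed or disinhibited). On top of the background, each planted
#' connection converts each presynaptic spike, with the session's
#' transmission probability, into one extra postsynaptic spike at a
#' truncated-normal latency in 0.5-2.5 ms; near-coincident postsynaptic
#' spikes (< 0.1 ms apart) are merged. Output is identical for identical
#' config (including seed).
#'
#' @param config A [sim_config()].
#' @return List with `trains` (named list of [spike_train()]s), `sessions`
#'   (a [session_set()] whose light intervals are the FAML epochs plus the
#'   REST pulses), and `truth` (list of data.frames `cells` and
#'   `connections` holding the planted ground truth: base and per-session
#'   true mean rates, light classes, per-session transmission
#'   probabilities and latency parameters).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  len <- config$session_lengths_s
  starts <- cumsum(c(0, unname(len[-length(len)])))
  sessions <- data.frame(label = names(len), start_s = starts,
                         end_s = starts + unname(len))
  faml_iv <- sessions[sessions$label == "FAML", c("start_s", "end_s")]
  rest_iv <- sessions[sessions$label == "REST", c("start_s", "end_s")]
  faml_epochs <- if (nrow(faml_iv))
    make_faml_epochs(faml_iv, config$faml_light$epoch_s, config$faml_light$duty)
  else data.frame(start_s = numeric(), end_s = numeric())
  rest_pulses <- if (nrow(rest_iv))
    make_rest_pulses(rest_iv, config$rest_pulse$width_s, config$rest_pulse$period_s)
  else data.frame(start_s = numeric(), end_s = numeric())
  sset <- session_set(sessions, rbind(faml_epochs, rest_pulses))

  fl <- config$faml_light
  cells <- NULL
  trains <- list()
  for (a in seq_len(config$n_animals)) {
    a_id <- sprintf("a%02d", a)
    a_fac <- exp(stats::rnorm(1, 0, config$animal_rate_sd))
    for (type in c("pyramidal", "interneuron")) {
      n_cells <- if (type == "pyramidal") config$n_pyr else config$n_int
      base <- if (type == "pyramidal")
        stats::rlnorm(n_cells, config$pyr_rate_meanlog, config$pyr_rate_sdlog)
      else
        stats::rlnorm(n_cells, config$int_rate_meanlog, config$int_rate_sdlog)
      cls <- vapply(seq_len(n_cells), function(i) {
        u <- stats::runif(1)
        if (type == "pyramidal") {
          if (u < fl$fraction_suppressed_pyr) "suppressed"
          else if (u < fl$fraction_suppressed_pyr + fl$fraction_disinhibited_pyr)
            "disinhibited"
          else "unmodulated"
        } else {
          if (u < fl$fraction_suppressed_int) "suppressed" else "unmodulated"
        }
      }, character(1))
      tag <- if (type == "pyramidal") "pyr" else "int"
      cells <- rbind(cells, data.frame(
        cell_id = sprintf("%s_%s%02d", a_id, tag, seq_len(n_cells)),
        animal_id = a_id, cell_type = type, index = seq_len(n_cells),
        base_rate_hz = base * a_fac, light_class = cls))
    }
  }

  light_factor <- function(cls) switch(cls, suppressed = fl$suppression_factor,
                                       disinhibited = fl$enhancement_factor, 1)
  for (i in seq_len(nrow(cells))) {
    rate <- cells$base_rate_hz[i]
    fac <- light_factor(cells$light_class[i])
    spikes <- numeric()
    for (s in seq_len(nrow(sessions))) {
      iv <- sessions[s, c("start_s", "end_s")]
      light <- switch(sessions$label[s], FAML = faml_epochs,
                      REST = rest_pulses,
                      data.frame(start_s = numeric(), end_s = numeric()))
      spikes <- c(spikes, gen_modulated_poisson(rate, iv, light, fac))
    }
    trains[[cells$cell_id[i]]] <- spike_train(cells$cell_id[i],
                                              cells$animal_id[i],
                                              cells$cell_type[i], spikes)
  }

  conns <- config$connections
  if (nrow(conns)) {
    conns$pre_id <- sprintf("a%02d_pyr%02d", conns$animal, conns$pre)
    conns$post_id <- sprintf("a%02d_int%02d", conns$animal, conns$post)
    conns$animal_id <- sprintf("a%02d", conns$animal)
    for (j in seq_len(nrow(conns))) {
      pre_t <- trains[[conns$pre_id[j]]]$spikes
      extra <- numeric()
      for (s in seq_len(nrow(sessions))) {
        p <- conns[[paste0("p_", sessions$label[s])]][j]
        if (p <= 0) next
        t_s <- restrict_spikes(pre_t, sessions[s, c("start_s", "end_s")])
        fire <- stats::runif(length(t_s)) < p
        if (!any(fire)) next
        lat <- rtruncnorm(sum(fire), conns$latency_mean_ms[j] / 1000,
                          conns$latency_sd_ms[j] / 1000, 0.5e-3, 2.5e-3)
        extra <- c(extra, t_s[fire] + lat)
      }
      if (length(extra)) {
        post <- trains[[conns$post_id[j]]]
        trains[[conns$post_id[j]]] <- spike_train(
          post$cell_id, post$animal_id, post$cell_type,
          merge_coincident(c(post$spikes, extra)))
      }
    }
  }

  # true mean session rates: duty-weighted for light-modulated cells
  for (s_lab in sessions$label) {
    iv <- sessions[sessions$label == s_lab, c("start_s", "end_s")]
    light <- switch(s_lab, FAML = faml_epochs, REST = rest_pulses,
                    data.frame(start_s = numeric(), end_s = numeric()))
    lit_frac <- if (nrow(light))
      sum(light$end_s - light$start_s) / (iv$end_s - iv$start_s) else 0
    fac <- vapply(cells$light_class, light_factor, numeric(1))
    cells[[paste0("rate_", s_lab)]] <-
      cells$base_rate_hz * (1 - lit_frac + lit_frac * fac)
  }

  truth_conns <- if (nrow(conns))
    conns[, c("pre_id", "post_id", "animal_id", paste0("p_", SESSION_LABELS),
              "latency_mean_ms", "latency_sd_ms")]
  else data.frame(pre_id = character(), post_id = character(),
                  animal_id = character())
  list(trains = trains, sessions = sset,
       truth = list(cells = cells, connections = truth_conns))
}
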