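#' Spike train container
#'
#' A `spike_train` holds one unit's sorted spike times (seconds) together with
#' its identity: the cell id, the animal the unit was recorded from, and the
#' putative cell type (pyramidal cell, interneuron, or unknown when no
#' waveform-based classification is available).
#'
#' @param cell_id Character scalar, unique unit label.
#' @param animal_id Character scalar.
#' @param cell_type One of `"pyramidal"`, `"interneuron"`, `"unknown"`.
#' @param spikes Numeric vector of spike times in seconds, non-negative and
#'   strictly ascending.
#'
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(cell_id, animal_id, cell_type = "unknown", spikes = numeric()) {
  cell_type <- match.arg(cell_type, c("pyramidal", "interneuron", "unknown"))
  spikes <- as.numeric(spikes)
  if (anyNA(spikes)) stop("spike times must not contain NA")
  if (length(spikes) && min(spikes) < 0) stop("spike times must be >= 0")
  if (is.unsorted(spikes, strictly = TRUE)) stop("spike times must be strictly ascending")
  structure(
    list(cell_id = as.character(cell_id), animal_id = as.character(animal_id),
         cell_type = cell_type, spikes = spikes),
    class = "spike_train"
  )
}

#' @exportS3Method base::print
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s (%s, animal %s): %d spikes",
              x$cell_id, x$cell_type, x$animal_id, length(x$spikes)))
  if (length(x$spikes))
    cat(sprintf(" over [%.3f, %.3f] s", x$spikes[1], x$spikes[length(x$spikes)]))
  cat("\n")
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$spikes)

# Normalise an interval argument: a length-2 numeric, a (start_s, end_s) row,
# or a data.frame of such rows. Returns a data.frame(start_s, end_s).
as_intervals <- function(interval) {
  if (is.data.frame(interval)) {
    stopifnot(all(c("start_s", "end_s") %in% names(interval)))
    iv <- data.frame(start_s = as.numeric(interval$start_s),
                     end_s = as.numeric(interval$end_s))
  } else {
    interval <- as.numeric(interval)
    stopifnot(length(interval) == 2L)
    iv <- data.frame(start_s = interval[1], end_s = interval[2])
  }
  if (any(iv$end_s <= iv$start_s)) stop("intervals must have start < end")
  iv[order(iv$start_s), , drop = FALSE]
}

# Spike times of `train` falling in [start, end) of any of the intervals.
restrict_spikes <- function(spikes, intervals) {
  iv <- as_intervals(intervals)
  keep <- logical(length(spikes))
  for (i in seq_len(nrow(iv)))
    keep <- keep | (spikes >= iv$start_s[i] & spikes < iv$end_s[i])
  spikes[keep]
}

SESSION_LABELS <- c("FAM1", "NOV", "FAML", "FAM2", "REST")

#' Session set: labelled recording epochs plus light-event intervals
#'
#' Sessions are non-overlapping `[start_s, end_s)` intervals labelled
#' FAM1 (familiar baseline), NOV (novel environment), FAML (familiar with
#' light stimulation), FAM2 (familiar post-light) and REST (quiet rest with
#' test light pulses). Light intervals (stimulation epochs in FAML, 500 ms
#' test pulses in REST) must each lie inside some session.
#'
#' @param sessions data.frame with columns `label`, `start_s`, `end_s`.
#' @param light_intervals Optional data.frame with columns `start_s`, `end_s`.
#'
#' @return An object of class `session_set` with elements `sessions`
#'   (ordered by `start_s`) and `light_intervals`.
#' @export
session_set <- function(sessions, light_intervals = NULL) {
  stopifnot(is.data.frame(sessions),
            all(c("label", "start_s", "end_s") %in% names(sessions)))
  sessions <- data.frame(label = as.character(sessions$label),
                         start_s = as.numeric(sessions$start_s),
                         end_s = as.numeric(sessions$end_s),
                         stringsAsFactors = FALSE)
  bad <- setdiff(sessions$label, SESSION_LABELS)
  if (length(bad)) stop("unknown session label(s): ", paste(bad, collapse = ", "))
  if (any(sessions$end_s <= sessions$start_s)) stop("sessions must have start_s < end_s")
  sessions <- sessions[order(sessions$start_s), , drop = FALSE]
  rownames(sessions) <- NULL
  if (nrow(sessions) > 1L &&
      any(sessions$start_s[-1L] < sessions$end_s[-nrow(sessions)]))
    stop("session intervals overlap")
  if (anyDuplicated(sessions$label)) stop("duplicate session labels")
  if (is.null(light_intervals) || !nrow(as.data.frame(light_intervals))) {
    light_intervals <- data.frame(start_s = numeric(), end_s = numeric())
  } else {
    light_intervals <- data.frame(start_s = as.numeric(light_intervals$start_s),
                                  end_s = as.numeric(light_intervals$end_s))
    if (any(light_intervals$end_s <= light_intervals$start_s))
      stop("light intervals must have start_s < end_s")
    inside <- vapply(seq_len(nrow(light_intervals)), function(i) {
      any(light_intervals$start_s[i] >= sessions$start_s &
            light_intervals$end_s[i] <= sessions$end_s)
    }, logical(1))
    if (!all(inside)) stop("every light interval must lie inside a session")
    light_intervals <- light_intervals[order(light_intervals$start_s), , drop = FALSE]
    rownames(light_intervals) <- NULL
  }
  structure(list(sessions = sessions, light_intervals = light_intervals),
            class = "session_set")
}

#' @exportS3Method base::print
print.session_set <- function(x, ...) {
  cat("<session_set>\n")
  for (i in seq_len(nrow(x$sessions)))
    cat(sprintf("  %-5s [%9.1f, %9.1f) s\n", x$sessions$label[i],
                x$sessions$start_s[i], x$sessions$end_s[i]))
  cat(sprintf("  %d light interval(s)\n", nrow(x$light_intervals)))
  invisible(x)
}

#' Interval of one session
#'
#' @param sset A [session_set()].
#' @param label Session label.
#' @return Numeric `c(start_s, end_s)`, or `NULL` if the label is absent.
#' @export
session_interval <- function(sset, label) {
  i <- match(label, sset$sessions$label)
  if (is.na(i)) return(NULL)
  c(sset$sessions$start_s[i], sset$sessions$end_s[i])
}

#' Light intervals overlapping one session
#'
#' @inheritParams session_interval
#' @return data.frame(start_s, end_s) of light intervals inside the session.
#' @export
session_light_intervals <- function(sset, label) {
  iv <- session_interval(sset, label)
  li <- sset$light_intervals
  if (is.null(iv) || !nrow(li)) return(data.frame(start_s = numeric(), end_s = numeric()))
  li[li$start_s >= iv[1] & li$end_s <= iv[2], , drop = FALSE]
}
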