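#' Read Klusters-style .res/.clu spike files
#'
#' The `.res` file holds one integer sample index per spike (one per line);
#' the `.clu` file starts with the number of clusters followed by one cluster
#' id per spike. Spike times are converted to seconds by dividing by
#' `sampling_rate_hz` (raw data resampled to 20 kHz is the usual convention).
#' Cluster ids 0 and 1 are treated as noise/artifact clusters and skipped;
#' set `noise_clusters` to change this dialect decision.
#'
#' @param res_path,clu_path Paths to the `.res` and `.clu` files.
#' @param sampling_rate_hz Samples per second used when the `.res` indices
#'   were written. Default 20000.
#' @param animal_id Animal label attached to every returned train.
#' @param cell_type Putative type for all clusters in the file (Klusters
#'   files carry no type information).
#' @param noise_clusters Integer cluster ids to drop. Default `c(0, 1)`.
#'
#' @return List of [spike_train()] objects, one per retained cluster, named
#'   `clu<k>`.
#' @export
load_klusters <- function(res_path, clu_path, sampling_rate_hz = 20000,
                          animal_id = "unknown", cell_type = "unknown",
                          noise_clusters = c(0L, 1L)) {
  stopifnot(sampling_rate_hz > 0)
  res <- scan(res_path, what = numeric(), quiet = TRUE)
  clu <- scan(clu_path, what = integer(), quiet = TRUE)
  if (!length(clu)) stop("empty .clu file (needs at least the cluster-count header)")
  clu <- clu[-1L]  # first line is the number of clusters
  if (length(res) != length(clu))
    stop(sprintf(".res/.clu length mismatch: %d spikes vs %d cluster ids",
                 length(res), length(clu)))
  out <- list()
  for (k in sort(setdiff(unique(clu), noise_clusters))) {
    t_k <- res[clu == k] / sampling_rate_hz
    if (is.unsorted(t_k)) {
      warning(sprintf("cluster %d: spike times not monotone; sorting", k))
      t_k <- sort(t_k)
    }
    n_dup <- sum(duplicated(t_k))
    if (n_dup > 0) {
      message(sprintf("cluster %d: dropped %d duplicate spike time(s)", k, n_dup))
      t_k <- unique(t_k)
    }
    out[[paste0("clu", k)]] <- spike_train(paste0("clu", k), animal_id,
                                           cell_type, t_k)
  }
  out
}

#' Write Klusters-style .res/.clu files
#'
#' Inverse of [load_klusters()]: spike times are rounded to the nearest
#' sample. Spikes from all trains are merged in time order.
#'
#' @param trains List of [spike_train()]s.
#' @param res_path,clu_path Output paths.
#' @param sampling_rate_hz Samples per second. Default 20000.
#' @param first_cluster Cluster id given to the first train (ids 0/1 are
#'   conventionally reserved for noise/artifact). Default 2.
#' @return Invisibly, the data.frame of (sample, cluster) written.
#' @export
write_klusters <- function(trains, res_path, clu_path, sampling_rate_hz = 20000,
                           first_cluster = 2L) {
  samples <- integer(); ids <- integer()
  for (i in seq_along(trains)) {
    s <- round(trains[[i]]$spikes * sampling_rate_hz)
    samples <- c(samples, s)
    ids <- c(ids, rep.int(first_cluster + i - 1L, length(s)))
  }
  o <- order(samples)
  samples <- samples[o]; ids <- ids[o]
  n_clu <- length(trains) + first_cluster  # count includes reserved ids
  writeLines(format(samples, scientific = FALSE, trim = TRUE), res_path)
  writeLines(c(as.character(n_clu), as.character(ids)), clu_path)
  invisible(data.frame(sample = samples, cluster = ids))
}

#' Read spike trains from the tabular interchange format
#'
#' Comma-delimited text with mandatory header
#' `cell_id,animal_id,cell_type,time_s`, one spike per row. Rows are grouped
#' by `cell_id`, times sorted; rows with negative times are rejected with a
#' message giving the count.
#'
#' @param path Path to the CSV file.
#' @return List of [spike_train()]s, named by `cell_id`.
#' @export
load_tabular_spikes <- function(path) {
  dt <- data.table::fread(path)
  need <- c("cell_id", "animal_id", "cell_type", "time_s")
  if (!all(need %in% names(dt)))
    stop("spike table header must contain: ", paste(need, collapse = ","))
  dt$cell_id <- as.character(dt$cell_id)
  dt$animal_id <- as.character(dt$animal_id)
  dt$cell_type <- as.character(dt$cell_type)
  dt$time_s <- as.numeric(dt$time_s)
  n_neg <- sum(dt$time_s < 0, na.rm = TRUE)
  if (n_neg > 0) {
    message(sprintf("rejected %d row(s) with negative time_s", n_neg))
    dt <- dt[dt$time_s >= 0, ]
  }
  out <- list()
  for (cid in unique(dt$cell_id)) {
    sub <- dt[dt$cell_id == cid, ]
    ct <- sub$cell_type[1]
    if (!ct %in% c("pyramidal", "interneuron")) ct <- "unknown"
    t_c <- sort(sub$time_s)
    n_dup <- sum(duplicated(t_c))
    if (n_dup > 0) {
      message(sprintf("cell %s: dropped %d duplicate spike time(s)", cid, n_dup))
      t_c <- unique(t_c)
    }
    out[[cid]] <- spike_train(cid, sub$animal_id[1], ct, t_c)
  }
  out
}

#' Write spike trains to the tabular interchange format
#'
#' @param trains List of [spike_train()]s.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_tabular_spikes <- function(trains, path) {
  dt <- data.table::rbindlist(lapply(trains, function(tr) {
    data.table::data.table(cell_id = tr$cell_id, animal_id = tr$animal_id,
                           cell_type = tr$cell_type, time_s = tr$spikes)
  }))
  if (!nrow(dt))
    dt <- data.table::data.table(cell_id = character(), animal_id = character(),
                                 cell_type = character(), time_s = numeric())
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a session table
#'
#' Comma-delimited text with header `label,start_s,end_s`. Rows whose label
#' is a session name (FAM1/NOV/FAML/FAM2/REST) define sessions; rows labelled
#' `LIGHT` define light-event intervals. Sessions given out of chronological
#' order are reordered by `start_s`; overlapping sessions or unknown labels
#' are hard errors.
#'
#' @param path Path to the CSV file.
#' @return A [session_set()].
#' @export
load_session_table <- function(path) {
  dt <- data.table::fread(path)
  if (!all(c("label", "start_s", "end_s") %in% names(dt)))
    stop("session table header must contain: label,start_s,end_s")
  dt$label <- as.character(dt$label)
  is_light <- dt$label == "LIGHT"
  bad <- setdiff(dt$label[!is_light], SESSION_LABELS)
  if (length(bad)) stop("unknown session label(s): ", paste(bad, collapse = ", "))
  session_set(as.data.frame(dt[!is_light, ]),
              if (any(is_light)) as.data.frame(dt[is_light, c("start_s", "end_s")]))
}

#' Write a session table
#'
#' @param sset A [session_set()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_session_table <- function(sset, path) {
  df <- sset$sessions
  if (nrow(sset$light_intervals))
    df <- rbind(df, data.frame(label = "LIGHT",
                               start_s = sset$light_intervals$start_s,
                               end_s = sset$light_intervals$end_s))
  data.table::fwrite(df, path)
  invisible(path)
}

# Mandatory identity/detection columns of a pair-session table; per-session
# metric columns (rate_pre_*, rate_post_*, trans_*, pairing_*, c_*) vary with
# the sessions analysed and are carried through as-is.
PAIR_TABLE_MANDATORY <- c("pair_id", "pre_id", "post_id", "animal_id",
                          "peak_z", "significant", "passes_filters")

#' Write / read the pair-session table
#'
#' The pair-session table is the tidy interface between detection and the
#' statistical layer: one row per detected (or candidate) pyramidal to
#' interneuron pair, with identity columns, the detection statistic, and
#' per-session metrics. Floats are written at full precision so the
#' round trip is lossless; missing values are written as empty fields.
#'
#' @param table data.frame containing at least the mandatory columns
#'   `pair_id, pre_id, post_id, animal_id, peak_z, significant,
#'   passes_filters`.
#' @param path CSV path.
#' @return `write_pair_table` returns `path` invisibly; `read_pair_table`
#'   returns the table as a data.frame.
#' @export
write_pair_table <- function(table, path) {
  miss <- setdiff(PAIR_TABLE_MANDATORY, names(table))
  if (length(miss)) stop("pair table is missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  out <- as.data.frame(table)
  for (j in seq_along(out)) {  # 17 significant digits round-trip a double
    if (is.double(out[[j]])) {
      v <- formatC(out[[j]], digits = 17, format = "g")
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  data.table::fwrite(out, path, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  dt <- data.table::fread(path, na.strings = "")
  miss <- setdiff(PAIR_TABLE_MANDATORY, names(dt))
  if (length(miss)) stop("pair table is missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  as.data.frame(dt)
}
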