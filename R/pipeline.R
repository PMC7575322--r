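#' Pipeline configuration
#'
#' Bundles every analysis parameter so that a full run is reproducible from
#' the config alone and sensitivity analyses are one-field changes. The
#' defaults are the standard analysis settings: 1 ms bins on +/-50 ms,
#' monosynaptic peak bins at +1/+2 ms (the 0.5-2.5 ms window), chance and
#' baseline from the 10-50 ms flanks, 3 SD detection threshold, 1000-count
#' and SD/mean < 1/3 quality filters, pairing windows 10/20/50/100 ms, and
#' 5 s split-half blocks.
#'
#' @param mode `"simulate"` (generate data from `sim`) or `"real"` (load
#'   from `spikes_path`/`sessions_path`).
#' @param sim A [sim_config()] (simulate mode).
#' @param spikes_path Tabular spike CSV ([load_tabular_spikes()]) (real
#'   mode).
#' @param sessions_path Session table CSV ([load_session_table()]) (real
#'   mode).
#' @param bin_ms,half_ms CCG lattice. Defaults 1 and 50.
#' @param peak_ms Peak bin centres (ms). Default `c(1, 2)`.
#' @param flank_ms Flank range (ms). Default `c(10, 50)`.
#' @param z_threshold Detection threshold in flank SD units. Default 3.
#' @param min_counts Quality filter: minimum coincidence counts. Default
#'   1000.
#' @param dispersion_threshold Quality filter: maximum SD/mean. Default 1/3.
#' @param dispersion_on `"flanks"` or `"all"`; see
#'   [apply_quality_filters()].
#' @param pairing_windows_ms Pairing-event windows. Default
#'   `c(10, 20, 50, 100)`.
#' @param block_s Split-half block length. Default 5.
#' @param seed Integer seed controlling every stochastic step.
#' @param outdir Output directory (created if needed); `NULL` disables file
#'   output.
#' @param save_ccgs Write one CSV per detected pair's detection CCG.
#'   Default FALSE.
#' @param verbose Emit per-stage messages with row counts. Default FALSE.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("simulate", "real"), sim = sim_config(),
                            spikes_path = NULL, sessions_path = NULL,
                            bin_ms = 1, half_ms = 50, peak_ms = c(1, 2),
                            flank_ms = c(10, 50), z_threshold = 3,
                            min_counts = 1000, dispersion_threshold = 1 / 3,
                            dispersion_on = "flanks",
                            pairing_windows_ms = c(10, 20, 50, 100),
                            block_s = 5, seed = 1L, outdir = NULL,
                            save_ccgs = FALSE, verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(bin_ms > 0, half_ms > 0, z_threshold > 0, min_counts > 0,
            dispersion_threshold > 0, block_s > 0,
            all(pairing_windows_ms > 0),
            !is.unsorted(pairing_windows_ms, strictly = TRUE))
  structure(list(mode = mode, sim = sim, spikes_path = spikes_path,
                 sessions_path = sessions_path, bin_ms = bin_ms,
                 half_ms = half_ms, peak_ms = peak_ms, flank_ms = flank_ms,
                 z_threshold = z_threshold, min_counts = min_counts,
                 dispersion_threshold = dispersion_threshold,
                 dispersion_on = dispersion_on,
                 pairing_windows_ms = pairing_windows_ms, block_s = block_s,
                 seed = as.integer(seed), outdir = outdir,
                 save_ccgs = save_ccgs, verbose = verbose),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `sim` key
#' holds [sim_config()] arguments (its `connections` sub-key, if present, is
#' converted to a data.frame).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$connections))
      y$sim$connections <- as.data.frame(
        do.call(rbind, lapply(y$sim$connections, as.data.frame)))
    if (!is.null(y$sim$session_lengths_s))
      y$sim$session_lengths_s <- unlist(y$sim$session_lengths_s)
    y$sim <- do.call(sim_config, y$sim)
  }
  do.call(pipeline_config, y)
}

stage_msg <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf(paste0("[monoconn] ", fmt), ...))
}

#' Detect monosynaptic pairs in a set of spike trains
#'
#' Screens every pyramidal-to-interneuron pair within each animal. The
#' detection CCG is computed over the union of the exploration sessions
#' (REST is excluded so pulse-locked firing cannot shape the histogram);
#' the quality filters are evaluated on the FAM1 and FAM2 session CCGs.
#'
#' @param trains Named list of [spike_train()]s.
#' @param sset A [session_set()].
#' @param cfg A [pipeline_config()].
#' @return data.frame with one row per candidate pair: ids, `peak_z`,
#'   `significant`, `passes_filters`, `filter_reasons`, `detected`
#'   (significant AND passing).
#' @export
detect_pairs <- function(trains, sset, cfg = pipeline_config()) {
  types <- vapply(trains, function(tr) tr$cell_type, character(1))
  animals <- vapply(trains, function(tr) tr$animal_id, character(1))
  expl <- sset$sessions[sset$sessions$label != "REST", c("start_s", "end_s")]
  iv1 <- session_interval(sset, "FAM1"); iv2 <- session_interval(sset, "FAM2")
  rows <- list()
  for (an in unique(animals)) {
    pyr_ids <- names(trains)[types == "pyramidal" & animals == an]
    int_ids <- names(trains)[types == "interneuron" & animals == an]
    for (p_id in pyr_ids) for (i_id in int_ids) {
      ccg_all <- compute_ccg(trains[[p_id]], trains[[i_id]], expl,
                             half_ms = cfg$half_ms, bin_ms = cfg$bin_ms)
      det <- detect_monosynaptic(ccg_all, cfg$z_threshold, cfg$peak_ms,
                                 cfg$flank_ms)
      c1 <- if (!is.null(iv1)) compute_ccg(trains[[p_id]], trains[[i_id]], iv1,
                                           cfg$half_ms, cfg$bin_ms)
      c2 <- if (!is.null(iv2)) compute_ccg(trains[[p_id]], trains[[i_id]], iv2,
                                           cfg$half_ms, cfg$bin_ms)
      qf <- apply_quality_filters(c1, c2, cfg$min_counts,
                                  cfg$dispersion_threshold, cfg$dispersion_on,
                                  cfg$flank_ms)
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = paste0(p_id, "->", i_id), pre_id = p_id, post_id = i_id,
        animal_id = an, peak_z = det$peak_z, significant = det$significant,
        passes_filters = qf$passes,
        filter_reasons = paste(qf$reasons, collapse = ";"),
        detected = det$significant && qf$passes)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(), pre_id = character(),
               post_id = character(), animal_id = character(),
               peak_z = numeric(), significant = logical(),
               passes_filters = logical(), filter_reasons = character(),
               detected = logical())
  stage_msg(cfg, "detection: %d candidate pairs, %d detected",
            nrow(out), sum(out$detected))
  out
}

#' Per-session metrics for detected pairs
#'
#' For each pair and each session: presynaptic and postsynaptic firing
#' rates, chance-subtracted spike-transmission probability, and
#' pairing-event counts for each window. Change scores
#' ([relative_change()]) against FAM1 are added for rates, transmission and
#' total pairing counts, plus FAM1 split-half (odd/even 5 s blocks) rates
#' and transmissions.
#'
#' @param pairs Detection table from [detect_pairs()] (only rows with
#'   `detected` are measured; pass a filtered table to override).
#' @param trains Named list of [spike_train()]s.
#' @param sset A [session_set()].
#' @param cfg A [pipeline_config()].
#' @return The pair-session table (data.frame), one row per detected pair.
#' @export
pair_session_metrics <- function(pairs, trains, sset, cfg = pipeline_config()) {
  pairs <- pairs[pairs$detected, , drop = FALSE]
  labels <- sset$sessions$label
  expl <- setdiff(labels, "REST")
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    pre <- trains[[pairs$pre_id[r]]]; post <- trains[[pairs$post_id[r]]]
    row <- pairs[r, c("pair_id", "pre_id", "post_id", "animal_id", "peak_z",
                      "significant", "passes_filters")]
    for (lab in expl) {
      iv <- session_interval(sset, lab)
      row[[paste0("rate_pre_", lab)]] <- session_rate(pre, iv)
      row[[paste0("rate_post_", lab)]] <- session_rate(post, iv)
      ccg_s <- compute_ccg(pre, post, iv, cfg$half_ms, cfg$bin_ms)
      row[[paste0("trans_", lab)]] <-
        transmission_probability(ccg_s, cfg$peak_ms, cfg$flank_ms)
      for (w in cfg$pairing_windows_ms) {
        pc <- pairing_counts(pre, post, iv, w)
        row[[sprintf("pairing_plus_w%d_%s", w, lab)]] <- pc$count_dir_plus
        row[[sprintf("pairing_minus_w%d_%s", w, lab)]] <- pc$count_dir_minus
        row[[sprintf("pairing_all_w%d_%s", w, lab)]] <- pc$count_all
      }
    }
    if ("FAM1" %in% labels) {
      iv1 <- session_interval(sset, "FAM1")
      sh_t <- split_half_transmission(pre, post, iv1, cfg$block_s,
                                      peak_ms = cfg$peak_ms,
                                      flank_ms = cfg$flank_ms)
      sh_pre <- split_half_rates(pre, iv1, cfg$block_s)
      sh_post <- split_half_rates(post, iv1, cfg$block_s)
      row$trans_FAM1_odd <- sh_t[["odd"]]; row$trans_FAM1_even <- sh_t[["even"]]
      row$rate_pre_FAM1_odd <- sh_pre[["odd"]]
      row$rate_pre_FAM1_even <- sh_pre[["even"]]
      row$rate_post_FAM1_odd <- sh_post[["odd"]]
      row$rate_post_FAM1_even <- sh_post[["even"]]
      for (lab in setdiff(expl, "FAM1")) {
        row[[paste0("c_rate_pre_", lab)]] <-
          relative_change(row$rate_pre_FAM1, row[[paste0("rate_pre_", lab)]])
        row[[paste0("c_rate_post_", lab)]] <-
          relative_change(row$rate_post_FAM1, row[[paste0("rate_post_", lab)]])
        row[[paste0("c_trans_", lab)]] <-
          change_score_signed(row$trans_FAM1, row[[paste0("trans_", lab)]])
        for (w in cfg$pairing_windows_ms)
          row[[sprintf("c_pairing_w%d_%s", w, lab)]] <-
            relative_change(row[[sprintf("pairing_all_w%d_FAM1", w)]],
                            row[[sprintf("pairing_all_w%d_%s", w, lab)]])
      }
    }
    rows[[r]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(pairs[, c("pair_id", "pre_id", "post_id", "animal_id", "peak_z",
                    "significant", "passes_filters")])
  rownames(out) <- NULL
  stage_msg(cfg, "metrics: %d pair rows, %d columns", nrow(out), ncol(out))
  out
}

# Change score for transmissions, which can be slightly negative for weak
# pairs: negative inputs are floored at 0 before the (b-a)/(b+a) score so the
# bound/antisymmetry contract of relative_change is preserved.
change_score_signed <- function(a, b) {
  relative_change(pmax(a, 0), pmax(b, 0))
}

#' Statistical report on a pair-session table
#'
#' Runs the standard statistical battery: (1) prediction of FAM2
#' transmission from FAM1/NOV/FAML with drop-one mixed-model comparison and
#' partial correlations; (2) regression of the FAM2-FAM1 transmission
#' change score on interneuron and pyramidal FAML-FAM1 rate change scores;
#' (3) pairing-change prediction of the transmission change for each window
#' with Holm-Bonferroni correction; (4) split-half stability baselines and
#' Fisher-Z comparison of the FAM1-FAML correlation against them; (5) the
#' likelihood-ratio test for the animal random effect on the main model.
#' Sections that cannot be computed (too few pairs) are reported as
#' skipped.
#'
#' @param tab Pair-session table from [pair_session_metrics()].
#' @param cfg A [pipeline_config()].
#' @return List of per-section results (`NULL` where skipped) plus `notes`.
#' @export
pair_statistics <- function(tab, cfg = pipeline_config()) {
  res <- list(notes = character())
  note <- function(msg) res$notes <<- c(res$notes, msg)
  n <- nrow(tab)
  if (n < 6L) {
    note(sprintf("only %d detected pair(s); statistical sections skipped", n))
    return(res)
  }
  has <- function(cols) all(cols %in% names(tab))

  if (has(c("trans_FAM2", "trans_FAM1", "trans_NOV", "trans_FAML"))) {
    res$fam2_model <- tryCatch(
      model_comparison(tab, "trans_FAM2", c("trans_FAM1", "trans_NOV", "trans_FAML")),
      error = function(e) { note(paste("FAM2 model failed:", conditionMessage(e))); NULL })
    res$fam2_partial <- data.frame(
      predictor = c("trans_FAM1", "trans_NOV", "trans_FAML"),
      r_partial = c(
        partial_correlation(tab$trans_FAM1, tab$trans_FAM2,
                            tab[, c("trans_NOV", "trans_FAML")]),
        partial_correlation(tab$trans_NOV, tab$trans_FAM2,
                            tab[, c("trans_FAM1", "trans_FAML")]),
        partial_correlation(tab$trans_FAML, tab$trans_FAM2,
                            tab[, c("trans_FAM1", "trans_NOV")])))
    m_with <- tryCatch(fit_lmm(tab, "trans_FAM2",
                               c("trans_FAM1", "trans_NOV", "trans_FAML")),
                       error = function(e) NULL)
    m_without <- tryCatch(fit_lmm(tab, "trans_FAM2",
                                  c("trans_FAM1", "trans_NOV", "trans_FAML"),
                                  group = NULL),
                          error = function(e) NULL)
    if (!is.null(m_with) && !is.null(m_with$group) && !is.null(m_without))
      res$animal_lrt <- lrt_random_effect(m_with, m_without)
  }

  if (has(c("c_trans_FAM2", "c_rate_post_FAML", "c_rate_pre_FAML"))) {
    res$rate_change_model <- tryCatch(
      model_comparison(tab, "c_trans_FAM2", c("c_rate_post_FAML", "c_rate_pre_FAML")),
      error = function(e) { note(paste("rate-change model failed:", conditionMessage(e))); NULL })
  }

  pair_cols <- sprintf("c_pairing_w%d_FAML", cfg$pairing_windows_ms)
  if (has(c("c_trans_FAM2", pair_cols))) {
    fits <- lapply(seq_along(cfg$pairing_windows_ms), function(i) {
      f <- tryCatch(fit_lmm(tab, "c_trans_FAM2", pair_cols[i]),
                    error = function(e) NULL)
      if (is.null(f)) return(data.frame(window_ms = cfg$pairing_windows_ms[i],
                                        estimate = NA_real_, p = NA_real_))
      ct <- f$coefficients
      data.frame(window_ms = cfg$pairing_windows_ms[i],
                 estimate = ct$estimate[ct$term == pair_cols[i]],
                 p = ct$p[ct$term == pair_cols[i]])
    })
    ptab <- do.call(rbind, fits)
    hb <- holm_bonferroni(ptab$p)
    ptab$p_adj <- hb$p_adj; ptab$reject <- hb$reject
    res$pairing_prediction <- ptab
    res$pairing_r2 <- tryCatch(do.call(rbind, lapply(
      seq_along(cfg$pairing_windows_ms), function(i) {
        rr <- r2_with_ci(tab, pair_cols[i],
                         c("c_rate_post_FAML", "c_rate_pre_FAML"),
                         n_boot = 200, seed = cfg$seed + i)
        data.frame(window_ms = cfg$pairing_windows_ms[i], r2 = rr$r2,
                   ci_lo = rr$ci[1], ci_hi = rr$ci[2])
      })), error = function(e) NULL)
  }

  if (has(c("trans_FAM1_odd", "trans_FAM1_even", "trans_FAM1", "trans_FAML"))) {
    r_split <- split_half_baseline(tab$trans_FAM1_odd, tab$trans_FAM1_even)
    ok <- stats::complete.cases(tab$trans_FAM1, tab$trans_FAML)
    r_cross <- if (sum(ok) >= 3L) stats::cor(tab$trans_FAM1[ok], tab$trans_FAML[ok]) else NA
    res$stability <- list(r_split_half = r_split, r_fam1_faml = r_cross)
    if (is.finite(r_split) && is.finite(r_cross) &&
        abs(r_split) < 1 && abs(r_cross) < 1 && n >= 4L)
      res$stability$fisher_z <- fisher_z_compare(r_split, n, r_cross, n)
  }
  res
}

format_report <- function(pairs, tab, stats) {
  ln <- c("monoconn pipeline report", strrep("=", 24), "",
          sprintf("candidate pairs screened : %d", nrow(pairs)),
          sprintf("significant (>= 3 SD)    : %d", sum(pairs$significant, na.rm = TRUE)),
          sprintf("passing quality filters  : %d", sum(pairs$passes_filters)),
          sprintf("detected pairs           : %d", sum(pairs$detected)), "")
  if (!sum(pairs$detected)) {
    ln <- c(ln, "NOTICE: no pairs detected; statistical sections are empty.")
    return(ln)
  }
  tcols <- grep("^trans_(FAM1|NOV|FAML|FAM2)$", names(tab), value = TRUE)
  if (length(tcols)) {
    ln <- c(ln, "per-session spike transmission (median [IQR]):")
    for (cc in tcols) {
      q <- stats::quantile(tab[[cc]], c(.25, .5, .75), na.rm = TRUE)
      ln <- c(ln, sprintf("  %-12s %.4f [%.4f, %.4f]", sub("trans_", "", cc),
                          q[2], q[1], q[3]))
    }
    ln <- c(ln, "")
  }
  if (!is.null(stats$fam2_model)) {
    ln <- c(ln, "FAM2 transmission ~ FAM1 + NOV + FAML (drop-one LRT):")
    m <- stats$fam2_model
    ln <- c(ln, sprintf("  %-12s est %8.4f  chisq %8.3f  p %.4g",
                        m$predictor, m$estimate, m$chisq, m$p), "")
  }
  if (!is.null(stats$animal_lrt))
    ln <- c(ln, sprintf("animal random effect LRT: stat %.3f, p %.4g",
                        stats$animal_lrt$stat, stats$animal_lrt$p), "")
  if (!is.null(stats$rate_change_model)) {
    m <- stats$rate_change_model
    ln <- c(ln, "FAM2-FAM1 transmission change ~ rate changes (FAML-FAM1):",
            sprintf("  %-16s est %8.4f  chisq %8.3f  p %.4g",
                    m$predictor, m$estimate, m$chisq, m$p), "")
  }
  if (!is.null(stats$pairing_prediction)) {
    m <- stats$pairing_prediction
    ln <- c(ln, "pairing-change prediction of transmission change (Holm-corrected):",
            sprintf("  w=%3d ms  est %8.4f  p %.4g  p_adj %.4g  %s",
                    m$window_ms, m$estimate, m$p, m$p_adj,
                    ifelse(m$reject, "*", "ns")), "")
  }
  if (!is.null(stats$stability)) {
    s <- stats$stability
    ln <- c(ln, sprintf("FAM1 split-half transmission r: %.3f", s$r_split_half),
            sprintf("FAM1 vs FAML transmission r   : %.3f", s$r_fam1_faml))
    if (!is.null(s$fisher_z))
      ln <- c(ln, sprintf("Fisher Z (split-half vs cross) : Z %.3f, p %.4g",
                          s$fisher_z$Z, s$fisher_z$p))
    ln <- c(ln, "")
  }
  if (length(stats$notes)) ln <- c(ln, paste("note:", stats$notes))
  ln
}

#' Run the full analysis pipeline
#'
#' Ingests or simulates spike trains, detects monosynaptic
#' pyramidal-to-interneuron pairs, computes the per-session pair metrics,
#' runs the statistical battery, and (when `outdir` is set) writes the
#' pair-session table, a plain-text report, and optionally per-pair CCG
#' CSVs. Fully deterministic for a fixed config (including seed).
#'
#' @param cfg A [pipeline_config()].
#' @return List with `pairs` (detection table), `table` (pair-session
#'   table), `stats`, `report` (character lines), `sessions`, `truth`
#'   (simulate mode only) and `paths` of written files.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  set.seed(cfg$seed)
  if (cfg$mode == "simulate") {
    sim <- simulate_dataset(cfg$sim)
    trains <- sim$trains; sset <- sim$sessions; truth <- sim$truth
    stage_msg(cfg, "simulated %d trains over %d sessions", length(trains),
              nrow(sset$sessions))
  } else {
    if (is.null(cfg$spikes_path) || is.null(cfg$sessions_path))
      stop("real mode requires spikes_path and sessions_path")
    trains <- load_tabular_spikes(cfg$spikes_path)
    sset <- load_session_table(cfg$sessions_path)
    truth <- NULL
    stage_msg(cfg, "loaded %d trains", length(trains))
  }
  pairs <- detect_pairs(trains, sset, cfg)
  tab <- pair_session_metrics(pairs, trains, sset, cfg)
  stats <- pair_statistics(tab, cfg)
  report <- format_report(pairs, tab, stats)
  paths <- list()
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    paths$pair_table <- file.path(cfg$outdir, "pair_table.csv")
    write_pair_table(tab, paths$pair_table)
    paths$report <- file.path(cfg$outdir, "report.txt")
    writeLines(report, paths$report)
    if (isTRUE(cfg$save_ccgs) && any(pairs$detected)) {
      ccg_dir <- file.path(cfg$outdir, "ccg")
      dir.create(ccg_dir, showWarnings = FALSE)
      expl <- sset$sessions[sset$sessions$label != "REST",
                            c("start_s", "end_s")]
      for (r in which(pairs$detected)) {
        cg <- compute_ccg(trains[[pairs$pre_id[r]]],
                          trains[[pairs$post_id[r]]], expl,
                          cfg$half_ms, cfg$bin_ms)
        data.table::fwrite(as.data.frame(cg),
                           file.path(ccg_dir, paste0(gsub("->", "_", pairs$pair_id[r]),
                                                     ".csv")))
      }
      paths$ccg_dir <- ccg_dir
    }
    stage_msg(cfg, "wrote outputs to %s", cfg$outdir)
  }
  list(pairs = pairs, table = tab, stats = stats, report = report,
       sessions = sset, truth = truth, paths = paths)
}
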