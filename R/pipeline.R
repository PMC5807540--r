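# End-to-end orchestration: per-subject analysis, group topographies and
# cluster statistics, file-based study runs, and synthetic fixtures on disk.

#' Analyze one subject end to end
#'
#' Preprocesses (optional), rejects artifact epochs, scores architecture and
#' computes the requested per-channel metrics for each analysis window.
#'
#' @param rec raw or preprocessed [new_recording()].
#' @param hyp matching [hypnogram()].
#' @param windows named list of `list(stages =, cycle =)` selections.
#' @param what subset of `c("spindles", "slow_waves", "psd")`.
#' @param params [spindle_params()].
#' @param bands named list of bands for [band_power()].
#' @param artifact_factors `c(low, high)` multipliers for [reject_artifacts()].
#' @param preprocessed set `TRUE` if `rec` is already conditioned.
#' @return List with `architecture`, `artifact_mask` and one entry per
#'   window carrying masks, event tables and per-channel metric tables.
#' @export
analyze_subject <- function(rec, hyp,
                            windows = list(
                              whole_n2n3 = list(stages = c("N2", "N3"),
                                                cycle = NULL)),
                            what = c("spindles", "slow_waves", "psd"),
                            params = spindle_params(),
                            bands = list(delta = c(1, 4), sigma = c(12, 16)),
                            artifact_factors = c(4, 4),
                            preprocessed = FALSE) {
  if (!preprocessed) rec <- preprocess_recording(rec)
  amask <- reject_artifacts(rec, hyp, factor_low = artifact_factors[1],
                            factor_high = artifact_factors[2])
  arch <- score_architecture(hyp)
  env <- if ("spindles" %in% what) sigma_envelope(rec, band = params$band)
  out <- list(architecture = arch, artifact_mask = amask, windows = list())
  for (wn in names(windows)) {
    wd <- windows[[wn]]
    mask <- stage_mask(hyp, stages = wd$stages, cycle = wd$cycle,
                       artifact_mask = amask)
    res <- list(mask = mask)
    if ("spindles" %in% what) {
      ev <- detect_spindles(env, mask, params)
      res$spindles <- list(
        events = ev,
        metrics = lapply(setNames(nm = c("whole", "slow", "fast")),
                         function(rg) spindle_metrics(ev, mask,
                                                      labels = rec$labels,
                                                      range = rg)))
    }
    if ("slow_waves" %in% what) {
      sev <- detect_slow_waves(rec, mask)
      res$slow_waves <- list(events = sev,
                             metrics = slow_wave_metrics(sev, mask,
                                                         labels = rec$labels))
    }
    if ("psd" %in% what) {
      psd <- welch_psd(rec, mask)
      res$band_power <- lapply(bands, function(b) band_power(psd, b))
    }
    out$windows[[wn]] <- res
  }
  out
}

#' Stack per-subject metric tables into a topography matrix
#'
#' @param tables list of per-subject data frames with a `channel` column.
#' @param column metric column to extract.
#' @return subjects x channels matrix (rows follow the list order).
#' @export
topo_matrix <- function(tables, column) {
  labels <- tables[[1]]$channel
  M <- t(vapply(tables, function(tb) {
    v <- tb[[column]][match(labels, tb$channel)]
    as.numeric(v)
  }, numeric(length(labels))))
  colnames(M) <- labels
  rownames(M) <- names(tables)
  M
}

# default group-comparison metric set
study_metrics <- function() {
  list(
    spindle = list(table = "spindles", ranges = c("whole", "slow", "fast"),
                   columns = c("density", "duration", "isas")),
    slow_wave = list(table = "slow_waves",
                     columns = c("density", "npamp", "ads", "mds", "aus", "mus")))
}

#' Run a two-group study from a configuration
#'
#' The configuration (list, or path to a YAML file) names the subjects
#' (`subjects`: id, group, recording, hypnogram), the montage (path or
#' channel count), the analysis `windows`, spindle/statistics parameters and
#' an output directory.  Per-subject metrics, group topographies, cluster
#' reports and the architecture comparison are written as CSV under
#' `out_dir`; the full report is returned invisibly.  Deterministic for a
#' fixed `stats$seed`.
#'
#' @param config configuration list or YAML path.
#' @return Report list (invisibly).
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stopf("config needs out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  subs <- config$subjects
  if (is.list(subs) && !is.data.frame(subs))
    subs <- do.call(rbind, lapply(subs, as.data.frame))
  if (length(unique(subs$group)) != 2L) stopf("need exactly two groups")
  windows <- config$windows %||%
    list(whole_n2n3 = list(stages = c("N2", "N3"), cycle = NULL))
  what <- config$what %||% c("spindles", "slow_waves", "psd")
  stats_par <- utils::modifyList(
    list(t_thresh = NULL, n_perm = 8192, seed = 1, stat = "mass"),
    config$stats %||% list())
  params <- do.call(spindle_params, config$spindle %||% list())

  message(sprintf("run_study: %d subjects, windows: %s, seed %d",
                  nrow(subs), paste(names(windows), collapse = ","),
                  stats_par$seed))
  results <- list(); arch <- list(); failed <- character()
  for (i in seq_len(nrow(subs))) {
    id <- subs$id[i]
    res <- tryCatch({
      rec <- read_recording(subs$recording[i])
      hyp <- read_hypnogram(subs$hypnogram[i])
      analyze_subject(rec, hyp, windows = windows, what = what,
                      params = params)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("subject %s FAILED: %s", id, conditionMessage(res)))
      failed <- c(failed, id)
      next
    }
    message(sprintf("subject %s (%s): ok", id, subs$group[i]))
    results[[id]] <- res
    arch[[id]] <- res$architecture
    for (wn in names(windows)) {
      w <- res$windows[[wn]]
      if (!is.null(w$spindles))
        utils::write.csv(w$spindles$metrics$whole,
                         file.path(out_dir, sprintf("%s_%s_spindles.csv", id, wn)),
                         row.names = FALSE)
      if (!is.null(w$slow_waves))
        utils::write.csv(w$slow_waves$metrics,
                         file.path(out_dir, sprintf("%s_%s_slowwaves.csv", id, wn)),
                         row.names = FALSE)
    }
  }
  ok_ids <- names(results)
  groups <- setNames(subs$group, subs$id)[ok_ids]
  gA <- ok_ids[groups == unique(subs$group)[1]]
  gB <- ok_ids[groups == unique(subs$group)[2]]
  if (length(gA) < 2L || length(gB) < 2L)
    stopf("fewer than 2 usable subjects in a group (failed: %s)",
          paste(failed, collapse = ","))

  mon <- if (!is.null(config$montage) && is.character(config$montage))
    read_montage(config$montage) else make_montage(
      config$n_channels %||% nrow(results[[1]]$artifact_mask))
  adj <- build_adjacency(mon)

  report <- list(failed = failed, clusters = list(), architecture = NULL)
  arch_cmp <- compare_architecture(arch[gA], arch[gB])
  utils::write.csv(arch_cmp, file.path(out_dir, "architecture_comparison.csv"),
                   row.names = FALSE)
  report$architecture <- arch_cmp

  metric_value <- function(res, wn, spec, col, rg = NULL) {
    w <- res$windows[[wn]]
    if (spec$table == "spindles") w$spindles$metrics[[rg]] else w$slow_waves$metrics
  }
  cluster_rows <- list()
  for (wn in names(windows)) {
    for (mname in names(study_metrics())) {
      spec <- study_metrics()[[mname]]
      if (spec$table == "spindles" && is.null(results[[1]]$windows[[wn]]$spindles)) next
      if (spec$table == "slow_waves" && is.null(results[[1]]$windows[[wn]]$slow_waves)) next
      ranges <- spec$ranges %||% NA
      for (rg in ranges) {
        for (col in spec$columns) {
          tabs <- lapply(results, metric_value, wn = wn, spec = spec, col = col,
                         rg = if (is.na(rg)) NULL else rg)
          M <- topo_matrix(tabs, col)
          M[is.na(M)] <- 0
          key <- paste(c(wn, mname, if (!is.na(rg)) rg, col), collapse = ".")
          ct <- snpm_cluster_test(M[gA, , drop = FALSE], M[gB, , drop = FALSE],
                                  adj, t_thresh = stats_par$t_thresh,
                                  n_perm = stats_par$n_perm,
                                  seed = stats_par$seed, stat = stats_par$stat)
          report$clusters[[key]] <- ct
          if (nrow(ct))
            cluster_rows[[key]] <- cbind(metric = key, ct)
          utils::write.csv(
            data.frame(subject = rep(rownames(M), ncol(M)),
                       channel = rep(colnames(M), each = nrow(M)),
                       value = as.vector(M)),
            file.path(out_dir, paste0("topo_", key, ".csv")), row.names = FALSE)
        }
      }
    }
  }
  cl <- if (length(cluster_rows)) do.call(rbind, cluster_rows) else
    data.frame(metric = character(), cluster_id = integer(),
               channels = character(), n_channels = integer(),
               sign = numeric(), stat = numeric(), p = numeric())
  utils::write.csv(cl, file.path(out_dir, "cluster_report.csv"),
                   row.names = FALSE)
  report$cluster_table <- cl
  invisible(report)
}

#' Write a synthetic cohort fixture to disk
#'
#' Generates a two-group cohort and writes, per subject, an EDF recording, a
#' hypnogram CSV and a ground-truth event table under
#' `out_dir/cohort/<group>/<id>/`, plus `montage.json`, `manifest.csv` and a
#' ready-to-run `config.yaml` for [run_study()].
#'
#' @param out_dir output directory (must be empty unless `force`).
#' @param preset `"tiny"` (4+4 subjects, 8 channels, 30 min) or
#'   `"paperlike"` (16+16 subjects, 64 channels, 360 min).
#' @param seed master seed.
#' @param effect a [cohort_effect()].
#' @param force overwrite an existing non-empty directory.
#' @return Path to the written config, invisibly.
#' @export
make_fixture <- function(out_dir, preset = c("tiny", "paperlike"), seed = 1,
                         effect = cohort_effect(), force = FALSE) {
  preset <- match.arg(preset)
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stopf("directory %s is not empty (use force = TRUE)", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ps <- switch(preset,
    tiny = list(n = 4L, nch = 8L, mins = 30),
    paperlike = list(n = 16L, nch = 64L, mins = 360))
  cfg <- synth_config(n_channels = ps$nch)
  mon <- make_montage(ps$nch)
  # short records: allow sleep to appear quickly
  prof <- if (ps$mins < 60)
    stage_profile(sleep_latency_min = 2, rem_latency_min = 15)
  else stage_profile()
  man <- cohort_manifest(ps$n, seed)
  write_montage(mon, file.path(out_dir, "montage.json"))
  rows <- list()
  for (i in seq_len(nrow(man))) {
    sub <- cohort_subject(man, i, effect, ps$mins, mon, cfg, prof)
    d <- file.path(out_dir, "cohort", sub$group, sub$id)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_recording(sub$recording, file.path(d, "recording.edf"))
    write_hypnogram(sub$hypnogram, file.path(d, "hypnogram.csv"))
    tr <- sub$truth
    tr_ev <- tr[tr$kind != "artifact" & tr$start_s < tr$end_s, , drop = FALSE]
    if (nrow(tr_ev)) {
      base <- tr_ev[, c("channel", "start_s", "end_s")]
      base$amp <- tr_ev$amp; base$freq <- tr_ev$freq
      long <- rbind(events_to_table(base[tr_ev$kind == "spindle", ],
                                    sub$id, "spindle"),
                    events_to_table(base[tr_ev$kind == "slow_wave", ],
                                    sub$id, "slow_wave"))
      write_event_table(long, file.path(d, "truth.csv"))
    }
    rows[[i]] <- data.frame(id = sub$id, group = sub$group,
                            recording = file.path(d, "recording.edf"),
                            hypnogram = file.path(d, "hypnogram.csv"))
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  study <- list(
    subjects = lapply(seq_len(nrow(manifest)), function(i) as.list(manifest[i, ])),
    montage = file.path(out_dir, "montage.json"),
    out_dir = file.path(out_dir, "results"),
    stats = list(n_perm = 1024L, seed = seed))
  yaml::write_yaml(study, file.path(out_dir, "config.yaml"))
  invisible(file.path(out_dir, "config.yaml"))
}
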