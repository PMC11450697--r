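# Pipeline configuration and orchestration: synthetic study (or EDF inputs)
# -> preprocessing -> wavelet TFR -> cluster ImCoh -> long trial table,
# peak-beta records, connectivity-change maps and cluster permutation tests.

#' Pipeline configuration
#'
#' Collects every stage parameter with defaults fixed to the analysis
#' constants of the protocol: 0.5-95 Hz band-pass with a 50 Hz notch,
#' 500 Hz target rate, 2 s resting epochs, -2500 to 4500 ms event epochs,
#' 4-90 Hz wavelets with 3-13 cycles on a 20 ms grid, theta/alpha/beta/gamma
#' bands, -2000 to -1000 ms baseline, movement periods -500-0, 0-500 and
#' 1500-4000 ms, cluster-forming alpha 0.05 and a 97.5th-percentile
#' max-cluster rule.
#'
#' @param design A [study_design()] describing the synthetic study, or
#'   `NULL` when `edf_manifest` is supplied.
#' @param edf_manifest Optional data.frame with columns `path`,
#'   `participant`, `intensity`, `timepoint`, `mode` pointing at EDF+ files.
#' @param ... Overrides for any default listed by `pipeline_defaults()`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(design = NULL, edf_manifest = NULL, ...) {
  cfg <- utils::modifyList(pipeline_defaults(), list(...))
  unknown <- setdiff(names(list(...)), names(pipeline_defaults()))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg$design <- design
  cfg$edf_manifest <- edf_manifest
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
pipeline_defaults <- function() {
  list(
    filter_low = 0.5, filter_high = 95, notch = 50,
    target_rate = 500,
    resting_len_ms = 2000, event_window = c(-2500, 4500),
    force_threshold = 0.1, refractory_ms = 2000,
    ptp_limit = 200, min_trials = 20,
    fmin = 4, fmax = 90, fstep = 1, cycles_min = 3, cycles_max = 13,
    grid_step_ms = 20,
    baseline = c(-2000, -1000),
    bands = imcoh_bands(), periods = imcoh_periods(),
    stim_hz = 20,
    alpha = 0.05, percentile = 97.5, n_perm = 1000,
    seed = 1L)
}

validate_config <- function(cfg) {
  chk <- function(ok, key, msg) {
    if (!ok) stop(sprintf("invalid config key `%s`: %s", key, msg),
                  call. = FALSE)
  }
  chk(is.null(cfg$design) || inherits(cfg$design, "study_design"),
      "design", "must be a study_design or NULL")
  if (!is.null(cfg$edf_manifest)) {
    need <- c("path", "participant", "intensity", "timepoint", "mode")
    chk(is.data.frame(cfg$edf_manifest) &&
          all(need %in% names(cfg$edf_manifest)),
        "edf_manifest", paste("needs columns", paste(need, collapse = ", ")))
  }
  chk(!is.null(cfg$design) || !is.null(cfg$edf_manifest), "design",
      "either a design or an edf_manifest is required")
  chk(cfg$filter_low > 0 && cfg$filter_high > cfg$filter_low,
      "filter_low/filter_high", "need 0 < low < high")
  chk(cfg$target_rate > 2 * cfg$filter_high, "target_rate",
      "must exceed twice the upper band edge")
  known_bands <- names(imcoh_bands())
  chk(all(names(cfg$bands) %in% known_bands) && length(cfg$bands) > 0L,
      "bands", paste("band names must be among",
                     paste(known_bands, collapse = ", ")))
  chk(all(names(cfg$periods) %in% names(imcoh_periods())), "periods",
      "unknown period name")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha", "must be in (0, 1)")
  chk(cfg$n_perm >= 100, "n_perm", "must be >= 100")
  chk(cfg$fmin > 0 && cfg$fmax > cfg$fmin, "fmin/fmax", "need 0 < fmin < fmax")
  invisible(cfg)
}

# preprocess one recording end to end; returns eeg_epochs
preprocess_recording <- function(rec, mode, cfg) {
  rec <- bandpass_notch(rec, cfg$filter_low, cfg$filter_high, cfg$notch)
  rec <- resample_recording(rec, cfg$target_rate)
  onsets <- NULL
  if (mode == "event") {
    onsets <- if (!is.null(rec$force)) {
      detect_onsets(rec$force, cfg$force_threshold, rec$rate,
                    cfg$refractory_ms)
    } else {
      as.integer(round(rec$onsets * rec$rate)) + 1L
    }
  }
  ep <- epoch_recording(rec, mode, onsets = onsets,
                        resting_len_ms = cfg$resting_len_ms,
                        event_window = cfg$event_window)
  reject_and_reference(ep, cfg$ptp_limit, cfg$min_trials)
}

# long-format rows for one resting-state TFR
resting_trial_rows <- function(tfr, cfg, clusters) {
  vals <- cluster_imcoh(tfr, clusters$C3, clusters$C4, "within",
                        window = NULL)
  rows <- list()
  for (b in names(cfg$bands)) {
    v <- band_period_average(vals, cfg$bands[[b]])
    rows[[b]] <- data.frame(tfr$trial_meta,
                            band = b, period = "resting", value = v,
                            row.names = NULL)
  }
  do.call(rbind, rows)
}

# within-trial per-period values (baseline-subtracted per trial and
# frequency) for one event-related TFR; returns list(table, peaks)
event_trial_rows <- function(tfr, cfg, clusters) {
  base_vals <- cluster_imcoh(tfr, clusters$C3, clusters$C4, "within",
                             window = c(cfg$baseline[1L],
                                        cfg$baseline[2L] + cfg$grid_step_ms))
  rows <- list(); peaks <- list()
  period_names <- setdiff(names(cfg$periods), "resting")
  for (pd in period_names) {
    pv <- cluster_imcoh(tfr, clusters$C3, clusters$C4, "within",
                        window = cfg$periods[[pd]])
    dv <- pv - base_vals                 # per (trial, frequency)
    attr(dv, "freqs") <- tfr$freqs
    for (b in names(cfg$bands)) {
      v <- band_period_average(dv, cfg$bands[[b]])
      rows[[paste(pd, b)]] <- data.frame(tfr$trial_meta,
                                         band = b, period = pd, value = v,
                                         row.names = NULL)
    }
    pk <- apply(dv, 1L, peak_beta, freqs = tfr$freqs,
                band = cfg$bands$beta %||% c(13, 30))
    peaks[[pd]] <- data.frame(tfr$trial_meta, period = pd, peak_hz = pk,
                              diff_hz = endo_exo_diff(pk, cfg$stim_hz),
                              row.names = NULL)
  }
  list(table = do.call(rbind, rows), peaks = do.call(rbind, peaks))
}

#' Run the full connectivity pipeline
#'
#' Executes, in order: synthetic-study generation (or EDF reading),
#' preprocessing (filter, resample, epoch, reject, re-reference), wavelet
#' decomposition, cluster-pair ImCoh estimation (across-trial maps and
#' within-trial trial-level values), band/period aggregation into a
#' long-format trial table, per-trial peak-beta extraction,
#' connectivity-change (percent change between time points) maps, and --
#' when at least 4 participants are available -- cluster-based permutation
#' correlation tests per intensity, period and time-point pair.
#'
#' All artifacts are written under `out_dir`: `trial_table.csv`,
#' `peak_beta.csv`, `rejection_report.csv`, `cluster_results.json`,
#' `config.json`, `log.txt` and per-recording ImCoh maps under `maps/`
#' (RDS). Given the same configuration (which embeds every seed), the
#' CSV/JSON outputs are byte-identical across runs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the trial table, peak table, maps, and
#'   cluster test results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
  log_lines <- character(0)
  log_add <- function(...) log_lines <<- c(log_lines, sprintf(...))

  clusters <- default_clusters()
  bank <- build_wavelet_bank(config$fmin, config$fmax, config$fstep,
                             config$cycles_min, config$cycles_max)

  if (!is.null(config$design)) {
    study <- generate_study(config$design, materialize = FALSE)
    manifest <- study$manifest
    loader <- function(row) study$realize(row)
  } else {
    manifest <- config$edf_manifest
    manifest$id <- sprintf("p%02d_%s_%s_%s", manifest$participant,
                           manifest$intensity, manifest$timepoint,
                           manifest$mode)
    loader <- function(row) {
      rec <- read_edf(manifest$path[row])
      rec$meta <- list(participant = manifest$participant[row],
                       intensity = manifest$intensity[row],
                       timepoint = manifest$timepoint[row])
      rec
    }
  }

  trial_rows <- list(); peak_rows <- list(); reject_rows <- list()
  maps <- list()
  log_add("pipeline start: %d recordings", nrow(manifest))
  for (row in seq_len(nrow(manifest))) {
    id <- manifest$id[row]
    mode <- manifest$mode[row]
    rec <- loader(row)
    ep <- withCallingHandlers(
      preprocess_recording(rec, mode, config),
      imcoh_participant_excluded = function(w) {
        log_add("%s: %s", id, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    reject_rows[[id]] <- data.frame(
      id = id, trial = seq_along(ep$rejected), rejected = ep$rejected,
      reason = ep$reject_reason, row.names = NULL)
    if (isTRUE(attr(ep, "excluded"))) {
      log_add("%s: excluded (insufficient surviving trials)", id)
      next
    }
    ep <- select_channels(ep, c(clusters$C3$members, clusters$C4$members))
    if (mode == "resting") {
      tfr <- tfr_transform(ep, bank,
                           tfr_grid("resting", config$grid_step_ms))
      trial_rows[[id]] <- resting_trial_rows(tfr, config, clusters)
      map <- cluster_imcoh(tfr, clusters$C3, clusters$C4, "across")
    } else {
      tfr <- tfr_transform(ep, bank,
                           tfr_grid("event_full", config$grid_step_ms))
      res <- event_trial_rows(tfr, config, clusters)
      trial_rows[[id]] <- res$table
      peak_rows[[id]] <- res$peaks
      map <- cluster_imcoh(tfr, clusters$C3, clusters$C4, "across")
    }
    maps[[id]] <- map
    saveRDS(map, file.path(out_dir, "maps", paste0(id, ".rds")))
    log_add("%s: %d trials -> ok", id, dim(tfr$values)[1L])
  }

  trial_table <- do.call(rbind, unname(trial_rows))
  peak_table <- do.call(rbind, unname(peak_rows))
  reject_table <- do.call(rbind, unname(reject_rows))

  cluster_results <- run_cluster_stage(manifest, maps, peak_table, config,
                                       log_add)

  utils::write.csv(trial_table, file.path(out_dir, "trial_table.csv"),
                   row.names = FALSE)
  if (!is.null(peak_table)) {
    utils::write.csv(peak_table, file.path(out_dir, "peak_beta.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(reject_table, file.path(out_dir, "rejection_report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cluster_results_json(cluster_results),
                       file.path(out_dir, "cluster_results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(config_json(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(trial_table = trial_table, peak_table = peak_table,
                 reject_table = reject_table, maps = maps,
                 cluster_results = cluster_results, log = log_lines))
}

# percent-change maps between time points and permutation tests per
# intensity x period x timepoint pair, when enough participants survive.
run_cluster_stage <- function(manifest, maps, peak_table, config, log_add) {
  ev <- manifest[manifest$mode == "event", , drop = FALSE]
  participants <- sort(unique(ev$participant))
  if (length(participants) < 4L || is.null(peak_table)) {
    log_add("cluster stage skipped: %d participants (< 4) with event data",
            length(participants))
    return(list())
  }
  tps <- unique(ev$timepoint)
  pairs <- list()
  if (all(c("pre", "post1") %in% tps)) pairs$pre_post1 <- c("pre", "post1")
  if (all(c("pre", "post2") %in% tps)) pairs$pre_post2 <- c("pre", "post2")
  if (all(c("post1", "post2") %in% tps)) {
    pairs$post1_post2 <- c("post1", "post2")
  }
  out <- list()
  periods <- setdiff(names(config$periods), "resting")
  for (intensity in unique(ev$intensity)) {
    for (pd in periods) {
      # pre-stimulation trial-averaged endo-exo difference per participant
      sel <- peak_table$intensity == intensity &
        peak_table$timepoint == "pre" & peak_table$period == pd
      if (!any(sel)) next
      diffs <- tapply(peak_table$diff_hz[sel], peak_table$participant[sel],
                      mean)
      for (pr in names(pairs)) {
        tp <- pairs[[pr]]
        subj <- intersect(names(diffs), as.character(participants))
        arr <- NULL
        keep <- character(0)
        for (s in subj) {
          id_a <- sprintf("p%02d_%s_%s_event", as.integer(s), intensity,
                          tp[1L])
          id_b <- sprintf("p%02d_%s_%s_event", as.integer(s), intensity,
                          tp[2L])
          if (is.null(maps[[id_a]]) || is.null(maps[[id_b]])) next
          a <- crop_map(maps[[id_a]], config$periods[[pd]])
          b <- crop_map(maps[[id_b]], config$periods[[pd]])
          dm <- suppressWarnings(percent_change(a$values, b$values))
          if (is.null(arr)) {
            arr <- array(NA_real_, dim = c(length(subj), nrow(dm), ncol(dm)))
          }
          keep <- c(keep, s)
          arr[length(keep), , ] <- dm
        }
        if (length(keep) < 4L) {
          log_add("cluster test %s/%s/%s skipped: %d complete subjects",
                  intensity, pd, pr, length(keep))
          next
        }
        arr <- arr[seq_along(keep), , , drop = FALSE]
        dimnames(arr) <- list(keep, NULL, NULL)
        d <- diffs[keep]; names(d) <- keep
        res <- permutation_test(d, arr, n_perm = config$n_perm,
                                alpha = config$alpha,
                                percentile = config$percentile,
                                seed = config$seed)
        out[[sprintf("%s.%s.%s", intensity, pd, pr)]] <- res
        log_add("cluster test %s/%s/%s: %d clusters, %d significant",
                intensity, pd, pr, length(res$clusters),
                sum(vapply(res$clusters, `[[`, logical(1), "significant")))
      }
    }
  }
  out
}

cluster_results_json <- function(results) {
  lapply(results, function(r) {
    list(n = r$n, n_perm = r$n_perm, alpha = r$alpha, seed = r$seed,
         threshold = r$threshold,
         null_summary = list(mean = mean(r$null), max = max(r$null)),
         clusters = lapply(r$clusters, function(cl) {
           list(sign = cl$sign, n_cells = nrow(cl$cells), mass = cl$mass,
                p_perm = cl$p_perm, significant = cl$significant,
                cells = cl$cells)
         }))
  })
}

config_json <- function(config) {
  cfg <- unclass(config)
  cfg$edf_manifest <- NULL
  if (!is.null(cfg$design)) {
    d <- unclass(cfg$design)
    d$effect_map <- as.data.frame(d$effect_map)
    cfg$design <- d
  }
  cfg
}
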