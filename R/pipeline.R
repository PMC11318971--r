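#' Pipeline run configuration
#'
#' Collects every analysis constant in one auditable place. The configuration
#' is serialised verbatim into each output directory.
#'
#' @param input_dir Directory with `spikes.tsv`, `events.tsv`, `trials.tsv`
#'   (and optionally `tracking.tsv`); alternative to `synthetic`.
#' @param synthetic A [synthetic_config()]; alternative to `input_dir`.
#' @param threat_kind `"robot"` or `"stim"` (ignored for synthetic input,
#'   which knows its own).
#' @param z_threshold,n_test_bins,bin_width,window,baseline PETH and
#'   classification settings.
#' @param exclusivity Robot-cell exclusivity rule, see
#'   [classify_event_response()].
#' @param cc_bin,cc_lag_range,cc_test_window,cc_null,n_shuffles,epoch_window,auc_per_event
#'   Synchrony settings, see [epoch_cc_table()].
#' @param min_rate Rate filter (Hz).
#' @param speed_bin_width,alpha Speed-screen settings.
#' @param seed Root seed for all stochastic stages.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir = NULL, synthetic = NULL,
                       threat_kind = "robot", z_threshold = 3,
                       n_test_bins = 5, bin_width = 0.1, window = c(-5, 5),
                       baseline = c(-5, 0), exclusivity = "both",
                       cc_bin = 0.01, cc_lag_range = c(-0.5, 0.5),
                       cc_test_window = c(0, 0.1), cc_null = "shuffle",
                       n_shuffles = 100,
                       epoch_window = c(0, 2), auc_per_event = TRUE,
                       min_rate = 0.1, speed_bin_width = 1, alpha = 0.05,
                       seed = 1) {
  for (v in c("z_threshold", "n_test_bins", "bin_width", "cc_bin",
              "n_shuffles", "min_rate", "speed_bin_width", "alpha")) {
    val <- get(v)
    if (!is.numeric(val) || val <= 0) {
      abort(sprintf("Config threshold `%s` must be positive.", v))
    }
  }
  structure(
    list(input_dir = input_dir, synthetic = synthetic,
         threat_kind = threat_kind, z_threshold = z_threshold,
         n_test_bins = n_test_bins, bin_width = bin_width, window = window,
         baseline = baseline, exclusivity = exclusivity, cc_bin = cc_bin,
         cc_lag_range = cc_lag_range, cc_test_window = cc_test_window,
         cc_null = cc_null, n_shuffles = n_shuffles,
         epoch_window = epoch_window,
         auc_per_event = auc_per_event, min_rate = min_rate,
         speed_bin_width = speed_bin_width, alpha = alpha, seed = seed),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes session assembly (reading tables or simulating them), trial
#' exclusions, the rate filter, per-unit classification, pairwise synchrony,
#' and the behavioural metrics, writing `units_classified.tsv`, `pairs.tsv`,
#' `behavior.tsv`, `summary.txt`, the verbatim `config.yaml`, and `log.txt`
#' (seed, config hash, per-stage timings) into `out_dir`. Runs are
#' deterministic given `(inputs, config, seed)`. A failing stage aborts with
#' the stage name and leaves an `INCOMPLETE` marker.
#'
#' @param config A [run_config()] (or a YAML path readable by
#'   [read_run_config()]).
#' @param out_dir Output directory.
#' @param seed Root seed; defaults to the config's.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- seed %||% config$seed
  if (is.null(config$input_dir) && is.null(config$synthetic)) {
    abort("Configuration error: supply either `input_dir` or a `synthetic` spec.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  file.create(file.path(out_dir, "INCOMPLETE"))
  timings <- list()
  stage <- function(name, code) {
    t0 <- Sys.time()
    out <- tryCatch(force(code), error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }

  session <- stage("data_model", {
    s <- if (!is.null(config$input_dir)) {
      read_session(config$input_dir, threat_kind = config$threat_kind,
                   config = unclass(config))
    } else {
      simulate_session(config$synthetic, seed = derive_seed(seed, 100))$session
    }
    s <- apply_trial_exclusions(s)
    filter_low_rate_units(s, config$min_rate)
  })

  units <- stage("classification", {
    classify_units(session, window = config$window,
                   bin_width = config$bin_width, baseline = config$baseline,
                   n_test_bins = config$n_test_bins,
                   z_threshold = config$z_threshold,
                   exclusivity = config$exclusivity,
                   speed_bin_width = config$speed_bin_width,
                   alpha = config$alpha)
  })
  readr::write_tsv(units, file.path(out_dir, "units_classified.tsv"),
                   progress = FALSE)

  pairs <- stage("synchrony", {
    epoch_cc_table(session, units, epoch_window = config$epoch_window,
                   lag_range = config$cc_lag_range, bin = config$cc_bin,
                   n_shuffles = config$n_shuffles,
                   test_window = config$cc_test_window,
                   z_threshold = config$z_threshold,
                   cc_null = config$cc_null,
                   min_rate = config$min_rate,
                   auc_per_event = config$auc_per_event,
                   seed = derive_seed(seed, 200))
  })
  readr::write_tsv(pairs, file.path(out_dir, "pairs.tsv"), progress = FALSE)

  behavior <- stage("behavior", {
    if (is.null(session$tracking)) {
      tibble(trial_index = integer(), phase = character(),
             outbound_time_s = numeric(), at_cap = logical(),
             outcome = character(), excluded = logical())
    } else {
      session_behavior(session)
    }
  })
  readr::write_tsv(behavior, file.path(out_dir, "behavior.tsv"),
                   progress = FALSE)

  stage("report", {
    cfg_path <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(serializable_config(config), cfg_path)
    writeLines(render_summary(session, units, pairs, behavior),
               file.path(out_dir, "summary.txt"))
    writeLines(c(
      sprintf("seed: %d", seed),
      sprintf("config_md5: %s", unname(tools::md5sum(cfg_path))),
      sprintf("timing_%s_s: %.3f", names(timings), unlist(timings))
    ), file.path(out_dir, "log.txt"))
  })
  file.remove(file.path(out_dir, "INCOMPLETE"))
  invisible(out_dir)
}

serializable_config <- function(config) {
  out <- unclass(config)
  if (!is.null(out$synthetic)) {
    out$synthetic$units <- lapply(out$synthetic$units, function(u) {
      c(u[setdiff(names(u), "profile")], unclass(u$profile))
    })
    out$synthetic$pairs <- lapply(out$synthetic$pairs, function(p) {
      c(p[setdiff(names(p), "coupling")], unclass(p$coupling))
    })
    out$synthetic$n_trials <- as.list(out$synthetic$n_trials)
  }
  out
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with [run_config()] fields; `synthetic` blocks are
#'   reassembled into [synthetic_config()], `response_profile()` and
#'   [pair_coupling()] objects.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synthetic)) {
    syn <- raw$synthetic
    syn$n_trials <- unlist(syn$n_trials)
    syn$units <- lapply(syn$units %||% list(), function(u) {
      list(n = u$n, region = u$region %||% "BLA", speed_b = u$speed_b %||% 0,
           profile = response_profile(
             baseline_rate = u$baseline_rate, amplitude = u$amplitude %||% 0,
             onset_latency = u$onset_latency %||% 0.05,
             duration = u$duration %||% 0.3,
             kernel = u$kernel %||% "exp_decay",
             phase_mask = unlist(u$phase_mask) %||% character()
           ))
    })
    syn$pairs <- lapply(syn$pairs %||% list(), function(p) {
      list(n = p$n, rate = p$rate %||% 5,
           coupling = pair_coupling(
             p_share = p$p_share, lag = p$lag %||% 0,
             jitter_sd = p$jitter_sd %||% 0,
             epoch_mask = unlist(p$epoch_mask) %||% "post_robot_surge"
           ))
    })
    raw$synthetic <- do.call(synthetic_config, syn[intersect(
      names(syn), names(formals(synthetic_config)))])
  }
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

render_summary <- function(session, units, pairs, behavior) {
  lines <- c(sprintf("Session %s (threat = %s): %d units, %d trials (%d excluded)",
                     session$session_id, session$threat_kind, nrow(units),
                     nrow(session$trials), sum(session$trials$excluded)))
  if (nrow(units) == 0) {
    return(c(lines, "No units; nothing to summarise."))
  }
  pop <- population_summary(units)
  lines <- c(lines, "", "Unit labels (classifiable units):",
             sprintf("  %-10s %4d  (%.1f%%)", pop$proportions$label,
                     pop$proportions$n, pop$proportions$pct),
             sprintf("  non-classifiable: %d",
                     pop$n_units - pop$n_classifiable))
  if (!is.null(pop$contingency)) {
    tab <- pop$contingency
    lines <- c(lines, "", "Robot x stim contingency:",
               sprintf("  %-10s stim %4d  non_stim %4d", rownames(tab),
                       tab[, "stim"], tab[, "non_stim"]))
    if (!is.null(pop$chisq)) {
      lines <- c(lines, sprintf("  chi-square = %.3f, p = %.4g",
                                pop$chisq$statistic, pop$chisq$p.value))
    }
  }
  if (nrow(pairs) > 0) {
    sync <- pairs %>%
      group_by(.data$epoch) %>%
      summarise(n_pairs = dplyr::n_distinct(.data$pair_id),
                n_significant = sum(.data$significant, na.rm = TRUE),
                mean_auc_0_100 = mean(.data$auc_0_100, na.rm = TRUE))
    lines <- c(lines, "", "Synchrony by epoch:",
               sprintf("  %-18s %3d pairs, %3d significant, mean AUC[0,100ms] %.4g",
                       sync$epoch, sync$n_pairs, sync$n_significant,
                       sync$mean_auc_0_100))
  }
  if (nrow(behavior) > 0) {
    sr <- success_rate(behavior %>%
                         select("trial_index", "phase", "outcome", "excluded"))
    ot <- behavior %>%
      filter(!.data$excluded) %>%
      group_by(.data$phase) %>%
      summarise(median_outbound_s = median(.data$outbound_time_s, na.rm = TRUE))
    beh <- left_join(sr, ot, by = "phase")
    lines <- c(lines, "", "Behaviour by phase:",
               sprintf("  %-7s %2d trials, success %5.1f%%, median outbound %.2f s",
                       beh$phase, beh$n_trials, beh$success_pct,
                       beh$median_outbound_s))
  }
  lines
}

#' Summarise a completed pipeline run
#'
#' Re-reads the output tables of [run_pipeline()] and returns the per-label
#' proportions, per-epoch synchrony, and per-phase behaviour as tibbles plus
#' the rendered report text. Re-running on the same outputs yields an
#' identical report.
#'
#' @param run_dir A directory written by [run_pipeline()].
#' @return List with `units`, `proportions`, `pairs_by_epoch`,
#'   `behavior_by_phase`, and `text`.
#' @export
summarize_run <- function(run_dir) {
  if (file.exists(file.path(run_dir, "INCOMPLETE"))) {
    warn("Run directory is marked INCOMPLETE.")
  }
  units <- readr::read_tsv(file.path(run_dir, "units_classified.tsv"),
                           show_col_types = FALSE)
  pairs <- readr::read_tsv(file.path(run_dir, "pairs.tsv"),
                           show_col_types = FALSE)
  behavior <- readr::read_tsv(file.path(run_dir, "behavior.tsv"),
                              show_col_types = FALSE)
  proportions <- if (nrow(units) > 0) population_summary(units)$proportions else NULL
  pairs_by_epoch <- if (nrow(pairs) > 0) {
    pairs %>%
      group_by(.data$epoch, .data$category) %>%
      summarise(n_pairs = dplyr::n_distinct(.data$pair_id),
                n_significant = sum(.data$significant, na.rm = TRUE),
                mean_auc_0_100 = mean(.data$auc_0_100, na.rm = TRUE),
                mean_auc_0_50 = mean(.data$auc_0_50, na.rm = TRUE),
                mean_auc_50_100 = mean(.data$auc_50_100, na.rm = TRUE),
                .groups = "drop")
  } else {
    NULL
  }
  behavior_by_phase <- if (nrow(behavior) > 0) success_rate(behavior) else NULL
  list(
    units = units,
    proportions = proportions,
    pairs_by_epoch = pairs_by_epoch,
    behavior_by_phase = behavior_by_phase,
    text = readLines(file.path(run_dir, "summary.txt"))
  )
}
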