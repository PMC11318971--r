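#' Assemble a recording session
#'
#' Bundles the four tables of one recording day — spikes, behavioural events,
#' trials, and (optionally) position tracking — into a validated
#' `forage_session` object. A day has successive pre, threat, and post
#' sessions (the threat session is either a robot-predator or an optogenetic
#' stimulation session), optionally followed by an extra robot session on
#' combined stimulation + robot days (phase `"robot"`).
#'
#' @param spikes Tibble with columns `unit_id`, `region`, `time_s`.
#' @param events Tibble with columns `kind`, `trial_index`, `time_s`.
#' @param trials Tibble with columns `trial_index`, `phase`,
#'   `gate_open_time`, `outcome` and optionally `excluded`,
#'   `exclusion_reason`.
#' @param tracking Optional tracking tibble (`t`, `x`, `y`).
#' @param session_id,rat_id Identifiers carried into every output table.
#' @param threat_kind `"robot"` or `"stim"`: what the threat session's
#'   alignment event is.
#' @param config Named list of analysis settings, stored verbatim.
#' @return A `forage_session` object (a list with class
#'   `"forage_session"`).
#' @export
forage_session <- function(spikes, events, trials, tracking = NULL,
                           session_id = "session", rat_id = NA_character_,
                           threat_kind = c("robot", "stim"), config = list()) {
  threat_kind <- match.arg(threat_kind)
  spikes <- validate_spikes(as_tibble(spikes))
  events <- arrange(as_tibble(events), .data$kind, .data$time_s)
  trials <- arrange(as_tibble(trials), .data$trial_index)
  if (!"excluded" %in% names(trials)) trials$excluded <- FALSE
  if (!"exclusion_reason" %in% names(trials)) trials$exclusion_reason <- ""

  if (any(trials$excluded & !nzchar(trials$exclusion_reason))) {
    abort("Excluded trials must carry a non-empty `exclusion_reason`.")
  }
  phase_rank <- match(trials$phase, PHASES)
  if (anyNA(phase_rank)) {
    abort(sprintf("Unknown phase; allowed: %s", paste(PHASES, collapse = ", ")))
  }
  ord <- order(trials$gate_open_time)
  if (is.unsorted(phase_rank[ord])) {
    abort("Trial phases must be ordered pre < threat < post (< robot) in time.")
  }
  bad_trial <- setdiff(unique(events$trial_index), trials$trial_index)
  if (length(bad_trial) > 0) {
    abort(sprintf("Events reference unknown trial_index %s", bad_trial[1]))
  }
  t_end <- max(c(spikes$time_s, events$time_s, trials$gate_open_time,
                 if (!is.null(tracking)) tracking$t else numeric(0)), 0)
  if (any(events$time_s < 0) || any(events$time_s > t_end)) {
    abort("Event times must lie within [0, session end].")
  }
  if (!is.null(tracking)) {
    tracking <- validate_tracking(as_tibble(tracking))
  }
  structure(
    list(
      session_id = session_id,
      rat_id = rat_id,
      threat_kind = threat_kind,
      spikes = spikes,
      events = events,
      trials = trials,
      tracking = tracking,
      t_end = t_end,
      units = unit_table(spikes, t_end),
      config = config
    ),
    class = "forage_session"
  )
}

unit_table <- function(spikes, duration) {
  spikes %>%
    group_by(.data$unit_id, .data$region) %>%
    summarise(n_spikes = n(), .groups = "drop") %>%
    mutate(rate_hz = .data$n_spikes / duration)
}

#' @export
print.forage_session <- function(x, ...) {
  cat(sprintf("<forage_session> %s (rat %s, threat = %s)\n",
              x$session_id, x$rat_id, x$threat_kind))
  cat(sprintf("  %d units, %d spikes, %d trials (%d excluded), %d events, %.1f s\n",
              nrow(x$units), nrow(x$spikes), nrow(x$trials),
              sum(x$trials$excluded), nrow(x$events), x$t_end))
  if (!is.null(x$tracking)) {
    cat(sprintf("  tracking: %d samples at %.1f Hz\n",
                nrow(x$tracking), tracking_rate(x$tracking)))
  }
  invisible(x)
}

#' Read a session from a directory of tables
#'
#' Expects `spikes.tsv`, `events.tsv`, `trials.tsv` and optionally
#' `tracking.tsv` in `dir` (the layout written by [make_dataset()] and
#' [run_pipeline()]).
#'
#' @param dir Directory holding the tables.
#' @inheritParams forage_session
#' @return A `forage_session`.
#' @export
read_session <- function(dir, session_id = basename(dir),
                         rat_id = NA_character_,
                         threat_kind = c("robot", "stim"), config = list()) {
  tracking_path <- file.path(dir, "tracking.tsv")
  forage_session(
    spikes = read_spike_table(file.path(dir, "spikes.tsv")),
    events = read_event_table(file.path(dir, "events.tsv")),
    trials = read_trial_table(file.path(dir, "trials.tsv")),
    tracking = if (file.exists(tracking_path)) read_tracking(tracking_path) else NULL,
    session_id = session_id, rat_id = rat_id,
    threat_kind = match.arg(threat_kind), config = config
  )
}

#' Write a session's tables to a directory
#'
#' @param session A `forage_session`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_spike_table(session$spikes, file.path(dir, "spikes.tsv"))
  write_event_table(session$events, file.path(dir, "events.tsv"))
  write_trial_table(session$trials, file.path(dir, "trials.tsv"))
  if (!is.null(session$tracking)) {
    write_tracking(session$tracking, file.path(dir, "tracking.tsv"))
  }
  invisible(dir)
}

#' Movement speed from a tracking trace
#'
#' Centred finite-difference speed (one-sided at the two endpoints), smoothed
#' with a centred boxcar. The boxcar length is `smooth_window` rounded to an
#' odd number of samples; at the edges the average runs over the samples
#' available.
#'
#' @param tracking Tracking tibble (`t`, `x`, `y`), uniformly sampled.
#' @param smooth_window Boxcar width in seconds; must be at least one sample
#'   step.
#' @return The input tibble with a `speed` column (cm/s).
#' @export
compute_speed <- function(tracking, smooth_window = 0.5) {
  if (nrow(tracking) < 2) abort("Need >= 2 tracking samples.")
  step <- 1 / tracking_rate(tracking)
  if (smooth_window < step - 1e-12) {
    abort(sprintf("`smooth_window` (%g s) is below the sample step (%g s).",
                  smooth_window, step))
  }
  vx <- centred_diff(tracking$x, step)
  vy <- centred_diff(tracking$y, step)
  speed <- sqrt(vx^2 + vy^2)
  k <- max(1L, round(smooth_window / step))
  if (k %% 2L == 0L) k <- k + 1L
  mutate(tracking, speed = boxcar_mean(speed, k))
}

centred_diff <- function(p, step) {
  n <- length(p)
  d <- numeric(n)
  if (n > 2) d[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (2 * step)
  d[1] <- (p[2] - p[1]) / step
  d[n] <- (p[n] - p[n - 1]) / step
  d
}

boxcar_mean <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Exclude trials around rapid pellet re-attempts
#'
#' A pellet attempt occurring within 10 s (strictly) after a robot activation
#' or stimulation onset contaminates the unit-response windows, so the trial
#' in which it occurs and the following trial are excluded with reason
#' `"reattempt_within_10s"`. An attempt is a `pellet_procurement` or
#' `approach_zone_entry` event. The operation is idempotent.
#'
#' @param session A `forage_session`.
#' @param window_s Exclusion window after the activation (default 10 s;
#'   strict `<`).
#' @return The session with updated `trials$excluded` flags.
#' @export
apply_trial_exclusions <- function(session, window_s = 10) {
  ev <- session$events
  activations <- filter(ev, .data$kind %in% c("robot_activation", "stim_onset"))
  attempts <- filter(ev, .data$kind %in% c("pellet_procurement", "approach_zone_entry"))
  if (nrow(activations) == 0 || nrow(attempts) == 0) {
    return(session)
  }
  hit <- purrr::map_lgl(seq_len(nrow(activations)), function(i) {
    a <- activations$time_s[i]
    any(attempts$time_s > a & attempts$time_s - a < window_s)
  })
  bad_trials <- unique(activations$trial_index[hit])
  if (length(bad_trials) == 0) {
    return(session)
  }
  trials <- session$trials
  idx <- sort(trials$trial_index)
  following <- idx[match(bad_trials, idx) + 1L]
  mark <- trials$trial_index %in% c(bad_trials, following[!is.na(following)])
  trials$excluded[mark] <- TRUE
  trials$exclusion_reason[mark] <- "reattempt_within_10s"
  session$trials <- trials
  session
}

#' Flag units too sparse for cross-correlogram analysis
#'
#' Units firing below `min_rate` over the full recording day produce spurious
#' cross-correlogram peaks and are flagged for exclusion from the synchrony
#' analysis. Spike times are untouched and flagged units remain available to
#' the peri-event classification.
#'
#' @param session A `forage_session`.
#' @param min_rate Minimum overall firing rate in Hz (default 0.1).
#' @return The session with a logical `cc_excluded` column in
#'   `session$units`.
#' @export
filter_low_rate_units <- function(session, min_rate = 0.1) {
  if (session$t_end <= 0) abort("Session duration must be > 0.")
  session$units <- mutate(session$units, cc_excluded = .data$rate_hz < min_rate)
  session
}

# events of one kind restricted to the usable (non-excluded) trials of a phase
phase_events <- function(session, kinds, phases, include_excluded = FALSE) {
  trials <- session$trials
  if (!include_excluded) trials <- filter(trials, !.data$excluded)
  keep <- filter(trials, .data$phase %in% phases)
  session$events %>%
    filter(.data$kind %in% kinds, .data$trial_index %in% keep$trial_index) %>%
    arrange(.data$time_s)
}

# the alignment event kind of a phase: food procurement in pre/post, the
# threat onset (robot surge or light onset) in the threat session
alignment_kind <- function(phase, threat_kind) {
  switch(phase,
    pre = "pellet_procurement",
    post = "pellet_procurement",
    threat = if (threat_kind == "stim") "stim_onset" else "robot_activation",
    robot = "robot_activation",
    abort(sprintf("Unknown phase '%s'", phase))
  )
}

#' Spike times of one unit
#'
#' @param session A `forage_session`.
#' @param unit_id Unit identifier.
#' @return Numeric vector of spike times (s).
#' @export
unit_spikes <- function(session, unit_id) {
  session$spikes$time_s[session$spikes$unit_id == unit_id]
}
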