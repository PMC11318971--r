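#' Arena zone geometry
#'
#' The arena frame puts the nest gate at `x = 0` with the foraging area
#' extending to `x = 202` cm (width 58 cm). The food-approach zone is a 19 cm
#' radius around the pellet; the robot is triggered when the rat comes within
#' ~25 cm of the pellet.
#'
#' @param nest_exit_x Gate x coordinate (cm).
#' @param pellet_xy Pellet position `c(x, y)` in cm.
#' @param approach_radius Food-approach zone radius (cm), default 19.
#' @param trigger_distance Robot-trigger distance from the pellet (cm),
#'   default 25.
#' @param arena_length,arena_width Arena dimensions (cm).
#' @return A `zone_geometry` list.
#' @export
zone_geometry <- function(nest_exit_x = 0, pellet_xy = c(75, 29),
                          approach_radius = 19, trigger_distance = 25,
                          arena_length = 202, arena_width = 58) {
  if (approach_radius <= 0 || trigger_distance <= 0) {
    abort("Zone radii must be > 0.")
  }
  if (pellet_xy[1] < 0 || pellet_xy[1] > arena_length ||
      pellet_xy[2] < 0 || pellet_xy[2] > arena_width) {
    abort("Pellet must lie inside the arena bounds.")
  }
  structure(
    list(nest_exit_x = nest_exit_x, pellet_xy = pellet_xy,
         approach_radius = approach_radius,
         trigger_distance = trigger_distance,
         arena_length = arena_length, arena_width = arena_width),
    class = "zone_geometry"
  )
}

pellet_distance <- function(tracking, geometry) {
  sqrt((tracking$x - geometry$pellet_xy[1])^2 +
         (tracking$y - geometry$pellet_xy[2])^2)
}

#' Outbound foraging time of one trial
#'
#' Latency from gate opening to the first entry into the pellet zone: the
#' robot-trigger distance (~25 cm) in threat trials, the 19 cm food-approach
#' zone otherwise. Trials are capped at 3 minutes; a never-entering trial is
#' reported at the cap and flagged.
#'
#' @param tracking Tracking tibble covering the trial.
#' @param geometry A [zone_geometry()].
#' @param gate_open_time Gate opening time (s).
#' @param cap Trial duration cap (s), default 180.
#' @param zone `"trigger"` (threat trials) or `"approach"`.
#' @param t_stop Optional end of the trial segment (e.g. the next trial's gate
#'   opening); defaults to `gate_open_time + cap`.
#' @return One-row tibble: `outbound_time_s`, `at_cap`, `entered`, and
#'   `gap_flagged` (`TRUE` when a tracking gap spans the detected entry).
#' @export
outbound_foraging_time <- function(tracking, geometry, gate_open_time,
                                   cap = 180, zone = c("trigger", "approach"),
                                   t_stop = NULL) {
  zone <- match.arg(zone)
  radius <- if (zone == "trigger") geometry$trigger_distance else geometry$approach_radius
  t_stop <- min(t_stop %||% Inf, gate_open_time + cap)
  seg <- filter(tracking, .data$t >= gate_open_time, .data$t < t_stop)
  if (nrow(seg) == 0) {
    return(tibble(outbound_time_s = NA_real_, at_cap = TRUE, entered = FALSE,
                  gap_flagged = TRUE))
  }
  inside <- pellet_distance(seg, geometry) <= radius
  i <- which(inside)[1]
  if (is.na(i)) {
    return(tibble(outbound_time_s = cap, at_cap = TRUE, entered = FALSE,
                  gap_flagged = FALSE))
  }
  gap <- if (i > 1) {
    step <- median(diff(seg$t))
    (seg$t[i] - seg$t[i - 1]) > 2 * step
  } else {
    FALSE
  }
  elapsed <- min(seg$t[i] - gate_open_time, cap)
  tibble(outbound_time_s = elapsed, at_cap = elapsed >= cap, entered = TRUE,
         gap_flagged = gap)
}

#' Per-phase pellet success rate
#'
#' @param trials Trial tibble with `phase`, `outcome` and `excluded` columns.
#' @return Tibble with `phase`, `n_trials` (non-excluded), `n_success` and
#'   `success_pct`; phases with no usable trials report `NA` and are flagged.
#' @export
success_rate <- function(trials) {
  phases <- intersect(PHASES, unique(trials$phase))
  purrr::map_dfr(phases, function(p) {
    usable <- filter(trials, .data$phase == p, !.data$excluded)
    tibble(
      phase = p,
      n_trials = nrow(usable),
      n_success = sum(usable$outcome == "success"),
      success_pct = if (nrow(usable) > 0) {
        100 * sum(usable$outcome == "success") / nrow(usable)
      } else {
        NA_real_
      },
      defined = nrow(usable) > 0
    )
  })
}

#' Derive zone-crossing and flee-turn events from tracking
#'
#' Per trial: `approach_zone_entry` is the first crossing into the 19 cm
#' food-approach zone after gate opening; `flee_turn` is the first sample
#' after the trial's robot activation (or stimulation onset) at which the
#' outbound x velocity reverses sign and stays negative for at least
#' `min_reversal_s`. Only first crossings are emitted; trials without a
#' sustained reversal yield no `flee_turn`.
#'
#' @param tracking Tracking tibble.
#' @param trials Trial tibble.
#' @param geometry A [zone_geometry()].
#' @param activations Optional event tibble of `robot_activation`/`stim_onset`
#'   events used to anchor the flee-turn search.
#' @param min_reversal_s Minimum sustained reversal (s), default 0.3.
#' @param smooth_window Speed-smoothing window passed to [compute_speed()].
#' @return Event tibble (`kind`, `trial_index`, `time_s`).
#' @export
derive_zone_events <- function(tracking, trials, geometry, activations = NULL,
                               min_reversal_s = 0.3, smooth_window = 0.5) {
  step <- 1 / tracking_rate(tracking)
  vx <- centred_diff(tracking$x, step)
  dist <- pellet_distance(tracking, geometry)
  trials <- arrange(trials, .data$gate_open_time)
  ends <- c(trials$gate_open_time[-1], Inf)

  rows <- purrr::map(seq_len(nrow(trials)), function(k) {
    in_trial <- tracking$t >= trials$gate_open_time[k] & tracking$t < ends[k]
    out <- list()
    enter <- which(in_trial & dist <= geometry$approach_radius)[1]
    if (!is.na(enter)) {
      out$entry <- tibble(kind = "approach_zone_entry",
                          trial_index = trials$trial_index[k],
                          time_s = tracking$t[enter])
    }
    anchor <- if (!is.null(activations)) {
      a <- filter(activations, .data$trial_index == trials$trial_index[k])
      if (nrow(a) > 0) min(a$time_s) else NA_real_
    } else {
      NA_real_
    }
    if (!is.na(anchor)) {
      need <- max(1L, ceiling(min_reversal_s / step))
      cand <- which(in_trial & tracking$t >= anchor & vx < 0)
      turn <- NA_integer_
      for (i in cand) {
        run <- i + seq_len(need) - 1L
        if (max(run) <= nrow(tracking) && all(vx[run] < 0)) {
          turn <- i
          break
        }
      }
      if (!is.na(turn)) {
        out$turn <- tibble(kind = "flee_turn",
                           trial_index = trials$trial_index[k],
                           time_s = tracking$t[turn])
      }
    }
    bind_rows(out)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    tibble(kind = character(), trial_index = integer(), time_s = numeric())
  } else {
    arrange(out, .data$kind, .data$time_s)
  }
}

#' Behavioural metrics for every trial of a session
#'
#' @param session A `forage_session` with tracking.
#' @param geometry A [zone_geometry()].
#' @param cap Trial cap (s), default 180.
#' @return Tibble with one row per trial: `trial_index`, `phase`,
#'   `outbound_time_s`, `at_cap`, `outcome`, `excluded`.
#' @export
session_behavior <- function(session, geometry = zone_geometry(), cap = 180) {
  if (is.null(session$tracking)) abort("Session has no tracking trace.")
  trials <- arrange(session$trials, .data$gate_open_time)
  ends <- c(trials$gate_open_time[-1], Inf)
  purrr::map_dfr(seq_len(nrow(trials)), function(k) {
    zone <- if (trials$phase[k] %in% c("threat", "robot")) "trigger" else "approach"
    res <- outbound_foraging_time(session$tracking, geometry,
                                  trials$gate_open_time[k], cap, zone,
                                  t_stop = ends[k])
    tibble(
      trial_index = trials$trial_index[k],
      phase = trials$phase[k],
      outbound_time_s = res$outbound_time_s,
      at_cap = res$at_cap,
      outcome = trials$outcome[k],
      excluded = trials$excluded[k]
    )
  })
}
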