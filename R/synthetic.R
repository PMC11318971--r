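#' Event-locked firing-rate response profile
#'
#' Describes the ground-truth response of a synthetic unit: a Poisson
#' background at `baseline_rate` plus an event-locked transient of height
#' `amplitude` starting `onset_latency` after each alignment event of the
#' phases in `phase_mask`. The `boxcar` kernel holds the amplitude for
#' `duration` seconds (closed-form checks); `exp_decay` decays with time
#' constant `duration / 3` and is truncated at `duration`.
#'
#' @param baseline_rate Background rate (Hz), > 0.
#' @param amplitude Transient height (Hz); may be negative (suppression) but
#'   must exceed `-baseline_rate` so the rate stays non-negative.
#' @param onset_latency Response onset after the event (s).
#' @param duration Response duration (s), > 0.
#' @param kernel `"exp_decay"` (default) or `"boxcar"`.
#' @param phase_mask Phases in which the response is active: subset of
#'   `c("pre", "threat", "post", "robot")`.
#' @return A `response_profile` list.
#' @export
response_profile <- function(baseline_rate, amplitude = 0, onset_latency = 0.05,
                             duration = 0.3,
                             kernel = c("exp_decay", "boxcar"),
                             phase_mask = character()) {
  kernel <- match.arg(kernel)
  stopifnot_scalar_number(baseline_rate, "baseline_rate", positive = TRUE)
  stopifnot_scalar_number(duration, "duration", positive = TRUE)
  if (amplitude <= -baseline_rate) {
    abort("`amplitude` must exceed -baseline_rate (rates never negative).")
  }
  if (length(phase_mask) > 0 && !all(phase_mask %in% PHASES)) {
    abort(sprintf("`phase_mask` must be a subset of {%s}.",
                  paste(PHASES, collapse = ", ")))
  }
  structure(
    list(baseline_rate = baseline_rate, amplitude = amplitude,
         onset_latency = onset_latency, duration = duration, kernel = kernel,
         phase_mask = phase_mask),
    class = "response_profile"
  )
}

kernel_fun <- function(kernel, duration) {
  switch(kernel,
    boxcar = function(s) as.numeric(s >= 0 & s < duration),
    exp_decay = function(s) {
      ifelse(s >= 0 & s < duration, exp(-3 * s / duration), 0)
    },
    abort(sprintf("Unknown kernel '%s'", kernel))
  )
}

#' Ground-truth label implied by a response profile
#'
#' The label is a pure function of the profile, mirroring the classifier's
#' semantics: a positive threat-only response is a robot cell, pre-only is a
#' pellet cell, pre + threat is a BOTH cell, a negative threat response is
#' inhibited, anything else (including a flat profile) is none.
#'
#' @param profile A [response_profile()].
#' @return One of `"robot"`, `"pellet"`, `"both"`, `"inhibited"`, `"none"`.
#' @export
profile_label <- function(profile) {
  mask <- profile$phase_mask
  threat <- any(c("threat", "robot") %in% mask)
  if (profile$amplitude == 0 || length(mask) == 0) return("none")
  if (profile$amplitude < 0) return(if (threat) "inhibited" else "none")
  pre <- "pre" %in% mask
  post <- "post" %in% mask
  if (pre && threat) return("both")
  if (pre) return("pellet")
  if (threat && !post) return("robot")
  "none"
}

#' Sample an inhomogeneous Poisson spike train by thinning
#'
#' Candidate spikes are drawn as a homogeneous Poisson process at `rate_max`
#' on `[t0, t1)`; each candidate at time `t` is kept with probability
#' `rate_fn(t) / rate_max`. The result is sorted and lies in `[t0, t1)`.
#'
#' @param rate_fn Vectorised function of time returning the instantaneous
#'   rate (Hz); must not exceed `rate_max` anywhere (checked at every
#'   candidate).
#' @param t0,t1 Interval bounds (s).
#' @param rate_max Majorising rate (Hz), > 0.
#' @param seed Optional seed.
#' @return Sorted numeric vector of spike times.
#' @export
sample_inhomogeneous_poisson <- function(rate_fn, t0, t1, rate_max,
                                         seed = NULL) {
  stopifnot_scalar_number(rate_max, "rate_max", positive = TRUE)
  if (t1 <= t0) return(numeric(0))
  with_seed(seed, {
    n <- rpois(1, rate_max * (t1 - t0))
    if (n == 0) return(numeric(0))
    cand <- sort(runif(n, t0, t1))
    r <- rate_fn(cand)
    if (any(r > rate_max + 1e-9)) {
      abort(sprintf("rate_fn exceeds rate_max (%.4g > %.4g) at t = %.4g.",
                    max(r), rate_max, cand[which.max(r)]))
    }
    cand[runif(n) < pmax(r, 0) / rate_max]
  })
}

# drop spikes closer than the acquisition resolution to their predecessor
enforce_resolution <- function(times) {
  times <- sort(times)
  if (length(times) < 2) return(times)
  keep <- c(TRUE, diff(times) >= TIME_RESOLUTION)
  times[keep]
}

#' Simulate the trial and event schedule of a recording day
#'
#' Successive phases with `n_trials[phase]` trials each. Every trial opens the
#' gate, has an approach-zone entry, and one alignment event (pellet
#' procurement in pre/post; robot activation or stimulation onset in threat).
#' Inter-trial gaps are `iti_min + Exponential(iti_mean - iti_min)`, keeping
#' consecutive alignment events more than 10 s apart so the re-attempt
#' exclusion rule never fires unless injected deliberately.
#'
#' @param n_trials Named vector of trials per phase, e.g.
#'   `c(pre = 10, threat = 10, post = 10)`; a fourth `robot` entry adds the
#'   combined-day robot session. Values outside 5-15 are allowed but warned
#'   about.
#' @param iti_mean,iti_min Inter-trial-interval mean and floor (s);
#'   `iti_mean > iti_min` required.
#' @param threat_kind `"robot"` or `"stim"`.
#' @param t_start Time of the first gate opening (s); must leave room for the
#'   5 s baseline window.
#' @param seed Optional seed.
#' @return List with `trials`, `events`, `threat_kind`, and `t_end`.
#' @export
make_event_schedule <- function(n_trials = c(pre = 10, threat = 10, post = 10),
                                iti_mean = 30, iti_min = 15,
                                threat_kind = c("robot", "stim"),
                                t_start = 20, seed = NULL) {
  threat_kind <- match.arg(threat_kind)
  if (iti_mean <= iti_min) abort("`iti_mean` must exceed `iti_min`.")
  if (is.null(names(n_trials)) || !all(names(n_trials) %in% PHASES)) {
    abort("`n_trials` must be named with phases pre/threat/post (and optionally robot).")
  }
  if (any(n_trials < 5 | n_trials > 15)) {
    warn("Trials per phase outside the typical 5-15 range.")
  }
  with_seed(seed, {
    trials <- list()
    events <- list()
    t <- t_start
    k <- 0L
    for (phase in intersect(PHASES, names(n_trials))) {
      a_kind <- alignment_kind(phase, threat_kind)
      for (j in seq_len(n_trials[[phase]])) {
        k <- k + 1L
        g <- t
        d <- runif(1, 2, 6) # gate-to-alignment latency
        a <- g + d
        trials[[k]] <- tibble(
          trial_index = k, phase = phase, gate_open_time = g,
          outcome = if (phase %in% c("threat", "robot")) "fail" else "success",
          excluded = FALSE, exclusion_reason = ""
        )
        events[[k]] <- tibble(
          kind = c("gate_open", "approach_zone_entry", a_kind),
          trial_index = k,
          time_s = c(g, a - 0.5, a)
        )
        t <- a + 8 + iti_min + rexp(1, 1 / (iti_mean - iti_min))
      }
    }
    list(
      trials = bind_rows(trials),
      events = arrange(bind_rows(events), .data$kind, .data$time_s),
      threat_kind = threat_kind,
      t_end = t + 10
    )
  })
}

schedule_alignment_events <- function(schedule, phases) {
  phases <- intersect(phases, unique(schedule$trials$phase))
  out <- lapply(phases, function(p) {
    kind <- alignment_kind(p, schedule$threat_kind)
    keep <- schedule$trials$trial_index[schedule$trials$phase == p]
    schedule$events$time_s[schedule$events$kind == kind &
                             schedule$events$trial_index %in% keep]
  })
  sort(unlist(out))
}

#' Simulate one unit with a known response profile
#'
#' The unit's rate function is the profile baseline plus the event-locked
#' transient summed over the alignment events of the masked phases (plus an
#' optional additive rate modifier, e.g. speed coupling from
#' [make_speed_trace()]); spikes are drawn with
#' [sample_inhomogeneous_poisson()]. Spikes closer than the 1/32000 s
#' acquisition resolution are collapsed.
#'
#' @param profile A [response_profile()].
#' @param schedule A schedule from [make_event_schedule()].
#' @param rate_modifier Optional vectorised function of time added to the
#'   rate (Hz); negative totals are clamped at zero.
#' @param rate_modifier_max Upper bound of the modifier, used for the
#'   thinning envelope.
#' @param seed Optional seed.
#' @return List with `times` (spike times) and `truth` (one-row tibble:
#'   `label`, `baseline_rate`, `amplitude`).
#' @export
make_unit <- function(profile, schedule, rate_modifier = NULL,
                      rate_modifier_max = 0, seed = NULL) {
  ev <- schedule_alignment_events(schedule, profile$phase_mask)
  kf <- kernel_fun(profile$kernel, profile$duration)
  onset <- profile$onset_latency
  rate_fn <- function(t) {
    r <- rep(profile$baseline_rate, length(t))
    if (length(ev) > 0 && profile$amplitude != 0) {
      idx <- findInterval(t, ev + onset)
      hit <- idx >= 1
      if (any(hit)) {
        s <- t[hit] - (ev[idx[hit]] + onset)
        r[hit] <- r[hit] + profile$amplitude * kf(s)
      }
    }
    if (!is.null(rate_modifier)) r <- r + rate_modifier(t)
    pmax(r, 0)
  }
  rate_max <- profile$baseline_rate + max(profile$amplitude, 0) +
    max(rate_modifier_max, 0)
  times <- with_seed(seed, {
    sample_inhomogeneous_poisson(rate_fn, 0, schedule$t_end, rate_max)
  })
  list(
    times = enforce_resolution(times),
    truth = tibble(label = profile_label(profile),
                   baseline_rate = profile$baseline_rate,
                   amplitude = profile$amplitude)
  )
}

#' Pairwise coupling specification
#'
#' Common-input construction: a mother Poisson train is generated inside the
#' active epochs; a fraction `p_share` of mother spikes is copied into both
#' daughters (the second daughter's copies shifted by `lag` plus Gaussian
#' jitter), and independent spikes top each daughter up to its target rate.
#' The corrected cross-correlogram's expected excess coincidence mass is
#' `p_share * mother rate * active time`.
#'
#' @param p_share Probability that a mother spike is shared, in `[0, 1]`.
#' @param lag Imposed lag (s) of the target relative to the reference.
#' @param jitter_sd Gaussian jitter SD (s) on the target's shared spikes.
#' @param epoch_mask Epochs in which coupling is active: subset of
#'   `c("post_robot_surge", "post_pellet", "post_stim", "all")`.
#' @return A `pair_coupling` list.
#' @export
pair_coupling <- function(p_share, lag = 0, jitter_sd = 0,
                          epoch_mask = "post_robot_surge") {
  if (p_share < 0 || p_share > 1) abort("`p_share` must lie in [0, 1].")
  if (jitter_sd < 0) abort("`jitter_sd` must be >= 0.")
  allowed <- c("post_robot_surge", "post_pellet", "post_stim", "all")
  if (!all(epoch_mask %in% allowed)) {
    abort(sprintf("`epoch_mask` must be a subset of {%s}.",
                  paste(allowed, collapse = ", ")))
  }
  structure(list(p_share = p_share, lag = lag, jitter_sd = jitter_sd,
                 epoch_mask = epoch_mask),
            class = "pair_coupling")
}

epoch_windows <- function(schedule, epoch_mask, epoch_window = c(0, 2)) {
  if ("all" %in% epoch_mask) {
    return(matrix(c(0, schedule$t_end), ncol = 2))
  }
  kinds <- c(post_robot_surge = "robot_activation",
             post_pellet = "pellet_procurement", post_stim = "stim_onset")
  starts <- sort(schedule$events$time_s[schedule$events$kind %in%
                                          kinds[epoch_mask]])
  if (length(starts) == 0) return(matrix(numeric(0), ncol = 2))
  cbind(starts + epoch_window[1], starts + epoch_window[2])
}

sample_poisson_windows <- function(rate, windows) {
  if (rate <= 0 || nrow(windows) == 0) return(numeric(0))
  out <- lapply(seq_len(nrow(windows)), function(i) {
    n <- rpois(1, rate * (windows[i, 2] - windows[i, 1]))
    runif(n, windows[i, 1], windows[i, 2])
  })
  sort(unlist(out))
}

complement_windows <- function(windows, t0, t1) {
  if (nrow(windows) == 0) return(matrix(c(t0, t1), ncol = 2))
  windows <- windows[order(windows[, 1]), , drop = FALSE]
  starts <- c(t0, windows[, 2])
  ends <- c(windows[, 1], t1)
  keep <- ends > starts
  cbind(starts[keep], ends[keep])
}

#' Simulate a synchronised unit pair with known coupling
#'
#' @param schedule A schedule from [make_event_schedule()].
#' @param rate Target firing rate (Hz) of each unit; also the mother rate.
#' @param coupling A [pair_coupling()].
#' @param epoch_window Window (s) after the epoch-defining events in which
#'   coupling is active, default `c(0, 2)`.
#' @param seed Optional seed.
#' @return List with `ref_times`, `target_times`, `n_clipped` (shifted
#'   spikes falling before time zero, removed with a warning), and `truth`
#'   (one-row tibble: `coupled`, `p_share`, `lag_s`, `jitter_sd`).
#' @export
make_pair <- function(schedule, rate = 5, coupling = pair_coupling(0.3, 0.005),
                      epoch_window = c(0, 2), seed = NULL) {
  stopifnot_scalar_number(rate, "rate", positive = TRUE)
  W <- epoch_windows(schedule, coupling$epoch_mask, epoch_window)
  Wc <- complement_windows(W, 0, schedule$t_end)
  res <- with_seed(seed, {
    mother <- sample_poisson_windows(rate, W)
    shared <- mother[runif(length(mother)) < coupling$p_share]
    ref <- c(shared,
             sample_poisson_windows(rate * (1 - coupling$p_share), W),
             sample_poisson_windows(rate, Wc))
    tgt_shared <- shared + coupling$lag +
      if (coupling$jitter_sd > 0) rnorm(length(shared), 0, coupling$jitter_sd) else 0
    tgt <- c(tgt_shared,
             sample_poisson_windows(rate * (1 - coupling$p_share), W),
             sample_poisson_windows(rate, Wc))
    list(ref = ref, tgt = tgt)
  })
  n_clipped <- sum(res$tgt < 0)
  if (n_clipped > 0) {
    warn(sprintf("Removed %d shifted spike(s) falling before time zero.", n_clipped))
  }
  list(
    ref_times = enforce_resolution(res$ref),
    target_times = enforce_resolution(res$tgt[res$tgt >= 0]),
    n_clipped = n_clipped,
    truth = tibble(coupled = coupling$p_share > 0, p_share = coupling$p_share,
                   lag_s = coupling$lag, jitter_sd = coupling$jitter_sd)
  )
}

#' Simulate a tracking trace tied to the trial schedule
#'
#' Piecewise trajectory per trial: nest dwell, a gate crossing, an outbound
#' run reaching the pellet exactly at the trial's alignment time (so per-trial
#' outbound speeds vary with the sampled gate-to-alignment latency), a short
#' pellet dwell on food trials, and a fast return (flee on threat trials).
#' Sampled at `sample_rate` with small positional noise. When `b != 0` the
#' returned `modifier` adds `b * speed(t)` (Hz) to a unit's rate function.
#'
#' @param schedule A schedule from [make_event_schedule()].
#' @param b Speed-coupling coefficient (Hz per cm/s).
#' @param sample_rate Sampling rate (Hz), default 10.
#' @param geometry A [zone_geometry()].
#' @param nest_x Resting x position inside the nest (cm, negative).
#' @param seed Optional seed.
#' @return List with `tracking` (tibble `t`, `x`, `y`), `modifier`
#'   (function of time, identically zero when `b = 0`), and `modifier_max`.
#' @export
make_speed_trace <- function(schedule, b = 0, sample_rate = 10,
                             geometry = zone_geometry(), nest_x = -20,
                             seed = NULL) {
  if (!is.finite(b)) abort("`b` must be finite.")
  trials <- arrange(schedule$trials, .data$gate_open_time)
  align <- vapply(trials$trial_index, function(k) {
    kinds <- c("pellet_procurement", "robot_activation", "stim_onset")
    min(schedule$events$time_s[schedule$events$trial_index == k &
                                 schedule$events$kind %in% kinds])
  }, numeric(1))
  px <- geometry$pellet_xy[1]
  py <- geometry$pellet_xy[2]

  keyt <- 0
  keyx <- nest_x
  for (k in seq_len(nrow(trials))) {
    g <- trials$gate_open_time[k]
    a <- align[k]
    threat <- trials$phase[k] %in% c("threat", "robot")
    ret_speed <- if (threat) 60 else 40
    t_back <- (px - nest_x) / ret_speed
    dwell <- if (threat) 0 else 1
    keyt <- c(keyt, g, g + 1, a, a + dwell, a + dwell + t_back)
    keyx <- c(keyx, nest_x, 0, px, px, nest_x)
  }
  keyt <- c(keyt, schedule$t_end)
  keyx <- c(keyx, nest_x)
  keep <- !duplicated(keyt)
  keyt <- keyt[keep]
  keyx <- keyx[keep]

  with_seed(seed, {
    t <- seq(0, schedule$t_end, by = 1 / sample_rate)
    x <- stats::approx(keyt, keyx, xout = t, rule = 2)$y + rnorm(length(t), 0, 0.05)
    y <- py + rnorm(length(t), 0, 0.05)
    tracking <- tibble(t = t, x = pmin(pmax(x, -57), geometry$arena_length),
                       y = pmin(pmax(y, 0), geometry$arena_width))
    if (b == 0) {
      list(tracking = tracking, modifier = function(tt) rep(0, length(tt)),
           modifier_max = 0)
    } else {
      sp <- compute_speed(tracking)$speed
      f <- stats::approxfun(t, b * sp, rule = 2)
      list(tracking = tracking, modifier = f, modifier_max = max(b * sp, 0))
    }
  })
}

#' Configuration for a synthetic session
#'
#' @param n_trials,iti_mean,iti_min,threat_kind See [make_event_schedule()].
#' @param units List of unit groups, each
#'   `list(n =, profile = response_profile(...), region =, speed_b =)`.
#' @param pairs List of pair groups, each
#'   `list(n =, rate =, coupling = pair_coupling(...))`.
#' @param sample_rate Tracking sample rate (Hz); `NULL` disables tracking.
#' @return A named list understood by [simulate_session()] and
#'   [make_dataset()].
#' @export
synthetic_config <- function(n_trials = c(pre = 10, threat = 10, post = 10),
                             iti_mean = 30, iti_min = 15,
                             threat_kind = "robot",
                             units = list(), pairs = list(),
                             sample_rate = 10) {
  list(n_trials = n_trials, iti_mean = iti_mean, iti_min = iti_min,
       threat_kind = threat_kind, units = units, pairs = pairs,
       sample_rate = sample_rate)
}

#' Simulate a complete session with ground truth
#'
#' Fully deterministic given `seed`: the root seed is expanded through a
#' counter-based scheme so the schedule, the tracking trace, and every unit
#' and pair draw from their own reproducible streams.
#'
#' @param config A [synthetic_config()].
#' @param seed Root seed (integer).
#' @param session_id,rat_id Identifiers.
#' @return List with `session` (a `forage_session`) and `ground_truth`
#'   (tibble: `entity_id`, `type`, `label`, `coupled`, `p_share`, `lag_s`,
#'   `speed_b`).
#' @export
simulate_session <- function(config, seed = 1, session_id = "synthetic",
                             rat_id = "synthetic") {
  schedule <- make_event_schedule(config$n_trials, config$iti_mean,
                                  config$iti_min, config$threat_kind,
                                  seed = derive_seed(seed, 1))
  tracking <- NULL
  speed_b <- vapply(config$units, function(u) u$speed_b %||% 0, numeric(1))
  if (!is.null(config$sample_rate)) {
    # one shared trace; modifiers are scaled per unit below
    trace <- make_speed_trace(schedule, b = 1,
                              sample_rate = config$sample_rate,
                              seed = derive_seed(seed, 2))
    tracking <- trace$tracking
  }

  spikes <- list()
  truth <- list()
  uidx <- 0L
  for (gi in seq_along(config$units)) {
    grp <- config$units[[gi]]
    bcoef <- grp$speed_b %||% 0
    for (j in seq_len(grp$n)) {
      uidx <- uidx + 1L
      uid <- sprintf("u%03d", uidx)
      mod <- NULL
      mod_max <- 0
      if (bcoef != 0 && !is.null(tracking)) {
        mod <- function(tt) bcoef * trace$modifier(tt)
        mod_max <- bcoef * trace$modifier_max
      }
      unit <- make_unit(grp$profile, schedule, rate_modifier = mod,
                        rate_modifier_max = mod_max,
                        seed = derive_seed(seed, c(3, uidx)))
      spikes[[uid]] <- tibble(unit_id = uid,
                              region = grp$region %||% "BLA",
                              time_s = unit$times)
      truth[[uid]] <- mutate(unit$truth, entity_id = uid, type = "unit",
                             speed_b = bcoef)
    }
  }
  pidx <- 0L
  for (gi in seq_along(config$pairs)) {
    grp <- config$pairs[[gi]]
    for (j in seq_len(grp$n)) {
      pidx <- pidx + 1L
      ids <- sprintf("p%03d%s", pidx, c("a", "b"))
      pr <- make_pair(schedule, rate = grp$rate %||% 5,
                      coupling = grp$coupling,
                      seed = derive_seed(seed, c(4, pidx)))
      spikes[[ids[1]]] <- tibble(unit_id = ids[1],
                                 region = grp$region %||% "BLA",
                                 time_s = pr$ref_times)
      spikes[[ids[2]]] <- tibble(unit_id = ids[2],
                                 region = grp$region %||% "BLA",
                                 time_s = pr$target_times)
      truth[[paste(ids, collapse = ":")]] <-
        mutate(pr$truth, entity_id = paste(ids, collapse = ":"), type = "pair")
    }
  }
  empty_spikes <- tibble(unit_id = character(), region = character(),
                         time_s = numeric())
  session <- forage_session(
    spikes = bind_rows(c(list(empty_spikes), spikes)),
    events = schedule$events,
    trials = schedule$trials,
    tracking = tracking,
    session_id = session_id, rat_id = rat_id,
    threat_kind = config$threat_kind,
    config = config[setdiff(names(config), c("units", "pairs"))]
  )
  gt <- bind_rows(c(list(tibble(entity_id = character(), type = character())),
                    truth))
  for (col in c("label", "coupled", "p_share", "lag_s", "speed_b")) {
    if (!col %in% names(gt)) gt[[col]] <- NA
  }
  list(
    session = session,
    ground_truth = select(gt, "entity_id", "type", "label", "coupled",
                          "p_share", "lag_s", "speed_b")
  )
}

#' Write a synthetic dataset to disk
#'
#' Writes `spikes.tsv`, `events.tsv`, `trials.tsv`, `tracking.tsv`,
#' `ground_truth.tsv`, and the generating `config.yaml` into `dir`.
#' Byte-identical output for identical `(config, seed)`.
#'
#' @inheritParams simulate_session
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
make_dataset <- function(config, dir, seed = 1) {
  sim <- simulate_session(config, seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_session(sim$session, dir)
  readr::write_tsv(sim$ground_truth, file.path(dir, "ground_truth.tsv"),
                   progress = FALSE)
  serializable <- config
  serializable$units <- lapply(config$units, function(u) {
    c(u[setdiff(names(u), "profile")], unclass(u$profile))
  })
  serializable$pairs <- lapply(config$pairs, function(p) {
    c(p[setdiff(names(p), "coupling")], unclass(p$coupling))
  })
  serializable$n_trials <- as.list(config$n_trials)
  yaml::write_yaml(c(serializable, list(seed = seed)),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
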