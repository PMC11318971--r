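#' Classify a unit's event responsiveness across phases
#'
#' A phase is "responsive" (H) when any of the first `n_test_bins` post-event
#' bins (500 ms at the 0.1 s canonical bin width) of its baseline-normalised
#' PETH exceeds `z_threshold`. Labels:
#' * `robot`: H in the threat phase only (exclusive of pre, and of post when
#'   `exclusivity = "both"`),
#' * `pellet`: H in pre but not threat,
#' * `both`: H in pre and threat,
#' * `inhibited`: no excitatory H anywhere and some first-five threat bin
#'   below `-z_threshold`,
#' * `none` otherwise.
#'
#' Mixed excitation + inhibition resolves to the excitatory label.
#'
#' @param z_by_phase Named list with elements `pre`, `threat`, `post`, each a
#'   z vector aligned to that phase's alignment event (pellet procurement in
#'   pre/post, robot surge or light onset in threat).
#' @param bin_left Left bin edges (event-relative s) shared by the z vectors.
#' @param n_test_bins Number of post-event bins tested (default 5).
#' @param z_threshold Excitation threshold (default 3).
#' @param exclusivity `"both"` (default): a robot cell must lack excitation in
#'   both pre and post; `"pre_only"`: only pre is checked.
#' @return One of `"robot"`, `"pellet"`, `"both"`, `"inhibited"`, `"none"`,
#'   or `NA` if any phase is non-classifiable (all-`NA` z).
#' @export
classify_event_response <- function(z_by_phase, bin_left, n_test_bins = 5,
                                    z_threshold = 3,
                                    exclusivity = c("both", "pre_only")) {
  exclusivity <- match.arg(exclusivity)
  for (p in c("pre", "threat", "post")) {
    if (is.null(z_by_phase[[p]])) abort(sprintf("Missing phase '%s' in `z_by_phase`.", p))
  }
  idx <- test_bin_indices(bin_left, n_test_bins)
  if (any(vapply(z_by_phase[c("pre", "threat", "post")],
                 function(z) all(is.na(z)), logical(1)))) {
    return(NA_character_)
  }
  H <- function(z) any(z[idx] > z_threshold, na.rm = TRUE)
  h_pre <- H(z_by_phase$pre)
  h_threat <- H(z_by_phase$threat)
  h_post <- H(z_by_phase$post)
  inhibited <- any(z_by_phase$threat[idx] < -z_threshold, na.rm = TRUE)

  if (h_pre && h_threat) return("both")
  if (h_pre) return("pellet")
  robot_ok <- h_threat && !h_pre && (exclusivity == "pre_only" || !h_post)
  if (robot_ok) return("robot")
  if (!h_pre && !h_threat && !h_post && inhibited) return("inhibited")
  "none"
}

test_bin_indices <- function(bin_left, n_test_bins) {
  idx <- which(bin_left >= -1e-12)
  if (length(idx) < n_test_bins) {
    abort(sprintf("PETH has fewer than %d post-event bins.", n_test_bins))
  }
  idx[seq_len(n_test_bins)]
}

#' Is a unit stimulation-responsive?
#'
#' A stim cell shows z > `z_threshold` within the first `n_test_bins`
#' post-onset bins when aligned to the light onset during the stim session,
#' but in neither the pre-stim nor the post-stim session.
#'
#' @param z_by_phase Named list with `pre`, `threat` (the stim session,
#'   aligned to stimulation onset) and `post` z vectors.
#' @inheritParams classify_event_response
#' @return `TRUE`/`FALSE`, or `NA` if any phase is non-classifiable.
#' @export
classify_stim_response <- function(z_by_phase, bin_left, n_test_bins = 5,
                                   z_threshold = 3) {
  for (p in c("pre", "threat", "post")) {
    if (is.null(z_by_phase[[p]])) abort(sprintf("Missing phase '%s' in `z_by_phase`.", p))
  }
  if (any(vapply(z_by_phase[c("pre", "threat", "post")],
                 function(z) all(is.na(z)), logical(1)))) {
    return(NA)
  }
  idx <- test_bin_indices(bin_left, n_test_bins)
  H <- function(z) any(z[idx] > z_threshold, na.rm = TRUE)
  H(z_by_phase$threat) && !H(z_by_phase$pre) && !H(z_by_phase$post)
}

#' Latency of the first significant post-event bin
#'
#' @param z z vector of a PETH.
#' @param bin_width Bin width (s).
#' @param bin_left Left bin edges; when `NULL`, `z` is taken to start at the
#'   event.
#' @inheritParams classify_event_response
#' @return Left edge (s) of the first post-event bin with z above threshold
#'   within the test window, or `NA` if none crosses.
#' @export
response_latency <- function(z, bin_width, bin_left = NULL, n_test_bins = 5,
                             z_threshold = 3) {
  if (is.null(bin_left)) bin_left <- bin_width * (seq_along(z) - 1)
  idx <- test_bin_indices(bin_left, n_test_bins)
  hit <- idx[which(z[idx] > z_threshold)]
  if (length(hit) == 0) NA_real_ else bin_left[hit[1]]
}

#' Maximal trial-averaged firing rate in a post-event window
#'
#' @param counts Trial-by-bin count matrix from [bin_spikes()].
#' @param bin_width Bin width (s).
#' @param window Post-event window, default the first 500 ms.
#' @return Maximum per-bin trial-averaged rate (Hz) over the window.
#' @export
max_rate_window <- function(counts, bin_width, window = c(0, 0.5)) {
  bin_left <- attr(counts, "bin_left")
  if (is.null(bin_left)) bin_left <- bin_width * (seq_len(ncol(counts)) - 1)
  sel <- bin_left >= window[1] - 1e-12 & bin_left < window[2] - 1e-12
  if (!any(sel)) return(0)
  max(colMeans(counts[, sel, drop = FALSE])) / bin_width
}

#' Movement-speed versus firing-rate correlation
#'
#' Screens a unit for speed coupling: spike counts and mean speed are
#' computed in `bin_width` bins restricted to epochs the animal spends out of
#' the nest (all tracking samples in the bin at `x >= nest_exit_x`), and a
#' two-sided Pearson test (t transform) is applied.
#'
#' @param times Spike times (s).
#' @param tracking Tracking tibble; a `speed` column is added with
#'   [compute_speed()] if absent.
#' @param bin_width Bin width in seconds (default 1 s for stable per-bin rate
#'   estimates).
#' @param alpha Significance level (default 0.05).
#' @param nest_exit_x Arena x coordinate of the nest gate (cm).
#' @param min_bins Minimum number of usable out-of-nest bins (default 10).
#' @return One-row tibble: `r`, `p`, `significant`, `n_bins`, `defined`.
#'   A zero-variance side yields `r = NA`, `significant = FALSE`,
#'   `defined = FALSE`.
#' @export
speed_rate_correlation <- function(times, tracking, bin_width = 1, alpha = 0.05,
                                   nest_exit_x = 0, min_bins = 10) {
  if (!"speed" %in% names(tracking)) tracking <- compute_speed(tracking)
  t0 <- tracking$t[1]
  t1 <- tracking$t[nrow(tracking)]
  n_bins <- floor((t1 - t0) / bin_width)
  if (n_bins < 1) abort("Tracking trace shorter than one bin.")
  bin <- bin_index(tracking$t, t0, bin_width, n_bins)
  ok <- !is.na(bin)
  f <- factor(bin[ok], levels = seq_len(n_bins))
  n_in_bin <- tabulate(bin[ok], nbins = n_bins)
  out_of_nest <- as.logical(tapply(tracking$x[ok] >= nest_exit_x, f, all))
  mean_speed <- as.numeric(tapply(tracking$speed[ok], f, mean))
  usable <- which(n_in_bin > 0 & !is.na(out_of_nest) & out_of_nest)
  if (length(usable) < min_bins) {
    abort(sprintf("Only %d usable out-of-nest bins; need >= %d.",
                  length(usable), min_bins))
  }
  spike_bin <- bin_index(times, t0, bin_width, n_bins)
  counts <- tabulate(spike_bin[!is.na(spike_bin)], nbins = n_bins)
  rate <- counts[usable] / bin_width
  speed <- mean_speed[usable]
  if (sd(rate) == 0 || sd(speed) == 0) {
    return(tibble(r = NA_real_, p = NA_real_, significant = FALSE,
                  n_bins = length(usable), defined = FALSE))
  }
  ct <- cor.test(rate, speed, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p = ct$p.value,
         significant = ct$p.value < alpha, n_bins = length(usable),
         defined = TRUE)
}

#' Classify every unit of a session
#'
#' Runs the full per-unit analysis: phase-wise PETHs with phase-appropriate
#' alignment (pellet procurement in pre/post, robot surge or light onset in
#' threat), responsiveness label, response latency, peak z and maximal rate in
#' the first 500 ms, stimulation responsiveness (stim-threat days), and the
#' speed-rate screen when tracking is available. Excluded trials' events are
#' omitted. Units with zero baseline variance in any phase are reported as
#' non-classifiable, never dropped.
#'
#' On combined days (stim threat session followed by a `robot` phase), the
#' event label is assessed against the robot phase and `stim_responsive`
#' against the stim session.
#'
#' @param session A `forage_session`.
#' @param window,bin_width,baseline PETH settings (see [compute_peth()]).
#' @inheritParams classify_event_response
#' @param speed_bin_width Bin width (s) of the speed-rate screen.
#' @param alpha Significance level of the speed-rate screen.
#' @return Tibble with one row per unit: `unit_id`, `region`, `label`,
#'   `stim_responsive`, `latency_s`, `peak_z_500ms`, `max_rate_500ms`,
#'   `speed_r`, `speed_p`, `speed_significant`, `classifiable`.
#' @export
classify_units <- function(session, window = c(-5, 5), bin_width = 0.1,
                           baseline = c(-5, 0), n_test_bins = 5,
                           z_threshold = 3,
                           exclusivity = c("both", "pre_only"),
                           speed_bin_width = 1, alpha = 0.05) {
  exclusivity <- match.arg(exclusivity)
  if (nrow(session$units) == 0) {
    return(tibble(
      unit_id = character(), region = character(), label = character(),
      stim_responsive = logical(), latency_s = numeric(),
      peak_z_500ms = numeric(), max_rate_500ms = numeric(),
      speed_r = numeric(), speed_p = numeric(),
      speed_significant = logical(), classifiable = logical()
    ))
  }
  phases <- intersect(PHASES, unique(session$trials$phase))
  align <- lapply(phases, function(p) {
    ev <- phase_events(session, alignment_kind(p, session$threat_kind), p)
    if (nrow(ev) == 0) {
      abort(sprintf("No usable alignment events for phase '%s'.", p))
    }
    ev$time_s
  })
  names(align) <- phases
  # which phase carries the threat response tested by the event label
  label_phase <- if ("robot" %in% phases) "robot" else "threat"
  has_stim <- session$threat_kind == "stim"

  rows <- purrr::map(seq_len(nrow(session$units)), function(i) {
    uid <- session$units$unit_id[i]
    times <- unit_spikes(session, uid)
    peths <- lapply(phases, function(p) {
      compute_peth(times, align[[p]], window, bin_width, baseline,
                   t_range = c(0, session$t_end), unit_id = uid,
                   event_kind = alignment_kind(p, session$threat_kind), phase = p)
    })
    names(peths) <- phases
    bin_left <- peths[[1]]$bin_left
    z_of <- function(p) peths[[p]]$z
    z_for_label <- list(pre = z_of("pre"), threat = z_of(label_phase),
                        post = z_of("post"))
    label <- classify_event_response(z_for_label, bin_left, n_test_bins,
                                     z_threshold, exclusivity)
    stim <- if (has_stim) {
      classify_stim_response(list(pre = z_of("pre"), threat = z_of("threat"),
                                  post = z_of("post")),
                             bin_left, n_test_bins, z_threshold)
    } else {
      NA
    }
    idx <- test_bin_indices(bin_left, n_test_bins)
    threat_peth <- peths[[label_phase]]
    speed <- if (!is.null(session$tracking)) {
      tryCatch(
        speed_rate_correlation(times, session$tracking, speed_bin_width, alpha),
        error = function(e) tibble(r = NA_real_, p = NA_real_,
                                   significant = NA, n_bins = 0L,
                                   defined = FALSE)
      )
    } else {
      tibble(r = NA_real_, p = NA_real_, significant = NA, n_bins = 0L,
             defined = NA)
    }
    tibble(
      unit_id = uid,
      region = session$units$region[i],
      label = label,
      stim_responsive = stim,
      latency_s = if (!is.na(label) && !label %in% c("none", "inhibited")) {
        response_latency(threat_peth$z, bin_width, bin_left, n_test_bins,
                         z_threshold)
      } else {
        NA_real_
      },
      peak_z_500ms = if (threat_peth$classifiable) max(threat_peth$z[idx]) else NA_real_,
      max_rate_500ms = max_rate_window(threat_peth$counts, bin_width),
      speed_r = speed$r,
      speed_p = speed$p,
      speed_significant = speed$significant,
      classifiable = !is.na(label)
    )
  })
  bind_rows(rows)
}

#' Population summary of unit classifications
#'
#' Counts and percentages per responsiveness label (over classifiable units)
#' and, when stimulation responsiveness is known, the 2x2 robot/non-robot by
#' stim/non-stim contingency table with its chi-square test (delegated to
#' [stats::chisq.test()]).
#'
#' @param classifications Output of [classify_units()].
#' @return List with `proportions` (tibble: `label`, `n`, `pct`),
#'   `n_classifiable`, `n_units`, and — when defined — `contingency` (2x2
#'   table) and `chisq` (htest object).
#' @export
population_summary <- function(classifications) {
  if (nrow(classifications) == 0) abort("Need at least one unit.")
  classified <- filter(classifications, !is.na(.data$label))
  labels <- c("robot", "pellet", "both", "none", "inhibited")
  proportions <- tibble(label = labels) %>%
    left_join(count(classified, .data$label), by = "label") %>%
    mutate(
      n = if_else(is.na(.data$n), 0L, .data$n),
      pct = if (nrow(classified) > 0) 100 * .data$n / nrow(classified) else 0
    )
  out <- list(
    proportions = proportions,
    n_units = nrow(classifications),
    n_classifiable = nrow(classified)
  )
  with_stim <- filter(classified, !is.na(.data$stim_responsive))
  if (nrow(with_stim) > 0) {
    tab <- table(
      factor(if_else(with_stim$label == "robot", "robot", "non_robot"),
             levels = c("robot", "non_robot")),
      factor(if_else(with_stim$stim_responsive, "stim", "non_stim"),
             levels = c("stim", "non_stim"))
    )
    out$contingency <- tab
    if (all(dim(tab) == c(2, 2)) && sum(tab) > 0 && all(rowSums(tab) > 0) &&
        all(colSums(tab) > 0)) {
      out$chisq <- suppressWarnings(stats::chisq.test(tab))
    }
  }
  out
}
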