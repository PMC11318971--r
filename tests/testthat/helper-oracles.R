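# Independent brute-force oracles used to validate the vectorised
# implementations, written from the definitions only.

# per-spike, per-bin membership test with the same half-open edge grid
oracle_peth_counts <- function(times, events, window = c(-5, 5), bw = 0.1) {
  n_bins <- round((window[2] - window[1]) / bw)
  edges <- window[1] + bw * (0:n_bins)
  m <- matrix(0L, nrow = length(events), ncol = n_bins)
  for (i in seq_along(events)) {
    rel <- times - events[i]
    for (b in seq_len(n_bins)) {
      m[i, b] <- sum(rel >= edges[b] & rel < edges[b + 1])
    }
  }
  m
}

# all pairwise target - ref lags within each epoch, histogrammed naively
oracle_raw_cc <- function(ref, tgt, events, epoch_window = c(0, 2),
                          lag_range = c(-0.5, 0.5), bin = 0.01) {
  n <- round((lag_range[2] - lag_range[1]) / bin)
  edges <- lag_range[1] + bin * (0:n)
  counts <- numeric(n)
  for (e in events) {
    r <- ref[ref - e >= epoch_window[1] & ref - e < epoch_window[2]] - e
    tg <- tgt[tgt - e >= epoch_window[1] & tgt - e < epoch_window[2]] - e
    for (a in tg) {
      for (b in r) {
        d <- a - b
        for (k in seq_len(n)) {
          if (d >= edges[k] && d < edges[k + 1]) counts[k] <- counts[k] + 1
        }
      }
    }
  }
  counts
}

# a small three-phase robot-day schedule shared by several tests
toy_schedule <- function(n = c(pre = 5, threat = 5, post = 5), seed = 42,
                         threat_kind = "robot") {
  make_event_schedule(n, iti_mean = 25, iti_min = 12,
                      threat_kind = threat_kind, seed = seed)
}

# alignment event times of a schedule phase, straight from the event table
schedule_alignments <- function(schedule, phase) {
  kind <- switch(phase,
                 pre = "pellet_procurement", post = "pellet_procurement",
                 threat = if (schedule$threat_kind == "stim") "stim_onset"
                          else "robot_activation",
                 robot = "robot_activation")
  keep <- schedule$trials$trial_index[schedule$trials$phase == phase]
  sort(schedule$events$time_s[schedule$events$kind == kind &
                                schedule$events$trial_index %in% keep])
}

# a tiny hand-checkable session: 2 units, 2 trials per phase
toy_session <- function(tracking = NULL) {
  trials <- tibble::tibble(
    trial_index = 1:6,
    phase = rep(c("pre", "threat", "post"), each = 2),
    gate_open_time = c(10, 50, 90, 130, 170, 210),
    outcome = c("success", "success", "fail", "fail", "success", "success")
  )
  align <- trials$gate_open_time + 5
  kinds <- c("pellet_procurement", "pellet_procurement",
             "robot_activation", "robot_activation",
             "pellet_procurement", "pellet_procurement")
  events <- tibble::tibble(
    kind = c(rep("gate_open", 6), kinds),
    trial_index = c(1:6, 1:6),
    time_s = c(trials$gate_open_time, align)
  )
  spikes <- tibble::tibble(
    unit_id = rep(c("u1", "u2"), each = 40),
    region = rep(c("dPAG", "BLA"), each = 40),
    time_s = c(seq(1, 235, length.out = 40), seq(2, 236, length.out = 40))
  )
  forage_session(spikes, events, trials, tracking = tracking,
                 session_id = "toy", rat_id = "r1", threat_kind = "robot")
}
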