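bl <- seq(-5, 4.9, by = 0.1) # canonical bin_left grid
flat <- rep(0, 100)
bump <- function(at_bin, value = 5) {
  z <- rep(0, 100)
  z[50 + at_bin] <- value
  z
}

test_that("event-response labels follow the exclusive crossing rules", {
  z_robot <- list(pre = flat, threat = bump(1), post = flat)
  expect_equal(classify_event_response(z_robot, bl), "robot")

  z_pellet <- list(pre = bump(2), threat = flat, post = flat)
  expect_equal(classify_event_response(z_pellet, bl), "pellet")

  z_both <- list(pre = bump(1), threat = bump(3), post = flat)
  expect_equal(classify_event_response(z_both, bl), "both")

  z_inh <- list(pre = flat, threat = bump(1, -5), post = flat)
  expect_equal(classify_event_response(z_inh, bl), "inhibited")

  expect_equal(classify_event_response(list(pre = flat, threat = flat,
                                            post = flat), bl), "none")
})

test_that("crossings outside the first five post-event bins do not count", {
  z <- list(pre = flat, threat = bump(6), post = flat)
  expect_equal(classify_event_response(z, bl), "none")
  # ... nor do pre-event crossings
  z <- list(pre = flat, threat = bump(-1), post = flat)
  expect_equal(classify_event_response(z, bl), "none")
  # a z exactly at threshold is not a crossing (strict >)
  z <- list(pre = flat, threat = bump(1, 3), post = flat)
  expect_equal(classify_event_response(z, bl), "none")
})

test_that("the exclusivity switch controls the post-phase veto", {
  z <- list(pre = flat, threat = bump(1), post = bump(1))
  expect_equal(classify_event_response(z, bl, exclusivity = "both"), "none")
  expect_equal(classify_event_response(z, bl, exclusivity = "pre_only"),
               "robot")
})

test_that("mixed excitation and inhibition resolves to the excitatory label", {
  z <- rep(0, 100)
  z[51] <- 5
  z[52] <- -5
  expect_equal(classify_event_response(list(pre = flat, threat = z,
                                            post = flat), bl), "robot")
})

test_that("non-classifiable phases propagate NA and errors name the phase", {
  z_na <- rep(NA_real_, 100)
  expect_true(is.na(classify_event_response(list(pre = z_na, threat = bump(1),
                                                 post = flat), bl)))
  expect_error(classify_event_response(list(pre = flat, threat = flat), bl),
               "Missing phase 'post'")
})

test_that("stim responsiveness requires threat-only excitation", {
  expect_true(classify_stim_response(list(pre = flat, threat = bump(1),
                                          post = flat), bl))
  expect_false(classify_stim_response(list(pre = bump(1), threat = bump(1),
                                           post = flat), bl))
  expect_false(classify_stim_response(list(pre = flat, threat = flat,
                                           post = flat), bl))
  expect_true(is.na(classify_stim_response(list(pre = rep(NA_real_, 100),
                                                threat = bump(1), post = flat),
                                           bl)))
})

test_that("latency is the left edge of the first crossing bin", {
  z <- rep(0, 100)
  z[53] <- 4 # third post-event bin
  expect_equal(response_latency(z, 0.1, bl), 0.2)
  z[51] <- 3.5
  expect_equal(response_latency(z, 0.1, bl), 0)
  expect_true(is.na(response_latency(flat, 0.1, bl)))
})

test_that("max_rate_window reports the peak trial-averaged rate", {
  counts <- rbind(c(0L, 2L, 4L, 1L), c(0L, 4L, 2L, 1L))
  attr(counts, "bin_left") <- c(-0.1, 0, 0.1, 0.2)
  # post-event bins average to 3, 3, 1 counts -> peak 3/0.1 = 30 Hz
  expect_equal(max_rate_window(counts, 0.1, c(0, 0.5)), 30)
})

test_that("speed-rate correlation detects a constructed positive coupling", {
  # 200 s at 10 Hz, out of the nest throughout; speed alternates between
  # slow and fast 10 s blocks, and spike counts follow the same pattern
  step <- 0.1
  t <- seq(0, 200 - step, by = step)
  block <- floor(t / 10) %% 2 # 0 = slow, 1 = fast
  v <- ifelse(block == 0, 2, 30)
  trk <- tibble::tibble(t = t, x = 50 + 20 * sin(cumsum(v * step) / 30),
                        y = 29)
  spikes <- unlist(lapply(0:199, function(s) {
    n <- if ((floor(s / 10) %% 2) == 0) 1 else 6
    s + seq_len(n) / (n + 1)
  }))
  res <- speed_rate_correlation(spikes, trk, bin_width = 1)
  expect_true(res$defined)
  expect_gt(res$r, 0.5)
  expect_true(res$significant)

  # zero rate variance -> undefined, not significant
  res0 <- speed_rate_correlation(0:199 + 0.5, trk, bin_width = 1)
  expect_false(res0$defined)
  expect_false(res0$significant)

  # too few usable bins -> error
  short <- dplyr::filter(trk, t < 5)
  expect_error(speed_rate_correlation(spikes, short, bin_width = 1),
               "usable out-of-nest bins")
})

test_that("classify_units labels a constructed robot unit in a session", {
  schedule <- toy_schedule(c(pre = 8, threat = 8, post = 8), seed = 21)
  robot <- make_unit(
    response_profile(4, amplitude = 20, kernel = "boxcar",
                     phase_mask = "threat"),
    schedule, seed = 101
  )
  none <- make_unit(response_profile(5), schedule, seed = 102)
  s <- forage_session(
    spikes = tibble::tibble(
      unit_id = rep(c("r1", "n1"), c(length(robot$times), length(none$times))),
      region = "dPAG",
      time_s = c(robot$times, none$times)
    ),
    events = schedule$events, trials = schedule$trials,
    threat_kind = "robot"
  )
  cls <- classify_units(s)
  expect_equal(cls$label[cls$unit_id == "r1"], "robot")
  expect_lt(cls$latency_s[cls$unit_id == "r1"], 0.5)
  expect_gt(cls$peak_z_500ms[cls$unit_id == "r1"], 3)
  expect_true(all(cls$classifiable))
})

test_that("population_summary counts labels and builds the contingency", {
  cls <- tibble::tibble(
    unit_id = sprintf("u%d", 1:6),
    label = c("robot", "robot", "pellet", "none", "none", NA),
    stim_responsive = c(TRUE, FALSE, FALSE, TRUE, FALSE, NA)
  )
  ps <- population_summary(cls)
  expect_equal(ps$n_units, 6)
  expect_equal(ps$n_classifiable, 5)
  expect_equal(ps$proportions$n[ps$proportions$label == "robot"], 2L)
  expect_equal(ps$proportions$pct[ps$proportions$label == "robot"], 40)
  expect_equal(sum(ps$proportions$n), 5L)
  expect_equal(unname(ps$contingency["robot", "stim"]), 1)
  expect_equal(unname(ps$contingency["non_robot", "non_stim"]), 2)
})
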