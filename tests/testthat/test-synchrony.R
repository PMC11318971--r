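test_that("raw cross-correlogram equals the brute-force oracle", {
  withr::local_seed(31)
  events <- c(50, 120, 200)
  for (rep in 1:5) {
    ref <- sort(runif(80, 0, 250))
    tgt <- sort(runif(80, 0, 250))
    got <- suppressWarnings(raw_cross_correlogram(ref, tgt, events))
    expect_equal(as.numeric(got), oracle_raw_cc(ref, tgt, events))
  }
})

test_that("only within-epoch spikes contribute, lags never cross events", {
  events <- 100
  # half-open epoch: the right edge is out, the left edge is in
  expect_equal(sum(raw_cross_correlogram(101.9, 102 - 1e-3, events)), 1)
  got <- suppressWarnings(raw_cross_correlogram(101.9, 102, events))
  expect_equal(sum(got), 0)
  expect_equal(sum(raw_cross_correlogram(100, 100.3, events)), 1)
  # spikes of different epochs are never paired
  got2 <- raw_cross_correlogram(c(101, 201), c(101.2, 201.3), c(100, 200))
  expect_equal(sum(got2), 2) # one lag per epoch, none across
})

test_that("mirror symmetry: swapping the pair reverses the lag axis", {
  withr::local_seed(32)
  events <- c(40, 90, 140)
  ref <- runif(120, 30, 160)
  tgt <- runif(120, 30, 160)
  fwd <- raw_cross_correlogram(ref, tgt, events)
  rev_ <- raw_cross_correlogram(tgt, ref, events)
  expect_identical(as.numeric(fwd), rev(as.numeric(rev_)))
})

test_that("the two-event shift predictor is the deterministic swap", {
  events <- c(100, 200)
  ref <- c(100.3337, 100.8111, 200.2417)
  tgt <- c(100.5224, 200.9630)
  pred <- shift_predictor(ref, tgt, events, n_shuffles = 10)
  # only one derangement of 2 elements exists, so every shuffle is identical
  expect_equal(as.numeric(pred$sd), rep(0, 100))
  # the swap pairs trial 1 refs with trial 2 targets and vice versa
  manual <- raw_cross_correlogram(c(0.3337, 0.8111), 0.9630, 0) +
    raw_cross_correlogram(0.2417, 0.5224, 0)
  expect_equal(as.numeric(pred$mean), as.numeric(manual))
  expect_error(shift_predictor(ref, tgt, 100), ">= 2 usable events")
})

test_that("derangements never map a trial to itself", {
  withr::local_seed(33)
  for (n in c(2, 3, 5, 10)) {
    for (rep in 1:20) {
      p <- spikeforage:::sample_derangement(n)
      expect_true(all(p != seq_len(n)))
      expect_equal(sort(p), seq_len(n))
    }
  }
})

test_that("corrected_cc subtracts the predictor and checks grids", {
  raw <- raw_cross_correlogram(c(10.2), c(10.4), 10)
  pred_mean <- rep(0.5, 100)
  attr(pred_mean, "lag_left") <- attr(raw, "lag_left")
  corr <- corrected_cc(raw, pred_mean)
  expect_equal(as.numeric(corr), as.numeric(raw) - 0.5)
  bad <- rep(0.5, 100)
  attr(bad, "lag_left") <- attr(raw, "lag_left") + 0.001
  expect_error(corrected_cc(raw, bad), "lag grids do not match")
})

test_that("cc_significance flags peaks and reports the peak lag", {
  lag_left <- seq(-0.5, 0.49, by = 0.01)
  corrected <- rep(0, 100)
  corrected[52] <- 10 # bin [0.01, 0.02)
  sd_ <- rep(2, 100)
  sig <- cc_significance(corrected, sd_, lag_left)
  expect_true(sig$significant)
  expect_equal(sig$peak_lag, 0.01)
  expect_equal(sig$z[52], 5)

  # outside the 0-100 ms test window the same peak does not count
  corrected2 <- rep(0, 100)
  corrected2[40] <- 10
  expect_false(cc_significance(corrected2, sd_, lag_left)$significant)

  # all-zero shuffle SD in the window -> undefined
  und <- cc_significance(corrected, rep(0, 100), lag_left)
  expect_false(und$defined)
  expect_true(is.na(und$significant))
})

test_that("the flank null standardises against out-of-window bins", {
  lag_left <- seq(-0.5, 0.49, by = 0.01)
  corrected <- rep(0, 100)
  corrected[52] <- 10 # bin [0.01, 0.02), inside the test window
  sd_ <- rep(2, 100)
  sig <- cc_significance(corrected, sd_, lag_left, cc_null = "flank")
  # flank = the 90 bins outside [0, 0.1): all zero except none -> mean 0, sd 0?
  # no: flank excludes bin 52, so flank is all zeros -> sd 0 -> undefined
  expect_false(sig$defined)

  # give the flank some structure so the z is hand-checkable
  corrected2 <- corrected
  corrected2[1:10] <- c(1, -1, 2, -2, 1, -1, 2, -2, 0, 0)
  fl <- corrected2[-(51:60)]
  sig2 <- cc_significance(corrected2, sd_, lag_left, cc_null = "flank")
  expect_true(sig2$defined)
  expect_equal(sig2$z[52], (10 - mean(fl)) / sd(fl))
  expect_true(sig2$significant)
  expect_equal(sig2$peak_lag, 0.01)
  # the shuffle sd argument is ignored under the flank null
  sig3 <- cc_significance(corrected2, rep(0, 100), lag_left, cc_null = "flank")
  expect_equal(sig3$z, sig2$z)
})

test_that("a coupled pair is detected under the flank null too", {
  schedule <- toy_schedule(seed = 44)
  events <- schedule_alignments(schedule, "threat")
  pr <- make_pair(schedule, rate = 8,
                  coupling = pair_coupling(0.5, lag = 0.005, jitter_sd = 0.001),
                  seed = 45)
  cc <- cross_correlogram(pr$ref_times, pr$target_times, events,
                          cc_null = "flank", seed = 46)
  expect_equal(cc$cc_null, "flank")
  expect_true(cc$significant)
  expect_gte(cc$peak_lag, 0)
  expect_lt(cc$peak_lag, 0.01)
})

test_that("AUC windows are additive and respect bin alignment", {
  lag_left <- seq(-0.5, 0.49, by = 0.01)
  withr::local_seed(34)
  corrected <- rnorm(100)
  a_full <- cc_auc(corrected, c(0, 0.1), lag_left = lag_left)
  a_lo <- cc_auc(corrected, c(0, 0.05), lag_left = lag_left)
  a_hi <- cc_auc(corrected, c(0.05, 0.1), lag_left = lag_left)
  expect_equal(a_full, a_lo + a_hi, tolerance = 1e-12)
  expect_equal(a_full, sum(corrected[51:60]) * 0.01, tolerance = 1e-12)
  expect_error(cc_auc(corrected, c(0, 0.055), lag_left = lag_left),
               "align to lag bin edges")
})

test_that("pair categories use the OR rule and reject unknown flags", {
  expect_equal(classify_pair(TRUE, FALSE), "stim_pair")
  expect_equal(classify_pair(FALSE, TRUE), "stim_pair")
  expect_equal(classify_pair(FALSE, FALSE), "non_stim_pair")
  expect_error(classify_pair(NA, TRUE), "must be known")
})

test_that("cross_correlogram recovers an injected 5 ms coupling", {
  schedule <- toy_schedule(seed = 35)
  events <- schedule_alignments(schedule, "threat")
  pr <- make_pair(schedule, rate = 8,
                  coupling = pair_coupling(0.5, lag = 0.005, jitter_sd = 0.001),
                  seed = 36)
  cc <- cross_correlogram(pr$ref_times, pr$target_times, events, seed = 37)
  expect_true(cc$significant)
  expect_gte(cc$peak_lag, 0)
  expect_lt(cc$peak_lag, 0.01)
  expect_gt(cc$auc_0_100, 0)
  td <- tidy(cc)
  expect_equal(nrow(td), 100)
  expect_s3_class(autoplot(cc), "ggplot")
  # deterministic given the seed
  cc2 <- cross_correlogram(pr$ref_times, pr$target_times, events, seed = 37)
  expect_equal(cc2$z, cc$z)
})

test_that("epoch_cc_table enumerates pairs x epochs deterministically", {
  cfg <- synthetic_config(
    n_trials = c(pre = 5, threat = 5, post = 5),
    units = list(list(n = 2, region = "dPAG",
                      profile = response_profile(6))),
    pairs = list(list(n = 1, rate = 6,
                      coupling = pair_coupling(0.4, lag = 0.005))),
    sample_rate = NULL
  )
  sim <- simulate_session(cfg, seed = 38)
  tab <- epoch_cc_table(sim$session, seed = 39)
  # 4 units -> 6 unordered pairs, 2 epochs with >= 2 events each
  expect_equal(sort(unique(tab$epoch)), c("post_pellet", "post_robot_surge"))
  expect_equal(nrow(tab), 12)
  expect_equal(length(unique(tab$pair_id)), 6)
  # the coupled pair is synchronized in the robot-surge epoch
  coupled <- tab[tab$pair_id == "p001a:p001b", ]
  expect_true(all(coupled$synchronized))
  expect_true(coupled$significant[coupled$epoch == "post_robot_surge"])

  tab2 <- epoch_cc_table(sim$session, seed = 39)
  expect_equal(tab2, tab)

  # AUC normalisation by event count
  tab_raw <- epoch_cc_table(sim$session, auc_per_event = FALSE, seed = 39)
  i <- which(tab$pair_id == "p001a:p001b" & tab$epoch == "post_robot_surge")
  expect_equal(tab$auc_0_100[i] * tab$n_events[i], tab_raw$auc_0_100[i])
})

test_that("rate-filtered units never enter the pair table", {
  cfg <- synthetic_config(
    n_trials = c(pre = 5, threat = 5, post = 5),
    units = list(list(n = 3, profile = response_profile(5))),
    sample_rate = NULL
  )
  sim <- simulate_session(cfg, seed = 40)
  s <- sim$session
  # starve one unit below 0.1 Hz
  keep <- s$spikes$unit_id != "u003" | s$spikes$time_s < 5
  s <- forage_session(s$spikes[keep, ], s$events, s$trials,
                      threat_kind = "robot")
  tab <- epoch_cc_table(s, seed = 41)
  expect_false(any(grepl("u003", tab$pair_id)))
  expect_equal(length(unique(tab$pair_id)), 1)
})
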