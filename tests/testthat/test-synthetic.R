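test_that("response_profile enforces its invariants", {
  expect_error(response_profile(0), "must be > 0")
  expect_error(response_profile(5, amplitude = -5), "exceed -baseline_rate")
  expect_error(response_profile(5, duration = 0), "must be > 0")
  expect_error(response_profile(5, phase_mask = "lunch"), "subset of")
  p <- response_profile(5, amplitude = 3, phase_mask = c("pre", "threat"))
  expect_s3_class(p, "response_profile")
})

test_that("profile_label mirrors the classifier semantics", {
  lab <- function(amp, mask) {
    profile_label(response_profile(5, amplitude = amp, phase_mask = mask))
  }
  expect_equal(lab(0, character()), "none")
  expect_equal(lab(5, character()), "none")
  expect_equal(lab(5, "threat"), "robot")
  expect_equal(lab(5, "robot"), "robot")
  expect_equal(lab(5, "pre"), "pellet")
  expect_equal(lab(5, c("pre", "threat")), "both")
  expect_equal(lab(-3, "threat"), "inhibited")
  expect_equal(lab(-3, "pre"), "none")
  expect_equal(lab(5, c("threat", "post")), "none")
})

test_that("the thinning sampler hits the target rate and validates envelopes", {
  times <- sample_inhomogeneous_poisson(function(t) rep(20, length(t)),
                                        0, 1000, 20, seed = 61)
  expect_false(is.unsorted(times))
  expect_true(all(times >= 0 & times < 1000))
  # 20000 expected spikes, Poisson sd ~ 141 -> 4 sd tolerance
  expect_lt(abs(length(times) - 20000), 4 * sqrt(20000))

  expect_error(
    sample_inhomogeneous_poisson(function(t) rep(25, length(t)),
                                 0, 100, 20, seed = 61),
    "exceeds rate_max"
  )
})

test_that("event schedules respect phase order and event spacing", {
  expect_warning(make_event_schedule(c(pre = 3, threat = 3, post = 3), seed = 1),
                 "outside the typical")
  sch <- toy_schedule(c(pre = 6, threat = 6, post = 6), seed = 62)
  expect_equal(nrow(sch$trials), 18)
  expect_equal(as.vector(table(sch$trials$phase)[c("pre", "threat", "post")]),
               rep(6L, 3))
  # phases are contiguous and ordered in time
  ord <- order(sch$trials$gate_open_time)
  expect_false(is.unsorted(match(sch$trials$phase[ord],
                                 c("pre", "threat", "post"))))
  # alignment events are > 10 s apart, so no spurious exclusions arise
  align <- sort(sch$events$time_s[sch$events$kind %in%
                                    c("pellet_procurement", "robot_activation")])
  expect_true(all(diff(align) > 10))
  # three events per trial
  expect_equal(nrow(sch$events), 54)
  # a session built from the schedule needs no exclusions
  s <- forage_session(
    tibble::tibble(unit_id = "u1", region = "dPAG",
                   time_s = seq(1, sch$t_end - 1, length.out = 50)),
    sch$events, sch$trials
  )
  expect_identical(apply_trial_exclusions(s)$trials$excluded, rep(FALSE, 18))
})

test_that("make_unit realises the profile rate around its events", {
  sch <- toy_schedule(c(pre = 5, threat = 5, post = 5), seed = 63)
  u <- make_unit(response_profile(6, amplitude = 30, duration = 0.5,
                                  kernel = "boxcar", phase_mask = "threat"),
                 sch, seed = 64)
  expect_equal(u$truth$label, "robot")
  ev <- schedule_alignments(sch, "threat")
  # counts in the 0.05-0.55 s response window across the 5 threat events:
  # expected (6 + 30) * 0.5 * 5 = 90
  n_resp <- sum(vapply(ev, function(e) {
    sum(u$times >= e + 0.05 & u$times < e + 0.55)
  }, numeric(1)))
  expect_gt(n_resp, 50)
  # overall rate away from events stays near baseline: 6 Hz * t_end
  expect_lt(length(u$times), 6 * sch$t_end + 30 * 0.5 * 5 +
              4 * sqrt(6 * sch$t_end))
  # no sub-resolution duplicates
  expect_true(all(diff(u$times) >= 1 / 32000))
})

test_that("make_pair produces the expected shared coincidence mass", {
  sch <- toy_schedule(c(pre = 5, threat = 5, post = 5), seed = 65)
  cpl <- pair_coupling(0.5, lag = 0.005, jitter_sd = 0,
                       epoch_mask = "post_robot_surge")
  pr <- make_pair(sch, rate = 10, coupling = cpl, seed = 66)
  expect_true(pr$truth$coupled)
  # shared spikes appear in both trains exactly 5 ms apart:
  # expected p_share * rate * (5 events * 2 s) = 25
  n_coinc <- sum(vapply(pr$ref_times, function(r) {
    any(abs(pr$target_times - r - 0.005) < 1e-9)
  }, logical(1)))
  expect_gt(n_coinc, 10)
  # both trains run at the target rate overall
  for (tr in list(pr$ref_times, pr$target_times)) {
    expect_lt(abs(length(tr) - 10 * sch$t_end), 5 * sqrt(10 * sch$t_end))
  }
  # uncoupled pairs share nothing systematic
  pr0 <- make_pair(sch, rate = 10, coupling = pair_coupling(0), seed = 66)
  n0 <- sum(vapply(pr0$ref_times, function(r) {
    any(abs(pr0$target_times - r - 0.005) < 1e-9)
  }, logical(1)))
  expect_equal(n0, 0)
})

test_that("speed traces follow the schedule and expose a rate modifier", {
  sch <- toy_schedule(c(pre = 5, threat = 5, post = 5), seed = 67)
  tr <- make_speed_trace(sch, b = 0.2, seed = 68)
  expect_equal(tr$tracking$t[1], 0)
  expect_true(all(abs(tr$tracking$y - 29) < 1))
  # the modifier is non-negative-rate-compatible and bounded
  mods <- tr$modifier(tr$tracking$t)
  expect_true(all(is.finite(mods)))
  expect_lte(max(mods), tr$modifier_max + 1e-9)
  # b = 0 yields the null modifier
  tr0 <- make_speed_trace(sch, b = 0, seed = 68)
  expect_equal(tr0$modifier(c(1, 2, 3)), c(0, 0, 0))
  # speed has the spread the screen needs
  sp <- compute_speed(tr$tracking)
  expect_gt(sd(sp$speed), 10)
})

test_that("simulate_session is deterministic and labels ground truth", {
  cfg <- synthetic_config(
    n_trials = c(pre = 5, threat = 5, post = 5),
    units = list(
      list(n = 1, region = "dPAG", profile = response_profile(
        4, amplitude = 10, kernel = "boxcar", phase_mask = "threat")),
      list(n = 1, region = "BLA", profile = response_profile(5))
    ),
    pairs = list(list(n = 1, rate = 5, coupling = pair_coupling(0.3, 0.005)))
  )
  a <- simulate_session(cfg, seed = 69)
  b <- simulate_session(cfg, seed = 69)
  expect_equal(a$session$spikes, b$session$spikes)
  expect_equal(a$session$tracking, b$session$tracking)
  expect_equal(a$ground_truth, b$ground_truth)
  d <- simulate_session(cfg, seed = 70)
  expect_false(identical(a$session$spikes, d$session$spikes))

  expect_equal(a$ground_truth$entity_id, c("u001", "u002", "p001a:p001b"))
  expect_equal(a$ground_truth$label[1:2], c("robot", "none"))
  expect_equal(a$ground_truth$type, c("unit", "unit", "pair"))
  expect_true(a$ground_truth$coupled[3])
  expect_equal(nrow(a$session$units), 4)
})

test_that("make_dataset writes byte-identical files for identical seeds", {
  cfg <- synthetic_config(
    n_trials = c(pre = 5, threat = 5, post = 5),
    units = list(list(n = 2, profile = response_profile(5)))
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_dataset(cfg, d1, seed = 71)
  make_dataset(cfg, d2, seed = 71)
  for (f in c("spikes.tsv", "events.tsv", "trials.tsv", "tracking.tsv",
              "ground_truth.tsv", "config.yaml")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # the dataset reads back as a valid session
  s <- read_session(d1, threat_kind = "robot")
  expect_s3_class(s, "forage_session")
  expect_equal(nrow(s$units), 2)
})
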