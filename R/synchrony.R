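#' Raw cross-correlogram over event-locked epochs
#'
#' For each event, spikes of both units inside `[event + w1, event + w2)` are
#' collected and all pairwise lags `target - ref` falling in `lag_range` are
#' histogrammed (half-open 10 ms bins by default); counts are summed over
#' events. Lags are computed within events only, never across.
#'
#' @param ref_times,target_times Spike times (s) of the reference and target
#'   unit.
#' @param event_times Epoch-defining event times, one per usable trial.
#' @param epoch_window Window around each event, default `c(0, 2)` s (the
#'   post-event surge period).
#' @param lag_range Lag histogram range, default `c(-0.5, 0.5)` s.
#' @param bin Lag bin width, default 0.01 s.
#' @return Numeric vector of per-lag coincidence counts with attributes
#'   `lag_left` (left bin edges, s) and `n_events`.
#' @export
raw_cross_correlogram <- function(ref_times, target_times, event_times,
                                  epoch_window = c(0, 2),
                                  lag_range = c(-0.5, 0.5), bin = 0.01) {
  if (length(event_times) == 0) abort("Need at least one usable event.")
  grid <- lag_grid(lag_range, bin)
  ref_rel <- epoch_relative_spikes(ref_times, event_times, epoch_window)
  tgt_rel <- epoch_relative_spikes(target_times, event_times, epoch_window)
  if (all(lengths(ref_rel) == 0) || all(lengths(tgt_rel) == 0)) {
    warn("Empty epoch(s): no spikes inside the epoch windows; zero histogram.")
  }
  counts <- numeric(grid$n)
  for (i in seq_along(event_times)) {
    counts <- counts + lag_hist(tgt_rel[[i]], ref_rel[[i]], grid)
  }
  attr(counts, "lag_left") <- grid$left
  attr(counts, "n_events") <- length(event_times)
  counts
}

lag_grid <- function(lag_range, bin) {
  n <- round((lag_range[2] - lag_range[1]) / bin)
  if (abs((lag_range[2] - lag_range[1]) - n * bin) > 1e-9 || n < 1) {
    abort("`bin` must divide the lag range exactly.")
  }
  list(left = lag_range[1] + bin * (seq_len(n) - 1), lo = lag_range[1],
       bin = bin, n = n)
}

lag_hist <- function(tgt, ref, grid) {
  if (length(tgt) == 0 || length(ref) == 0) return(numeric(grid$n))
  d <- as.vector(outer(tgt, ref, "-"))
  idx <- bin_index(d, grid$lo, grid$bin, grid$n)
  tabulate(idx[!is.na(idx)], nbins = grid$n)
}

epoch_relative_spikes <- function(times, event_times, epoch_window) {
  times <- sort(times)
  lapply(event_times, function(e) {
    lo <- findInterval(e + epoch_window[1] - 1, times, left.open = TRUE)
    hi <- findInterval(e + epoch_window[2] + 1, times, left.open = TRUE)
    if (hi <= lo) return(numeric(0))
    rel <- times[(lo + 1L):hi] - e
    rel[rel >= epoch_window[1] & rel < epoch_window[2]]
  })
}

#' Shift predictor of a cross-correlogram
#'
#' Estimates the chance (event-locked) coincidence level by re-pairing the
#' reference spikes of trial `i` with the target spikes of trial `pi(i)`,
#' where `pi` is a uniform random permutation with no fixed point (so no
#' within-trial coupling leaks into the predictor), and averaging the
#' surrogate histograms over `n_shuffles` shuffles.
#'
#' @inheritParams raw_cross_correlogram
#' @param n_shuffles Number of trial shuffles, default 100.
#' @return List with `mean` and `sd` (per-lag, over shuffles), each carrying
#'   the `lag_left` attribute, plus `n_shuffles`.
#' @export
shift_predictor <- function(ref_times, target_times, event_times,
                            epoch_window = c(0, 2), lag_range = c(-0.5, 0.5),
                            bin = 0.01, n_shuffles = 100) {
  n_ev <- length(event_times)
  if (n_ev < 2) abort("Shift predictor needs >= 2 usable events (no valid permutation).")
  grid <- lag_grid(lag_range, bin)
  ref_rel <- epoch_relative_spikes(ref_times, event_times, epoch_window)
  tgt_rel <- epoch_relative_spikes(target_times, event_times, epoch_window)
  # cross-trial histograms, computed once; shuffles then just sum rows
  cross <- array(0, dim = c(grid$n, n_ev, n_ev))
  for (i in seq_len(n_ev)) {
    for (j in seq_len(n_ev)) {
      if (i != j) cross[, i, j] <- lag_hist(tgt_rel[[j]], ref_rel[[i]], grid)
    }
  }
  surrogate <- matrix(0, nrow = grid$n, ncol = n_shuffles)
  for (s in seq_len(n_shuffles)) {
    p <- sample_derangement(n_ev)
    acc <- numeric(grid$n)
    for (i in seq_len(n_ev)) acc <- acc + cross[, i, p[i]]
    surrogate[, s] <- acc
  }
  m <- rowMeans(surrogate)
  s <- apply(surrogate, 1, sd)
  attr(m, "lag_left") <- grid$left
  attr(s, "lag_left") <- grid$left
  list(mean = m, sd = s, n_shuffles = n_shuffles)
}

sample_derangement <- function(n) {
  if (n < 2) abort("No fixed-point-free permutation of fewer than 2 elements.")
  if (n == 2) return(c(2L, 1L))
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}

#' Shift-predictor-corrected cross-correlogram
#'
#' @param raw Raw per-lag counts from [raw_cross_correlogram()].
#' @param predictor_mean Per-lag predictor mean from [shift_predictor()].
#' @return Per-lag corrected values (`raw - predictor_mean`); may be
#'   negative.
#' @export
corrected_cc <- function(raw, predictor_mean) {
  gl_r <- attr(raw, "lag_left")
  gl_p <- attr(predictor_mean, "lag_left")
  if (length(raw) != length(predictor_mean) ||
      (!is.null(gl_r) && !is.null(gl_p) &&
       (length(gl_r) != length(gl_p) || any(abs(gl_r - gl_p) > 1e-9)))) {
    abort("Raw and predictor lag grids do not match.")
  }
  out <- as.numeric(raw) - as.numeric(predictor_mean)
  attr(out, "lag_left") <- gl_r %||% gl_p
  out
}

#' Significance of a corrected cross-correlogram peak
#'
#' Standardises the corrected correlogram and tests for a peak above
#' `z_threshold` within the test window (0-100 ms by default). Two null
#' standardisations are available: `"shuffle"` (default) divides each lag by
#' the across-shuffle spread at that lag (`z = corrected / predictor_sd`);
#' `"flank"` centres and scales by the mean and SD of the corrected bins
#' outside the test window.
#'
#' @param corrected Corrected per-lag values from [corrected_cc()].
#' @param predictor_sd Per-lag shuffle SD from [shift_predictor()]; ignored
#'   under the flank null.
#' @param lag_left Left lag-bin edges (s); taken from the `lag_left`
#'   attribute when `NULL`.
#' @param test_window Lag window tested, default `c(0, 0.1)` s (bins with
#'   left edge inside it).
#' @param z_threshold Peak threshold, default 3.
#' @param cc_null `"shuffle"` or `"flank"`.
#' @return List: `z` (per lag; `NA` where the reference SD is zero),
#'   `significant`, `peak_lag` (left edge, s, of the max-z window lag), and
#'   `defined` (`FALSE`, with `significant = NA`, when the reference SD is
#'   zero across the whole window).
#' @export
cc_significance <- function(corrected, predictor_sd, lag_left = NULL,
                            test_window = c(0, 0.1), z_threshold = 3,
                            cc_null = c("shuffle", "flank")) {
  cc_null <- match.arg(cc_null)
  if (is.null(lag_left)) lag_left <- attr(corrected, "lag_left")
  if (is.null(lag_left)) abort("Supply `lag_left`.")
  sel <- lag_left >= test_window[1] - 1e-12 & lag_left < test_window[2] - 1e-12
  if (!any(sel)) abort("Test window contains no lag bins.")
  if (cc_null == "flank") {
    flank <- as.numeric(corrected)[!sel]
    if (length(flank) < 2) abort("Flank null needs >= 2 bins outside the test window.")
    f_sd <- sd(flank)
    if (f_sd == 0) {
      return(list(z = rep(NA_real_, length(corrected)), significant = NA,
                  peak_lag = NA_real_, defined = FALSE))
    }
    z <- (as.numeric(corrected) - mean(flank)) / f_sd
    zw <- z[sel]
    return(list(
      z = z,
      significant = any(zw > z_threshold, na.rm = TRUE),
      peak_lag = lag_left[sel][which.max(zw)],
      defined = TRUE
    ))
  }
  z <- ifelse(predictor_sd > 0, as.numeric(corrected) / as.numeric(predictor_sd),
              NA_real_)
  if (all(predictor_sd[sel] == 0)) {
    return(list(z = z, significant = NA, peak_lag = NA_real_, defined = FALSE))
  }
  zw <- z[sel]
  list(
    z = z,
    significant = any(zw > z_threshold, na.rm = TRUE),
    peak_lag = lag_left[sel][which.max(zw)],
    defined = TRUE
  )
}

#' Windowed area under a corrected cross-correlogram
#'
#' Coincidence mass over a lag window: the sum of corrected per-lag values
#' whose bins lie inside the window, times the bin width
#' (coincidences x seconds). The window must align to bin edges.
#'
#' @inheritParams cc_significance
#' @param bin Lag bin width (s).
#' @param window Lag window `c(a, b)` in seconds.
#' @return The area (coincidences x s).
#' @export
cc_auc <- function(corrected, window, bin = 0.01, lag_left = NULL) {
  if (is.null(lag_left)) lag_left <- attr(corrected, "lag_left")
  if (is.null(lag_left)) abort("Supply `lag_left`.")
  if (!is_multiple_of(window[1] - lag_left[1], bin) ||
      !is_multiple_of(window[2] - lag_left[1], bin)) {
    abort("AUC window must align to lag bin edges.")
  }
  sel <- lag_left >= window[1] - 1e-12 & lag_left < window[2] - 1e-12
  sum(as.numeric(corrected)[sel]) * bin
}

#' Stim-pair versus non-stim-pair category
#'
#' @param ref_stim,target_stim Logical stimulation-responsiveness flags of
#'   the two members.
#' @return `"stim_pair"` when at least one member is stimulation-responsive,
#'   else `"non_stim_pair"`.
#' @export
classify_pair <- function(ref_stim, target_stim) {
  if (is.na(ref_stim) || is.na(target_stim)) {
    abort("Both stimulation-responsiveness flags must be known.")
  }
  if (ref_stim || target_stim) "stim_pair" else "non_stim_pair"
}

#' Full cross-correlogram analysis for one ordered pair and epoch
#'
#' Computes the raw correlogram, its shift predictor, the corrected
#' correlogram, per-lag z, peak significance, and the three windowed AUCs
#' (0-100, 0-50, 50-100 ms).
#'
#' @inheritParams raw_cross_correlogram
#' @inheritParams shift_predictor
#' @inheritParams cc_significance
#' @param ref_unit,target_unit,epoch Optional labels carried into the output.
#' @param seed Optional seed for the shuffle RNG.
#' @return A `cross_correlogram` object with [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
cross_correlogram <- function(ref_times, target_times, event_times,
                              epoch_window = c(0, 2), lag_range = c(-0.5, 0.5),
                              bin = 0.01, n_shuffles = 100,
                              test_window = c(0, 0.1), z_threshold = 3,
                              cc_null = c("shuffle", "flank"),
                              ref_unit = NA_character_,
                              target_unit = NA_character_,
                              epoch = NA_character_, seed = NULL) {
  cc_null <- match.arg(cc_null)
  raw <- raw_cross_correlogram(ref_times, target_times, event_times,
                               epoch_window, lag_range, bin)
  pred <- with_seed(seed, shift_predictor(ref_times, target_times, event_times,
                                          epoch_window, lag_range, bin,
                                          n_shuffles))
  corr <- corrected_cc(raw, pred$mean)
  sig <- cc_significance(corr, pred$sd, attr(raw, "lag_left"), test_window,
                         z_threshold, cc_null)
  structure(
    list(
      ref_unit = ref_unit, target_unit = target_unit, epoch = epoch,
      lag_left = attr(raw, "lag_left"), bin = bin,
      raw = as.numeric(raw), predictor_mean = as.numeric(pred$mean),
      predictor_sd = as.numeric(pred$sd), corrected = as.numeric(corr),
      z = sig$z, significant = sig$significant, peak_lag = sig$peak_lag,
      defined = sig$defined, n_events = attr(raw, "n_events"),
      n_shuffles = n_shuffles, test_window = test_window,
      cc_null = cc_null,
      auc_0_100 = cc_auc(corr, c(0, 0.1), bin),
      auc_0_50 = cc_auc(corr, c(0, 0.05), bin),
      auc_50_100 = cc_auc(corr, c(0.05, 0.1), bin)
    ),
    class = "cross_correlogram"
  )
}

#' @export
print.cross_correlogram <- function(x, ...) {
  cat(sprintf("<cross_correlogram> %s -> %s (%s): %d events, %d shuffles\n",
              x$ref_unit, x$target_unit, x$epoch, x$n_events, x$n_shuffles))
  cat(sprintf("  significant: %s; peak lag %s ms; AUC[0,100ms] = %.4g\n",
              x$significant,
              if (is.na(x$peak_lag)) "NA" else format(1000 * x$peak_lag),
              x$auc_0_100))
  invisible(x)
}

#' @rdname cross_correlogram
#' @param x,object A `cross_correlogram`.
#' @param ... Unused.
#' @method tidy cross_correlogram
#' @export
tidy.cross_correlogram <- function(x, ...) {
  tibble(
    ref_unit = x$ref_unit, target_unit = x$target_unit, epoch = x$epoch,
    lag_left_s = x$lag_left, raw = x$raw, predictor_mean = x$predictor_mean,
    predictor_sd = x$predictor_sd, corrected = x$corrected, z = x$z
  )
}

#' @rdname cross_correlogram
#' @method glance cross_correlogram
#' @export
glance.cross_correlogram <- function(x, ...) {
  tibble(
    ref_unit = x$ref_unit, target_unit = x$target_unit, epoch = x$epoch,
    n_events = x$n_events, significant = x$significant,
    peak_lag_ms = 1000 * x$peak_lag, auc_0_100 = x$auc_0_100,
    auc_0_50 = x$auc_0_50, auc_50_100 = x$auc_50_100, defined = x$defined
  )
}

#' @rdname cross_correlogram
#' @method autoplot cross_correlogram
#' @export
autoplot.cross_correlogram <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 1000 * (.data$lag_left_s + object$bin / 2),
                                   y = .data$corrected)) +
    ggplot2::geom_col(width = 1000 * object$bin, fill = "grey40") +
    ggplot2::geom_vline(xintercept = 1000 * object$test_window, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(
      x = "Lag (ms, target - ref)", y = "Corrected coincidences",
      title = sprintf("%s -> %s (%s)", object$ref_unit, object$target_unit,
                      object$epoch)
    ) +
    ggplot2::theme_minimal()
}

#' Per-pair, per-epoch synchrony table
#'
#' Enumerates all unordered pairs of simultaneously recorded units passing the
#' 0.1 Hz rate filter and computes a shift-predictor-corrected
#' cross-correlogram per epoch: `post_robot_surge` (2 s after each robot
#' activation), `post_pellet` (2 s after each pellet procurement in pre/post),
#' and `post_stim` (2 s after each stimulation onset). A pair is
#' "synchronized" when its corrected correlogram has a significant 0-100 ms
#' peak in the `post_robot_surge` epoch. In mixed pairs the
#' stimulation-responsive member is the reference, otherwise the lower unit
#' id; the reference choice is recorded so lag signs stay interpretable.
#'
#' @param session A `forage_session` (phases pre/threat/post, optionally
#'   robot).
#' @param classifications Optional output of [classify_units()]; provides the
#'   stimulation-responsiveness flags for pair categories.
#' @param epoch_window,lag_range,bin,n_shuffles,test_window,z_threshold,cc_null
#'   See [cross_correlogram()].
#' @param min_rate Rate filter threshold (Hz), see [filter_low_rate_units()].
#' @param auc_per_event Normalise AUCs by the epoch's event count (default
#'   `TRUE`), so epochs with different trial counts compare on a per-event
#'   scale.
#' @param seed Root seed; each pair x epoch draws from a derived stream.
#' @return Tibble with one row per pair x epoch: `pair_id`, `ref`, `target`,
#'   `category`, `epoch`, `n_events`, `significant`, `peak_lag_ms`,
#'   `auc_0_100`, `auc_0_50`, `auc_50_100`, `synchronized`.
#' @export
epoch_cc_table <- function(session, classifications = NULL,
                           epoch_window = c(0, 2), lag_range = c(-0.5, 0.5),
                           bin = 0.01, n_shuffles = 100,
                           test_window = c(0, 0.1), z_threshold = 3,
                           cc_null = c("shuffle", "flank"),
                           min_rate = 0.1, auc_per_event = TRUE, seed = NULL) {
  cc_null <- match.arg(cc_null)
  if (!"cc_excluded" %in% names(session$units)) {
    session <- filter_low_rate_units(session, min_rate)
  }
  units <- filter(session$units, !.data$cc_excluded)
  if (nrow(units) < 2) return(empty_cc_table())

  epochs <- list(
    post_robot_surge = phase_events(session, "robot_activation",
                                    c("threat", "robot"))$time_s,
    post_pellet = phase_events(session, "pellet_procurement",
                               c("pre", "post"))$time_s,
    post_stim = phase_events(session, "stim_onset", "threat")$time_s
  )
  epochs <- epochs[lengths(epochs) >= 2]
  if (length(epochs) == 0) return(empty_cc_table())

  stim_flag <- function(uid) {
    if (is.null(classifications)) return(NA)
    i <- match(uid, classifications$unit_id)
    if (is.na(i)) NA else classifications$stim_responsive[i]
  }
  ids <- sort(units$unit_id)
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  spikes <- lapply(ids, function(u) unit_spikes(session, u))
  names(spikes) <- ids

  rows <- purrr::imap(pairs, function(pr, pi) {
    s1 <- stim_flag(pr[1])
    s2 <- stim_flag(pr[2])
    # stim-responsive member leads in mixed pairs
    if (isTRUE(s2) && !isTRUE(s1)) pr <- rev(pr)
    category <- if (is.na(s1) || is.na(s2)) {
      NA_character_
    } else {
      classify_pair(s1, s2)
    }
    per_epoch <- purrr::imap(epochs, function(ev, ep_name) {
      cc <- cross_correlogram(
        spikes[[pr[1]]], spikes[[pr[2]]], ev, epoch_window, lag_range, bin,
        n_shuffles, test_window, z_threshold, cc_null,
        ref_unit = pr[1], target_unit = pr[2], epoch = ep_name,
        seed = if (is.null(seed)) NULL else {
          derive_seed(seed, c(pi, match(ep_name, names(epochs))))
        }
      )
      g <- glance(cc)
      if (auc_per_event) {
        g <- mutate(g, across(c("auc_0_100", "auc_0_50", "auc_50_100"),
                              ~ .x / cc$n_events))
      }
      g
    })
    out <- bind_rows(per_epoch)
    sync <- if ("post_robot_surge" %in% out$epoch) {
      isTRUE(out$significant[out$epoch == "post_robot_surge"])
    } else {
      NA
    }
    out %>%
      mutate(
        pair_id = paste(pr[1], pr[2], sep = ":"),
        category = category,
        synchronized = sync
      ) %>%
      rename(ref = "ref_unit", target = "target_unit") %>%
      select("pair_id", "ref", "target", "category", "epoch", "n_events",
             "significant", "peak_lag_ms", "auc_0_100", "auc_0_50",
             "auc_50_100", "synchronized")
  })
  bind_rows(rows)
}

empty_cc_table <- function() {
  tibble(
    pair_id = character(), ref = character(), target = character(),
    category = character(), epoch = character(), n_events = integer(),
    significant = logical(), peak_lag_ms = numeric(), auc_0_100 = numeric(),
    auc_0_50 = numeric(), auc_50_100 = numeric(), synchronized = logical()
  )
}
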