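#' Bin spikes around repeated events
#'
#' Builds the trial-by-bin count matrix of a peri-event time histogram. Bins
#' are half-open: bin `j` of trial `i` counts spikes in
#' `[event_i + left + (j-1) bw, event_i + left + j bw)`, so a spike exactly on
#' an edge belongs to the bin that edge opens (a spike at the event time falls
#' in the first post-event bin). Trials whose window would extend beyond the
#' recording bounds are dropped with a warning rather than zero-padded, since
#' padding would bias the baseline variance.
#'
#' @param times Spike times of one unit (s); order irrelevant.
#' @param event_times Alignment event times (s), one per trial.
#' @param window Two-element window relative to the event, default
#'   `c(-5, 5)` s.
#' @param bin_width Bin width in seconds (0.1 s is the classification
#'   canonical; 1 s is used for population traces and speed screening).
#' @param t_range Optional recording bounds `c(t0, t1)` used to drop
#'   out-of-bounds trials.
#' @return Integer matrix of counts, one row per kept trial, with attributes
#'   `bin_left` (left bin edges, s, event-relative) and `dropped` (number of
#'   dropped trials).
#' @export
bin_spikes <- function(times, event_times, window = c(-5, 5), bin_width = 0.1,
                       t_range = NULL) {
  stopifnot_scalar_number(bin_width, "bin_width", positive = TRUE)
  span <- window[2] - window[1]
  n_bins <- round(span / bin_width)
  if (abs(span - n_bins * bin_width) > 1e-9 || n_bins < 1) {
    abort("`bin_width` must divide the window span exactly.")
  }
  if (length(event_times) == 0) abort("`event_times` must be non-empty.")

  keep <- rep(TRUE, length(event_times))
  if (!is.null(t_range)) {
    keep <- event_times + window[1] >= t_range[1] - 1e-12 &
      event_times + window[2] <= t_range[2] + 1e-12
    if (any(!keep)) {
      warn(sprintf("Dropped %d trial(s) whose window exceeds the recording bounds.",
                   sum(!keep)))
    }
  }
  events <- event_times[keep]
  counts <- matrix(0L, nrow = length(events), ncol = n_bins)
  times <- sort(times)
  for (i in seq_along(events)) {
    # pre-select with one bin of slack; exact membership is decided by
    # bin_index on event-relative times so the edge convention is uniform
    lo <- findInterval(events[i] + window[1] - bin_width, times, left.open = TRUE)
    hi <- findInterval(events[i] + window[2] + bin_width, times, left.open = TRUE)
    if (hi > lo) {
      idx <- bin_index(times[(lo + 1L):hi] - events[i], window[1], bin_width, n_bins)
      idx <- idx[!is.na(idx)]
      if (length(idx) > 0) counts[i, ] <- tabulate(idx, nbins = n_bins)
    }
  }
  attr(counts, "bin_left") <- window[1] + bin_width * (seq_len(n_bins) - 1)
  attr(counts, "dropped") <- sum(!keep)
  counts
}

#' Baseline z-normalisation of a PETH
#'
#' The trial-averaged per-bin rate is z-scored against the pre-event baseline
#' (by default the 50 bins covering -5 to 0 s at 0.1 s resolution): with
#' `mu` and `sigma` the mean and sample standard deviation (denominator
#' n - 1) of the averaged rate over the baseline bins,
#' `z_j = (rate_j - mu) / sigma`. When the baseline has zero variance the
#' unit is flagged non-classifiable and `z` is `NA`.
#'
#' @param counts Trial-by-bin count matrix from [bin_spikes()].
#' @param bin_width Bin width in seconds.
#' @param baseline_bins Indices of the baseline bins (default: all bins left
#'   of the event).
#' @return List with `mean_rate` (Hz per bin), `z`, `mu`, `sigma` (Hz), and
#'   `classifiable`.
#' @export
zscore_peth <- function(counts, bin_width, baseline_bins = NULL) {
  bin_left <- attr(counts, "bin_left")
  if (is.null(baseline_bins)) {
    if (is.null(bin_left)) {
      abort("Supply `baseline_bins` when `counts` carries no `bin_left` attribute.")
    }
    baseline_bins <- which(bin_left < 0)
  }
  if (length(baseline_bins) < 2) abort("Need at least 2 baseline bins.")
  mean_rate <- colMeans(counts) / bin_width
  mu <- mean(mean_rate[baseline_bins])
  sigma <- sd(mean_rate[baseline_bins])
  classifiable <- is.finite(sigma) && sigma > 0
  z <- if (classifiable) (mean_rate - mu) / sigma else rep(NA_real_, length(mean_rate))
  list(mean_rate = mean_rate, z = z, mu = mu, sigma = sigma,
       classifiable = classifiable)
}

#' Peri-event time histogram for one unit and one alignment event
#'
#' Convenience wrapper combining [bin_spikes()] and [zscore_peth()] into a
#' `peth` object.
#'
#' @inheritParams bin_spikes
#' @param baseline Baseline window `c(a, b)` in event-relative seconds
#'   (bins with left edge in `[a, b)`); default `c(-5, 0)`.
#' @param unit_id,event_kind,phase Optional labels carried into the output.
#' @return A `peth` object: list with the count matrix, per-bin `mean_rate`
#'   and `z`, baseline statistics, and metadata. Has [tidy()], [glance()]
#'   and [autoplot()] methods.
#' @export
compute_peth <- function(times, event_times, window = c(-5, 5), bin_width = 0.1,
                         baseline = c(-5, 0), t_range = NULL,
                         unit_id = NA_character_, event_kind = NA_character_,
                         phase = NA_character_) {
  counts <- bin_spikes(times, event_times, window, bin_width, t_range)
  bin_left <- attr(counts, "bin_left")
  baseline_bins <- which(bin_left >= baseline[1] - 1e-12 & bin_left < baseline[2] - 1e-12)
  zs <- zscore_peth(counts, bin_width, baseline_bins)
  structure(
    list(
      unit_id = unit_id, event_kind = event_kind, phase = phase,
      counts = counts, bin_left = bin_left, bin_width = bin_width,
      window = window, baseline = baseline, baseline_bins = baseline_bins,
      n_trials = nrow(counts), mean_rate = zs$mean_rate, z = zs$z,
      mu = zs$mu, sigma = zs$sigma, classifiable = zs$classifiable
    ),
    class = "peth"
  )
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("<peth> unit %s, %s, phase %s: %d trials x %d bins (%g s)\n",
              x$unit_id, x$event_kind, x$phase, x$n_trials,
              length(x$bin_left), x$bin_width))
  cat(sprintf("  baseline %.2f +/- %.2f Hz; %s\n", x$mu, x$sigma,
              if (x$classifiable) sprintf("peak z = %.2f", max(x$z)) else
                "non-classifiable (zero baseline variance)"))
  invisible(x)
}

#' @rdname compute_peth
#' @param x A `peth` object.
#' @param ... Unused.
#' @method tidy peth
#' @export
tidy.peth <- function(x, ...) {
  tibble(
    unit_id = x$unit_id, event_kind = x$event_kind, phase = x$phase,
    bin_left_s = x$bin_left, mean_rate_hz = x$mean_rate, z = x$z
  )
}

#' @rdname compute_peth
#' @method glance peth
#' @export
glance.peth <- function(x, ...) {
  tibble(
    unit_id = x$unit_id, event_kind = x$event_kind, phase = x$phase,
    n_trials = x$n_trials, n_bins = length(x$bin_left),
    baseline_mean_hz = x$mu, baseline_sd_hz = x$sigma,
    classifiable = x$classifiable,
    peak_z = if (x$classifiable) max(x$z) else NA_real_
  )
}

#' @rdname compute_peth
#' @param object A `peth` object.
#' @method autoplot peth
#' @export
autoplot.peth <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_left_s + object$bin_width / 2,
                                   y = .data$z)) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = c(-3, 3), linetype = 3) +
    ggplot2::labs(
      x = "Time from event (s)", y = "Firing rate (z)",
      title = sprintf("Unit %s | %s | %s", object$unit_id,
                      object$event_kind, object$phase)
    ) +
    ggplot2::theme_minimal()
}

#' Export a PETH table
#'
#' One row per bin: `unit_id`, `event_kind`, `phase`, `bin_left_s`,
#' `mean_rate_hz`, `z`.
#'
#' @param peths A `peth` object or list of them.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_peth_table <- function(peths, path) {
  if (inherits(peths, "peth")) peths <- list(peths)
  readr::write_tsv(bind_rows(lapply(peths, tidy)), path, progress = FALSE)
  invisible(path)
}
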