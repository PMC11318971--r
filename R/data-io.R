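#' Read and write spike, event, tracking, and trial tables
#'
#' Tab-delimited, header row, UTF-8, '.' decimal. These tables are the
#' on-disk interchange format of the package: `spikes.tsv` holds one row per
#' spike (`unit_id`, `region`, `time_s`), `events.tsv` one row per behavioural
#' event (`kind`, `trial_index`, `time_s`), `tracking.tsv` a uniformly sampled
#' position trace (`t`, `x`, `y` in seconds and centimetres), and `trials.tsv`
#' one row per trial (`trial_index`, `phase`, `gate_open_time`, `outcome`,
#' optionally `excluded` and `exclusion_reason`). Writing then reading any
#' table reproduces the in-memory tibble exactly.
#'
#' @param path Path of the file to read or write.
#' @param x Tibble to write, with the columns listed above.
#' @return The readers return a tibble: spikes sorted by `unit_id` then
#'   `time_s`; events sorted by `kind` then `time_s`; tracking in time order
#'   with a `sample_rate_hz` attribute; trials sorted by `trial_index`. The
#'   writers return `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_spike_table(
#'   tibble::tibble(unit_id = "u1", region = "dPAG", time_s = c(0.5, 0.2)), f
#' )
#' read_spike_table(f)
#' @name table_io
NULL

read_delim_checked <- function(path, required) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'", path))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("'%s' is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  df
}

parse_numeric_column <- function(df, col, path) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(x) & !is.na(df[[col]]))
  if (length(bad) > 0) {
    # +1 for the header row so the number matches the text file
    abort(sprintf("'%s': non-numeric value '%s' in column '%s' at line %d",
                  path, df[[col]][bad[1]], col, bad[1] + 1L))
  }
  if (anyNA(x)) {
    abort(sprintf("'%s': missing value in column '%s' at line %d",
                  path, col, which(is.na(x))[1] + 1L))
  }
  x
}

#' @rdname table_io
#' @export
read_spike_table <- function(path) {
  df <- read_delim_checked(path, c("unit_id", "region", "time_s"))
  spikes <- tibble(
    unit_id = df$unit_id,
    region = df$region,
    time_s = parse_numeric_column(df, "time_s", path)
  )
  bad_region <- setdiff(unique(spikes$region), REGIONS)
  if (length(bad_region) > 0) {
    abort(sprintf("'%s': unknown region '%s'; allowed: %s",
                  path, bad_region[1], paste(REGIONS, collapse = ", ")))
  }
  validate_spikes(spikes, source = path)
}

validate_spikes <- function(spikes, source = "spikes") {
  if (any(spikes$time_s < 0)) {
    abort(sprintf("%s: spike times must be >= 0", source))
  }
  spikes <- arrange(spikes, .data$unit_id, .data$time_s)
  dup <- spikes %>%
    group_by(.data$unit_id) %>%
    summarise(min_gap = if (n() > 1) min(diff(.data$time_s)) else Inf) %>%
    filter(.data$min_gap < TIME_RESOLUTION - 1e-12) # tolerance for text round-trips
  if (nrow(dup) > 0) {
    abort(sprintf(
      "%s: unit '%s' has spikes closer than the 1/32000 s acquisition resolution",
      source, dup$unit_id[1]
    ))
  }
  spikes
}

#' @rdname table_io
#' @export
write_spike_table <- function(x, path) {
  readr::write_tsv(x[, c("unit_id", "region", "time_s")], path, progress = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_event_table <- function(path) {
  df <- read_delim_checked(path, c("kind", "trial_index", "time_s"))
  bad <- setdiff(unique(df$kind), EVENT_KINDS)
  if (length(bad) > 0) {
    abort(sprintf("'%s': unknown event kind '%s'; allowed kinds: %s",
                  path, bad[1], paste(EVENT_KINDS, collapse = ", ")))
  }
  events <- tibble(
    kind = df$kind,
    trial_index = as.integer(parse_numeric_column(df, "trial_index", path)),
    time_s = parse_numeric_column(df, "time_s", path)
  )
  arrange(events, .data$kind, .data$time_s)
}

#' @rdname table_io
#' @export
write_event_table <- function(x, path) {
  readr::write_tsv(x[, c("kind", "trial_index", "time_s")], path, progress = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @param tolerance Maximum deviation (s) from uniform sampling before
#'   `read_tracking()` rejects the trace.
#' @export
read_tracking <- function(path, tolerance = 1e-6) {
  df <- read_delim_checked(path, c("t", "x", "y"))
  trace <- tibble(
    t = parse_numeric_column(df, "t", path),
    x = parse_numeric_column(df, "x", path),
    y = parse_numeric_column(df, "y", path)
  )
  validate_tracking(trace, tolerance = tolerance, source = path)
}

validate_tracking <- function(trace, tolerance = 1e-6, source = "tracking") {
  if (nrow(trace) >= 2) {
    dt <- diff(trace$t)
    if (any(dt <= 0)) {
      abort(sprintf("%s: time must be strictly increasing (first violation after t = %g)",
                    source, trace$t[which(dt <= 0)[1]]))
    }
    step <- median(dt)
    off <- which(abs(dt - step) > tolerance)
    if (length(off) > 0) {
      abort(sprintf(
        "%s: non-uniform sampling; gap of %g s between t = %g and t = %g (expected step %g s)",
        source, dt[off[1]], trace$t[off[1]], trace$t[off[1] + 1], step
      ))
    }
    attr(trace, "sample_rate_hz") <- 1 / step
  }
  trace
}

#' @rdname table_io
#' @export
write_tracking <- function(x, path) {
  readr::write_tsv(x[, c("t", "x", "y")], path, progress = FALSE)
  invisible(path)
}

#' Sampling rate of a tracking trace
#'
#' @param trace A tracking tibble with a `t` column.
#' @return Sampling rate in Hz.
#' @export
tracking_rate <- function(trace) {
  rate <- attr(trace, "sample_rate_hz")
  if (is.null(rate)) {
    if (nrow(trace) < 2) abort("Need >= 2 tracking samples to infer a rate.")
    rate <- 1 / median(diff(trace$t))
  }
  rate
}

#' @rdname table_io
#' @export
read_trial_table <- function(path) {
  df <- read_delim_checked(path, c("trial_index", "phase", "gate_open_time", "outcome"))
  bad <- setdiff(unique(df$phase), PHASES)
  if (length(bad) > 0) {
    abort(sprintf("'%s': unknown phase '%s'; allowed: %s",
                  path, bad[1], paste(PHASES, collapse = ", ")))
  }
  trials <- tibble(
    trial_index = as.integer(parse_numeric_column(df, "trial_index", path)),
    phase = df$phase,
    gate_open_time = parse_numeric_column(df, "gate_open_time", path),
    outcome = df$outcome,
    excluded = if ("excluded" %in% names(df)) as.logical(df$excluded) else FALSE,
    exclusion_reason = if ("exclusion_reason" %in% names(df)) {
      if_else(is.na(df$exclusion_reason), "", df$exclusion_reason)
    } else {
      ""
    }
  )
  arrange(trials, .data$trial_index)
}

#' @rdname table_io
#' @export
write_trial_table <- function(x, path) {
  cols <- c("trial_index", "phase", "gate_open_time", "outcome",
            "excluded", "exclusion_reason")
  if (!"excluded" %in% names(x)) x$excluded <- FALSE
  if (!"exclusion_reason" %in% names(x)) x$exclusion_reason <- ""
  readr::write_tsv(x[, cols], path, progress = FALSE)
  invisible(path)
}
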