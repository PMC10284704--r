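# Miniature EPSC event detection and per-cell summaries.
#
# Detection follows the stated acquisition filters: candidate deflections must
# reach 5 pA above the local baseline and have a 10-90% rise time under 3 ms.
# Baseline is a running median (window 50 ms); candidates are threshold
# crossings of the baseline-subtracted, lightly smoothed signal.  Inward
# currents are stored as positive magnitudes; negative-going raw traces are
# rectified at ingest.

#' Construct a current trace
#'
#' @param samples numeric vector of current samples (pA).  Positive-going
#'   deflections are event magnitudes; a predominantly negative-going trace is
#'   rectified by [detect_events()].
#' @param sample_rate_hz sampling rate (>= 2000 Hz for detection).
#' @param cell_id,condition_label identifiers carried through to summaries.
#' @param oxytocin was the slice recorded under oxytocin bath application?
#' @return object of class `current_trace`.
#' @export
current_trace <- function(samples, sample_rate_hz, cell_id = "cell",
                          condition_label = "saline", oxytocin = FALSE) {
  if (!length(samples) || any(!is.finite(samples)))
    stop("`samples` must be non-empty and finite", call. = FALSE)
  check_positive_scalar(sample_rate_hz, "sample_rate_hz")
  structure(list(samples = as.numeric(samples),
                 sample_rate_hz = sample_rate_hz,
                 cell_id = cell_id, condition_label = condition_label,
                 oxytocin = isTRUE(oxytocin)),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("Current trace '%s' (%s%s): %.3g s at %g kHz\n",
              x$cell_id, x$condition_label,
              if (x$oxytocin) ", +oxytocin" else "",
              length(x$samples) / x$sample_rate_hz,
              x$sample_rate_hz / 1000))
  invisible(x)
}

# Moving-average smoothing (centred); ends padded with the edge values.
smooth_ma <- function(x, n) {
  if (n <= 1L) return(x)
  xp <- c(rep(x[1L], n), x, rep(x[length(x)], n))
  as.numeric(stats::filter(xp, rep(1 / n, n), sides = 2L))[
    seq_along(x) + n]
}

# Interpolated crossing time (in samples) of `level`, walking left from
# index `peak` along `y` (not past `floor`); NA if the level is never
# crossed.
left_crossing <- function(y, peak, level, floor = 1L) {
  i <- peak
  while (i > floor && y[i - 1L] > level) i <- i - 1L
  if (i == floor) return(NA_real_)
  # y[i-1] <= level < y[i]
  (i - 1L) + (level - y[i - 1L]) / (y[i] - y[i - 1L])
}

# First upward crossing of `level` scanning forward from index `from` (may be
# fractional) up to `to`; NA if never crossed.
first_crossing <- function(y, from, to, level) {
  i <- max(2L, ceiling(from))
  while (i <= to && y[i] < level) i <- i + 1L
  if (i > to) return(NA_real_)
  (i - 1L) + (level - y[i - 1L]) / (y[i] - y[i - 1L])
}

#' Detect mEPSC events in a current trace
#'
#' Estimates the baseline with a running median, subtracts it, smooths the
#' residual with a short moving average, and takes contiguous regions above
#' `amp_threshold_pa` as candidate events.  Regions containing several peaks
#' separated by a dip below half the smaller peak are split.  For each
#' candidate, the amplitude is the raw baseline-subtracted maximum and the
#' 10-90\% rise time is measured on the smoothed signal by interpolated
#' threshold crossings left of the peak.  Candidates failing the amplitude or
#' rise-time filter are dropped; events are returned sorted by onset (the
#' 10\% crossing time).
#'
#' @param trace a [current_trace()].
#' @param amp_threshold_pa minimum amplitude above baseline (default 5 pA).
#' @param max_rise_ms maximum 10-90\% rise time (default 3 ms; slower events
#'   are discarded as non-synaptic).
#' @param baseline_window_s running-median window (default 0.05 s).
#' @param smooth_ms moving-average width for detection (default 0.5 ms).
#' @return data frame (`event_table`) with `onset_s`, `amplitude_pa`,
#'   `rise_ms`, sorted by onset.
#' @export
detect_events <- function(trace, amp_threshold_pa = 5, max_rise_ms = 3,
                          baseline_window_s = 0.05, smooth_ms = 0.5) {
  stopifnot(inherits(trace, "current_trace"))
  fs <- trace$sample_rate_hz
  if (fs < 2000) stop("sample rate must be >= 2 kHz", call. = FALSE)
  y <- trace$samples
  k <- round(baseline_window_s * fs)
  if (k %% 2 == 0) k <- k + 1L
  if (length(y) <= k)
    stop(sprintf("trace (%d samples) shorter than the baseline window (%d samples)",
                 length(y), k), call. = FALSE)
  med <- stats::median(y)
  if (abs(min(y) - med) > abs(max(y) - med)) y <- -(y - med) + med  # rectify
  base <- stats::runmed(y, k, endrule = "median")
  d <- y - base
  nsm <- max(1L, round(smooth_ms / 1000 * fs))
  dsm <- smooth_ma(d, nsm)

  above <- dsm > amp_threshold_pa
  if (!any(above))
    return(empty_event_table())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regions <- cbind(starts[r$values], ends[r$values])
  # a decaying event can dip just below threshold and re-cross on a noise
  # bump; merge regions separated by less than 3 ms so tails are not
  # re-counted (genuinely overlapping events are re-split by the peak rule)
  gap <- round(0.003 * fs)
  if (nrow(regions) > 1L) {
    merged <- regions[1L, , drop = FALSE]
    for (ri in 2:nrow(regions)) {
      if (regions[ri, 1L] - merged[nrow(merged), 2L] < gap)
        merged[nrow(merged), 2L] <- regions[ri, 2L]
      else merged <- rbind(merged, regions[ri, ])
    }
    regions <- merged
  }

  min_sep <- max(1L, round(0.001 * fs))  # 1 ms between split peaks
  events <- list()
  for (ri in seq_len(nrow(regions))) {
    s <- regions[ri, 1L]; e <- regions[ri, 2L]
    seg <- dsm[s:e]
    # local maxima within the region
    if (length(seg) < 3L) {
      peaks <- s + which.max(seg) - 1L
    } else {
      loc <- which(diff(sign(diff(seg))) < 0) + 1L
      if (!length(loc)) loc <- which.max(seg)
      peaks <- s + loc - 1L
      # keep peaks separated by a real dip (< 50% of the smaller peak)
      if (length(peaks) > 1L) {
        keep <- peaks[1L]
        for (p in peaks[-1L]) {
          prev <- keep[length(keep)]
          trough <- min(dsm[prev:p])
          if (p - prev >= min_sep && trough < 0.5 * min(dsm[prev], dsm[p]))
            keep <- c(keep, p)
          else if (dsm[p] > dsm[prev]) keep[length(keep)] <- p
        }
        peaks <- keep
      }
    }
    prev_peak <- 1L
    for (p in peaks) {
      pv <- dsm[p]
      w <- max(1L, round(0.0005 * fs))
      lo <- max(1L, p - w); hi <- min(length(d), p + w)
      amplitude <- max(d[lo:hi])
      # onset at the last 10% crossing before the peak; rise to the FIRST
      # 90% crossing after it, so late noise bumps on the decay plateau do
      # not stretch the measured rise
      c10 <- left_crossing(dsm, p, 0.1 * pv, floor = prev_peak)
      prev_peak <- p
      if (is.na(c10)) next  # truncated at trace start / unresolved overlap
      c90 <- first_crossing(dsm, c10, p, 0.9 * pv)
      if (is.na(c90)) next
      rise_ms <- (c90 - c10) / fs * 1000
      events[[length(events) + 1L]] <-
        c(onset = c10 / fs, amplitude = amplitude, rise = rise_ms)
    }
  }
  if (!length(events)) return(empty_event_table())
  ev <- as.data.frame(do.call(rbind, events))
  names(ev) <- c("onset_s", "amplitude_pa", "rise_ms")
  ev <- ev[ev$amplitude_pa >= amp_threshold_pa & ev$rise_ms < max_rise_ms &
             ev$rise_ms > 0, , drop = FALSE]
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

empty_event_table <- function() {
  data.frame(onset_s = numeric(0), amplitude_pa = numeric(0),
             rise_ms = numeric(0))
}

#' Summarise detected events for one cell
#'
#' Uses at most the first `cap` events (200 by default, matching standard
#' per-cell acquisition).  Frequency is events per second of analysed
#' duration: the full `duration_s` when the cap is not reached, otherwise the
#' time needed to collect `cap` events.  Inter-event intervals are successive
#' onset differences over the events used.
#'
#' @param events event table from [detect_events()] (or generator ground
#'   truth).
#' @param duration_s analysed trace duration in seconds.
#' @param cap maximum number of events used per cell.
#' @param cell_id,condition_label identifiers carried into the summary.
#' @return object of class `cell_summary`: `frequency_hz`,
#'   `mean_amplitude_pa`, `ieis_s`, `n_events_used`, `no_events` flag.
#' @export
summarize_cell <- function(events, duration_s, cap = 200,
                           cell_id = "cell", condition_label = "saline") {
  check_positive_scalar(duration_s, "duration_s")
  check_columns(events, c("onset_s", "amplitude_pa"), "event table")
  n <- nrow(events)
  if (n == 0L)
    return(structure(list(cell_id = cell_id,
                          condition_label = condition_label,
                          frequency_hz = 0, mean_amplitude_pa = NA_real_,
                          ieis_s = numeric(0), n_events_used = 0L,
                          no_events = TRUE), class = "cell_summary"))
  events <- events[order(events$onset_s), , drop = FALSE]
  used <- utils::head(events, cap)
  analysed <- if (n > cap) used$onset_s[cap] else duration_s
  structure(list(
    cell_id = cell_id,
    condition_label = condition_label,
    frequency_hz = nrow(used) / analysed,
    mean_amplitude_pa = mean(used$amplitude_pa),
    ieis_s = diff(used$onset_s),
    n_events_used = nrow(used),
    no_events = FALSE
  ), class = "cell_summary")
}

#' @export
print.cell_summary <- function(x, ...) {
  cat(sprintf("Cell '%s' (%s): %.3g Hz, mean amplitude %.3g pA (%d events)\n",
              x$cell_id, x$condition_label, x$frequency_hz,
              x$mean_amplitude_pa, x$n_events_used))
  invisible(x)
}

#' Combine cell summaries into a data frame
#'
#' @param summaries list of `cell_summary` objects.
#' @return data frame with one row per cell.
#' @export
bind_cell_summaries <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s)
    data.frame(cell_id = s$cell_id, condition_label = s$condition_label,
               frequency_hz = s$frequency_hz,
               mean_amplitude_pa = s$mean_amplitude_pa,
               n_events_used = s$n_events_used)))
}

#' Compare mEPSC frequency and amplitude across conditions
#'
#' One-way ANOVA on per-cell frequency and (separately) mean amplitude across
#' treatment conditions, with optional pairwise comparisons.  Conditions with
#' fewer than two cells are excluded with a warning record.
#'
#' @param summaries data frame from [bind_cell_summaries()] (columns
#'   `condition_label`, `frequency_hz`, `mean_amplitude_pa`).
#' @param pairs optional list of condition pairs for
#'   [multiple_comparisons()] on frequency.
#' @return list of class `condition_comparison`: `frequency` and `amplitude`
#'   ANOVA results, `pairwise` (or `NULL`), `excluded_conditions`,
#'   `group_means`.
#' @export
condition_comparison <- function(summaries, pairs = NULL) {
  check_columns(summaries,
                c("condition_label", "frequency_hz", "mean_amplitude_pa"),
                "summaries")
  counts <- table(summaries$condition_label)
  excluded <- names(counts)[counts < 2L]
  if (length(excluded))
    warning("condition(s) with a single cell excluded: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  keep <- summaries[!summaries$condition_label %in% excluded, , drop = FALSE]
  if (length(unique(keep$condition_label)) < 2L)
    stop("need at least 2 conditions with >= 2 cells each", call. = FALSE)
  freq_groups <- split(keep$frequency_hz, keep$condition_label)
  amp_groups <- split(keep$mean_amplitude_pa, keep$condition_label)
  pairwise <- if (!is.null(pairs))
    multiple_comparisons(freq_groups, pairs) else NULL
  structure(list(
    frequency = one_way_anova(freq_groups),
    amplitude = one_way_anova(amp_groups),
    pairwise = pairwise,
    excluded_conditions = excluded,
    group_means = data.frame(
      condition_label = names(freq_groups),
      mean_frequency_hz = vapply(freq_groups, mean, numeric(1)),
      mean_amplitude_pa = vapply(amp_groups, mean, numeric(1)),
      n_cells = lengths(freq_groups))
  ), class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("mEPSC condition comparison\n  frequency: ")
  cat(sprintf("F(%d,%d) = %.3g, P = %.4g\n", x$frequency$df[1L],
              x$frequency$df[2L], x$frequency$statistic,
              x$frequency$p_value))
  cat("  amplitude: ")
  cat(sprintf("F(%d,%d) = %.3g, P = %.4g\n", x$amplitude$df[1L],
              x$amplitude$df[2L], x$amplitude$statistic,
              x$amplitude$p_value))
  invisible(x)
}

#' Empirical cumulative distribution
#'
#' Right-continuous ECDF evaluated at the sorted observed values (reaches 1.0
#' at the maximum) — the form used for cumulative probability plots of
#' inter-event intervals and amplitudes.
#'
#' @param values numeric vector (n >= 1).
#' @return data frame with `value` (sorted) and `cumulative_probability`.
#' @export
cumulative_distribution <- function(values) {
  if (!length(values)) stop("empty input", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite values", call. = FALSE)
  s <- sort(values)
  data.frame(value = s, cumulative_probability = stats::ecdf(values)(s))
}
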