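#' Peak detector configuration
#'
#' Parameters of the streaming peak-detection algorithm run on the sensing
#' microcontroller. The baseline is a moving average of the most recent
#' `baseline_window` baseline-classified samples; samples inside an open
#' peak are excluded so transits do not drag the baseline upward. A peak
#' opens when the signal exceeds `baseline + threshold_multiple * SD` of
#' the window and closes when it returns to or below the threshold frozen
#' at entry.
#'
#' @param baseline_window number of recent baseline samples in the moving
#'   average (>= 2). Default 200 (20 ms at the default 10 kHz sampling).
#' @param threshold_multiple unitless multiple `k` of the window SD above
#'   the moving average; default 5 for standard 5-sigma false-positive
#'   suppression.
#' @param group_time seconds within which peaks belong to one droplet.
#' @param min_peak_samples peaks spanning fewer samples are discarded.
#' @param expected_peaks_per_droplet 1 (single laser) or 3 (three lasers).
#' @param sd_mode `"window"` (default) takes the SD of the samples in the
#'   moving window; `"mean"` divides by `sqrt(n)` to use the SD of the
#'   mean estimator instead (numerically fragile; provided for comparison).
#' @param baseline_guard_samples guard band around peaks: baseline commits
#'   are delayed through a FIFO of this length so the sub-threshold rising
#'   flank of a pulse can be discarded when the peak opens, and this many
#'   samples after a peak closes (the falling flank) are skipped. Without
#'   it, flank samples leak into the moving window and inflate its SD until
#'   small peaks are swallowed. Default 10 samples (1 ms at 10 kHz); 0
#'   disables the guard.
#' @param include_peaks_in_baseline diagnostic ablation: when TRUE, peak
#'   samples are fed back into the baseline average, reproducing the drift
#'   failure the exclusion rule exists to prevent. Default FALSE.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(baseline_window = 200,
                            threshold_multiple = 5,
                            group_time = 0.008,
                            min_peak_samples = 3,
                            expected_peaks_per_droplet = 3,
                            sd_mode = c("window", "mean"),
                            baseline_guard_samples = 10,
                            include_peaks_in_baseline = FALSE) {
  sd_mode <- match.arg(sd_mode)
  if (baseline_guard_samples < 0)
    stop("`baseline_guard_samples` must be >= 0", call. = FALSE)
  if (baseline_window < 2) stop("`baseline_window` must be >= 2", call. = FALSE)
  if (threshold_multiple <= 0)
    stop("`threshold_multiple` must be > 0", call. = FALSE)
  if (group_time <= 0) stop("`group_time` must be > 0", call. = FALSE)
  stopifnot(expected_peaks_per_droplet %in% c(1L, 3L))
  structure(
    list(baseline_window = as.integer(baseline_window),
         threshold_multiple = threshold_multiple,
         group_time = group_time,
         min_peak_samples = as.integer(min_peak_samples),
         expected_peaks_per_droplet = as.integer(expected_peaks_per_droplet),
         sd_mode = sd_mode,
         baseline_guard_samples = as.integer(baseline_guard_samples),
         include_peaks_in_baseline = isTRUE(include_peaks_in_baseline)),
    class = "detector_config"
  )
}

#' Create a streaming peak detector
#'
#' Returns a stateful detector that can be fed a trace in arbitrary chunks;
#' chunked invocation is bit-identical to a single pass over the same
#' samples. The first `baseline_window` samples are always classified as
#' baseline (warm-up); no peak can open there.
#'
#' @param cfg a [detector_config()].
#' @param sample_rate samples/second of the stream to be fed.
#' @param t0 time of the first sample (seconds).
#' @return An object of class `peak_detector` with methods used via
#'   [detector_feed()], [detector_finalize()] and [detector_baseline()].
#' @seealso [detect_peaks()] for the one-shot interface.
#' @export
peak_detector <- function(cfg, sample_rate, t0 = 0) {
  stopifnot(inherits(cfg, "detector_config"), sample_rate > 0)
  state <- list(
    buf = numeric(cfg$baseline_window),
    pend = numeric(max(1L, cfg$baseline_guard_samples)),
    head = 0L, nbuf = 0L, pend_head = 0L, pend_n = 0L,
    guard = cfg$baseline_guard_samples,
    bsum = 0, bsumsq = 0, nseen = 0, skip = 0L,
    in_peak = FALSE, peak_start = 0, peak_max = 0,
    entry_base = 0, entry_thr = 0, peak_nsamp = 0L,
    k = cfg$threshold_multiple, min_len = cfg$min_peak_samples,
    sd_mode = if (cfg$sd_mode == "mean") 1L else 0L,
    include_peaks_in_baseline = cfg$include_peaks_in_baseline
  )
  structure(list(cfg = cfg, sample_rate = sample_rate, t0 = t0,
                 state = state),
            class = "peak_detector")
}

#' @rdname peak_detector
#' @param det a `peak_detector`.
#' @param signal numeric vector of samples (volts).
#' @return `detector_feed()`: a list with the updated detector (`detector`)
#'   and the peaks closed during this chunk (`peaks`, a data.frame as in
#'   [detect_peaks()]).
#' @export
detector_feed <- function(det, signal) {
  stopifnot(inherits(det, "peak_detector"))
  out <- .detector_feed_cpp(as.numeric(signal), det$state)
  det$state <- out$state
  list(detector = det, peaks = peaks_to_df(out$peaks, det))
}

#' @rdname peak_detector
#' @return `detector_finalize()`: a data.frame holding the still-open peak
#'   closed at the last sample (if any survives `min_peak_samples`).
#' @export
detector_finalize <- function(det) {
  s <- det$state
  if (isTRUE(s$in_peak) && s$peak_nsamp >= s$min_len) {
    m <- matrix(c(s$peak_start, s$nseen, s$peak_max - s$entry_base,
                  s$entry_base), 1, 4,
                dimnames = list(NULL, c("start", "end", "mag", "base")))
    peaks_to_df(m, det)
  } else {
    peaks_to_df(matrix(numeric(0), 0, 4,
                       dimnames = list(NULL,
                                       c("start", "end", "mag", "base"))),
                det)
  }
}

#' @rdname peak_detector
#' @return `detector_baseline()`: the current moving-average baseline
#'   estimate (volts), `NA` before any baseline sample was seen.
#' @export
detector_baseline <- function(det) {
  s <- det$state
  if (s$nbuf == 0) NA_real_ else s$bsum / s$nbuf
}

peaks_to_df <- function(m, det) {
  idx_to_t <- function(i) det$t0 + (i - 1) / det$sample_rate
  data.frame(start_time = idx_to_t(m[, "start"]),
             end_time = idx_to_t(m[, "end"]),
             magnitude = m[, "mag"],
             baseline_at_entry = m[, "base"])
}

#' Detect peaks in a fluorescence trace
#'
#' Single forward pass of the streaming detector over a uniformly sampled
#' trace. A peak's magnitude is its maximum signal minus the baseline
#' frozen at peak entry; peaks shorter than `min_peak_samples` are
#' discarded; a peak still open at end-of-trace is closed at the last
#' sample.
#'
#' @param trace a `droplet_trace` (from [make_trace()] or [read_trace()]),
#'   or any data.frame with `time_s` and `signal_v` columns on a uniform
#'   time grid.
#' @param cfg a [detector_config()].
#' @return A data.frame with one row per peak: `start_time`, `end_time`
#'   (s), `magnitude` (V above baseline at entry), `baseline_at_entry` (V).
#' @examples
#' ps <- population_spec(droplets_per_group = 1,
#'                       group_means = default_group_means()[8, , drop = FALSE])
#' tr <- make_population_traces(ps)$trace
#' nrow(detect_peaks(tr, detector_config()))  # 3 peaks for one droplet
#' @export
detect_peaks <- function(trace, cfg) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "signal_v") %in% names(trace)))
  n <- nrow(trace)
  if (n == 0) stop("trace is empty", call. = FALSE)
  if (n < cfg$baseline_window)
    stop("trace shorter than `baseline_window`: insufficient warm-up",
         call. = FALSE)
  dt <- diff(trace$time_s)
  if (any(abs(dt - dt[1]) > 1e-9 * max(dt[1], 1)))
    stop("trace is not uniformly sampled", call. = FALSE)
  sr <- 1 / dt[1]
  det <- peak_detector(cfg, sr, t0 = trace$time_s[1])
  fed <- detector_feed(det, trace$signal_v)
  rbind(fed$peaks, detector_finalize(fed$detector))
}

#' Group peaks into droplet signatures
#'
#' Greedy left-to-right grouping: a group opens at the first ungrouped peak
#' and absorbs subsequent peaks starting within `group_time` of the group's
#' first peak start. Groups with a number of peaks different from
#' `expected_peaks_per_droplet` are flagged incomplete, with zeros padding
#' missing channels; the sorter must not deflect such droplets.
#'
#' @param peaks data.frame from [detect_peaks()], sorted by `start_time`.
#' @param cfg a [detector_config()].
#' @return A data.frame with one row per droplet: `droplet_time` (start of
#'   the group's first peak, s), `mag1..magE` (ordered peak magnitudes in
#'   laser order, volts; E = `expected_peaks_per_droplet`), `n_peaks`, and
#'   `complete` (TRUE iff exactly E peaks were found).
#' @export
group_peaks <- function(peaks, cfg) {
  e <- cfg$expected_peaks_per_droplet
  mag_cols <- paste0("mag", seq_len(e))
  if (nrow(peaks) == 0) {
    out <- data.frame(droplet_time = numeric(0))
    for (mc in mag_cols) out[[mc]] <- numeric(0)
    out$n_peaks <- integer(0)
    out$complete <- logical(0)
    return(out)
  }
  if (is.unsorted(peaks$start_time))
    stop("peaks must be sorted by `start_time`", call. = FALSE)
  starts <- peaks$start_time
  n <- length(starts)
  group <- integer(n)
  g <- 0L
  anchor <- -Inf
  for (i in seq_len(n)) {
    if (starts[i] - anchor > cfg$group_time) {
      g <- g + 1L
      anchor <- starts[i]
    }
    group[i] <- g
  }
  rows <- lapply(split(seq_len(n), group), function(idx) {
    mags <- peaks$magnitude[idx]
    padded <- rep(0, e)
    padded[seq_len(min(e, length(mags)))] <- mags[seq_len(min(e, length(mags)))]
    c(droplet_time = starts[idx[1]], padded, n_peaks = length(idx))
  })
  m <- do.call(rbind, rows)
  out <- data.frame(droplet_time = m[, 1])
  for (j in seq_len(e)) out[[mag_cols[j]]] <- m[, 1 + j]
  out$n_peaks <- as.integer(m[, e + 2])
  out$complete <- out$n_peaks == e
  rownames(out) <- NULL
  out
}

#' Score detected signatures against ground truth
#'
#' Matches detected droplet signatures to true droplets by time: a
#' signature matches a truth record if its `droplet_time` lies within
#' `group_time` of the true first-pulse center, greedily in time order and
#' one-to-one.
#'
#' @param signatures data.frame from [group_peaks()].
#' @param truth ground-truth data.frame from [make_population_traces()].
#' @param cfg the [detector_config()] used (supplies `group_time` and the
#'   expected channel count).
#' @return A list: `recall`, `precision`, `magnitude_rmse` (RMSE of matched
#'   complete-signature magnitudes vs true pulse heights, volts; `NA` if no
#'   matches), `n_matched`.
#' @export
detector_score <- function(signatures, truth, cfg) {
  e <- cfg$expected_peaks_per_droplet
  n_truth <- nrow(truth)
  det <- signatures[signatures$complete, , drop = FALSE]
  n_det <- nrow(det)
  matched_t <- logical(n_truth)
  matched_d <- integer(0)
  err2 <- numeric(0)
  j <- 1L
  for (i in seq_len(n_det)) {
    while (j <= n_truth &&
           truth$t1[j] < det$droplet_time[i] - cfg$group_time) j <- j + 1L
    if (j <= n_truth && !matched_t[j] &&
        abs(det$droplet_time[i] - truth$t1[j]) <= cfg$group_time) {
      matched_t[j] <- TRUE
      matched_d <- c(matched_d, i)
      tru <- as.numeric(truth[j, paste0("h", seq_len(e))])
      est <- as.numeric(det[i, paste0("mag", seq_len(e))])
      err2 <- c(err2, (est - tru)^2)
    }
  }
  list(recall = if (n_truth) sum(matched_t) / n_truth else NA_real_,
       precision = if (n_det) length(matched_d) / n_det else NA_real_,
       magnitude_rmse = if (length(err2)) sqrt(mean(err2)) else NA_real_,
       n_matched = length(matched_d))
}
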