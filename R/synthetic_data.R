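#' Specify a synthetic PMT trace
#'
#' A trace emulates the digitized photomultiplier-tube voltage recorded as
#' droplets transit laser excitation points: a baseline (optionally
#' drifting linearly, the simplest adversarial case for baseline tracking),
#' additive Gaussian noise, and a train of Gaussian pulses, one per
#' droplet/laser crossing.
#'
#' @param sample_rate samples per second (> 0).
#' @param duration trace length in seconds (> 0).
#' @param baseline_level baseline voltage.
#' @param baseline_drift_rate linear drift in volts/second.
#' @param noise_sd Gaussian noise standard deviation in volts (>= 0).
#' @param pulses data.frame (or NULL for none) with columns `center_time`
#'   (s), `height` (V above baseline) and `width_sd` (Gaussian sigma, s, > 0).
#' @param seed integer seed; identical seeds give bit-identical traces.
#' @return An object of class `trace_spec`.
#' @seealso [make_trace()]
#' @export
trace_spec <- function(sample_rate = 10000, duration = 1,
                       baseline_level = 0.5, baseline_drift_rate = 0,
                       noise_sd = 0.02, pulses = NULL, seed = 1L) {
  if (is.null(pulses)) {
    pulses <- data.frame(center_time = numeric(0), height = numeric(0),
                         width_sd = numeric(0))
  }
  stopifnot(is.data.frame(pulses),
            all(c("center_time", "height", "width_sd") %in% names(pulses)))
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number", call. = FALSE)
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    stop("`duration` must be a single positive number", call. = FALSE)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0)
    stop("`noise_sd` must be a single non-negative number", call. = FALSE)
  if (nrow(pulses) > 0 && any(pulses$width_sd <= 0))
    stop("all pulse `width_sd` must be > 0", call. = FALSE)
  structure(
    list(sample_rate = sample_rate, duration = duration,
         baseline_level = baseline_level,
         baseline_drift_rate = baseline_drift_rate,
         noise_sd = noise_sd, pulses = pulses, seed = as.integer(seed)),
    class = "trace_spec"
  )
}

#' Generate a synthetic PMT trace
#'
#' Evaluates `baseline + drift * t + noise + sum of Gaussian pulses` on a
#' uniform time grid. Deterministic given the spec's seed.
#'
#' @param spec a [trace_spec()].
#' @return A data.frame of class `droplet_trace` with columns `time_s` and
#'   `signal_v`, plus a `sample_rate` attribute.
#' @examples
#' tr <- make_trace(trace_spec(duration = 0.1, noise_sd = 0,
#'   pulses = data.frame(center_time = 0.05, height = 1, width_sd = 1e-3)))
#' max(tr$signal_v)
#' @export
make_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  n <- floor(spec$sample_rate * spec$duration)
  if (n < 1) stop("trace would contain no samples", call. = FALSE)
  t <- (seq_len(n) - 1) / spec$sample_rate
  sig <- spec$baseline_level + spec$baseline_drift_rate * t
  if (spec$noise_sd > 0) {
    sig <- sig + withr_rng(spec$seed, rnorm(n, 0, spec$noise_sd))
  } else {
    # still burn the RNG identically so pulse-free/noise-free specs with
    # equal seeds remain reproducible without touching the global stream
    invisible(NULL)
  }
  if (nrow(spec$pulses) > 0) {
    for (i in seq_len(nrow(spec$pulses))) {
      p <- spec$pulses[i, ]
      # evaluate only within +-6 sigma of the center: exact to double
      # precision for any realistic pulse, and O(width) not O(trace)
      lo <- max(1L, ceiling((p$center_time - 6 * p$width_sd) *
                              spec$sample_rate))
      hi <- min(n, floor((p$center_time + 6 * p$width_sd) *
                           spec$sample_rate) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      sig[idx] <- sig[idx] +
        p$height * exp(-0.5 * ((t[idx] - p$center_time) / p$width_sd)^2)
    }
  }
  structure(data.frame(time_s = t, signal_v = sig),
            class = c("droplet_trace", "data.frame"),
            sample_rate = spec$sample_rate)
}

# evaluate `expr` under a local RNG seeded with `seed`, leaving the global
# RNG stream untouched
withr_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify a mixed droplet population stream
#'
#' Describes the droplet stream a reinjection experiment would feed past
#' the three-laser sensing station: each droplet belongs to one of up to 8
#' fluorophore groups and contributes exactly three pulses (one per laser
#' position) whose heights are drawn from the group's per-channel
#' distribution.
#'
#' Default group means place each channel at a "low" (0.2 V) or "high"
#' (2.0 V) level according to the palette encoding, giving a
#' signal-to-noise ratio of 10 for the low level at the default trace noise
#' of 0.02 V.
#'
#' @param group_means numeric matrix, one row per group, 3 columns (mean
#'   pulse height per channel, volts, laser order 405/488/561 nm). Default:
#'   the 8 palette corners at low = 0.2 V, high = 2.0 V.
#' @param group_cv per-channel coefficient of variation of pulse heights
#'   (recycled across groups).
#' @param droplets_per_group droplets generated per group (balanced design);
#'   ignored when `group_sequence` is given.
#' @param group_sequence optional explicit arrival sequence of group ids
#'   (1-based row indices into `group_means`); overrides the balanced
#'   shuffled design. Used by the workflow simulator.
#' @param transit_spacing seconds between the three laser pulses of one
#'   droplet; must be smaller than `inter_droplet_gap` so one droplet's
#'   peaks can be grouped before the next arrives.
#' @param inter_droplet_gap seconds between successive droplet arrivals.
#' @param pulse_width_sd Gaussian pulse sigma in seconds.
#' @param lead_in seconds of pulse-free baseline before the first droplet
#'   (detector warm-up).
#' @param sample_rate,baseline_level,baseline_drift_rate,noise_sd trace
#'   parameters, as in [trace_spec()].
#' @param seed integer seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(group_means = default_group_means(),
                            group_cv = 0.05,
                            droplets_per_group = 50,
                            group_sequence = NULL,
                            transit_spacing = 0.003,
                            inter_droplet_gap = 0.02,
                            pulse_width_sd = 3e-4,
                            lead_in = 0.05,
                            sample_rate = 10000,
                            baseline_level = 0.5,
                            baseline_drift_rate = 0,
                            noise_sd = 0.02,
                            seed = 1L) {
  group_means <- as.matrix(group_means)
  stopifnot(ncol(group_means) == 3)
  if (any(group_means < 0))
    stop("group means must be non-negative", call. = FALSE)
  if (transit_spacing >= inter_droplet_gap)
    stop("`transit_spacing` must be < `inter_droplet_gap`: droplets would ",
         "be inseparable", call. = FALSE)
  if (!is.null(group_sequence)) {
    group_sequence <- as.integer(group_sequence)
    stopifnot(all(group_sequence >= 1),
              all(group_sequence <= nrow(group_means)))
  }
  structure(
    list(group_means = group_means, group_cv = group_cv,
         droplets_per_group = droplets_per_group,
         group_sequence = group_sequence,
         transit_spacing = transit_spacing,
         inter_droplet_gap = inter_droplet_gap,
         pulse_width_sd = pulse_width_sd, lead_in = lead_in,
         sample_rate = sample_rate, baseline_level = baseline_level,
         baseline_drift_rate = baseline_drift_rate,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "population_spec"
  )
}

#' Default palette-corner group means
#'
#' The 8 fluorophore groups at low = 0.2 V / high = 2.0 V per channel,
#' row `i` corresponding to palette index `i - 1`.
#'
#' @param low,high per-channel mean pulse heights (volts) for the two
#'   fluorophore levels.
#' @return An 8 x 3 matrix (channels: blue, green, red).
#' @export
default_group_means <- function(low = 0.2, high = 2.0) {
  lv <- palette_levels(0:7)
  m <- lv * high + (1 - lv) * low
  rownames(m) <- paste0("palette", 0:7)
  m
}

#' Generate a population trace with ground truth
#'
#' Concatenates droplet transits into one PMT trace. Each droplet
#' contributes exactly three Gaussian pulses (one per laser position)
#' spaced `transit_spacing` apart; heights are drawn per channel from
#' `Normal(mean, cv * mean)` truncated at zero. Droplet arrival order is a
#' seeded random permutation of the balanced design unless
#' `group_sequence` is supplied.
#'
#' @param spec a [population_spec()].
#' @return A list with `trace` (a `droplet_trace`) and `truth`, a
#'   data.frame with one row per droplet: `droplet_id`, `group_id`
#'   (1-based), `palette` (`group_id - 1` when the default palette-corner
#'   means are used, else `NA`), arrival time `t0`, pulse centers
#'   `t1,t2,t3` and true pulse heights `h1,h2,h3`.
#' @examples
#' ps <- population_spec(droplets_per_group = 2, seed = 7)
#' out <- make_population_traces(ps)
#' nrow(out$truth)  # 16 droplets
#' @export
make_population_traces <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n_groups <- nrow(spec$group_means)
  res <- withr_rng(spec$seed, {
    groups <- if (!is.null(spec$group_sequence)) spec$group_sequence
      else sample(rep(seq_len(n_groups), each = spec$droplets_per_group))
    n <- length(groups)
    if (n == 0) {
      list(groups = integer(0), heights = matrix(0, 0, 3))
    } else {
      cv <- rep_len(spec$group_cv, 3)
      mu <- spec$group_means[groups, , drop = FALSE]
      h <- mu * (1 + matrix(rnorm(3 * n), n, 3) *
                   matrix(cv, n, 3, byrow = TRUE))
      h[h < 0] <- 0
      list(groups = groups, heights = h)
    }
  })
  n <- length(res$groups)
  t0 <- spec$lead_in + (seq_len(n) - 1) * spec$inter_droplet_gap
  pulse_times <- cbind(t0, t0 + spec$transit_spacing,
                       t0 + 2 * spec$transit_spacing)
  pulses <- if (n > 0) {
    data.frame(center_time = as.vector(t(pulse_times)),
               height = as.vector(t(res$heights)),
               width_sd = spec$pulse_width_sd)
  } else NULL
  duration <- 2 * spec$lead_in +
    if (n > 0) (n - 1) * spec$inter_droplet_gap + 2 * spec$transit_spacing
    else 0
  # offset seed so trace noise uses a different stream than height draws
  ts <- trace_spec(sample_rate = spec$sample_rate, duration = duration,
                   baseline_level = spec$baseline_level,
                   baseline_drift_rate = spec$baseline_drift_rate,
                   noise_sd = spec$noise_sd, pulses = pulses,
                   seed = (spec$seed + 1L) %% .Machine$integer.max)
  default_means <- isTRUE(all.equal(unname(spec$group_means),
                                    unname(default_group_means())))
  truth <- data.frame(
    droplet_id = seq_len(n),
    group_id = res$groups,
    palette = if (default_means && n > 0) res$groups - 1L
      else rep(NA_integer_, n),
    t0 = t0,
    t1 = pulse_times[, 1], t2 = pulse_times[, 2], t3 = pulse_times[, 3],
    h1 = res$heights[, 1], h2 = res$heights[, 2], h3 = res$heights[, 3]
  )
  list(trace = make_trace(ts), truth = truth)
}
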