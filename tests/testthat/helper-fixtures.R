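# shared fixtures, built in code at test time

# small balanced 8-group population trace + detection products, computed once
pop_fixture <- local({
  cache <- NULL
  function(droplets_per_group = 10, seed = 42L) {
    key <- paste(droplets_per_group, seed)
    if (!is.null(cache) && cache$key == key) return(cache)
    ps <- population_spec(droplets_per_group = droplets_per_group,
                          seed = seed)
    gen <- make_population_traces(ps)
    cfg <- detector_config()
    peaks <- detect_peaks(gen$trace, cfg)
    sigs <- group_peaks(peaks, cfg)
    cache <<- list(key = key, spec = ps, trace = gen$trace,
                   truth = gen$truth, cfg = cfg, peaks = peaks,
                   sigs = sigs)
    cache
  }
})

random_tile <- function(seed, nrow = 5, ncol = 5) {
  set.seed(seed)
  pixel_grid(sample(0:7, nrow * ncol, replace = TRUE), nrow, ncol)
}

# offline oracle: moving average over the most recent `window`
# non-pulse samples of a trace, given ground-truth pulse locations
oracle_baseline <- function(trace, pulse_centers, pulse_sd, window,
                            at_index = nrow(trace)) {
  is_pulse <- rep(FALSE, nrow(trace))
  for (ct in pulse_centers) {
    is_pulse <- is_pulse | abs(trace$time_s - ct) < 6 * pulse_sd
  }
  base_idx <- which(!is_pulse & seq_len(nrow(trace)) <= at_index)
  mean(trace$signal_v[utils::tail(base_idx, window)])
}
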