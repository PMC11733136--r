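test_that("flat noisy trace yields no peaks at 5 sigma", {
  tr <- make_trace(trace_spec(duration = 1, noise_sd = 0.02, seed = 8))
  expect_equal(nrow(detect_peaks(tr, detector_config())), 0)
})

test_that("one droplet's transit yields exactly three peaks", {
  for (g in c(1, 4, 8)) {   # all-low, blue-high, all-high groups
    ps <- population_spec(droplets_per_group = 1, seed = g,
                          group_means = default_group_means()[g, , drop = FALSE])
    tr <- make_population_traces(ps)$trace
    expect_equal(nrow(detect_peaks(tr, detector_config())), 3,
                 info = paste("group", g))
  }
})

test_that("detector input validation", {
  cfg <- detector_config()
  expect_error(detect_peaks(data.frame(time_s = numeric(0),
                                       signal_v = numeric(0)), cfg),
               "empty")
  short <- data.frame(time_s = (0:50) / 1e4, signal_v = rnorm(51))
  expect_error(detect_peaks(short, cfg), "warm-up")
  nonuni <- data.frame(time_s = c(0, 1e-4, 3e-4, 4e-4, 6e-4) * rep(1, 5),
                       signal_v = rnorm(5))
  nonuni <- data.frame(time_s = cumsum(c(0, runif(400, 0.5, 1.5)) / 1e4),
                       signal_v = rnorm(401))
  expect_error(detect_peaks(nonuni, cfg), "uniform")
})

test_that("baseline tracks a drifting trace; peaks all found", {
  cfg <- detector_config()
  ns <- 0.02
  # drift of 0.1 noise SD per baseline window
  drift <- 0.1 * ns / (cfg$baseline_window / 1e4)
  centers <- 0.1 + 0.025 * (0:19)
  sp <- trace_spec(duration = 0.7, noise_sd = ns, baseline_level = 0.5,
                   baseline_drift_rate = drift,
                   pulses = data.frame(center_time = centers, height = 0.5,
                                       width_sd = 3e-4), seed = 31)
  tr <- make_trace(sp)
  det <- peak_detector(cfg, 1e4)
  fed <- detector_feed(det, tr$signal_v)
  peaks <- rbind(fed$peaks, detector_finalize(fed$detector))
  expect_equal(nrow(peaks), 20)
  true_end <- 0.5 + drift * max(tr$time_s)
  expect_lt(abs(detector_baseline(fed$detector) - true_end), 3 * ns)
  # against the offline oracle: moving average of recent non-pulse samples
  orc <- oracle_baseline(tr, centers, 3e-4, cfg$baseline_window)
  expect_lt(abs(detector_baseline(fed$detector) - orc), 3 * ns)
})

test_that("chunked streaming equals a single pass", {
  fx <- pop_fixture()
  cfg <- fx$cfg
  whole <- detect_peaks(fx$trace, cfg)
  for (n_chunks in c(3, 17)) {
    det <- peak_detector(cfg, 1e4)
    sizes <- diff(round(seq(0, nrow(fx$trace), length.out = n_chunks + 1)))
    got <- list()
    off <- 0L
    for (s in sizes) {
      fed <- detector_feed(det, fx$trace$signal_v[off + seq_len(s)])
      det <- fed$detector
      got[[length(got) + 1]] <- fed$peaks
      off <- off + s
    }
    got[[length(got) + 1]] <- detector_finalize(det)
    chunked <- do.call(rbind, got)
    rownames(chunked) <- NULL
    expect_identical(chunked, whole, info = paste(n_chunks, "chunks"))
  }
})

test_that("raising the threshold never yields more peaks", {
  fx <- pop_fixture()
  counts <- vapply(c(3, 5, 8, 12, 20, 60), function(k) {
    nrow(detect_peaks(fx$trace,
                      detector_config(threshold_multiple = k)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("peak conservation at high SNR", {
  fx <- pop_fixture()          # all pulse heights >= 10 noise SDs
  expect_equal(nrow(fx$peaks), 3 * nrow(fx$truth))
})

test_that("grouping: peaks within group_time form one complete signature", {
  cfg <- detector_config(group_time = 0.005)
  pk <- data.frame(start_time = c(0, 0.001, 0.002),
                   end_time = c(0.0005, 0.0015, 0.0025),
                   magnitude = c(1, 2, 3), baseline_at_entry = 0.5)
  sg <- group_peaks(pk, cfg)
  expect_equal(nrow(sg), 1)
  expect_true(sg$complete)
  expect_equal(unlist(sg[, c("mag1", "mag2", "mag3")], use.names = FALSE),
               c(1, 2, 3))
})

test_that("grouping: separated peaks give incomplete zero-padded groups", {
  cfg <- detector_config(group_time = 0.005)
  pk <- data.frame(start_time = c(0, 0.01), end_time = c(0.001, 0.011),
                   magnitude = c(1, 2), baseline_at_entry = 0.5)
  sg <- group_peaks(pk, cfg)
  expect_equal(nrow(sg), 2)
  expect_false(any(sg$complete))
  expect_equal(sg$mag2, c(0, 0))
  expect_equal(group_peaks(pk[0, ], cfg)$complete, logical(0))
  expect_error(group_peaks(pk[2:1, ], cfg), "sorted")
})

test_that("two-droplet magnitudes match ground truth within one noise SD", {
  ps <- population_spec(droplets_per_group = 1, seed = 17,
                        group_means = default_group_means()[c(3, 6), ])
  gen <- make_population_traces(ps)
  cfg <- detector_config()
  sg <- group_peaks(detect_peaks(gen$trace, cfg), cfg)
  expect_equal(nrow(sg), 2)
  expect_true(all(sg$complete))
  est <- as.matrix(sg[, c("mag1", "mag2", "mag3")])
  tru <- as.matrix(gen$truth[, c("h1", "h2", "h3")])
  expect_true(all(abs(est - tru) <= ps$noise_sd))
})

test_that("detector_score: perfect, empty, and degenerate cases", {
  fx <- pop_fixture()
  sc <- detector_score(fx$sigs, fx$truth, fx$cfg)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
  expect_lt(sc$magnitude_rmse, 2 * fx$spec$noise_sd)
  # threshold so high nothing is found
  none <- detect_peaks(fx$trace, detector_config(threshold_multiple = 1e5))
  sc0 <- detector_score(group_peaks(none, fx$cfg), fx$truth, fx$cfg)
  expect_equal(sc0$recall, 0)
})

test_that("ablated detector (peaks in baseline) has larger terminal error", {
  ns <- 0.02
  centers <- seq(0.06, 0.548, by = 0.004)    # pulse-dense to the last sample
  sp <- trace_spec(duration = 0.55, noise_sd = ns, baseline_level = 0.5,
                   pulses = data.frame(center_time = centers, height = 2,
                                       width_sd = 3e-4), seed = 77)
  tr <- make_trace(sp)
  run <- function(cfg) {
    det <- peak_detector(cfg, 1e4)
    fed <- detector_feed(det, tr$signal_v)
    abs(detector_baseline(fed$detector) - 0.5)
  }
  err_good <- run(detector_config())
  err_ablated <- run(detector_config(include_peaks_in_baseline = TRUE))
  expect_lt(err_good, err_ablated)
  expect_lt(err_good, 3 * ns)
})
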