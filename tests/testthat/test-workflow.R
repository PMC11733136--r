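test_that("verify_grid reports exact mismatch positions", {
  g <- random_tile(4)
  expect_equal(nrow(verify_grid(g, g)), 0)
  flipped <- unclass(g)
  flipped[3, 2] <- (flipped[3, 2] + 1L) %% 8L
  rep1 <- verify_grid(pixel_grid(flipped), g)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$row, 3)
  expect_equal(rep1$col, 2)
  expect_equal(rep1$expected, g[3, 2])
  expect_error(verify_grid(g, random_tile(1, 4, 4)), "do not match")
})

test_that("a fault-free run reproduces its target exactly", {
  tile <- random_tile(21)
  log <- run_workflow(workflow_config(target = tile, seed = 5))
  expect_true(log$clean)
  expect_identical(unclass(log$final_grid), unclass(tile))
  expect_equal(sum(log$droplets$sorted), 25)
  # only droplets matching the pending instruction were deflected
  sorted <- log$droplets[log$droplets$sorted, ]
  expect_equal(sorted$classified,
               as.integer(log$target[anchor_array()$serpentine][25:1]))
})

test_that("runs are deterministic given the seed", {
  cfg <- workflow_config(target = random_tile(8), seed = 33)
  a <- run_workflow(cfg)
  b <- run_workflow(cfg)
  expect_identical(a$droplets, b$droplets)
  expect_identical(unclass(a$final_grid), unclass(b$final_grid))
})

test_that("empty instruction lists run to an empty log", {
  cfg <- workflow_config(
    instructions = structure(integer(0), class = "instruction_list"),
    target = random_tile(1))
  log <- run_workflow(cfg)
  expect_equal(log$n_stream_used, 0)
  expect_length(log$push_log, 0)
})

test_that("certain nonspecific sorting corrupts pixels and names them", {
  tile <- random_tile(13)
  log <- run_workflow(workflow_config(target = tile,
                                      nonspecific_sort_prob = 1, seed = 2))
  expect_gte(nrow(log$mismatches), 1)
  wrong <- subset(log$droplets, sorted &
                    classified != as.integer(compile_instructions(tile))[
                      instruction_index])
  expect_gte(nrow(wrong), 1)          # offending instruction indices logged
  expect_false(any(is.na(wrong$instruction_index)))
})

test_that("anchor skips leave mismatches at or after the skipped anchor", {
  tile <- pixel_grid(rep(c(1L, 6L), length.out = 25), 5, 5)
  found <- FALSE
  for (seed in 1:10) {
    log <- run_workflow(workflow_config(target = tile,
                                        anchor_skip_prob = 0.08,
                                        seed = seed))
    skips <- which(log$droplets$anchor_event == "skip")
    if (length(skips) == 0) next
    found <- TRUE
    # instruction j fills serpentine position 26 - j; skipping j shifts
    # everything sorted at or before it one anchor toward the far end, so
    # serpentine positions below 26 - max(skipped j) stay correct
    max_skip <- max(log$droplets$instruction_index[skips])
    serp <- anchor_array()$serpentine
    mism_pos <- match(paste(log$mismatches$row, log$mismatches$col),
                      paste(serp[, 1], serp[, 2]))
    expect_gte(nrow(log$mismatches), 1)
    expect_true(all(mism_pos >= 26 - max_skip))
    expect_true(log$underfilled)
  }
  expect_true(found)
})

test_that("expected corruption grows with each fault probability", {
  tile <- random_tile(30)
  mean_mismatch <- function(param, level, seeds = 1:4) {
    args <- list(target = tile)
    args[[param]] <- level
    mean(vapply(seeds, function(s) {
      args$seed <- s
      nrow(run_workflow(do.call(workflow_config, args))$mismatches)
    }, numeric(1)))
  }
  for (param in c("nonspecific_sort_prob", "anchor_skip_prob",
                  "double_occupancy_prob")) {
    m <- vapply(c(0, 0.15, 0.9), function(l) mean_mismatch(param, l),
                numeric(1))
    expect_true(all(diff(m) >= 0), info = param)
    expect_equal(m[1], 0, info = param)
  }
})

test_that("sort intervals respect the 80 droplets/s cap", {
  log <- run_workflow(workflow_config(target = random_tile(2), seed = 9))
  st <- sort(log$droplets$sort_time[log$droplets$sorted])
  expect_true(all(diff(st) >= 1 / 80 - 1e-12))
})

test_that("stream exhaustion raises an incomplete-run condition", {
  cfg <- workflow_config(target = random_tile(3), stream_factor = 0.02,
                         seed = 1)
  err <- tryCatch(run_workflow(cfg), error = identity)
  expect_s3_class(err, "dropletpix_incomplete_run")
  expect_match(conditionMessage(err), "instructions fulfilled")
  expect_lt(err$fulfilled, err$n_instructions)
})

test_that("symbol library is 35 two-color 5x5 glyphs", {
  sym <- symbol_library()
  expect_length(sym, 35)
  expect_true(all(vapply(sym, function(s) all(dim(s) == c(5, 5)),
                         logical(1))))
  expect_true(all(vapply(sym, function(s)
    all(unique(as.vector(s)) %in% c(0L, 7L)), logical(1))))
  expect_error(run_symbol_library(list(random_tile(1)),
                                  workflow_config(target = random_tile(1))),
               "2-color")
})

test_that("single symbols verify clean; injected faults localize", {
  all_white <- pixel_grid(rep(7L, 25), 5, 5)
  res <- run_symbol_library(list(all_white),
                            workflow_config(target = all_white), seed = 3)
  expect_true(res$all_clean)
  # corrupt exactly one symbol of a small library
  sym <- symbol_library()[1:3]
  cfgs <- workflow_config(target = sym[[1]])
  clean <- suppressWarnings(run_symbol_library(sym, cfgs, seed = 11))
  expect_true(clean$all_clean)
  cfg_bad <- cfgs
  cfg_bad$nonspecific_sort_prob <- 1
  one_bad <- list(
    run_workflow({ c1 <- cfgs; c1$target <- sym[[1]]
      c1$instructions <- compile_instructions(sym[[1]]); c1$seed <- 12L; c1 }),
    run_workflow({ c2 <- cfg_bad; c2$target <- sym[[2]]
      c2$instructions <- compile_instructions(sym[[2]]); c2$seed <- 13L; c2 }),
    run_workflow({ c3 <- cfgs; c3$target <- sym[[3]]
      c3$instructions <- compile_instructions(sym[[3]]); c3$seed <- 14L; c3 })
  )
  ok <- vapply(one_bad, function(l) l$clean, logical(1))
  expect_equal(ok, c(TRUE, FALSE, TRUE))
})
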