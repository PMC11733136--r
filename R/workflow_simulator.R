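#' Configure an end-to-end workflow simulation
#'
#' Describes one desk-scale stand-in for the hardware loop: droplets of the
#' 8-color population arrive in random order past the three-laser sensing
#' station; each is detected and classified; the sorter deflects a droplet
#' iff its classified color matches the next unfulfilled instruction
#' (wait-for-color semantics — non-matching droplets pass to waste);
#' deflected droplets are pushed into the serpentine anchor array; the run
#' ends when all instructions are fulfilled.
#'
#' Fault injection reproduces the failure modes that corrupt a pixel
#' array: `nonspecific_sort_prob` (a non-matching droplet is deflected and
#' consumes the instruction), `anchor_skip_prob` (a sorted droplet skips
#' the array and is lost) and `double_occupancy_prob` (a sorted droplet
#' lands twice, displacing occupants one extra anchor).
#'
#' @param target target [pixel_grid()] tile (instructions are compiled
#'   from it), or NULL if `instructions` are given directly.
#' @param instructions optional explicit [compile_instructions()] output.
#' @param population a [population_spec()] template; its `group_sequence`
#'   and seed are set by the simulator.
#' @param detector a [detector_config()].
#' @param classifier a `droplet_classifier`; default
#'   [calibrate_thresholds()] on the population's group means.
#' @param array an [anchor_array()] defining the geometry.
#' @param nonspecific_sort_prob,anchor_skip_prob,double_occupancy_prob
#'   fault probabilities in `[0, 1]`, all 0 by default.
#' @param max_sort_rate_hz sorter throughput cap (droplets/second); sorts
#'   are never logged closer together than `1/max_sort_rate_hz`.
#' @param stream_factor stream length as a multiple of
#'   `8 * length(instructions)` (the expected consumption for a uniform
#'   8-color stream); the run errors if the stream is exhausted first.
#' @param seed integer seed controlling arrival order, signal noise and
#'   fault draws.
#' @return An object of class `workflow_config`.
#' @export
workflow_config <- function(target = NULL, instructions = NULL,
                            population = population_spec(),
                            detector = detector_config(),
                            classifier = NULL,
                            array = anchor_array(),
                            nonspecific_sort_prob = 0,
                            anchor_skip_prob = 0,
                            double_occupancy_prob = 0,
                            max_sort_rate_hz = 80,
                            stream_factor = 4,
                            seed = 1L) {
  probs <- c(nonspecific_sort_prob, anchor_skip_prob, double_occupancy_prob)
  if (any(probs < 0 | probs > 1))
    stop("fault probabilities must lie in [0, 1]", call. = FALSE)
  stopifnot(max_sort_rate_hz > 0, stream_factor > 0)
  if (is.null(instructions)) {
    if (is.null(target))
      stop("either `target` or `instructions` must be given", call. = FALSE)
    instructions <- compile_instructions(target, array)
  } else if (is.null(target)) {
    target <- replay_instructions(instructions, array)
  }
  if (is.null(classifier))
    classifier <- calibrate_thresholds(population$group_means)
  structure(
    list(target = target, instructions = instructions,
         population = population, detector = detector,
         classifier = classifier, array = array,
         nonspecific_sort_prob = nonspecific_sort_prob,
         anchor_skip_prob = anchor_skip_prob,
         double_occupancy_prob = double_occupancy_prob,
         max_sort_rate_hz = max_sort_rate_hz,
         stream_factor = stream_factor, seed = as.integer(seed)),
    class = "workflow_config"
  )
}

#' Run the end-to-end workflow simulation
#'
#' Generates the droplet stream trace, runs peak detection, grouping and
#' classification, applies the wait-for-color sorting policy (with fault
#' injection), pushes sorted droplets through the anchor array and renders
#' the final grid. Deterministic given the config seed.
#'
#' @param config a [workflow_config()].
#' @return An object of class `workflow_runlog`: list with `droplets`
#'   (per-droplet data.frame: arrival time, true group/palette, detection
#'   and classification results, sort decision, sort time, instruction
#'   index, anchor event), `final_grid`, `target`, `mismatches` (from
#'   [verify_grid()]), `clean` (TRUE iff no mismatches), `n_stream_used`
#'   and `push_log`.
#' @examples
#' \donttest{
#' tile <- pixel_grid(sample(0:7, 25, replace = TRUE), 5, 5)
#' log <- run_workflow(workflow_config(target = tile, seed = 7))
#' log$clean
#' }
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "workflow_config"))
  instr <- as.integer(config$instructions)
  n_instr <- length(instr)
  n_groups <- nrow(config$population$group_means)
  n_stream <- max(1L, ceiling(config$stream_factor * n_groups * n_instr))

  if (n_instr == 0) {
    return(structure(
      list(droplets = data.frame(), final_grid = NULL,
           target = config$target, mismatches = NULL, clean = NA,
           n_stream_used = 0L, push_log = integer(0)),
      class = "workflow_runlog"))
  }

  rng <- withr_rng(config$seed, {
    list(groups = sample.int(n_groups, n_stream, replace = TRUE),
         u_nonspec = runif(n_stream), u_skip = runif(n_stream),
         u_double = runif(n_stream))
  })

  pop <- config$population
  pop$group_sequence <- rng$groups
  pop$seed <- config$seed
  gen <- make_population_traces(pop)
  peaks <- detect_peaks(gen$trace, config$detector)
  sigs <- group_peaks(peaks, config$detector)
  colors <- classify_signatures(sigs, config$classifier)

  # align detected signatures with the known arrival schedule
  sig_of_droplet <- match_signatures(sigs, gen$truth, config$detector)

  ptr <- 1L
  min_gap <- 1 / config$max_sort_rate_hz
  last_sort <- -Inf
  push_log <- integer(0)
  rec <- data.frame(
    droplet_id = gen$truth$droplet_id, arrival_time = gen$truth$t0,
    true_group = gen$truth$group_id, true_palette = gen$truth$palette,
    detected = FALSE, classified = NA_integer_, sorted = FALSE,
    sort_time = NA_real_, instruction_index = NA_integer_,
    anchor_event = NA_character_
  )
  used <- n_stream
  for (i in seq_len(n_stream)) {
    if (ptr > n_instr) { used <- i - 1L; break }
    si <- sig_of_droplet[i]
    if (is.na(si)) next                       # droplet missed by detector
    rec$detected[i] <- TRUE
    col <- colors[si]
    rec$classified[i] <- col
    if (is.na(col)) next                      # incomplete: never deflected
    match_instr <- col == instr[ptr]
    deflect <- match_instr ||
      rng$u_nonspec[i] < config$nonspecific_sort_prob
    if (!deflect) next
    rec$sorted[i] <- TRUE
    rec$instruction_index[i] <- ptr
    rec$sort_time[i] <- max(rec$arrival_time[i], last_sort + min_gap)
    last_sort <- rec$sort_time[i]
    if (rng$u_skip[i] < config$anchor_skip_prob) {
      rec$anchor_event[i] <- "skip"
    } else if (rng$u_double[i] < config$double_occupancy_prob) {
      rec$anchor_event[i] <- "double"
      push_log <- c(push_log, col, col)
    } else {
      rec$anchor_event[i] <- "push"
      push_log <- c(push_log, col)
    }
    ptr <- ptr + 1L
  }
  if (ptr <= n_instr) {
    stop(structure(class = c("dropletpix_incomplete_run", "error",
                             "condition"),
                   list(message = sprintf(
                     paste0("droplet stream exhausted after %d droplets ",
                            "with %d/%d instructions fulfilled"),
                     n_stream, ptr - 1L, n_instr),
                     call = NULL,
                     fulfilled = ptr - 1L, n_instructions = n_instr)))
  }

  # excess pushes (double occupancy) knock the earliest droplets off the
  # far end of the serpentine; unoccupied far anchors (skips) render dark
  arr <- config$array
  occ <- rev(push_log)[seq_len(min(length(push_log), arr$n_anchors))]
  underfilled <- length(occ) < arr$n_anchors
  arr$occupancy <- c(occ, rep(0L, arr$n_anchors - length(occ)))
  final_grid <- array_to_grid(arr)
  mism <- verify_grid(final_grid, config$target)
  structure(
    list(droplets = rec[seq_len(used), , drop = FALSE],
         final_grid = final_grid, target = config$target,
         mismatches = mism, clean = nrow(mism) == 0,
         underfilled = underfilled,
         n_stream_used = used, push_log = push_log),
    class = "workflow_runlog"
  )
}

# one-to-one greedy time matching of detected signatures to scheduled
# droplets (same rule as detector_score)
match_signatures <- function(sigs, truth, cfg) {
  out <- rep(NA_integer_, nrow(truth))
  if (nrow(sigs) == 0) return(out)
  j <- 1L
  for (i in seq_len(nrow(sigs))) {
    while (j <= nrow(truth) &&
           truth$t1[j] < sigs$droplet_time[i] - cfg$group_time) j <- j + 1L
    if (j <= nrow(truth) && is.na(out[j]) &&
        abs(sigs$droplet_time[i] - truth$t1[j]) <= cfg$group_time) {
      out[j] <- i
      j <- j + 1L
    }
  }
  out
}

#' @export
print.workflow_runlog <- function(x, ...) {
  cat("workflow_runlog:", x$n_stream_used, "droplets streamed,",
      sum(x$droplets$sorted), "sorted\n")
  if (!is.null(x$mismatches))
    cat("verification:", if (nrow(x$mismatches) == 0) "clean"
        else paste(nrow(x$mismatches), "mismatching pixel(s)"), "\n")
  invisible(x)
}

#' Verify a realized grid against its target
#'
#' Pixel-exact comparison; the pixel array is the visually verifiable
#' signature that all upstream droplet processing was correct, so any
#' mismatch localizes an upstream fault.
#'
#' @param grid,target equally sized [pixel_grid()]s.
#' @return A data.frame with one row per mismatch: `row`, `col`,
#'   `expected`, `observed`; zero rows iff the grids are identical.
#' @export
verify_grid <- function(grid, target) {
  stopifnot(inherits(grid, "pixel_grid"), inherits(target, "pixel_grid"))
  if (nrow(grid) != nrow(target) || ncol(grid) != ncol(target))
    stop("grid dimensions (", nrow(grid), "x", ncol(grid),
         ") do not match target (", nrow(target), "x", ncol(target), ")",
         call. = FALSE)
  idx <- which(unclass(grid) != unclass(target), arr.ind = TRUE)
  data.frame(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
             expected = target[idx], observed = grid[idx])
}

#' Run a library of symbols through fault-free workflows
#'
#' One simulated run per 5x5 black/white symbol; a symbol verifies clean
#' only if all 25 droplets were deflected in exactly the instructed order,
#' so the set of rendered symbols is an end-to-end correctness certificate
#' for the whole sense/sort/anchor chain.
#'
#' @param symbols list of [pixel_grid()]s using a 2-color sub-palette
#'   (default: the built-in 35-symbol alphanumeric library,
#'   [symbol_library()]).
#' @param config a [workflow_config()] template; its target and seed are
#'   replaced per symbol.
#' @param seed base seed; symbol `i` runs with `seed + i`.
#' @return A list with `logs` (per-symbol `workflow_runlog`s), `clean`
#'   (logical per symbol) and `all_clean`.
#' @export
run_symbol_library <- function(symbols = symbol_library(),
                               config = workflow_config(
                                 target = symbols[[1]]),
                               seed = 1L) {
  for (s in symbols) {
    if (length(unique(as.vector(s))) > 2)
      stop("symbols must use a 2-color sub-palette", call. = FALSE)
  }
  logs <- vector("list", length(symbols))
  for (i in seq_along(symbols)) {
    cfg <- config
    cfg$target <- symbols[[i]]
    cfg$instructions <- compile_instructions(symbols[[i]], cfg$array)
    cfg$seed <- as.integer(seed + i)
    logs[[i]] <- run_workflow(cfg)
  }
  clean <- vapply(logs, function(l) isTRUE(l$clean), logical(1))
  names(clean) <- names(symbols)
  if (!all(clean))
    warning("symbols failed verification: ",
            paste(which(!clean), collapse = ", "), call. = FALSE)
  list(logs = logs, clean = clean, all_clean = all(clean))
}
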