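#' Read and write fluorescence traces as CSV
#'
#' Traces are exchanged as two-column CSV files with header
#' `time_s,signal_v`. Reading validates the schema and uniform sampling
#' and reports the offending row of a malformed file.
#'
#' @param trace a `droplet_trace` data.frame.
#' @param path file path.
#' @return `read_trace()`: a `droplet_trace` data.frame.
#' @export
write_trace <- function(trace, path) {
  stopifnot(all(c("time_s", "signal_v") %in% names(trace)))
  write.csv(trace[, c("time_s", "signal_v")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path)
  if (!all(c("time_s", "signal_v") %in% names(df)))
    stop("trace file ", path, " must have columns time_s,signal_v",
         call. = FALSE)
  df$time_s <- suppressWarnings(as.numeric(df$time_s))
  df$signal_v <- suppressWarnings(as.numeric(df$signal_v))
  bad <- which(!is.finite(df$time_s) | !is.finite(df$signal_v))
  if (length(bad) > 0)
    stop("trace file ", path, ": non-numeric value at data row ", bad[1],
         call. = FALSE)
  structure(df, class = c("droplet_trace", "data.frame"),
            sample_rate = if (nrow(df) > 1) 1 / diff(df$time_s[1:2]) else NA)
}

#' Read and write images (PPM always; PNG when available)
#'
#' Plain-text PPM (P3) is the portable interchange format; 8-bit RGB PNG
#' is supported through the `png` package when installed. Round trips are
#' lossless for 8-bit RGB content.
#'
#' @param image an H x W x 3 array, values in 0-1 or 0-255.
#' @param path file path; format chosen by extension (`.ppm` or `.png`).
#' @return `read_image()`: an H x W x 3 array with values in 0-1.
#' @export
write_image <- function(image, path) {
  stopifnot(is.array(image), length(dim(image)) == 3)
  ext <- tolower(tools::file_ext(path))
  if (max(image) <= 1) image <- image * 255
  image <- round(image)
  if (ext == "ppm") {
    h <- dim(image)[1]; w <- dim(image)[2]
    # P3 pixel order: rows top to bottom, channels interleaved per pixel
    px <- aperm(image, c(3, 2, 1))   # channel, col, row
    writeLines(c("P3", paste(w, h), "255",
                 paste(as.integer(px), collapse = " ")), path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the `png` package is required to write PNG files", call. = FALSE)
    png::writePNG(image / 255, path)
  } else {
    stop("unsupported image extension: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ppm") {
    txt <- readLines(path, warn = FALSE)
    toks <- unlist(strsplit(paste(txt[!startsWith(txt, "#")],
                                  collapse = " "), "[[:space:]]+"))
    toks <- toks[nzchar(toks)]
    if (length(toks) < 4 || toks[1] != "P3")
      stop("not a plain-text P3 PPM file: ", path, call. = FALSE)
    w <- as.integer(toks[2]); h <- as.integer(toks[3])
    maxv <- as.numeric(toks[4])
    vals <- suppressWarnings(as.numeric(toks[-(1:4)]))
    if (anyNA(vals) || length(vals) != 3 * w * h)
      stop("malformed PPM body in ", path, " (expected ", 3 * w * h,
           " values, got ", length(vals), ")", call. = FALSE)
    px <- array(vals, c(3, w, h))           # channel, col, row
    aperm(px, c(3, 2, 1)) / maxv
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the `png` package is required to read PNG files", call. = FALSE)
    img <- png::readPNG(path)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE][, , 1:3]
  } else {
    stop("unsupported image extension: .", ext, call. = FALSE)
  }
}

#' Read and write pixel grids, instruction lists and classifier models
#'
#' JSON serializations of the machine artifacts exchanged between the
#' compiler, the simulator and the (hardware) device: pixel grids as
#' row-lists of palette indices, instruction lists as
#' `{"tile_id": ..., "order": [...]}`, classifier models with centroids or
#' thresholds plus the palette label map.
#'
#' @param grid a [pixel_grid()].
#' @param path file path.
#' @return readers return the reconstructed object.
#' @export
write_grid_json <- function(grid, path) {
  stopifnot(inherits(grid, "pixel_grid"))
  jsonlite::write_json(
    list(nrow = nrow(grid), ncol = ncol(grid),
         rows = lapply(seq_len(nrow(grid)), function(i) unclass(grid)[i, ])),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_grid_json
#' @export
read_grid_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- if (is.list(x$rows)) do.call(rbind, x$rows) else as.matrix(x$rows)
  stopifnot(nrow(rows) == x$nrow, ncol(rows) == x$ncol)
  pixel_grid(rows)
}

#' @rdname write_grid_json
#' @param instructions an `instruction_list`.
#' @param tile_id identifier recorded alongside the order.
#' @export
write_instructions_json <- function(instructions, path, tile_id = 1L) {
  jsonlite::write_json(list(tile_id = tile_id,
                            order = as.integer(instructions)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_grid_json
#' @export
read_instructions_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(as.integer(x$order), class = "instruction_list",
            tile_id = x$tile_id)
}

#' @rdname write_grid_json
#' @param model a `droplet_classifier`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "droplet_classifier"))
  out <- unclass(model)
  if (!is.null(out$centroids)) out$centroids <- unname(as.matrix(out$centroids))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (x$type == "threshold") return(threshold_model(x$thresholds))
  structure(list(type = "kmeans", centroids = as.matrix(x$centroids),
                 labels = as.integer(x$labels),
                 channel_mids = x$channel_mids),
            class = "droplet_classifier")
}

#' Read a project configuration file
#'
#' Configurations are JSON (machine-written) or YAML (human-written, when
#' the `yaml` package is available). Unknown keys are rejected so typos
#' fail loudly; omitted keys fall back to the package defaults, which
#' reproduce the characterized hardware constants.
#'
#' @param path file path (`.json`, `.yaml` or `.yml`).
#' @return A named list with entries `detector` (a [detector_config()]),
#'   `population` (a [population_spec()]) and `seed`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the `yaml` package is required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else stop("unsupported config extension: .", ext, call. = FALSE)
  known_top <- c("detector", "population", "seed")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  build <- function(fn, args, what) {
    ok <- names(formals(fn))
    bad <- setdiff(names(args), ok)
    if (length(bad) > 0)
      stop("unknown ", what, " config key(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    do.call(fn, args)
  }
  pop_args <- raw$population
  if (!is.null(pop_args$group_means))
    pop_args$group_means <- do.call(rbind, pop_args$group_means)
  list(detector = build(detector_config,
                        as.list(raw$detector), "detector"),
       population = build(population_spec, as.list(pop_args), "population"),
       seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
}
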