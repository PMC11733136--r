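#' Pixel grids of palette indices
#'
#' A `pixel_grid` is an integer matrix of palette indices 0-7 (rows =
#' image rows, top to bottom) — the "dropletized" representation of an
#' image, where each cell will be realized by one anchored droplet.
#'
#' @param cells integer matrix (or vector with `nrow`/`ncol`) of palette
#'   indices 0-7.
#' @param nrow,ncol dimensions when `cells` is a vector.
#' @return An object of class `pixel_grid`.
#' @export
pixel_grid <- function(cells, nrow = NULL, ncol = NULL) {
  if (!is.matrix(cells)) cells <- matrix(as.integer(cells), nrow, ncol)
  storage.mode(cells) <- "integer"
  if (anyNA(cells) || any(cells < 0L | cells > 7L))
    stop("all cells must be palette indices 0-7", call. = FALSE)
  structure(cells, class = c("pixel_grid", "matrix"))
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat("pixel_grid ", nrow(x), "x", ncol(x), "\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Dropletize an image to the 8-color palette
#'
#' Quantizes an RGB raster to the colors realizable by droplet fluorophore
#' combinations: the image is first block-averaged down to the target grid
#' resolution, then each cell takes the palette color minimizing Euclidean
#' distance in raw RGB (the palette sits at corners of the RGB cube, so
#' this equals a per-channel midpoint threshold); exact ties go to the
#' lowest palette index. Quantization is idempotent: a rendered
#' `pixel_grid` quantizes back to itself.
#'
#' @param image an H x W x 3 numeric array, values in 0-1 or 0-255.
#' @param grid_nrow,grid_ncol target grid resolution; defaults to the
#'   image's pixel dimensions (no downsampling).
#' @return A [pixel_grid()].
#' @export
quantize_image <- function(image, grid_nrow = dim(image)[1],
                           grid_ncol = dim(image)[2]) {
  stopifnot(is.array(image), length(dim(image)) == 3, dim(image)[3] == 3)
  if (max(image) <= 1) image <- image * 255
  h <- dim(image)[1]; w <- dim(image)[2]
  ri <- ceiling(seq_len(h) / (h / grid_nrow))   # pixel row -> grid row
  ci <- ceiling(seq_len(w) / (w / grid_ncol))
  pal <- palette_rgb_matrix()
  avg <- vapply(1:3, function(ch) {
    m <- rowsum(image[, , ch], ri)              # sum over block rows
    t(rowsum(t(m), ci)) / outer(tabulate(ri), tabulate(ci))
  }, matrix(0, grid_nrow, grid_ncol))
  flat <- cbind(as.vector(avg[, , 1]), as.vector(avg[, , 2]),
                as.vector(avg[, , 3]))
  d2 <- outer(rowSums(flat^2), rep(1, 8)) - 2 * flat %*% t(pal) +
    outer(rep(1, nrow(flat)), rowSums(pal^2))
  idx <- apply(d2, 1, function(row) min(which(row <= min(row) + 1e-9))) - 1L
  pixel_grid(matrix(idx, grid_nrow, grid_ncol))
}

#' Render a pixel grid to an RGB raster
#'
#' Paints each cell with its palette display color at an integer pixel
#' scale (e.g. the droplet diameter in screen pixels).
#'
#' @param grid a [pixel_grid()].
#' @param scale integer magnification per cell.
#' @return An H x W x 3 array with values in 0-1.
#' @export
render_grid <- function(grid, scale = 1L) {
  stopifnot(inherits(grid, "pixel_grid"), scale >= 1)
  pal <- palette_rgb_matrix() / 255
  big <- grid[rep(seq_len(nrow(grid)), each = scale),
              rep(seq_len(ncol(grid)), each = scale), drop = FALSE]
  out <- array(0, c(nrow(big), ncol(big), 3))
  for (ch in 1:3) out[, , ch] <- matrix(pal[as.vector(big) + 1, ch],
                                        nrow(big), ncol(big))
  out
}

#' Decompose a grid into 5x5 tiles and unique patterns
#'
#' Splits a mosaic into non-overlapping tiles in row-major order and
#' identifies the unique patterns (exact cell equality) so each pattern is
#' generated on the hardware only once and reused across the mosaic.
#'
#' @param grid a [pixel_grid()] whose dimensions are divisible by `tile`.
#' @param tile tile edge length (default 5, the anchor-array geometry).
#' @return A list: `tiles` (list of `pixel_grid` in row-major tile order),
#'   `positions` (data.frame `tile_row`, `tile_col`, 1-based),
#'   `unique_patterns` (list of distinct `pixel_grid`s in first-seen
#'   order), and `pattern_map` (integer: tile -> index into
#'   `unique_patterns`).
#' @export
decompose_grid <- function(grid, tile = 5L) {
  stopifnot(inherits(grid, "pixel_grid"))
  if (nrow(grid) %% tile != 0 || ncol(grid) %% tile != 0)
    stop("grid dimensions (", nrow(grid), "x", ncol(grid),
         ") are not divisible by the tile size ", tile, call. = FALSE)
  tr <- nrow(grid) %/% tile
  tc <- ncol(grid) %/% tile
  tiles <- vector("list", tr * tc)
  pos <- data.frame(tile_row = integer(tr * tc), tile_col = integer(tr * tc))
  keys <- character(tr * tc)
  k <- 0L
  for (i in seq_len(tr)) for (j in seq_len(tc)) {
    k <- k + 1L
    cells <- grid[(i - 1) * tile + seq_len(tile),
                  (j - 1) * tile + seq_len(tile), drop = FALSE]
    tiles[[k]] <- pixel_grid(cells)
    pos$tile_row[k] <- i; pos$tile_col[k] <- j
    keys[k] <- paste(cells, collapse = ",")
  }
  ukeys <- unique(keys)
  pattern_map <- match(keys, ukeys)
  list(tiles = tiles, positions = pos,
       unique_patterns = tiles[match(ukeys, keys)],
       pattern_map = pattern_map)
}

#' Stitch tiles back into a mosaic
#'
#' Inverse of [decompose_grid()]: places tiles at their (tile_row,
#' tile_col) positions. Every position of the implied mosaic must be
#' covered exactly once.
#'
#' @param tiles list of equally sized [pixel_grid()] tiles.
#' @param positions data.frame with `tile_row` and `tile_col` (1-based).
#' @return The stitched [pixel_grid()].
#' @export
stitch_tiles <- function(tiles, positions) {
  stopifnot(length(tiles) == nrow(positions), length(tiles) > 0)
  tile <- nrow(tiles[[1]])
  if (any(vapply(tiles, function(t) nrow(t) != tile || ncol(t) != tile,
                 logical(1))))
    stop("all tiles must be the same square size", call. = FALSE)
  tr <- max(positions$tile_row)
  tc <- max(positions$tile_col)
  seen <- matrix(FALSE, tr, tc)
  out <- matrix(NA_integer_, tr * tile, tc * tile)
  for (k in seq_along(tiles)) {
    i <- positions$tile_row[k]; j <- positions$tile_col[k]
    if (seen[i, j])
      stop("overlapping tile at position (", i, ", ", j, ")", call. = FALSE)
    seen[i, j] <- TRUE
    out[(i - 1) * tile + seq_len(tile), (j - 1) * tile + seq_len(tile)] <-
      tiles[[k]]
  }
  if (!all(seen)) {
    miss <- which(!seen, arr.ind = TRUE)[1, ]
    stop("missing tile at position (", miss[1], ", ", miss[2], ")",
         call. = FALSE)
  }
  pixel_grid(out)
}

#' Serpentine anchor array with FIFO dynamics
#'
#' Models the serpentine chain of droplet anchors: each newly sorted
#' droplet enters at position 1 and knocks every occupant one anchor
#' further down the chain (a displacement shift register). The serpentine
#' map is the boustrophedon traversal of the grid from the entrance at the
#' top-left: row 1 left-to-right, row 2 right-to-left, and so on.
#'
#' @param nrow,ncol grid dimensions (5 x 5 for the standard array).
#' @return An object of class `anchor_array` with fields `n_anchors`,
#'   `serpentine` (n x 2 matrix, linear position -> row, col) and
#'   `occupancy` (vector of droplet values ordered from the entrance;
#'   grows with each [anchor_push()]).
#' @export
anchor_array <- function(nrow = 5L, ncol = 5L) {
  n <- nrow * ncol
  serp <- matrix(0L, n, 2, dimnames = list(NULL, c("row", "col")))
  p <- 0L
  for (i in seq_len(nrow)) {
    cols <- if (i %% 2 == 1) seq_len(ncol) else rev(seq_len(ncol))
    for (j in cols) {
      p <- p + 1L
      serp[p, ] <- c(i, j)
    }
  }
  structure(list(n_anchors = n, nrow = nrow, ncol = ncol,
                 serpentine = serp, occupancy = integer(0)),
            class = "anchor_array")
}

#' @rdname anchor_array
#' @param array an `anchor_array`.
#' @param droplet droplet value (a palette index, or any id) to push in at
#'   the entrance.
#' @return `anchor_push()`: the updated array; after `n` pushes position
#'   `i` holds the `(n + 1 - i)`-th pushed droplet.
#' @export
anchor_push <- function(array, droplet) {
  stopifnot(inherits(array, "anchor_array"))
  if (length(array$occupancy) >= array$n_anchors)
    stop("anchor array overflow: all ", array$n_anchors,
         " anchors are occupied", call. = FALSE)
  array$occupancy <- c(droplet, array$occupancy)
  array
}

#' @rdname anchor_array
#' @return `array_to_grid()`: the [pixel_grid()] formed by reading the
#'   (full) array's occupancy through the serpentine map.
#' @export
array_to_grid <- function(array) {
  stopifnot(inherits(array, "anchor_array"))
  if (length(array$occupancy) != array$n_anchors)
    stop("array is not full (", length(array$occupancy), "/",
         array$n_anchors, " anchors occupied)", call. = FALSE)
  cells <- matrix(NA_integer_, array$nrow, array$ncol)
  cells[array$serpentine] <- as.integer(array$occupancy)
  pixel_grid(cells)
}

#' Compile sort instructions for a target tile
#'
#' Inverts the serpentine FIFO dynamics: because each push displaces all
#' occupants one anchor down the chain, the first droplet sorted ends up at
#' the anchor farthest from the entrance. The instruction list is therefore
#' the target tile's colors read along the serpentine from the farthest
#' anchor back to the entrance; replaying it through [anchor_push()]
#' reproduces the tile exactly.
#'
#' @param tile target [pixel_grid()] matching the array geometry.
#' @param array an [anchor_array()] (defines geometry and serpentine map).
#' @return An integer vector of class `instruction_list`: palette indices
#'   in sort order, length `n_anchors`.
#' @export
compile_instructions <- function(tile, array = anchor_array()) {
  stopifnot(inherits(tile, "pixel_grid"), inherits(array, "anchor_array"))
  if (nrow(tile) != array$nrow || ncol(tile) != array$ncol)
    stop("tile geometry (", nrow(tile), "x", ncol(tile),
         ") does not match the anchor array (", array$nrow, "x",
         array$ncol, ")", call. = FALSE)
  along_serp <- tile[array$serpentine]     # color at serpentine position p
  structure(as.integer(rev(along_serp)), class = "instruction_list")
}

#' @rdname compile_instructions
#' @param instructions an `instruction_list` (or integer vector of palette
#'   indices).
#' @return `replay_instructions()`: the [pixel_grid()] produced by pushing
#'   the instructions through a fresh array — the oracle for the
#'   compile/replay round trip.
#' @export
replay_instructions <- function(instructions, array = anchor_array()) {
  for (d in instructions) array <- anchor_push(array, d)
  array_to_grid(array)
}
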