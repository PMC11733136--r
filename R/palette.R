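#' The 8-color droplet palette
#'
#' Droplet colors are combinations of high/low levels of three fluorophores,
#' one per excitation laser: Cascade Blue (405 nm, "blue" channel),
#' Fluorescein (488 nm, "green" channel) and Texas Red (561 nm, "red"
#' channel). Two levels per channel give the 2^3 = 8 realizable colors.
#'
#' Palette indices are the binary encoding of the per-channel levels with
#' blue as the most significant bit: `index = 4*blue + 2*green + 1*red`,
#' so 0 is all-low (black), 7 all-high (white) and 4 blue-high-only.
#' Display colors put each level at a corner of the RGB cube (low = 0,
#' high = 255), which makes nearest-color quantization equivalent to a
#' per-channel midpoint threshold.
#'
#' @return A data.frame with one row per palette color and columns `index`
#'   (0-7), `blue`, `green`, `red` (0 = low, 1 = high; laser order
#'   405/488/561 nm), and display values `R`, `G`, `B` (0-255).
#' @examples
#' droplet_palette()
#' @export
droplet_palette <- function() {
  idx <- 0:7
  blue <- idx %/% 4
  green <- (idx %/% 2) %% 2
  red <- idx %% 2
  data.frame(
    index = idx, blue = blue, green = green, red = red,
    R = 255L * red, G = 255L * green, B = 255L * blue
  )
}

#' @rdname droplet_palette
#' @param index integer vector of palette indices (0-7).
#' @return `palette_levels()`: an `length(index) x 3` matrix of 0/1 levels
#'   in channel order (blue, green, red).
#' @export
palette_levels <- function(index) {
  stopifnot(all(index %in% 0:7))
  cbind(blue = index %/% 4, green = (index %/% 2) %% 2, red = index %% 2)
}

#' @rdname droplet_palette
#' @param levels a length-3 0/1 vector or 3-column matrix (blue, green, red).
#' @return `palette_index()`: integer palette indices.
#' @export
palette_index <- function(levels) {
  if (is.null(dim(levels))) levels <- matrix(levels, ncol = 3)
  stopifnot(ncol(levels) == 3, all(levels %in% 0:1))
  as.integer(4 * levels[, 1] + 2 * levels[, 2] + levels[, 3])
}

# display RGB (0-255 triples, rows = palette index 0..7) used by the
# quantizer and renderer
palette_rgb_matrix <- function() {
  pal <- droplet_palette()
  as.matrix(pal[, c("R", "G", "B")])
}
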