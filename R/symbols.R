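#' Built-in 5x5 alphanumeric symbol library
#'
#' A library of 35 black-and-white 5x5 patterns (letters A-Z and digits
#' 0-8) rendered with a 2-color sub-palette: background `bg` (default 0,
#' all-low/black droplets) and foreground `fg` (default 7, all-high/white
#' droplets). Because every glyph needs all 25 droplets deflected in
#' exactly the instructed order, a cleanly rendered library certifies the
#' whole sense/sort/anchor chain end to end.
#'
#' @param fg,bg palette indices for foreground and background.
#' @return A named list of 35 [pixel_grid()]s.
#' @examples
#' length(symbol_library())  # 35
#' @export
symbol_library <- function(fg = 7L, bg = 0L) {
  defs <- list(
    A = c(".###.", "#...#", "#####", "#...#", "#...#"),
    B = c("####.", "#...#", "####.", "#...#", "####."),
    C = c(".####", "#....", "#....", "#....", ".####"),
    D = c("####.", "#...#", "#...#", "#...#", "####."),
    E = c("#####", "#....", "###..", "#....", "#####"),
    F = c("#####", "#....", "###..", "#....", "#...."),
    G = c(".####", "#....", "#..##", "#...#", ".###."),
    H = c("#...#", "#...#", "#####", "#...#", "#...#"),
    I = c("#####", "..#..", "..#..", "..#..", "#####"),
    J = c("..###", "...#.", "...#.", "#..#.", ".##.."),
    K = c("#...#", "#..#.", "###..", "#..#.", "#...#"),
    L = c("#....", "#....", "#....", "#....", "#####"),
    M = c("#...#", "##.##", "#.#.#", "#...#", "#...#"),
    N = c("#...#", "##..#", "#.#.#", "#..##", "#...#"),
    O = c(".###.", "#...#", "#...#", "#...#", ".###."),
    P = c("####.", "#...#", "####.", "#....", "#...."),
    Q = c(".###.", "#...#", "#.#.#", "#..#.", ".##.#"),
    R = c("####.", "#...#", "####.", "#..#.", "#...#"),
    S = c(".####", "#....", ".###.", "....#", "####."),
    T = c("#####", "..#..", "..#..", "..#..", "..#.."),
    U = c("#...#", "#...#", "#...#", "#...#", ".###."),
    V = c("#...#", "#...#", "#...#", ".#.#.", "..#.."),
    W = c("#...#", "#...#", "#.#.#", "##.##", "#...#"),
    X = c("#...#", ".#.#.", "..#..", ".#.#.", "#...#"),
    Y = c("#...#", ".#.#.", "..#..", "..#..", "..#.."),
    Z = c("#####", "...#.", "..#..", ".#...", "#####"),
    `0` = c(".###.", "#..##", "#.#.#", "##..#", ".###."),
    `1` = c("..#..", ".##..", "..#..", "..#..", ".###."),
    `2` = c(".###.", "#...#", "..##.", ".#...", "#####"),
    `3` = c("####.", "....#", ".###.", "....#", "####."),
    `4` = c("#..#.", "#..#.", "#####", "...#.", "...#."),
    `5` = c("#####", "#....", "####.", "....#", "####."),
    `6` = c(".###.", "#....", "####.", "#...#", ".###."),
    `7` = c("#####", "....#", "...#.", "..#..", "..#.."),
    `8` = c(".###.", "#...#", ".###.", "#...#", ".###.")
  )
  lapply(defs, function(rows) {
    m <- do.call(rbind, strsplit(rows, ""))
    pixel_grid(ifelse(m == "#", fg, bg))
  })
}
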