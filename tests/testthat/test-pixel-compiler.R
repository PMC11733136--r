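test_that("quantize maps palette-exact images to their indices", {
  white <- array(1, c(5, 5, 3))
  expect_true(all(unclass(quantize_image(white)) == 7L))
  black <- array(0, c(4, 6, 3))
  expect_true(all(unclass(quantize_image(black)) == 0L))
  g <- quantize_image(array(runif(75), c(5, 5, 3)))
  expect_s3_class(g, "pixel_grid")
  expect_equal(dim(g), c(5, 5))                 # 25 droplet pixels
})

test_that("mid-gray ties resolve to the lowest palette index", {
  gray <- array(127.5, c(2, 2, 3))
  d <- sqrt(rowSums((matrix(127.5, 8, 3) -
                       as.matrix(droplet_palette()[, c("R", "G", "B")]))^2))
  expect_true(all(abs(d - d[1]) < 1e-9))        # all 8 equidistant
  expect_true(all(unclass(quantize_image(gray)) == 0L))
})

test_that("quantization is idempotent through rendering", {
  for (seed in 1:5) {
    g <- random_tile(seed, 10, 10)
    img <- render_grid(g, scale = 3)
    expect_identical(unclass(quantize_image(img, 10, 10)), unclass(g))
  }
})

test_that("block averaging downsamples before quantization", {
  # 10x10 image of pure-red and pure-green 5x5 blocks
  img <- array(0, c(10, 10, 3))
  img[1:5, , 1] <- 1
  img[6:10, , 2] <- 1
  g <- quantize_image(img, 2, 1)
  expect_equal(as.vector(unclass(g)), c(1L, 2L))  # red row, green row
})

test_that("decompose counts tiles and unique patterns", {
  g50 <- random_tile(99, 50, 50)
  dec <- decompose_grid(g50)
  expect_length(dec$tiles, 100)
  expect_lte(length(dec$unique_patterns), 100)
  expect_equal(length(dec$pattern_map), 100)
  one <- decompose_grid(random_tile(1, 5, 5))
  expect_length(one$tiles, 1)
  expect_length(one$unique_patterns, 1)
  # four identical tiles -> one unique pattern
  tile <- random_tile(7)
  quad <- stitch_tiles(list(tile, tile, tile, tile),
                       data.frame(tile_row = c(1, 1, 2, 2),
                                  tile_col = c(1, 2, 1, 2)))
  dq <- decompose_grid(quad)
  expect_length(dq$tiles, 4)
  expect_length(dq$unique_patterns, 1)
  expect_equal(dq$pattern_map, rep(1L, 4))
  expect_error(decompose_grid(random_tile(2, 7, 10)), "not divisible")
})

test_that("stitch is the inverse of decompose and validates coverage", {
  g <- random_tile(123, 50, 50)
  dec <- decompose_grid(g)
  expect_identical(unclass(stitch_tiles(dec$tiles, dec$positions)),
                   unclass(g))
  # rebuilding from unique patterns + map reproduces the mosaic
  rebuilt <- stitch_tiles(dec$unique_patterns[dec$pattern_map],
                          dec$positions)
  expect_identical(unclass(rebuilt), unclass(g))
  expect_error(stitch_tiles(dec$tiles[-1], dec$positions[-1, ]),
               "missing tile at position \\(1, 1\\)")
  dup <- dec$positions
  dup$tile_col[2] <- 1L
  expect_error(stitch_tiles(dec$tiles, dup), "overlapping")
})

test_that("anchor FIFO law holds exhaustively at N = 25", {
  arr <- anchor_array()
  expect_equal(arr$n_anchors, 25)
  # serpentine map is a bijection onto the grid
  expect_equal(nrow(unique(arr$serpentine)), 25)
  for (n in 1:25) {
    a <- anchor_array()
    for (d in 1:n) a <- anchor_push(a, d)
    expect_equal(a$occupancy, rev(seq_len(n)))  # position i holds n+1-i
  }
  full <- Reduce(anchor_push, 1:25, anchor_array())
  expect_error(anchor_push(full, 26), "overflow")
})

test_that("compile/replay round trip reproduces arbitrary tiles", {
  uni <- pixel_grid(rep(3L, 25), 5, 5)
  expect_equal(as.integer(compile_instructions(uni)), rep(3L, 25))
  for (seed in 1:25) {
    tile <- random_tile(seed)
    ins <- compile_instructions(tile)
    expect_identical(unclass(replay_instructions(ins)), unclass(tile))
    # the entrance-position color is the last instruction emitted
    entrance <- anchor_array()$serpentine[1, ]
    expect_equal(ins[25], tile[entrance[1], entrance[2]])
  }
  expect_error(compile_instructions(random_tile(1, 4, 4)),
               "does not match")
})

test_that("render paints palette colors and fixes under re-quantization", {
  card <- pixel_grid(0:7, 2, 4)                 # 8-color test card
  img <- render_grid(card, scale = 2)
  cols <- unique(matrix(img, ncol = 3))
  expect_equal(nrow(cols), 8)                   # 8 distinct RGB values
  expect_identical(render_grid(quantize_image(render_grid(card)), 1),
                   render_grid(card, 1))
  dark <- render_grid(pixel_grid(rep(0L, 25), 5, 5))
  expect_true(all(dark == 0))
})
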