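# Shared fixtures, all generated in code.

# Gaussian blob(s) as an n x 2 matrix.
make_blob <- function(n, center = c(0, 0), sd = 5) {
  cbind(stats::rnorm(n, center[1], sd), stats::rnorm(n, center[2], sd))
}

# A small cell_map with an explicit full tile grid.
toy_cell_map <- function(xy_px, types = "lymphocyte", tile_size_px = 400,
                         pixel_spacing = 0.25, n_tiles_x = 2, n_tiles_y = 2) {
  xy_px <- matrix(xy_px, ncol = 2)
  n <- nrow(xy_px)
  tiles <- expand.grid(tile_x_px = (seq_len(n_tiles_x) - 1) * tile_size_px,
                       tile_y_px = (seq_len(n_tiles_y) - 1) * tile_size_px)
  cell_map("toy",
           data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                      x_px = xy_px[, 1], y_px = xy_px[, 2],
                      cell_type = rep_len(types, n),
                      stringsAsFactors = FALSE),
           tiles, tile_size_px = tile_size_px, pixel_spacing = pixel_spacing)
}

# Two-class feature matrix with one informative column among noise.
planted_features <- function(n = 80, p = 8, shift = 2, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    x <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    x[, 1] <- x[, 1] + shift * y
    list(x = x, y = y)
  })
}
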