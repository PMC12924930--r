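#' Analysis window
#'
#' The continuous coordinate frame for simulated cores. Internally all
#' geometry is in micrometers; `pixel_spacing` converts to the pixel
#' units used in centroid and tile files (0.25 um/px corresponds to a
#' standard 40x scan).
#'
#' @param width,height window extent in micrometers.
#' @param pixel_spacing micrometers per pixel (default 0.25).
#' @export
new_window <- function(width, height = width, pixel_spacing = 0.25) {
  stopifnot_scalar_num(width, "width", 0, strict = TRUE)
  stopifnot_scalar_num(height, "height", 0, strict = TRUE)
  stopifnot_scalar_num(pixel_spacing, "pixel_spacing", 0, strict = TRUE)
  structure(list(width = width, height = height,
                 pixel_spacing = pixel_spacing), class = "window")
}

cell_types <- function() {
  c("lymphocyte", "epithelial", "macrophage", "neutrophil", "other")
}

#' One core's cell centroids plus its tumor-bed tile set
#'
#' @param core_id core identifier.
#' @param cells data.frame with columns `cell_id`, `x_px`, `y_px`,
#'   `cell_type` (vocabulary: lymphocyte, epithelial, macrophage,
#'   neutrophil, other). May have zero rows.
#' @param tiles data.frame with columns `tile_x_px`, `tile_y_px` (tile
#'   origins); tumor-bed tiles the centroids are filtered against.
#' @param tile_size_px tile edge length in pixels (the pipeline default
#'   is 750).
#' @param pixel_spacing micrometers per pixel.
#' @return an object of class `cell_map`.
#' @export
cell_map <- function(core_id, cells, tiles, tile_size_px = 750,
                     pixel_spacing = 0.25) {
  cells <- as.data.frame(cells)
  tiles <- as.data.frame(tiles)
  need <- c("cell_id", "x_px", "y_px", "cell_type")
  if (!all(need %in% names(cells))) {
    stop("`cells` must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(cells) > 0) {
    if (anyDuplicated(cells$cell_id)) stop("cell ids must be unique within a core", call. = FALSE)
    if (any(cells$x_px < 0) || any(cells$y_px < 0)) stop("coordinates must be >= 0", call. = FALSE)
    bad <- setdiff(unique(cells$cell_type), cell_types())
    if (length(bad)) stop("unknown cell_type: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(c("tile_x_px", "tile_y_px") %in% names(tiles))) {
    stop("`tiles` must have columns tile_x_px, tile_y_px", call. = FALSE)
  }
  stopifnot_scalar_num(tile_size_px, "tile_size_px", 0, strict = TRUE)
  structure(list(core_id = as.character(core_id), cells = cells,
                 tiles = tiles, tile_size_px = tile_size_px,
                 pixel_spacing = pixel_spacing), class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("<cell_map> core %s: %d cells (%d lymphocytes), %d tumor-bed tiles of %g px\n",
              x$core_id, nrow(x$cells),
              sum(x$cells$cell_type == "lymphocyte"), nrow(x$tiles),
              x$tile_size_px))
  invisible(x)
}

# Lymphocyte coordinates in micrometers, as an n x 2 matrix.
cells_um <- function(cm, type = "lymphocyte") {
  keep <- if (is.null(type)) rep(TRUE, nrow(cm$cells)) else cm$cells$cell_type %in% type
  cbind(x = cm$cells$x_px[keep], y = cm$cells$y_px[keep]) * cm$pixel_spacing
}

## ---- plain-text interchange formats ------------------------------------

#' Read / write centroid tables
#'
#' Comma-separated text with header
#' `cell_id,core_id,x_px,y_px,cell_type`, the format emitted by nuclei
#' segmenters downstream of this pipeline.
#'
#' @param path file path.
#' @rdname centroid-io
#' @export
read_centroids <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "core_id", "x_px", "y_px", "cell_type")
  if (!all(need %in% names(df))) {
    stop("centroid table must have columns ", paste(need, collapse = ","), call. = FALSE)
  }
  df[need]
}

#' @param cell_maps a `cell_map` or list of them.
#' @rdname centroid-io
#' @export
write_centroids <- function(cell_maps, path) {
  if (inherits(cell_maps, "cell_map")) cell_maps <- list(cell_maps)
  rows <- lapply(cell_maps, function(cm) {
    if (nrow(cm$cells) == 0) return(NULL)
    data.frame(cell_id = cm$cells$cell_id, core_id = cm$core_id,
               x_px = cm$cells$x_px, y_px = cm$cells$y_px,
               cell_type = cm$cells$cell_type, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(cell_id = character(), core_id = character(),
                     x_px = numeric(), y_px = numeric(),
                     cell_type = character())
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write tumor-bed tile lists
#'
#' Comma-separated text with header
#' `core_id,tile_x_px,tile_y_px,tile_size_px`.
#'
#' @param path file path.
#' @rdname tile-io
#' @export
read_tiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("core_id", "tile_x_px", "tile_y_px", "tile_size_px")
  if (!all(need %in% names(df))) {
    stop("tile list must have columns ", paste(need, collapse = ","), call. = FALSE)
  }
  df[need]
}

#' @param cell_maps a `cell_map` or list of them.
#' @rdname tile-io
#' @export
write_tiles <- function(cell_maps, path) {
  if (inherits(cell_maps, "cell_map")) cell_maps <- list(cell_maps)
  rows <- lapply(cell_maps, function(cm) {
    data.frame(core_id = cm$core_id, tile_x_px = cm$tiles$tile_x_px,
               tile_y_px = cm$tiles$tile_y_px,
               tile_size_px = cm$tile_size_px, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble cell_map objects from centroid and tile tables
#'
#' @param centroids data.frame as returned by [read_centroids()].
#' @param tiles data.frame as returned by [read_tiles()].
#' @param pixel_spacing micrometers per pixel.
#' @return named list of `cell_map`, one per core id present in `tiles`.
#' @export
cell_maps_from_tables <- function(centroids, tiles, pixel_spacing = 0.25) {
  out <- list()
  for (cid in unique(tiles$core_id)) {
    tl <- tiles[tiles$core_id == cid, , drop = FALSE]
    cc <- centroids[centroids$core_id == cid, , drop = FALSE]
    out[[as.character(cid)]] <- cell_map(
      core_id = cid,
      cells = cc[c("cell_id", "x_px", "y_px", "cell_type")],
      tiles = data.frame(tile_x_px = tl$tile_x_px, tile_y_px = tl$tile_y_px),
      tile_size_px = tl$tile_size_px[1],
      pixel_spacing = pixel_spacing)
  }
  out
}
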