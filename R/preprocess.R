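## Image front end: foreground detection, tiling, stain normalization,
## and assignment of cell centroids to the tumor bed. The CNN stages of
## the original pipeline (tumor-bed probability maps, nuclei
## classification) are consumed as inputs, never computed here.

# Otsu's threshold on values in [0, 1], using a 256-bin histogram.
otsu_threshold <- function(v) {
  h <- tabulate(pmin(pmax(floor(v * 255) + 1L, 1L), 256L), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 1))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  # midpoint of the maximizing plateau, so a two-level image thresholds
  # halfway between the levels rather than hugging the dark class
  k <- mean(range(which(sigma_b == max(sigma_b))))
  (k + 0.5) / 255
}

# Connected-component labels for a logical matrix (4-connectivity),
# two-pass with union-find.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j]) next
    up <- if (i > 1) labels[i - 1, j] else 0L
    lf <- if (j > 1) labels[i, j - 1] else 0L
    if (up == 0L && lf == 0L) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; labels[i, j] <- nxt
    } else if (up != 0L && lf != 0L) {
      ru <- find(up); rl <- find(lf)
      labels[i, j] <- ru
      if (ru != rl) parent[rl] <- ru
    } else {
      labels[i, j] <- max(up, lf)
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    compact <- match(roots, unique(roots))
    idx <- labels > 0L
    labels[idx] <- compact[labels[idx]]
  }
  labels
}

#' Otsu foreground detection
#'
#' Separates tissue from slide background by Otsu's criterion on the
#' luminance channel, after white-balance clipping at the 99th
#' percentile (robust to glass glare). Tissue is the darker side of the
#' threshold. The boundary of the largest foreground component is
#' returned alongside the mask, mirroring the contoured biopsy outline
#' used to seed tiling.
#'
#' @param image `h x w x 3` RGB array in `[0, 1]`, or a grayscale
#'   matrix.
#' @return list with `mask` (logical matrix, `TRUE` = tissue),
#'   `threshold`, and `boundary` (two-column matrix of row/col pixel
#'   indices of the largest component's border pixels).
#' @export
otsu_foreground <- function(image) {
  if (length(dim(image)) == 3) {
    lum <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else {
    lum <- image
  }
  if (length(lum) == 0) stop("empty image", call. = FALSE)
  hi <- stats::quantile(lum, 0.99, names = FALSE)
  lum <- pmin(lum, hi) / max(hi, .Machine$double.eps)
  if (max(lum) - min(lum) < 1e-8) {
    stop("constant image: Otsu threshold is degenerate", call. = FALSE)
  }
  thr <- otsu_threshold(lum)
  mask <- lum < thr # tissue is dark on a bright slide
  # guard against thresholding pure sensor noise: a real tissue/glass
  # split separates the class means by much more than the noise floor
  if (any(mask) && any(!mask) &&
      mean(lum[!mask]) - mean(lum[mask]) < 0.1) {
    mask[] <- FALSE
  }
  boundary <- NULL
  if (any(mask)) {
    labs <- label_components(mask)
    big <- which.max(tabulate(labs[labs > 0L]))
    comp <- labs == big
    # border pixels: component pixels with a non-component 4-neighbor
    h <- nrow(comp); w <- ncol(comp)
    pad <- matrix(FALSE, h + 2, w + 2); pad[2:(h + 1), 2:(w + 1)] <- comp
    interior <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
      pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
    boundary <- which(comp & !interior, arr.ind = TRUE)
  }
  list(mask = mask, threshold = thr, boundary = boundary)
}

#' Tile a foreground mask into a non-overlapping grid
#'
#' Lays a grid of `tile_size x tile_size` tiles anchored at the image
#' origin, drops partial border tiles, and drops tiles whose background
#' fraction (1 - foreground fraction under `mask`) exceeds
#' `max_background`. The pipeline defaults follow the 750-pixel /
#' 10%-background convention.
#'
#' @param mask logical matrix (`TRUE` = foreground tissue); rows are y,
#'   columns are x.
#' @param tile_size tile edge in pixels (default 750).
#' @param max_background maximum tolerated background proportion
#'   (default 0.10).
#' @param core_id identifier carried into the tile list.
#' @return data.frame with `tile_x_px`, `tile_y_px` (origins, 0-based)
#'   and `background`; attribute `tile_size`.
#' @export
tile_image <- function(mask, tile_size = 750, max_background = 0.10,
                       core_id = "core01") {
  stopifnot_scalar_num(tile_size, "tile_size", 0, strict = TRUE)
  if (max_background < 0 || max_background > 1) {
    stop("`max_background` must lie in [0, 1]", call. = FALSE)
  }
  h <- nrow(mask); w <- ncol(mask)
  nx <- floor(w / tile_size); ny <- floor(h / tile_size)
  if (nx == 0 || ny == 0) {
    warning("tile_size exceeds the image; empty grid")
    out <- data.frame(tile_x_px = numeric(0), tile_y_px = numeric(0),
                      background = numeric(0))
    attr(out, "tile_size") <- tile_size
    return(out)
  }
  rows <- list()
  for (iy in seq_len(ny) - 1L) for (ix in seq_len(nx) - 1L) {
    sub <- mask[(iy * tile_size + 1):((iy + 1) * tile_size),
                (ix * tile_size + 1):((ix + 1) * tile_size)]
    bgfrac <- 1 - mean(sub)
    if (bgfrac <= max_background) {
      rows[[length(rows) + 1L]] <- data.frame(
        tile_x_px = ix * tile_size, tile_y_px = iy * tile_size,
        background = bgfrac)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(tile_x_px = numeric(0), tile_y_px = numeric(0),
               background = numeric(0))
  }
  attr(out, "tile_size") <- tile_size
  attr(out, "core_id") <- core_id
  out
}

## ---- Macenko stain normalization ---------------------------------------

# Optical density transform with a floor to avoid log(0).
to_od <- function(img, eps = 1 / 255) -log(pmax(img, eps))

# Estimate the 2-column H&E stain matrix (unit OD vectors) by the
# Macenko procedure: SVD plane of tissue OD pixels, robust extreme
# angles at the 1st/99th percentile.
macenko_stains <- function(img, beta = 0.15, alpha = 1) {
  od <- matrix(to_od(img), ncol = 3)
  tissue <- od[rowSums(od) / 3 > beta, , drop = FALSE]
  if (nrow(tissue) < 20) return(NULL)
  v <- svd(stats::cov(tissue))$u[, 1:2]
  proj <- tissue %*% v
  phi <- atan2(proj[, 2], proj[, 1])
  lo <- stats::quantile(phi, alpha / 100, names = FALSE)
  hi <- stats::quantile(phi, 1 - alpha / 100, names = FALSE)
  s1 <- v %*% c(cos(lo), sin(lo))
  s2 <- v %*% c(cos(hi), sin(hi))
  if (any(s1 < 0)) s1 <- -s1
  if (any(s2 < 0)) s2 <- -s2
  # hematoxylin first (more blue OD)
  stains <- if (s1[3] >= s2[3]) cbind(s1, s2) else cbind(s2, s1)
  sweep(stains, 2, sqrt(colSums(stains^2)), "/")
}

stain_concentrations <- function(img, stains) {
  od <- t(matrix(to_od(img), ncol = 3)) # 3 x npix
  qr.solve(stains, od)                  # 2 x npix, least squares
}

#' Macenko stain normalization
#'
#' Maps a tile's stain appearance onto a reference tile: stain vectors
#' are estimated per image (Macenko SVD-plane method), concentrations
#' are rescaled so the tile's 99th-percentile concentration per stain
#' matches the reference's, and the image is rebuilt in the reference
#' stain basis. A near-white tile (no measurable stain) is passed
#' through with a warning.
#'
#' @param tile,reference `h x w x 3` RGB arrays in `[0, 1]`.
#' @return normalized RGB array, same dimensions as `tile`.
#' @export
stain_normalize <- function(tile, reference) {
  st_t <- macenko_stains(tile)
  st_r <- macenko_stains(reference)
  if (is.null(st_t) || is.null(st_r)) {
    warning("near-white tile or reference: stain normalization skipped")
    return(tile)
  }
  conc_t <- stain_concentrations(tile, st_t)
  conc_r <- stain_concentrations(reference, st_r)
  q_t <- apply(conc_t, 1, stats::quantile, 0.99, names = FALSE)
  q_r <- apply(conc_r, 1, stats::quantile, 0.99, names = FALSE)
  scale <- ifelse(q_t > 1e-8, q_r / q_t, 1)
  # swap the stain component into the reference basis while keeping the
  # off-plane residual, so a tile already matching the reference is a
  # fixed point (up to clipping)
  od <- t(matrix(to_od(tile), ncol = 3))
  od_new <- od - st_t %*% conc_t + st_r %*% (conc_t * scale)
  out <- pmin(pmax(exp(-od_new), 0), 1)
  array(t(out), dim = dim(tile))
}

#' Filter a cell map down to tumor-bed lymphocytes
#'
#' Retains only cells typed `lymphocyte` whose centroid falls inside
#' some tumor-bed tile. Tile membership is half-open,
#' `[origin, origin + size)` in both axes, so shared tile edges are
#' never double-counted. Idempotent.
#'
#' @param cm a [cell_map()].
#' @return a [cell_map()] containing only the retained lymphocytes.
#' @export
assign_tils_to_tumor_bed <- function(cm) {
  stopifnot(inherits(cm, "cell_map"))
  cells <- cm$cells[cm$cells$cell_type == "lymphocyte", , drop = FALSE]
  if (nrow(cells) > 0 && nrow(cm$tiles) > 0) {
    ts <- cm$tile_size_px
    inside <- vapply(seq_len(nrow(cells)), function(i) {
      any(cells$x_px[i] >= cm$tiles$tile_x_px &
          cells$x_px[i] < cm$tiles$tile_x_px + ts &
          cells$y_px[i] >= cm$tiles$tile_y_px &
          cells$y_px[i] < cm$tiles$tile_y_px + ts)
    }, logical(1))
    cells <- cells[inside, , drop = FALSE]
  } else {
    cells <- cells[integer(0), , drop = FALSE]
  }
  rownames(cells) <- NULL
  cell_map(cm$core_id, cells, cm$tiles, cm$tile_size_px, cm$pixel_spacing)
}
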