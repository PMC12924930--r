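## The spatial feature catalogue. All geometry is computed on lymphocyte
## centroids in micrometers; every family reduces a distribution of
## geometric quantities through summary_stats() (mean, population std,
## min-max ratio, disorder).

# rank of the centered coordinate matrix; < 2 means collinear/degenerate
points_collinear <- function(xy) {
  if (nrow(xy) < 3) return(TRUE)
  qr(sweep(xy, 2, colMeans(xy)))$rank < 2
}

#' Delaunay triangulation features (8)
#'
#' Summary statistics of the Delaunay edge lengths (4) and triangle
#' areas (4). Each edge is counted once. Fewer than 3 points, or a
#' collinear configuration, yields all-`NA`.
#'
#' @param points n x 2 coordinate matrix (micrometers).
#' @return named numeric vector of length 8 (`DE-*`, `DTA-*`).
#' @export
delaunay_features <- function(points) {
  nm <- c(paste0("DE-", stat_suffixes()), paste0("DTA-", stat_suffixes()))
  out <- stats::setNames(rep(NA_real_, 8L), nm)
  if (points_collinear(points)) return(out)
  dd <- deldir::deldir(points[, 1], points[, 2], suppressMsge = TRUE)
  e <- dd$delsgs
  len <- sqrt((points[e$ind1, 1] - points[e$ind2, 1])^2 +
              (points[e$ind1, 2] - points[e$ind2, 2])^2)
  tri <- deldir::triang.list(dd)
  areas <- vapply(tri, function(t) {
    x <- t$x; y <- t$y
    abs(x[1] * (y[2] - y[3]) + x[2] * (y[3] - y[1]) + x[3] * (y[1] - y[2])) / 2
  }, numeric(1))
  out[1:4] <- summary_stats_vec(len)
  out[5:8] <- summary_stats_vec(areas)
  out
}

#' Voronoi tessellation features (12)
#'
#' Voronoi cells clipped to a rectangular window; summary statistics of
#' the clipped cell areas (`VA`), perimeters (`VP`) and maximum chord
#' lengths ("Voronoi max distance", `VMD`). Clipped areas partition the
#' window. Fewer than 2 points yields all-`NA`.
#'
#' @param points n x 2 coordinate matrix (micrometers).
#' @param window clipping rectangle `c(xmin, xmax, ymin, ymax)` in
#'   micrometers, or a [new_window()] (taken as `[0,w] x [0,h]`).
#' @return named numeric vector of length 12.
#' @export
voronoi_features <- function(points, window) {
  nm <- c(paste0("VA-", stat_suffixes()), paste0("VP-", stat_suffixes()),
          paste0("VMD-", stat_suffixes()))
  out <- stats::setNames(rep(NA_real_, 12L), nm)
  if (nrow(points) < 2) return(out)
  rw <- if (inherits(window, "window")) c(0, window$width, 0, window$height) else window
  dd <- deldir::deldir(points[, 1], points[, 2], rw = rw, suppressMsge = TRUE)
  tl <- deldir::tile.list(dd)
  areas <- vapply(tl, function(t) t$area, numeric(1))
  perim <- vapply(tl, function(t) {
    v <- cbind(t$x, t$y)
    sum(sqrt(rowSums((v - v[c(2:nrow(v), 1), , drop = FALSE])^2)))
  }, numeric(1))
  chord <- vapply(tl, function(t) {
    max(stats::dist(cbind(t$x, t$y)))
  }, numeric(1))
  out[1:4] <- summary_stats_vec(areas)
  out[5:8] <- summary_stats_vec(perim)
  out[9:12] <- summary_stats_vec(chord)
  out
}

#' Euclidean minimum spanning tree features (4)
#'
#' Summary statistics of the EMST's n-1 edge lengths. Fewer than 2
#' points yields all-`NA`.
#'
#' @param points n x 2 coordinate matrix (micrometers).
#' @return named numeric vector of length 4 (`MST-*`).
#' @export
mst_features <- function(points) {
  nm <- paste0("MST-", stat_suffixes())
  out <- stats::setNames(rep(NA_real_, 4L), nm)
  if (nrow(points) < 2) return(out)
  mst <- prim_mst(dist_matrix(points))
  out[1:4] <- summary_stats_vec(mst[, 3])
  out
}

# MST edge index pairs, for the EMST-subset-of-Delaunay property.
mst_edges <- function(points) {
  e <- prim_mst(dist_matrix(points))
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Density features (216)
#'
#' Two sweeps over per-cell quantities:
#' * DND ("density neighbors in distance"): for each of 40 radii, the
#'   count of other cells within that radius of each cell (40 x 4 = 160).
#' * DDN ("density distance for neighbors"): for each of 14 neighbor
#'   ranks k, the distance from each cell to its k-th nearest neighbor
#'   (14 x 4 = 56).
#'
#' Ranks with `k >= n` cannot be computed and yield `NA`.
#'
#' @param points n x 2 coordinate matrix (micrometers).
#' @param config a [density_config()].
#' @return named numeric vector of length 216 in registry order.
#' @export
density_features <- function(points, config = density_config()) {
  nm <- c(
    as.vector(vapply(seq_along(config$radii) - 1L,
                     function(i) sprintf("DND-%s_%d", stat_suffixes(), i),
                     character(4))),
    as.vector(vapply(seq_along(config$k_values) - 1L,
                     function(i) sprintf("DDN-%s_%d", stat_suffixes(), i),
                     character(4))))
  out <- stats::setNames(rep(NA_real_, 216L), nm)
  n <- nrow(points)
  if (n < 2) return(out)
  d <- dist_matrix(points)
  diag(d) <- Inf
  for (i in seq_along(config$radii)) {
    counts <- rowSums(d <= config$radii[i])
    out[(i - 1L) * 4L + 1:4] <- summary_stats_vec(counts)
  }
  kmax <- min(max(config$k_values), n - 1L)
  nnd <- FNN::get.knn(points, k = kmax)$nn.dist
  for (j in seq_along(config$k_values)) {
    k <- config$k_values[j]
    if (k <= n - 1L) {
      out[160L + (j - 1L) * 4L + 1:4] <- summary_stats_vec(nnd[, k])
    }
  }
  out
}

#' Lymphocyte frequency within the tumor bed (1)
#'
#' Tumor-bed lymphocyte count per square millimeter of tumor-bed tile
#' area (tile count times tile area, converted through the pixel
#' spacing).
#'
#' @param cm a [cell_map()] already filtered to tumor-bed lymphocytes
#'   (see [assign_tils_to_tumor_bed()]).
#' @return single numeric (`NA` if the tile set is empty).
#' @export
til_frequency <- function(cm) {
  stopifnot(inherits(cm, "cell_map"))
  n_tiles <- nrow(cm$tiles)
  if (n_tiles == 0) return(NA_real_)
  tile_mm <- cm$tile_size_px * cm$pixel_spacing / 1000
  area_mm2 <- n_tiles * tile_mm^2
  sum(cm$cells$cell_type == "lymphocyte") / area_mm2
}

#' Extract the full 371-feature vector for one core
#'
#' Applies every family of the registry to the core's tumor-bed
#' lymphocytes: 130 clustering + 12 Voronoi + 8 Delaunay + 4 MST +
#' 216 density + 1 frequency. The Voronoi clipping window is the
#' axis-aligned bounding box of the tumor-bed tiles. Features that
#' cannot be computed on a degenerate input are emitted as `NA`
#' (imputed downstream with training-set medians).
#'
#' @param cm a [cell_map()]; cells not typed lymphocyte or outside the
#'   tumor bed are dropped first (the operation is a no-op on already
#'   filtered maps).
#' @param density a [density_config()].
#' @param cluster a [cluster_config()].
#' @return named numeric vector of length 371, names and order matching
#'   [feature_registry()].
#' @export
extract_all <- function(cm, density = density_config(),
                        cluster = cluster_config()) {
  cm <- assign_tils_to_tumor_bed(cm)
  pts <- cells_um(cm)
  sp <- cm$pixel_spacing
  bbox <- if (nrow(cm$tiles)) {
    c(min(cm$tiles$tile_x_px), max(cm$tiles$tile_x_px) + cm$tile_size_px,
      min(cm$tiles$tile_y_px), max(cm$tiles$tile_y_px) + cm$tile_size_px) * sp
  } else c(0, 1, 0, 1)
  vals <- c(
    clustering_features(pts, cluster),
    voronoi_features(pts, bbox),
    delaunay_features(pts),
    mst_features(pts),
    density_features(pts, density),
    `TIL-FREQ` = if (nrow(pts) == 0 && nrow(cm$tiles) > 0) 0 else til_frequency(cm))
  reg <- feature_registry(density, cluster)
  stopifnot(identical(names(vals), reg$name))
  vals
}

#' Feature matrix for a list of cores or a cohort
#'
#' @param cohort list of patient records from [simulate_cohort()], or a
#'   named list of [cell_map()]s.
#' @param density,cluster family configurations.
#' @return data.frame with `patient_id`, `core_id`, and 371 feature
#'   columns.
#' @export
extract_cohort_features <- function(cohort, density = density_config(),
                                    cluster = cluster_config()) {
  rows <- list()
  for (p in cohort) {
    if (inherits(p, "cell_map")) {
      p <- list(patient_id = p$core_id, cores = list(p))
    }
    for (cm in p$cores) {
      v <- extract_all(cm, density, cluster)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(patient_id = p$patient_id, core_id = cm$core_id,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(v), check.names = FALSE))
    }
  }
  do.call(rbind, rows)
}

#' Write / read a feature matrix as comma-separated text
#'
#' @param features data.frame from [extract_cohort_features()].
#' @param path file path.
#' @rdname feature-io
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname feature-io
#' @export
read_features <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
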