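#' Configuration of the density feature families
#'
#' The density family has two sub-families: DND ("density neighbors in
#' distance"), the per-cell count of other cells within a radius, swept
#' over 40 radii indexed 0-39; and DDN ("density distance for neighbors"),
#' the per-cell distance to its k-th nearest neighbor, swept over 14
#' neighbor ranks indexed 0-13. Each sweep value is reduced by
#' [summary_stats()], giving 40*4 + 14*4 = 216 features.
#'
#' @param radii strictly increasing vector of 40 radii in micrometers;
#'   default `5 * (1:40)` (5-200 um), spanning lymphocyte-neighborhood
#'   scales.
#' @param k_values strictly increasing positive integers, length 14;
#'   default `1:14`.
#' @return an object of class `density_config`.
#' @export
density_config <- function(radii = 5 * (1:40), k_values = 1:14) {
  if (length(radii) != 40L || any(diff(radii) <= 0) || any(radii <= 0)) {
    stop("`radii` must be 40 strictly increasing positive lengths", call. = FALSE)
  }
  if (length(k_values) != 14L || any(diff(k_values) <= 0) ||
      any(k_values < 1) || any(k_values != as.integer(k_values))) {
    stop("`k_values` must be 14 strictly increasing positive integers", call. = FALSE)
  }
  structure(list(radii = radii, k_values = as.integer(k_values)),
            class = "density_config")
}

#' Configuration of the clustering feature family
#'
#' HDBSCAN is run once per `min_cluster_size`; each run emits 13 named
#' statistics (see [clustering_features()]), giving the 130-feature
#' cluster family.
#'
#' @param min_cluster_sizes 10 integers, default `seq(10, 100, by = 10)`.
#' @return an object of class `cluster_config`.
#' @export
cluster_config <- function(min_cluster_sizes = seq(10L, 100L, by = 10L)) {
  if (length(min_cluster_sizes) != 10L || any(min_cluster_sizes < 2)) {
    stop("`min_cluster_sizes` must be 10 integers >= 2", call. = FALSE)
  }
  structure(list(min_cluster_sizes = as.integer(min_cluster_sizes)),
            class = "cluster_config")
}

# The 13 per-size cluster statistics, in registry order. Abbreviations
# follow the field's naming: CCF clustered cell fraction, OF outlier
# fraction, CS cluster size, CP cluster persistence, MCS/MCP medians,
# DBS Davies-Bouldin score, MICD mean intra-cluster pairwise distance.
cluster_stat_names <- function() {
  c("NC", "CCF", "OF",
    "MEAN-CS", "MCS", "STD-CS", "MMR-CS", "DIS-CS",
    "MEAN-CP", "MCP", "STD-CP",
    "DBS", "MICD")
}

stat_suffixes <- function() c("MEAN", "STD", "MMR", "DIS")

#' The 371-feature registry
#'
#' Enumerates every feature the extractor emits: name, family
#' (CLUSTER/VORONOI/DELAUNAY/MST/DENSITY/FREQUENCY), the sweep parameter
#' it belongs to, and the reducing statistic. Family cardinalities are
#' fixed at 130/12/8/4/216/1 (total 371).
#'
#' @param density [density_config()] controlling radii and neighbor ranks.
#' @param cluster [cluster_config()] controlling HDBSCAN sizes.
#' @return a data.frame with columns `name`, `family`, `parameter`,
#'   `statistic`, one row per feature, in canonical order.
#' @examples
#' reg <- feature_registry()
#' table(reg$family)
#' @export
feature_registry <- function(density = density_config(),
                             cluster = cluster_config()) {
  rows <- list()
  add <- function(name, family, parameter, statistic) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, family = family,
      parameter = parameter, statistic = statistic,
      stringsAsFactors = FALSE)
  }

  # CLUSTER: 10 sizes x 13 statistics = 130
  for (s in cluster$min_cluster_sizes) {
    for (st in cluster_stat_names()) {
      add(sprintf("%s_%d", st, s), "CLUSTER", as.character(s), st)
    }
  }
  # VORONOI: 3 geometric quantities (area VA, perimeter VP, max chord VMD) x 4
  for (q in c("VA", "VP", "VMD")) {
    for (st in stat_suffixes()) add(sprintf("%s-%s", q, st), "VORONOI", q, st)
  }
  # DELAUNAY: edge length DE and triangle area DTA x 4
  for (q in c("DE", "DTA")) {
    for (st in stat_suffixes()) add(sprintf("%s-%s", q, st), "DELAUNAY", q, st)
  }
  # MST: edge length x 4
  for (st in stat_suffixes()) add(sprintf("MST-%s", st), "MST", "edge", st)
  # DENSITY: DND 40 radii x 4, then DDN 14 ranks x 4 = 216
  for (i in seq_along(density$radii)) {
    for (st in stat_suffixes()) {
      add(sprintf("DND-%s_%d", st, i - 1L), "DENSITY",
          sprintf("r=%g", density$radii[i]), st)
    }
  }
  for (i in seq_along(density$k_values)) {
    for (st in stat_suffixes()) {
      add(sprintf("DDN-%s_%d", st, i - 1L), "DENSITY",
          sprintf("k=%d", density$k_values[i]), st)
    }
  }
  add("TIL-FREQ", "FREQUENCY", "per-mm2", "count")

  reg <- do.call(rbind, rows)
  stopifnot(nrow(reg) == 371L, !anyDuplicated(reg$name))
  reg
}

#' Export the feature registry as JSON
#'
#' @param path output file path.
#' @param ... passed to [feature_registry()].
#' @export
write_registry_json <- function(path, ...) {
  reg <- feature_registry(...)
  jsonlite::write_json(reg, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
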