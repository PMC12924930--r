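# Geometric feature families against independent oracles (see helper-oracles.R).



test_that("Delaunay features match single-triangle geometry and scale linearly", {
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  f <- delaunay_features(tri)
  expect_equal(unname(f["DE-MEAN"]), (2 + sqrt(2)) / 3)
  expect_equal(unname(f["DE-MMR"]), 1 / sqrt(2))
  expect_equal(unname(f["DTA-MEAN"]), 0.5)
  expect_equal(unname(f["DTA-STD"]), 0)

  withr::with_seed(21, pts <- cbind(runif(50) * 100, runif(50) * 100))
  f1 <- delaunay_features(pts)
  f2 <- delaunay_features(pts * 2)
  expect_equal(unname(f2["DE-MEAN"]), unname(2 * f1["DE-MEAN"]))
  expect_equal(unname(f2["DE-MMR"]), unname(f1["DE-MMR"]))
  expect_equal(unname(f2["DE-DIS"]), unname(f1["DE-DIS"]))
  expect_equal(unname(f2["DTA-MEAN"]), unname(4 * f1["DTA-MEAN"]))

  expect_true(all(is.na(delaunay_features(rbind(c(0, 0), c(1, 1))))))
  expect_true(all(is.na(delaunay_features(cbind(1:5, 2 * (1:5))))))
})

test_that("Delaunay edge set equals the empty-circumcircle oracle", {
  withr::with_seed(22, pts <- cbind(runif(60) * 100, runif(60) * 100))
  dd <- deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)$delsgs
  got <- sort(paste(pmin(dd$ind1, dd$ind2), pmax(dd$ind1, dd$ind2)))
  expect_identical(got, brute_delaunay_edges(pts))
})

test_that("Voronoi features respect symmetry, partition and Monte-Carlo areas", {
  lattice <- rbind(c(0.5, 0.5), c(1.5, 0.5), c(0.5, 1.5), c(1.5, 1.5))
  f <- voronoi_features(lattice, c(0, 2, 0, 2))
  expect_equal(unname(f["VA-MEAN"]), 1)
  expect_equal(unname(f["VA-MMR"]), 1)
  expect_equal(unname(f["VA-DIS"]), 0)
  expect_equal(unname(f["VP-MEAN"]), 4)
  expect_equal(unname(f["VMD-MEAN"]), sqrt(2)) # unit-square cell diagonal

  withr::with_seed(23, pts <- cbind(runif(50) * 100, runif(50) * 100))
  dd <- deldir::deldir(pts[, 1], pts[, 2], rw = c(0, 100, 0, 100),
                       suppressMsge = TRUE)
  areas <- vapply(deldir::tile.list(dd), function(t) t$area, numeric(1))
  expect_equal(sum(areas), 100 * 100, tolerance = 1e-6)

  # Monte-Carlo point-in-cell oracle: nearest-site assignment of 1e6
  # uniform samples, independent of the tessellation code path
  withr::with_seed(77, samp <- cbind(runif(1e6) * 100, runif(1e6) * 100))
  nearest <- FNN::get.knnx(pts, samp, k = 1)$nn.index[, 1]
  mc_area <- tabulate(nearest, 50) / 1e6 * 100 * 100
  expect_lt(max(abs(mc_area - areas) / pmax(areas, 1)), 0.02)

  expect_true(all(is.na(voronoi_features(rbind(c(1, 1)), c(0, 2, 0, 2)))))
})

test_that("MST features match line geometry and the Kruskal oracle", {
  line <- cbind(c(0, 10, 25), 0)
  f <- mst_features(line)
  expect_equal(unname(f["MST-MEAN"]), 12.5)
  expect_equal(unname(f["MST-MMR"]), 2 / 3)

  withr::with_seed(25, pts <- cbind(runif(60) * 50, runif(60) * 50))
  m <- tilgraph:::prim_mst(as.matrix(dist(pts)))
  expect_equal(nrow(m), 59)
  expect_equal(sum(m[, 3]), kruskal_weight(pts), tolerance = 1e-10)

  expect_true(all(is.na(mst_features(rbind(c(0, 0))))))
})

test_that("every EMST edge is a Delaunay edge", {
  withr::with_seed(26, pts <- cbind(runif(100) * 100, runif(100) * 100))
  me <- tilgraph:::mst_edges(pts)
  dd <- deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)$delsgs
  del <- paste(pmin(dd$ind1, dd$ind2), pmax(dd$ind1, dd$ind2))
  expect_true(all(paste(me[, 1], me[, 2]) %in% del))
  # and total MST weight cannot exceed total Delaunay weight
  dlen <- sqrt((pts[dd$ind1, 1] - pts[dd$ind2, 1])^2 +
               (pts[dd$ind1, 2] - pts[dd$ind2, 2])^2)
  expect_lte(sum(mst_features(pts)["MST-MEAN"] * 99), sum(dlen))
})

test_that("density sweeps match hand geometry and O(n^2) brute force", {
  line <- cbind(c(0, 10, 20), 0) # 3 collinear points spaced 10 um
  f <- density_features(line)
  # radius index 2 is r = 15: counts {1, 2, 1}
  expect_equal(unname(f["DND-MEAN_2"]), 4 / 3)
  expect_equal(unname(f["DDN-MEAN_0"]), 10)
  expect_equal(unname(f["DDN-STD_0"]), 0)
  expect_equal(unname(f["DDN-DIS_0"]), 0)
  # k = 2 needs 3 points; k = 3 impossible at n = 3
  expect_false(is.na(f["DDN-MEAN_1"]))
  expect_true(all(is.na(f[sprintf("DDN-MEAN_%d", 2:13)])))

  withr::with_seed(27, pts <- cbind(runif(500) * 400, runif(500) * 400))
  cfg <- density_config()
  f <- density_features(pts, cfg)
  d <- as.matrix(dist(pts)); diag(d) <- Inf
  for (i in c(1, 13, 40)) {
    counts <- rowSums(d <= cfg$radii[i])
    expect_equal(unname(f[sprintf("DND-MEAN_%d", i - 1)]), mean(counts))
    expect_equal(unname(f[sprintf("DND-STD_%d", i - 1)]),
                 sqrt(mean((counts - mean(counts))^2)))
  }
  dsort <- t(apply(d, 1, sort))
  for (k in c(1, 7, 14)) {
    expect_equal(unname(f[sprintf("DDN-MEAN_%d", k - 1)]), mean(dsort[, k]))
  }
  # monotonicity of the sweeps
  dnd <- f[sprintf("DND-MEAN_%d", 0:39)]
  ddn <- f[sprintf("DDN-MEAN_%d", 0:13)]
  expect_true(all(diff(dnd) >= 0))
  expect_true(all(diff(ddn) >= 0))
})

test_that("TIL frequency follows its definition and proportionality", {
  # 4 tiles of 400 px at 0.25 um/px = 100 um -> 0.01 mm^2 each, 0.04 total
  withr::with_seed(28, xy <- cbind(runif(100, 0, 800), runif(100, 0, 800)))
  cm <- toy_cell_map(xy, tile_size_px = 400)
  expect_equal(til_frequency(cm), 100 / 0.04)
  cm0 <- toy_cell_map(matrix(numeric(0), ncol = 2), tile_size_px = 400)
  expect_equal(til_frequency(cm0), 0)
  # doubling the tile set at fixed count halves the frequency
  cm2 <- cell_map("t2", cm$cells,
                  rbind(cm$tiles, data.frame(tile_x_px = c(800, 1200, 800, 1200),
                                             tile_y_px = c(0, 0, 400, 400))),
                  tile_size_px = 400, pixel_spacing = 0.25)
  expect_equal(til_frequency(cm2), til_frequency(cm) / 2)
})

test_that("extract_all emits the full registry deterministically and invariantly", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 371)
  expect_equal(as.vector(table(reg$family)[c("CLUSTER", "VORONOI", "DELAUNAY",
                                             "MST", "DENSITY", "FREQUENCY")]),
               c(130, 12, 8, 4, 216, 1))
  expect_true(all(c("CCF_10", "DBS_70", "OF_100", "MCP_10", "MCS_10",
                    "STD-CP_30", "VMD-MMR", "DND-STD_39", "DDN-MMR_13",
                    "DND-MMR_0", "DND-DIS_0", "DDN-DIS_13") %in% reg$name))

  w <- new_window(400, 400)
  cm <- simulate_core(process_params("THOMAS", parent_intensity = 5e-5,
                                     offspring_mean = 40, offspring_sd = 12,
                                     seed = 30), w, tile_size_px = 400)
  v1 <- extract_all(cm)
  expect_length(v1, 371)
  expect_identical(names(v1), reg$name)
  expect_identical(v1, extract_all(cm))

  # translation by whole tiles leaves every feature unchanged
  cm_t <- cm
  cm_t$cells$x_px <- cm_t$cells$x_px + 1200
  cm_t$cells$y_px <- cm_t$cells$y_px + 1200
  cm_t$tiles$tile_x_px <- cm_t$tiles$tile_x_px + 1200
  cm_t$tiles$tile_y_px <- cm_t$tiles$tile_y_px + 1200
  v2 <- extract_all(cm_t)
  expect_equal(v1, v2, tolerance = 1e-9)

  # empty core: all features missing except frequency 0
  cm0 <- simulate_core(process_params("CSR", intensity = 0, seed = 1), w, 400)
  v0 <- extract_all(cm0)
  expect_equal(unname(v0["TIL-FREQ"]), 0)
  expect_equal(unname(v0["CCF_10"]), 0)
  expect_true(all(is.na(v0[c("DE-MEAN", "MST-MEAN", "VA-MEAN", "DND-MEAN_0")])))
})
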