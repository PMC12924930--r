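# Independent brute-force oracles shared across test files.

# O(n^3)-ish Delaunay oracle: a triangle is Delaunay iff its
# circumcircle is empty; edges are the union of such triangles' edges.
brute_delaunay_edges <- function(pts) {
  n <- nrow(pts)
  edges <- character(0)
  combs <- utils::combn(n, 3)
  for (c in seq_len(ncol(combs))) {
    i <- combs[1, c]; j <- combs[2, c]; k <- combs[3, c]
    ax <- pts[i, 1]; ay <- pts[i, 2]
    bx <- pts[j, 1]; by <- pts[j, 2]
    cx <- pts[k, 1]; cy <- pts[k, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    dd <- (pts[, 1] - ux)^2 + (pts[, 2] - uy)^2
    if (all(dd[-c(i, j, k)] > r2 - 1e-9)) {
      edges <- c(edges, paste(sort(c(i, j))[1], sort(c(i, j))[2]),
                 paste(sort(c(i, k))[1], sort(c(i, k))[2]),
                 paste(sort(c(j, k))[1], sort(c(j, k))[2]))
    }
  }
  sort(unique(edges))
}

# Kruskal MST total weight (union-find), independent of Prim.
kruskal_weight <- function(pts) {
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[upper.tri(d)])
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  total <- 0; used <- 0
  for (e in ord) {
    a <- find(idx[e, 1]); b <- find(idx[e, 2])
    if (a != b) {
      parent[a] <- b
      total <- total + d[idx[e, 1], idx[e, 2]]
      used <- used + 1
      if (used == n - 1) break
    }
  }
  total
}

# Brute-force pairwise AUC, independent of the rank computation.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
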