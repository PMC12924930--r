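## Hierarchical density-based clustering with noise (HDBSCAN),
## implemented from the mutual-reachability formulation:
##   1. core distance = distance to the min_samples-th nearest neighbor
##      (the point itself counts as the first),
##   2. mutual reachability d_mr(a,b) = max(core_a, core_b, d(a,b)),
##   3. minimum spanning tree of the mutual-reachability graph,
##   4. single-linkage hierarchy, condensed at min_cluster_size,
##   5. excess-of-mass cluster selection by stability.
## Cluster "persistence" is the stability value of a selected cluster in
## the condensed tree (sum over member points of lambda_point -
## lambda_birth, lambda = 1/distance).

# Prim's algorithm on a dense symmetric weight matrix; returns a
# (n-1) x 3 matrix (from, to, weight).
prim_mst <- function(w) {
  n <- nrow(w)
  if (n < 2) return(matrix(numeric(0), ncol = 3))
  in_tree <- logical(n)
  best <- rep(Inf, n)
  parent <- integer(n)
  in_tree[1] <- TRUE
  best <- w[1, ]
  parent[] <- 1L
  best[1] <- Inf
  edges <- matrix(0, n - 1, 3)
  for (t in seq_len(n - 1)) {
    j <- which.min(best)
    edges[t, ] <- c(parent[j], j, best[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & w[j, ] < best
    best[upd] <- w[j, upd]
    parent[upd] <- j
    best[j] <- Inf
  }
  edges
}

# Single-linkage dendrogram from MST edges. Returns merge children
# (2 x (n-1)), node heights, where node ids 1..n are leaves and
# n+t is the node created by merge t (edges must be sorted ascending).
single_linkage <- function(edges, n) {
  ord <- order(edges[, 3])
  edges <- edges[ord, , drop = FALSE]
  parent <- seq_len(2L * n - 1L)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  comp_node <- seq_len(n) # current dendrogram node of each component root
  children <- matrix(0L, 2, n - 1)
  heights <- numeric(n - 1)
  sizes <- c(rep(1L, n), integer(n - 1))
  for (t in seq_len(n - 1)) {
    a <- find(edges[t, 1]); b <- find(edges[t, 2])
    node <- n + t
    children[, t] <- c(comp_node[a], comp_node[b])
    heights[t] <- edges[t, 3]
    sizes[node] <- sizes[comp_node[a]] + sizes[comp_node[b]]
    parent[a] <- b
    comp_node[b] <- node
  }
  list(children = children, heights = heights, sizes = sizes)
}

# Leaves under each dendrogram node (iterative).
node_leaves <- function(node, children, n) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (nd <= n) out <- c(out, nd)
    else stack <- c(stack, children[, nd - n])
  }
  out
}

#' HDBSCAN clustering of a planar point set
#'
#' @param xy n x 2 coordinate matrix.
#' @param min_cluster_size smallest cluster the hierarchy will report.
#' @param min_samples smoothing parameter for the core distance;
#'   defaults to `min_cluster_size`.
#' @return list with `labels` (integer, 0 = noise), `n_clusters`,
#'   `sizes`, `persistence` (stability per cluster), and the distance
#'   matrix used (for downstream cluster geometry).
#' @export
hdbscan_til <- function(xy, min_cluster_size, min_samples = min_cluster_size) {
  n <- nrow(xy)
  if (n < max(min_cluster_size, 2L) || min_samples > n) {
    return(list(labels = rep(0L, n), n_clusters = 0L,
                sizes = integer(0), persistence = numeric(0),
                dist = NULL))
  }
  d <- dist_matrix(xy)
  core <- apply(d, 1, function(r) sort.int(r, partial = min_samples)[min_samples])
  mrd <- pmax(d, outer(core, core, pmax))
  mst <- prim_mst(mrd)
  sl <- single_linkage(mst, n)

  ## condense the hierarchy -----------------------------------------------
  mcs <- min_cluster_size
  root <- 2L * n - 1L
  # condensed clusters: parallel vectors
  cl_parent <- integer(0); cl_birth <- numeric(0)
  cl_stab <- numeric(0); cl_points <- list()
  new_cluster <- function(parent, birth) {
    cl_parent[length(cl_parent) + 1L] <<- parent
    cl_birth[length(cl_birth) + 1L] <<- birth
    cl_stab[length(cl_stab) + 1L] <<- 0
    cl_points[[length(cl_points) + 1L]] <<- integer(0)
    length(cl_parent)
  }
  # the root cluster is born where the hierarchy first exists: the
  # lambda of the largest mutual-reachability MST edge
  root_cl <- new_cluster(0L, 1 / max(sl$heights, .Machine$double.eps))
  stack_node <- root; stack_cl <- root_cl
  while (length(stack_node)) {
    nd <- stack_node[length(stack_node)]
    cl <- stack_cl[length(stack_cl)]
    stack_node <- stack_node[-length(stack_node)]
    stack_cl <- stack_cl[-length(stack_cl)]
    if (nd <= n) { # isolated leaf still inside a cluster (mcs == 1 only)
      cl_points[[cl]] <- c(cl_points[[cl]], nd)
      next
    }
    t <- nd - n
    lam <- 1 / max(sl$heights[t], .Machine$double.eps)
    a <- sl$children[1, t]; b <- sl$children[2, t]
    sa <- sl$sizes[a]; sb <- sl$sizes[b]
    if (sa >= mcs && sb >= mcs) {
      # true split: current cluster dies here, two children are born
      cl_stab[cl] <- cl_stab[cl] + (sa + sb) * (lam - cl_birth[cl])
      ca <- new_cluster(cl, lam); cb <- new_cluster(cl, lam)
      stack_node <- c(stack_node, a, b)
      stack_cl <- c(stack_cl, ca, cb)
    } else if (sa >= mcs || sb >= mcs) {
      big <- if (sa >= mcs) a else b
      small <- if (sa >= mcs) b else a
      pts <- node_leaves(small, sl$children, n)
      cl_stab[cl] <- cl_stab[cl] + length(pts) * (lam - cl_birth[cl])
      cl_points[[cl]] <- c(cl_points[[cl]], pts)
      stack_node <- c(stack_node, big)
      stack_cl <- c(stack_cl, cl)
    } else {
      pts <- node_leaves(nd, sl$children, n)
      cl_stab[cl] <- cl_stab[cl] + length(pts) * (lam - cl_birth[cl])
      cl_points[[cl]] <- c(cl_points[[cl]], pts)
    }
  }

  ## excess-of-mass selection ----------------------------------------------
  n_cl <- length(cl_parent)
  selected <- logical(n_cl)
  subtree_stab <- cl_stab
  kids <- lapply(seq_len(n_cl), function(i) which(cl_parent == i))
  # children were appended after parents, so reverse order is bottom-up
  # Bottom-up excess-of-mass selection over non-root clusters, the
  # field-standard rule: the root (the whole data set) is not a
  # candidate cluster, so diffuse uniform patterns resolve to noise
  # plus local clusters rather than one all-covering cluster.
  for (i in rev(seq_len(n_cl))) {
    ch <- kids[[i]]
    if (i == root_cl) next
    if (length(ch) == 0) {
      selected[i] <- TRUE
      subtree_stab[i] <- cl_stab[i]
    } else if (cl_stab[i] > sum(subtree_stab[ch])) {
      selected[i] <- TRUE
      subtree_stab[i] <- cl_stab[i]
      # deselect all descendants
      desc <- ch
      while (length(desc)) {
        selected[desc] <- FALSE
        desc <- unlist(kids[desc])
      }
    } else {
      subtree_stab[i] <- sum(subtree_stab[ch])
    }
  }
  if (!any(selected) && n_cl == 1L) {
    # the hierarchy never produced a viable split: report the root as a
    # single cluster rather than labeling every point noise
    selected[root_cl] <- TRUE
  }

  labels <- rep(0L, n)
  sel_idx <- which(selected)
  persistence <- numeric(length(sel_idx))
  for (k in seq_along(sel_idx)) {
    # members: points recorded in the selected cluster's condensed subtree
    members <- integer(0)
    sub <- sel_idx[k]
    while (length(sub)) {
      members <- c(members, unlist(cl_points[sub]))
      sub <- unlist(kids[sub])
    }
    labels[members] <- k
    persistence[k] <- cl_stab[sel_idx[k]]
  }
  list(labels = labels, n_clusters = length(sel_idx),
       sizes = if (length(sel_idx)) tabulate(labels[labels > 0L], length(sel_idx)) else integer(0),
       persistence = persistence, dist = d)
}

# Davies-Bouldin index on clustered points (labels > 0); NA if < 2 clusters.
davies_bouldin <- function(xy, labels) {
  ks <- sort(unique(labels[labels > 0L]))
  if (length(ks) < 2) return(NA_real_)
  cents <- t(vapply(ks, function(k) colMeans(xy[labels == k, , drop = FALSE]),
                    numeric(2)))
  scat <- vapply(seq_along(ks), function(i) {
    pts <- xy[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, cents[i, ])^2)))
  }, numeric(1))
  m <- as.matrix(stats::dist(cents))
  db <- vapply(seq_along(ks), function(i) {
    r <- (scat[i] + scat[-i]) / m[i, -i]
    max(r)
  }, numeric(1))
  mean(db)
}

#' Clustering features for one min_cluster_size sweep value
#'
#' Runs [hdbscan_til()] and reduces the result to 13 statistics:
#' cluster count (NC), clustered cell fraction (CCF), outlier fraction
#' (OF = 1 - CCF), mean/median/std/min-max-ratio/disorder of cluster
#' sizes, mean/median/std of cluster persistences, Davies-Bouldin score
#' (DBS) and mean intra-cluster pairwise distance (MICD). When no
#' cluster is found, CCF = 0, OF = 1 and all cluster-conditional
#' statistics are `NA`.
#'
#' @param xy n x 2 coordinate matrix (micrometers).
#' @param min_cluster_size HDBSCAN minimum cluster size.
#' @return named numeric vector of length 13.
#' @export
clustering_stats <- function(xy, min_cluster_size) {
  out <- stats::setNames(rep(NA_real_, 13L), cluster_stat_names())
  n <- nrow(xy)
  res <- hdbscan_til(xy, min_cluster_size)
  if (res$n_clusters == 0L) {
    out["NC"] <- 0; out["CCF"] <- 0; out["OF"] <- 1
    return(out)
  }
  lab <- res$labels
  out["NC"] <- res$n_clusters
  out["CCF"] <- mean(lab > 0L)
  out["OF"] <- 1 - out["CCF"]
  sz <- as.numeric(res$sizes)
  ss <- summary_stats(sz)
  out["MEAN-CS"] <- ss$mean; out["MCS"] <- stats::median(sz)
  out["STD-CS"] <- ss$std; out["MMR-CS"] <- ss$mmr; out["DIS-CS"] <- ss$disorder
  ps <- summary_stats(res$persistence)
  out["MEAN-CP"] <- ps$mean; out["MCP"] <- stats::median(res$persistence)
  out["STD-CP"] <- ps$std
  out["DBS"] <- davies_bouldin(xy, lab)
  d <- res$dist
  intra <- unlist(lapply(seq_len(res$n_clusters), function(k) {
    idx <- which(lab == k)
    if (length(idx) < 2) return(numeric(0))
    d[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]
  }))
  out["MICD"] <- if (length(intra)) mean(intra) else NA_real_
  out
}

#' Full HDBSCAN feature family (130 features)
#'
#' @param points n x 2 coordinate matrix (micrometers).
#' @param config a [cluster_config()].
#' @return named numeric vector of length 130 in registry order.
#' @export
clustering_features <- function(points, config = cluster_config()) {
  out <- unlist(lapply(config$min_cluster_sizes, function(s) {
    st <- clustering_stats(points, s)
    stats::setNames(st, sprintf("%s_%d", names(st), s))
  }))
  out
}
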