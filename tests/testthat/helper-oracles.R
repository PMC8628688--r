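# Independent brute-force oracles used to validate the geometry and
# neighbour computations. These deliberately avoid the code paths they
# check (no deldir, no FNN, no igraph).

# Prim's algorithm on the complete Euclidean graph; returns sorted edge
# lengths of the MST.
prim_mst_branches <- function(pts) {
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  branches <- numeric(0)
  while (sum(in_tree) < n) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    branches <- c(branches, unname(best[j]))
    in_tree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  sort(branches)
}

# O(n^2) k-th nearest neighbour distances (self excluded).
brute_knn_dist <- function(pts, k) {
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  apply(d, 1, function(row) sort(row)[k])
}

# O(n^2) counts of neighbours within radius (self excluded).
brute_radius_counts <- function(pts, radius) {
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  rowSums(d <= radius)
}

# Rasterized nearest-site Voronoi cell areas: assign a fine pixel grid to
# its nearest site and count. Returns per-site areas over the given window.
raster_voronoi_areas <- function(pts, xlim, ylim, res = 400) {
  gx <- seq(xlim[1], xlim[2], length.out = res)
  gy <- seq(ylim[1], ylim[2], length.out = res)
  px_area <- diff(gx[1:2]) * diff(gy[1:2])
  grid <- cbind(rep(gx, times = res), rep(gy, each = res))
  d2 <- outer(rowSums(grid^2), rep(1, nrow(pts))) -
    2 * grid %*% t(pts) +
    outer(rep(1, nrow(grid)), rowSums(pts^2))
  nearest <- max.col(-d2)
  tabulate(nearest, nbins = nrow(pts)) * px_area
}

# Exhaustive one-to-one instance matching maximizing the number of pairs
# with IoU >= threshold (checks the greedy matcher on small scenes).
exhaustive_match_tp <- function(iou, threshold) {
  ng <- nrow(iou); np <- ncol(iou)
  if (ng == 0 || np == 0) return(0L)
  best <- 0L
  assign_rec <- function(g, used_p, tp) {
    if (g > ng) {
      best <<- max(best, tp)
      return(invisible())
    }
    assign_rec(g + 1L, used_p, tp) # leave g unmatched
    for (p in seq_len(np)) {
      if (!used_p[p] && iou[g, p] >= threshold) {
        used_p[p] <- TRUE
        assign_rec(g + 1L, used_p, tp + 1L)
        used_p[p] <- FALSE
      }
    }
  }
  assign_rec(1L, rep(FALSE, np), 0L)
  best
}

# Closed-form IoU of two radius-r disks with centers distance d apart.
disk_pair_iou <- function(r, d) {
  if (d >= 2 * r) return(0)
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  lens / (2 * pi * r^2 - lens)
}

# Small deterministic point cloud.
random_points <- function(n, extent = c(100, 100), seed = 42) {
  set.seed(seed)
  tibble::tibble(x = runif(n, 0, extent[1]), y = runif(n, 0, extent[2]))
}
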