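#' Summary statistics for a per-object feature distribution
#'
#' Collapses the per-object values of one spatial measurement (e.g. the areas
#' of all Voronoi cells in a section) into the four-statistic summary used
#' throughout the nuclear-architecture feature set: mean, population standard
#' deviation, min/max ratio and the disorder statistic
#' \eqn{\sigma / (\mu + \sigma)}.
#'
#' The disorder statistic is an algebraic rewriting of
#' \eqn{1 - 1/(1 + \sigma/\mu)} that stays defined when \eqn{\mu = 0}; it is
#' set to 0 whenever \eqn{\sigma = 0}. The min/max ratio is defined as 1 when
#' all values are equal (including the all-zero case).
#'
#' @param values Numeric vector of non-negative per-object values.
#' @return A one-row tibble with columns `mean`, `stddev`, `min_max_ratio`
#'   and `disorder`.
#' @examples
#' popstats(c(2, 4)) # disorder 0.25, min_max_ratio 0.5
#' @export
popstats <- function(values) {
  if (length(values) == 0L) {
    stop_nucleograde("`values` must be non-empty.", "nucleograde_parameter_error")
  }
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop_nucleograde("`values` must be finite numeric.", "nucleograde_parameter_error")
  }
  if (any(values < 0)) {
    stop_nucleograde("`values` must be non-negative.", "nucleograde_parameter_error")
  }
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2)) # population convention
  rng <- range(values)
  mmr <- if (rng[1] == rng[2]) 1 else rng[1] / rng[2]
  dis <- if (sigma == 0) 0 else sigma / (mu + sigma)
  tibble::tibble(mean = mu, stddev = sigma, min_max_ratio = mmr, disorder = dis)
}

# Internal: popstats as a named vector with a feature-name prefix.
popstats_named <- function(values, prefix) {
  s <- popstats(values)
  setNames(
    c(s$mean, s$stddev, s$min_max_ratio, s$disorder),
    paste(prefix, c("mean", "stddev", "min_max_ratio", "disorder"), sep = ".")
  )
}

#' Density-feature configuration
#'
#' Controls the neighbourhood scales of the 27 nuclear-density features:
#' four radii for neighbours-within-distance counts, two neighbour counts for
#' k-th-nearest-neighbour distances, and the neighbour count used for the
#' local density estimate \eqn{\rho_i = k / (\pi r_k(i)^2)}.
#'
#' Defaults (radii 25/50/75/100 px, k = 3 and 5, density k = 5) are plausible
#' nuclear neighbourhood scales at 40x magnification; together with the four
#' summary statistics and the min/median/max of \eqn{\rho} they yield the
#' canonical 16 + 8 + 3 = 27 density features.
#'
#' @param radii Strictly increasing positive radii (pixels), length 4 under
#'   the default feature registry.
#' @param neighbor_counts Strictly increasing positive integers, length 2
#'   under the default registry.
#' @param k_density Neighbour count for the density estimate.
#' @return An object of class `density_config`.
#' @export
density_config <- function(radii = c(25, 50, 75, 100),
                           neighbor_counts = c(3L, 5L),
                           k_density = 5L) {
  if (any(radii <= 0) || any(diff(radii) <= 0)) {
    stop_nucleograde("`radii` must be positive and strictly increasing.",
                     "nucleograde_parameter_error")
  }
  neighbor_counts <- as.integer(neighbor_counts)
  if (any(neighbor_counts < 1L) || any(diff(neighbor_counts) <= 0L)) {
    stop_nucleograde("`neighbor_counts` must be increasing positive integers.",
                     "nucleograde_parameter_error")
  }
  structure(
    list(radii = radii, neighbor_counts = neighbor_counts,
         k_density = as.integer(k_density)),
    class = "density_config"
  )
}

# Internal: coerce a points argument (matrix / data frame with x,y) to a
# deduplicated two-column matrix. Duplicate coordinates are merged so the
# tessellations stay well-posed.
as_points <- function(points, dedup = TRUE) {
  if (is.data.frame(points)) {
    pts <- cbind(points$x, points$y)
  } else {
    pts <- as.matrix(points)
  }
  if (is.null(pts) || ncol(pts) != 2L) {
    stop_nucleograde("`points` must have x and y columns.",
                     "nucleograde_parameter_error")
  }
  storage.mode(pts) <- "double"
  if (dedup && nrow(pts) > 1L) {
    dup <- duplicated(pts)
    if (any(dup)) {
      inform(sprintf("Merged %d duplicate centroid(s).", sum(dup)))
      pts <- pts[!dup, , drop = FALSE]
    }
  }
  pts
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_perimeter <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(sqrt((x - x[j])^2 + (y - y[j])^2))
}

max_pairwise_distance <- function(x, y) {
  max(stats::dist(cbind(x, y)))
}

# Internal: deldir tessellation with a window wide enough that any cell
# clipped by it is genuinely unbounded.
run_deldir <- function(pts) {
  rx <- range(pts[, 1]); ry <- range(pts[, 2])
  diag_len <- max(sqrt(diff(rx)^2 + diff(ry)^2), 1)
  pad <- 10 * diag_len
  suppressMessages(deldir::deldir(
    pts[, 1], pts[, 2],
    rw = c(rx[1] - pad, rx[2] + pad, ry[1] - pad, ry[2] + pad),
    round = FALSE
  ))
}

#' Voronoi-diagram features of a nuclear point pattern
#'
#' Tessellates the centroids and summarises the bounded Voronoi cells: per-cell
#' polygon area, perimeter and maximum vertex-to-vertex distance, each
#' collapsed with [popstats()]. Unbounded cells (cells of convex-hull points)
#' are excluded rather than clipped to an arbitrary box.
#'
#' @param points Matrix or data frame of centroid coordinates (columns x, y).
#' @return Named numeric vector of 12 features
#'   (`voronoi.{area,perimeter,max_dist}.{mean,stddev,min_max_ratio,disorder}`).
#' @export
voronoi_features <- function(points) {
  pts <- as_points(points)
  if (nrow(pts) < 4L) {
    stop_nucleograde("Voronoi features need at least 4 points.",
                     "nucleograde_degenerate_geometry")
  }
  dd <- tryCatch(run_deldir(pts), error = function(e) NULL)
  tl <- if (is.null(dd)) NULL else deldir::tile.list(dd)
  if (is.null(tl)) {
    stop_nucleograde("Degenerate geometry: Voronoi tessellation failed.",
                     "nucleograde_degenerate_geometry")
  }
  bounded <- Filter(function(tile) !any(tile$bp), tl)
  if (length(bounded) == 0L) {
    stop_nucleograde("Degenerate geometry: all Voronoi cells are unbounded.",
                     "nucleograde_degenerate_geometry")
  }
  areas <- vapply(bounded, function(t) polygon_area(t$x, t$y), numeric(1))
  perims <- vapply(bounded, function(t) polygon_perimeter(t$x, t$y), numeric(1))
  maxd <- vapply(bounded, function(t) max_pairwise_distance(t$x, t$y), numeric(1))
  c(
    popstats_named(areas, "voronoi.area"),
    popstats_named(perims, "voronoi.perimeter"),
    popstats_named(maxd, "voronoi.max_dist")
  )
}

#' Delaunay-triangulation features of a nuclear point pattern
#'
#' Triangulates the centroids and summarises the unique edge ("side") lengths
#' and the per-triangle areas with [popstats()]. Each shared edge is counted
#' once.
#'
#' @inheritParams voronoi_features
#' @return Named numeric vector of 8 features
#'   (`delaunay.{sides,area}.{mean,stddev,min_max_ratio,disorder}`).
#' @export
delaunay_features <- function(points) {
  pts <- as_points(points)
  if (nrow(pts) < 3L) {
    stop_nucleograde("Delaunay features need at least 3 points.",
                     "nucleograde_degenerate_geometry")
  }
  dd <- tryCatch(run_deldir(pts), error = function(e) NULL)
  tri <- if (is.null(dd)) NULL else deldir::triang.list(dd)
  if (is.null(tri) || length(tri) == 0L) {
    stop_nucleograde("Degenerate geometry: Delaunay triangulation failed (collinear input?).",
                     "nucleograde_degenerate_geometry")
  }
  seg <- dd$delsgs
  sides <- sqrt((pts[seg$ind1, 1] - pts[seg$ind2, 1])^2 +
                  (pts[seg$ind1, 2] - pts[seg$ind2, 2])^2)
  areas <- vapply(tri, function(t) polygon_area(t$x, t$y), numeric(1))
  c(
    popstats_named(sides, "delaunay.sides"),
    popstats_named(areas, "delaunay.area")
  )
}

# Internal: Euclidean MST branch lengths. Built on the Delaunay edge set
# (the Euclidean MST is a subgraph of the Delaunay triangulation); falls back
# to the complete graph for tiny or collinear inputs.
mst_branch_lengths <- function(pts) {
  n <- nrow(pts)
  edges <- NULL
  if (n >= 3L) {
    dd <- tryCatch(run_deldir(pts), error = function(e) NULL)
    if (!is.null(dd)) {
      seg <- dd$delsgs
      w <- sqrt((pts[seg$ind1, 1] - pts[seg$ind2, 1])^2 +
                  (pts[seg$ind1, 2] - pts[seg$ind2, 2])^2)
      edges <- cbind(seg$ind1, seg$ind2, w)
    }
  }
  if (is.null(edges)) {
    dmat <- as.matrix(stats::dist(pts))
    idx <- which(upper.tri(dmat), arr.ind = TRUE)
    edges <- cbind(idx[, 1], idx[, 2], dmat[idx])
  }
  g <- igraph::graph_from_edgelist(cbind(edges[, 1], edges[, 2]), directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = edges[, 3])
  if (igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  igraph::E(mst)$weight
}

#' Minimum-spanning-tree features of a nuclear point pattern
#'
#' Summarises the branch (edge) lengths of the Euclidean minimum spanning
#' tree over the centroids with [popstats()].
#'
#' @inheritParams voronoi_features
#' @return Named numeric vector of 4 features
#'   (`mst.branches.{mean,stddev,min_max_ratio,disorder}`).
#' @export
mst_features <- function(points) {
  pts <- as_points(points)
  if (nrow(pts) < 2L) {
    stop_nucleograde("MST features need at least 2 points.",
                     "nucleograde_degenerate_geometry")
  }
  popstats_named(mst_branch_lengths(pts), "mst.branches")
}

# Internal: full sorted neighbour-distance matrix (self excluded) via the
# kd-tree in FNN; row i holds distances to the 1st..kmax-th nearest neighbour.
knn_distance_matrix <- function(pts, kmax) {
  FNN::get.knn(pts, k = kmax)$nn.dist
}

#' Nuclear-density features of a point pattern
#'
#' Computes the 27 density features: for each radius \eqn{d} the per-nucleus
#' count of neighbours within \eqn{d} (ball-tree-style fixed-radius query),
#' for each neighbour count \eqn{k} the per-nucleus distance to the k-th
#' nearest neighbour (kd-tree query), each summarised with [popstats()], and
#' the min/median/max of the local density estimate
#' \eqn{\rho_i = k_\rho / (\pi\, r_{k_\rho}(i)^2)}. A nucleus is never its own
#' neighbour.
#'
#' @inheritParams voronoi_features
#' @param config A [density_config()].
#' @return Named numeric vector of 27 features.
#' @export
density_features <- function(points, config = density_config()) {
  pts <- as_points(points)
  n <- nrow(pts)
  kmax <- max(config$neighbor_counts, config$k_density)
  if (n <= kmax) {
    stop_nucleograde(
      sprintf("Density features need n > max(neighbor_counts, k_density) = %d; got n = %d.",
              kmax, n),
      "nucleograde_parameter_error"
    )
  }
  nd <- knn_distance_matrix(pts, kmax = n - 1L)
  out <- numeric(0)
  for (i in seq_along(config$radii)) {
    counts <- rowSums(nd <= config$radii[i])
    out <- c(out, popstats_named(counts, sprintf("density.neighbors_in_distance.%d", i)))
  }
  for (i in seq_along(config$neighbor_counts)) {
    rk <- nd[, config$neighbor_counts[i]]
    out <- c(out, popstats_named(rk, sprintf("density.distance_for_neighbors.%d", i)))
  }
  rho <- config$k_density / (pi * nd[, config$k_density]^2)
  out <- c(out,
           setNames(c(min(rho), median(rho), max(rho)),
                    c("density.rho.min", "density.rho.median", "density.rho.max")))
  out
}

#' Names of the default 52-feature registry
#'
#' @param config A [density_config()] (affects only the density-block names).
#' @return Character vector of 52 feature names in extraction order:
#'   12 Voronoi + 8 Delaunay + 4 MST graph features, 27 density features and
#'   the nuclear count.
#' @export
spatial_feature_names <- function(config = density_config()) {
  stats4 <- c("mean", "stddev", "min_max_ratio", "disorder")
  graph <- c(
    paste("voronoi.area", stats4, sep = "."),
    paste("voronoi.perimeter", stats4, sep = "."),
    paste("voronoi.max_dist", stats4, sep = "."),
    paste("delaunay.sides", stats4, sep = "."),
    paste("delaunay.area", stats4, sep = "."),
    paste("mst.branches", stats4, sep = ".")
  )
  dens <- c(
    unlist(lapply(seq_along(config$radii), function(i)
      paste(sprintf("density.neighbors_in_distance.%d", i), stats4, sep = "."))),
    unlist(lapply(seq_along(config$neighbor_counts), function(i)
      paste(sprintf("density.distance_for_neighbors.%d", i), stats4, sep = "."))),
    c("density.rho.min", "density.rho.median", "density.rho.max")
  )
  c(graph, dens, "nuclei_count")
}

#' Extract the full spatial feature vector of one section
#'
#' Concatenates the Voronoi (12), Delaunay (8), MST (4), density (27) and
#' nuclear-count (1) blocks into the 52-feature vector describing the nuclear
#' architecture of one core-needle-biopsy section.
#'
#' @inheritParams density_features
#' @param min_nuclei Sections with fewer retained centroids are rejected
#'   (condition class `nucleograde_section_excluded`); 10 keeps all geometry
#'   well-posed.
#' @return Named numeric vector of 52 finite features.
#' @export
extract_spatial_features <- function(points, config = density_config(),
                                     min_nuclei = 10L) {
  pts <- as_points(points)
  if (nrow(pts) < min_nuclei) {
    stop_nucleograde(
      sprintf("Section has %d nuclei after dedup, below min_nuclei = %d; excluded.",
              nrow(pts), min_nuclei),
      "nucleograde_section_excluded"
    )
  }
  out <- c(
    voronoi_features(pts),
    delaunay_features(pts),
    mst_features(pts),
    density_features(pts, config),
    nuclei_count = nrow(pts)
  )
  out[spatial_feature_names(config)]
}

#' Extract spatial features for every section of a centroid table
#'
#' Tidy wrapper over [extract_spatial_features()]: takes the long centroid
#' table written by the cohort generator (or produced by any nucleus
#' segmenter) and returns one feature row per section. Sections below
#' `min_nuclei` are excluded from the result and reported in the
#' `excluded` attribute (and via a message), never silently dropped.
#'
#' @param centroids Data frame with columns `patient_id`, `section_id`, `x`,
#'   `y`.
#' @inheritParams extract_spatial_features
#' @return A tibble with `patient_id`, `section_id` and the 52 feature
#'   columns; attribute `excluded` lists skipped sections and their nucleus
#'   counts.
#' @export
extract_features <- function(centroids, config = density_config(),
                             min_nuclei = 10L) {
  stopifnot(all(c("patient_id", "section_id", "x", "y") %in% names(centroids)))
  split_idx <- split(seq_len(nrow(centroids)), centroids$section_id)
  rows <- list()
  excluded <- list()
  for (sid in names(split_idx)) {
    sub <- centroids[split_idx[[sid]], ]
    fv <- tryCatch(
      extract_spatial_features(sub, config = config, min_nuclei = min_nuclei),
      nucleograde_section_excluded = function(e) e
    )
    if (inherits(fv, "condition")) {
      excluded[[sid]] <- tibble::tibble(
        patient_id = sub$patient_id[1], section_id = sid, n_nuclei = nrow(sub)
      )
      next
    }
    rows[[sid]] <- dplyr::bind_cols(
      tibble::tibble(patient_id = sub$patient_id[1], section_id = sid),
      tibble::as_tibble(as.list(fv))
    )
  }
  excluded <- dplyr::bind_rows(excluded)
  if (nrow(excluded) > 0) {
    inform(sprintf("Excluded %d section(s) below the %d-nucleus minimum.",
                   nrow(excluded), min_nuclei))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "excluded") <- excluded
  out
}

#' Univariate group comparison of spatial features
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of every feature between
#' the two grade groups, with group medians for box-plot style reporting.
#' Constant features are reported with p = 1 and a tie flag rather than an
#' error.
#'
#' @param features Data frame of feature columns (id columns are ignored if
#'   named `patient_id` / `section_id`).
#' @param labels Binary vector (0 = G1,2, 1 = G3) aligned with the rows.
#' @return A tibble with `feature`, `statistic` (rank-sum U), `p_value`,
#'   `median_g12`, `median_g3`, `tied`.
#' @export
univariate_compare <- function(features, labels) {
  feat <- dplyr::select(tibble::as_tibble(features),
                        -dplyr::any_of(c("patient_id", "section_id")))
  labels <- as.integer(labels)
  if (length(labels) != nrow(feat)) {
    stop_nucleograde("`labels` must align with feature rows.",
                     "nucleograde_parameter_error")
  }
  if (min(table(labels)) < 2L) {
    stop_nucleograde("Need at least 2 sections per group.",
                     "nucleograde_parameter_error")
  }
  purrr::map_dfr(names(feat), function(fn) {
    v <- feat[[fn]]
    g3 <- v[labels == 1L]; g12 <- v[labels == 0L]
    if (length(unique(v)) == 1L) {
      return(tibble::tibble(feature = fn, statistic = NA_real_, p_value = 1,
                            median_g12 = median(g12), median_g3 = median(g3),
                            tied = TRUE))
    }
    wt <- suppressWarnings(wilcox.test(g3, g12, alternative = "two.sided"))
    tibble::tibble(feature = fn, statistic = unname(wt$statistic),
                   p_value = wt$p.value,
                   median_g12 = median(g12), median_g3 = median(g3),
                   tied = FALSE)
  })
}
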