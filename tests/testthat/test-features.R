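test_that("popstats matches hand computation and handles degenerate input", {
  s <- popstats(c(2, 4))
  expect_equal(s$mean, 3)
  expect_equal(s$stddev, 1)
  expect_equal(s$min_max_ratio, 0.5)
  expect_equal(s$disorder, 0.25)

  s0 <- popstats(c(5, 5, 5))
  expect_equal(s0$stddev, 0)
  expect_equal(s0$disorder, 0)
  expect_equal(s0$min_max_ratio, 1)

  expect_equal(popstats(c(0, 0))$min_max_ratio, 1)
  expect_error(popstats(numeric(0)), class = "nucleograde_parameter_error")
  expect_error(popstats(c(1, -1)), class = "nucleograde_parameter_error")
})

test_that("popstats disorder equals the direct formula on random draws", {
  set.seed(11)
  v <- runif(1000)
  s <- popstats(v)
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  expect_equal(s$disorder, sigma / (mu + sigma))
  expect_gt(s$disorder, 0)
  expect_lt(s$disorder, 1)
})

test_that("Voronoi features of a unit lattice are unit squares", {
  g <- expand.grid(x = as.numeric(0:4), y = as.numeric(0:4))
  v <- voronoi_features(g)
  # 9 interior bounded cells, each a unit square
  expect_equal(unname(v["voronoi.area.mean"]), 1)
  expect_equal(unname(v["voronoi.area.stddev"]), 0)
  expect_equal(unname(v["voronoi.perimeter.mean"]), 4)
  expect_equal(unname(v["voronoi.max_dist.mean"]), sqrt(2))
})

test_that("Voronoi statistics scale correctly under similarity transforms", {
  pts <- random_points(40, seed = 5)
  v1 <- voronoi_features(pts)
  c_fac <- 3.7
  v2 <- voronoi_features(dplyr::mutate(pts, x = x * c_fac, y = y * c_fac))
  expect_equal(unname(v2["voronoi.area.mean"]),
               unname(v1["voronoi.area.mean"]) * c_fac^2, tolerance = 1e-9)
  expect_equal(unname(v2["voronoi.perimeter.mean"]),
               unname(v1["voronoi.perimeter.mean"]) * c_fac, tolerance = 1e-9)
  expect_equal(unname(v2["voronoi.max_dist.stddev"]),
               unname(v1["voronoi.max_dist.stddev"]) * c_fac, tolerance = 1e-9)
  expect_equal(unname(v2["voronoi.area.disorder"]),
               unname(v1["voronoi.area.disorder"]), tolerance = 1e-9)
  expect_equal(unname(v2["voronoi.area.min_max_ratio"]),
               unname(v1["voronoi.area.min_max_ratio"]), tolerance = 1e-9)
})

test_that("Voronoi cell areas agree with a rasterized nearest-site oracle", {
  pts <- random_points(50, extent = c(100, 100), seed = 9)
  m <- as.matrix(pts)
  dd <- deldir::deldir(m[, 1], m[, 2],
                       rw = c(-1000, 1100, -1000, 1100))
  tl <- deldir::tile.list(dd)
  # bounded cells whose polygon lies inside the raster window
  inside <- which(vapply(tl, function(t) {
    !any(t$bp) && all(t$x > -50 & t$x < 150 & t$y > -50 & t$y < 150)
  }, logical(1)))
  expect_gt(length(inside), 20)
  areas <- vapply(tl[inside], function(t) {
    n <- length(t$x); j <- c(n, seq_len(n - 1))
    abs(sum(t$x[j] * t$y - t$x * t$y[j])) / 2
  }, numeric(1))
  oracle <- raster_voronoi_areas(m, xlim = c(-50, 150), ylim = c(-50, 150),
                                 res = 600)
  expect_equal(unname(areas), oracle[inside], tolerance = 0.02)
})

test_that("Voronoi features reject degenerate geometry", {
  expect_error(voronoi_features(cbind(0:5, 0:5)),
               class = "nucleograde_degenerate_geometry")
  expect_error(voronoi_features(cbind(c(0, 1), c(0, 0))),
               class = "nucleograde_degenerate_geometry")
})

test_that("Delaunay features match hand geometry", {
  tri <- cbind(c(0, 1, 0), c(0, 0, 1))
  d <- delaunay_features(tri)
  expect_equal(unname(d["delaunay.area.mean"]), 0.5)
  expect_equal(unname(d["delaunay.sides.mean"]), (1 + 1 + sqrt(2)) / 3)

  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  ds <- delaunay_features(sq)
  expect_equal(unname(ds["delaunay.area.mean"]), 0.5)
  expect_equal(unname(ds["delaunay.area.stddev"]), 0)
  expect_equal(unname(ds["delaunay.area.disorder"]), 0)

  expect_error(delaunay_features(cbind(0:4, rep(0, 5))),
               class = "nucleograde_degenerate_geometry")
})

test_that("Delaunay triangle areas tessellate the convex hull", {
  pts <- random_points(30, seed = 13)
  m <- as.matrix(pts)
  dd <- deldir::deldir(m[, 1], m[, 2], rw = c(-500, 600, -500, 600))
  tri <- deldir::triang.list(dd)
  tri_area <- sum(vapply(tri, function(t) {
    abs((t$x[2] - t$x[1]) * (t$y[3] - t$y[1]) -
          (t$x[3] - t$x[1]) * (t$y[2] - t$y[1])) / 2
  }, numeric(1)))
  hull <- chull(m)
  hx <- m[hull, 1]; hy <- m[hull, 2]
  j <- c(length(hx), seq_len(length(hx) - 1))
  hull_area <- abs(sum(hx[j] * hy - hx * hy[j])) / 2
  expect_equal(tri_area, hull_area, tolerance = 1e-9)
})

test_that("MST features match hand computation and the Prim oracle", {
  tri <- cbind(c(0, 1, 0), c(0, 0, 1))
  m <- mst_features(tri)
  expect_equal(unname(m["mst.branches.mean"]), 1)
  expect_equal(unname(m["mst.branches.min_max_ratio"]), 1)
  expect_equal(unname(m["mst.branches.disorder"]), 0)

  line <- cbind(0:6, rep(0, 7))
  ml <- mst_features(line)
  expect_equal(unname(ml["mst.branches.mean"]), 1)
  expect_equal(unname(ml["mst.branches.stddev"]), 0)

  for (seed in c(1, 2, 3)) {
    pts <- random_points(40, seed = seed)
    got <- mst_features(pts)
    oracle <- prim_mst_branches(as.matrix(pts))
    expect_equal(unname(got["mst.branches.mean"]), mean(oracle),
                 tolerance = 1e-12)
    expect_equal(unname(got["mst.branches.stddev"]),
                 sqrt(mean((oracle - mean(oracle))^2)), tolerance = 1e-12)
  }
  expect_error(mst_features(cbind(1, 1)),
               class = "nucleograde_degenerate_geometry")
})

test_that("density features match hand counts on collinear points", {
  pts <- cbind(c(0, 3, 7), c(0, 0, 0))
  cfg <- density_config(radii = c(5, 6, 7, 8), neighbor_counts = c(1L, 2L),
                        k_density = 2L)
  d <- density_features(pts, cfg)
  # r_1 = {3, 3, 4} -> mean 10/3; r for neighbors index 1 is k = 1
  expect_equal(unname(d["density.distance_for_neighbors.1.mean"]),
               mean(c(3, 3, 4)))
  # radius 5: counts {1, 2, 1}
  expect_equal(unname(d["density.neighbors_in_distance.1.mean"]),
               mean(c(1, 2, 1)))
  expect_error(density_features(pts, density_config(neighbor_counts = c(3L, 5L))),
               class = "nucleograde_parameter_error")
})

test_that("density features agree exactly with the brute-force oracle", {
  cfg <- density_config(radii = c(10, 20, 30, 40), neighbor_counts = c(3L, 5L),
                        k_density = 5L)
  for (seed in c(7, 8)) {
    pts <- random_points(60, seed = seed)
    m <- as.matrix(pts)
    d <- density_features(pts, cfg)
    for (i in 1:4) {
      expect_equal(unname(d[sprintf("density.neighbors_in_distance.%d.mean", i)]),
                   mean(brute_radius_counts(m, cfg$radii[i])), tolerance = 1e-12)
    }
    for (i in 1:2) {
      expect_equal(unname(d[sprintf("density.distance_for_neighbors.%d.mean", i)]),
                   mean(brute_knn_dist(m, cfg$neighbor_counts[i])),
                   tolerance = 1e-12)
    }
    rho_oracle <- cfg$k_density / (pi * brute_knn_dist(m, cfg$k_density)^2)
    expect_equal(unname(d["density.rho.min"]), min(rho_oracle), tolerance = 1e-12)
    expect_equal(unname(d["density.rho.median"]), median(rho_oracle),
                 tolerance = 1e-12)
    expect_equal(unname(d["density.rho.max"]), max(rho_oracle), tolerance = 1e-12)
  }
})

test_that("the full feature vector has 52 finite values in three blocks", {
  pts <- random_points(80, seed = 21)
  fv <- extract_spatial_features(pts)
  expect_length(fv, 52)
  expect_true(all(is.finite(fv)))
  nm <- names(fv)
  expect_equal(sum(startsWith(nm, "voronoi.") | startsWith(nm, "delaunay.") |
                     startsWith(nm, "mst.")), 24)
  expect_equal(sum(startsWith(nm, "density.")), 27)
  expect_equal(unname(fv["nuclei_count"]), 80)
  expect_identical(nm, spatial_feature_names())
})

test_that("feature vectors are invariant to translation and input order", {
  pts <- random_points(60, seed = 31)
  fv <- extract_spatial_features(pts)
  shifted <- dplyr::mutate(pts, x = x + 123.4, y = y - 55.5)
  expect_equal(extract_spatial_features(shifted), fv, tolerance = 1e-8)
  set.seed(1)
  perm <- pts[sample(nrow(pts)), ]
  expect_equal(extract_spatial_features(perm), fv, tolerance = 1e-10)
})

test_that("disorder and min-max ratio stay in range on many patterns", {
  for (seed in 1:5) {
    pts <- random_points(50, seed = seed)
    fv <- extract_spatial_features(pts)
    dis <- fv[grepl("\\.disorder$", names(fv))]
    mmr <- fv[grepl("\\.min_max_ratio$", names(fv))]
    expect_true(all(dis >= 0 & dis < 1))
    expect_true(all(mmr >= 0 & mmr <= 1))
  }
})

test_that("tiny sections are excluded with a report, not dropped silently", {
  set.seed(3)
  cent <- dplyr::bind_rows(
    dplyr::mutate(random_points(40, seed = 1), patient_id = "P1",
                  section_id = "P1_S01"),
    dplyr::mutate(random_points(5, seed = 2), patient_id = "P1",
                  section_id = "P1_S02")
  )
  expect_message(out <- extract_features(cent), "Excluded 1 section")
  expect_equal(nrow(out), 1)
  excl <- attr(out, "excluded")
  expect_equal(excl$section_id, "P1_S02")
  expect_equal(excl$n_nuclei, 5)
})

test_that("duplicate centroids are merged before tessellation", {
  pts <- random_points(30, seed = 44)
  dup <- dplyr::bind_rows(pts, pts[1:3, ])
  expect_message(fv <- extract_spatial_features(dup), "duplicate")
  expect_equal(unname(fv["nuclei_count"]), 30)
})

test_that("univariate rank-sum statistic matches exhaustive enumeration", {
  vals <- c(1, 2, 3, 4, 5, 6)
  labs <- c(0, 0, 0, 1, 1, 1)
  res <- univariate_compare(tibble::tibble(f = vals), labs)
  # Exact two-sided p over all 20 equally likely group assignments
  combs <- combn(6, 3)
  stats <- apply(combs, 2, function(idx) sum(rank(vals)[idx]) - 6)
  observed <- sum(rank(vals)[labs == 1]) - 6
  p_exact <- mean(abs(stats - 4.5) >= abs(observed - 4.5))
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
  expect_equal(res$statistic, 9) # W = all 9 cross-pairs won by group 1
})

test_that("univariate comparison detects a large shift and flags constants", {
  set.seed(12)
  n <- 30
  f_shift <- c(rnorm(n), rnorm(n) + 5)
  f_const <- rep(1, 2 * n)
  labs <- rep(c(0, 1), each = n)
  res <- univariate_compare(
    tibble::tibble(shifted = f_shift, constant = f_const), labs)
  expect_lt(res$p_value[res$feature == "shifted"], 0.05)
  expect_equal(res$p_value[res$feature == "constant"], 1)
  expect_true(res$tied[res$feature == "constant"])
  expect_gt(res$median_g3[res$feature == "shifted"],
            res$median_g12[res$feature == "shifted"])
})

test_that("null labels give approximately uniform p-values", {
  set.seed(77)
  n <- 40
  X <- tibble::as_tibble(matrix(rnorm(n * 40), n,
                                dimnames = list(NULL, paste0("f", 1:40))))
  labs <- rep(c(0, 1), each = n / 2)
  res <- univariate_compare(X, labs)
  expect_lt(mean(res$p_value < 0.05), 0.2) # ~5% expected, allow slack
  expect_gt(min(res$p_value), 0)
})
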