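# Desk-scale slide pre-processing: tissue/background separation, tiling with
# a background cap, and stain normalization. Images are numeric arrays
# [height, width, 3] in [0, 1]; masks are logical matrices. Tumor-bed
# probability per tile is an injected interface (no CNN here).

#' Tissue mask of an RGB image
#'
#' Otsu-thresholds the grayscale render (tissue is darker than the slide
#' background), then applies binary closing and small-object removal.
#'
#' @param img Numeric array `[h, w, 3]` with values in \[0, 1\].
#' @param brush_size Diameter of the closing brush (odd integer, pixels).
#' @param min_object_px Connected components smaller than this are removed.
#' @return Logical matrix; `TRUE` = tissue.
#' @export
tissue_mask <- function(img, brush_size = 5L, min_object_px = 64L) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop_nucleograde("Package 'EBImage' is required for tissue masking.",
                     "nucleograde_parameter_error")
  }
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  if (diff(range(gray)) < 1e-8) {
    warn("Degenerate histogram: uniform image; returning empty mask.")
    return(matrix(FALSE, nrow(gray), ncol(gray)))
  }
  thr <- EBImage::otsu(EBImage::Image(gray))
  mask <- gray < thr
  brush <- EBImage::makeBrush(brush_size, shape = "disc")
  closed <- EBImage::closing(EBImage::Image(mask), brush)
  lab <- EBImage::bwlabel(closed)
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_object_px])
  out <- matrix(as.integer(lab) %in% keep, nrow(gray), ncol(gray))
  out
}

#' Tile an image grid under a background cap
#'
#' Lays a non-overlapping tile grid anchored at the origin over the image and
#' discards tiles whose background fraction (1 minus tissue fraction under
#' the mask) exceeds the cap. The grid is exhaustive: retained plus discarded
#' tiles equal the full in-bounds grid.
#'
#' @param mask Logical tissue mask (`TRUE` = tissue).
#' @param size Tile side in pixels (default 750).
#' @param max_background Maximum tolerated background fraction (default 0.10).
#' @param allow_clip If the image is smaller than one tile, return a single
#'   clipped tile instead of erroring.
#' @return A tibble of class `tile_grid`: `tile_id`, `x0`, `y0` (0-based
#'   origins), `background_fraction`, `retained`.
#' @export
tile_image <- function(mask, size = 750L, max_background = 0.10,
                       allow_clip = FALSE) {
  h <- nrow(mask); w <- ncol(mask)
  if (h < size || w < size) {
    if (!allow_clip) {
      stop_nucleograde("Image smaller than one tile (set allow_clip = TRUE to clip).",
                       "nucleograde_parameter_error")
    }
    bf <- 1 - mean(mask)
    out <- tibble::tibble(tile_id = 1L, x0 = 0L, y0 = 0L,
                          background_fraction = bf,
                          retained = bf <= max_background)
    class(out) <- c("tile_grid", class(out))
    return(out)
  }
  x0s <- seq(0L, w - size, by = size)
  y0s <- seq(0L, h - size, by = size)
  grid <- expand.grid(x0 = x0s, y0 = y0s)
  bf <- vapply(seq_len(nrow(grid)), function(i) {
    sub <- mask[grid$y0[i] + seq_len(size), grid$x0[i] + seq_len(size)]
    1 - mean(sub)
  }, numeric(1))
  out <- tibble::tibble(tile_id = seq_len(nrow(grid)),
                        x0 = as.integer(grid$x0), y0 = as.integer(grid$y0),
                        background_fraction = bf,
                        retained = bf <= max_background)
  class(out) <- c("tile_grid", class(out))
  out
}

#' Attach tumor-bed probabilities and derive section tumor-bed area
#'
#' The tumor-bed classifier is a pluggable input: `prob` may be a numeric
#' vector aligned with the tiles or a function `f(tiles)` returning one.
#' The tumor-bed area of the section is the summed pixel area of retained
#' tiles whose probability reaches the threshold, ready to feed
#' [compute_tbr()].
#'
#' @param tiles A [tile_image()] result.
#' @param prob Per-tile tumor-bed probabilities or a callable oracle.
#' @param size Tile side used to build the grid.
#' @param threshold Tumor-bed membership threshold (default 0.5).
#' @return The tile tibble with a `tumor_bed_prob` column; attribute
#'   `tumor_bed_area_px` holds the section's area.
#' @export
assign_tumor_bed <- function(tiles, prob, size = 750L, threshold = 0.5) {
  p <- if (is.function(prob)) prob(tiles) else prob
  assert_probability(p, "prob")
  if (length(p) != nrow(tiles)) {
    stop_nucleograde("One tumor-bed probability per tile is required.",
                     "nucleograde_parameter_error")
  }
  out <- dplyr::mutate(tiles, tumor_bed_prob = p)
  attr(out, "tumor_bed_area_px") <-
    sum(out$retained & out$tumor_bed_prob >= threshold) * as.numeric(size)^2
  out
}

#' Default Macenko stain reference
#'
#' Standard H&E optical-density stain vectors (columns: hematoxylin, eosin)
#' and the reference 99th-percentile concentrations.
#'
#' @return A list with `he` (3 x 2 matrix) and `max_c` (length 2).
#' @export
default_stain_reference <- function() {
  list(
    he = matrix(c(0.5626, 0.7201, 0.4062,
                  0.2159, 0.8012, 0.5581), ncol = 2),
    max_c = c(1.9705, 1.0308)
  )
}

#' Macenko stain normalization of an H&E tile
#'
#' Estimates the tile's two stain vectors from the extreme angles of the
#' optical-density point cloud in the plane of its top two principal
#' components, unmixes pixel concentrations by least squares, rescales the
#' concentration distribution to the reference, and reconstructs the tile
#' with the reference stain matrix. Near-white tiles with too few stained
#' pixels are returned unchanged with attribute `no_stain = TRUE`.
#'
#' @param img Numeric array `[h, w, 3]` in \[0, 1\].
#' @param reference A [default_stain_reference()]-shaped list.
#' @param beta Optical-density threshold below which pixels count as
#'   unstained (default 0.15).
#' @param alpha Percentile (in percent) for the robust extreme angles
#'   (default 1).
#' @param min_stained_px Minimum stained pixels required to fit stain
#'   vectors.
#' @return Normalized array of the same shape, clipped to \[0, 1\].
#' @export
stain_normalize <- function(img, reference = default_stain_reference(),
                            beta = 0.15, alpha = 1, min_stained_px = 50L) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  d <- dim(img)
  I <- pmin(pmax(img, 0), 1)
  od <- -log((matrix(I, ncol = 3) * 255 + 1) / 256)
  stained <- rowSums(od > beta) == 3L
  if (sum(stained) < min_stained_px) {
    out <- img
    attr(out, "no_stain") <- TRUE
    return(out)
  }
  odh <- od[stained, , drop = FALSE]
  ev <- eigen(stats::cov(odh), symmetric = TRUE)$vectors[, 1:2]
  # orient the first axis along the OD cloud so angles do not wrap at +/- pi
  if (sum(odh %*% ev[, 1]) < 0) ev[, 1] <- -ev[, 1]
  proj <- odh %*% ev
  phi <- atan2(proj[, 2], proj[, 1])
  q <- quantile(phi, c(alpha / 100, 1 - alpha / 100))
  v1 <- ev %*% c(cos(q[1]), sin(q[1]))
  v2 <- ev %*% c(cos(q[2]), sin(q[2]))
  if (v1[1] < 0) v1 <- -v1
  if (v2[1] < 0) v2 <- -v2
  he <- if (v1[1] > v2[1]) cbind(v1, v2) else cbind(v2, v1)
  conc <- t(qr.solve(he, t(od)))
  max_c <- apply(conc, 2, quantile, probs = 0.99)
  max_c[max_c <= 0] <- 1
  conc_n <- sweep(conc, 2, reference$max_c / max_c, "*")
  od_n <- conc_n %*% t(reference$he)
  In <- (256 * exp(-od_n) - 1) / 255
  out <- array(pmin(pmax(In, 0), 1), dim = d)
  attr(out, "no_stain") <- FALSE
  out
}
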