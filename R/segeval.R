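# Instance-segmentation evaluation: AJI, one-to-one instance matching at an
# IoU threshold, and unscored average precision over an IoU ladder. Masks are
# integer matrices (0 = background, positive ids = instances); ids need not
# be consecutive.

# Internal: pairwise intersection counts and instance sizes between two
# label masks, computed from the joint label table on non-background pixels.
mask_overlap <- function(gt, pred) {
  if (!all(dim(gt) == dim(pred))) {
    stop_nucleograde("Masks must share the same extent.",
                     "nucleograde_parameter_error")
  }
  gt_ids <- sort(unique(gt[gt > 0]))
  pred_ids <- sort(unique(pred[pred > 0]))
  idx <- which(gt > 0 | pred > 0)
  tab <- table(factor(gt[idx], levels = c(0, gt_ids)),
               factor(pred[idx], levels = c(0, pred_ids)))
  inter <- as.matrix(tab)[-1, -1, drop = FALSE]
  list(
    gt_ids = gt_ids, pred_ids = pred_ids,
    inter = inter,
    gt_size = vapply(gt_ids, function(i) sum(gt == i), numeric(1)),
    pred_size = vapply(pred_ids, function(i) sum(pred == i), numeric(1))
  )
}

# Internal: IoU matrix (ground truth x prediction).
iou_matrix <- function(ov) {
  if (length(ov$gt_ids) == 0L || length(ov$pred_ids) == 0L) {
    return(matrix(numeric(0), nrow = length(ov$gt_ids),
                  ncol = length(ov$pred_ids)))
  }
  un <- outer(ov$gt_size, ov$pred_size, "+") - ov$inter
  ov$inter / un
}

#' Aggregated Jaccard Index of two instance masks
#'
#' Each ground-truth instance is greedily paired (in stable ascending-id
#' order, ties broken by larger intersection) with the unused predicted
#' instance of maximal IoU; the matched intersections and unions are
#' aggregated, unmatched ground-truth pixels enlarge the union, and the
#' pixels of every unused predicted instance are added to the denominator.
#'
#' @param gt,pred Integer label masks of equal extent (0 = background).
#' @return AJI in \[0, 1\].
#' @examples
#' m <- matrix(0L, 8, 8); m[2:3, 2:3] <- 1L
#' aji(m, m) # 1
#' @export
aji <- function(gt, pred) {
  if (!any(gt > 0)) {
    stop_nucleograde("AJI undefined: empty ground truth.",
                     "nucleograde_parameter_error")
  }
  ov <- mask_overlap(gt, pred)
  iou <- iou_matrix(ov)
  used <- logical(length(ov$pred_ids))
  C <- 0; U <- 0
  for (g in seq_along(ov$gt_ids)) {
    if (length(ov$pred_ids) == 0L) {
      U <- U + ov$gt_size[g]
      next
    }
    cand <- iou[g, ]
    cand[used] <- -1
    best <- which(cand == max(cand))
    if (length(best) > 1L) best <- best[which.max(ov$inter[g, best])]
    if (cand[best] > 0) {
      used[best] <- TRUE
      C <- C + ov$inter[g, best]
      U <- U + ov$gt_size[g] + ov$pred_size[best] - ov$inter[g, best]
    } else {
      U <- U + ov$gt_size[g]
    }
  }
  U <- U + sum(ov$pred_size[!used])
  C / U
}

#' One-to-one instance matching at an IoU threshold
#'
#' Pairs ground-truth and predicted instances greedily in descending-IoU
#' order, each instance used at most once, keeping pairs with IoU at or
#' above the threshold. Matched pairs are true positives, unmatched
#' predictions false positives, unmatched ground truths false negatives.
#'
#' @inheritParams aji
#' @param iou_threshold Threshold in (0, 1\].
#' @return A list with `tp`, `fp`, `fn`, the matched `pairs` tibble
#'   (gt, pred, iou) and `precision`, `recall`, `f1`.
#' @export
match_instances <- function(gt, pred, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold > 1) {
    stop_nucleograde("`iou_threshold` must lie in (0, 1].",
                     "nucleograde_parameter_error")
  }
  ov <- mask_overlap(gt, pred)
  iou <- iou_matrix(ov)
  pairs <- tibble::tibble(gt = integer(0), pred = integer(0), iou = numeric(0))
  if (length(iou) > 0) {
    cand <- which(iou >= iou_threshold, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(iou[cand], decreasing = TRUE), , drop = FALSE]
      used_g <- logical(nrow(iou)); used_p <- logical(ncol(iou))
      for (i in seq_len(nrow(cand))) {
        g <- cand[i, 1]; p <- cand[i, 2]
        if (used_g[g] || used_p[p]) next
        used_g[g] <- TRUE; used_p[p] <- TRUE
        pairs <- dplyr::add_row(pairs, gt = as.integer(ov$gt_ids[g]),
                                pred = as.integer(ov$pred_ids[p]),
                                iou = iou[g, p])
      }
    }
  }
  tp <- nrow(pairs)
  fp <- length(ov$pred_ids) - tp
  fn <- length(ov$gt_ids) - tp
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(tp = tp, fp = fp, fn = fn, pairs = pairs,
       precision = precision, recall = recall, f1 = f1)
}

#' Average precision over an IoU-threshold ladder
#'
#' Unscored instance-segmentation AP: at each threshold `t`,
#' `AP(t) = TP / (TP + FP + FN)` from the one-to-one matching of
#' [match_instances()]; `mAP` is the mean over the ladder (default 0.50 to
#' 0.95 in steps of 0.05). This convention applies when predictions carry no
#' confidence scores and differs from score-ranked COCO AP.
#'
#' @inheritParams aji
#' @param thresholds IoU ladder (default `seq(0.5, 0.95, 0.05)`).
#' @return A list with `per_threshold` (tibble of threshold, ap, tp, fp, fn)
#'   and `map`.
#' @export
average_precision <- function(gt, pred, thresholds = seq(0.5, 0.95, by = 0.05)) {
  rows <- purrr::map_dfr(thresholds, function(t) {
    m <- match_instances(gt, pred, t)
    denom <- m$tp + m$fp + m$fn
    tibble::tibble(threshold = t,
                   ap = if (denom == 0) 0 else m$tp / denom,
                   tp = m$tp, fp = m$fp, fn = m$fn)
  })
  list(per_threshold = rows, map = mean(rows$ap))
}

#' Full segmentation metric report for a mask pair
#'
#' @inheritParams aji
#' @return A list with `aji`, `map`, `per_threshold` AP, and
#'   precision/recall/F1 at IoU 0.5 and 0.7.
#' @export
segmentation_metrics <- function(gt, pred) {
  ap <- average_precision(gt, pred)
  m50 <- match_instances(gt, pred, 0.5)
  m70 <- match_instances(gt, pred, 0.7)
  list(
    aji = aji(gt, pred),
    map = ap$map,
    per_threshold = ap$per_threshold,
    at_iou_0.5 = list(precision = m50$precision, recall = m50$recall, f1 = m50$f1),
    at_iou_0.7 = list(precision = m70$precision, recall = m70$recall, f1 = m70$f1)
  )
}

#' Read / write a 16-bit label mask as TIFF
#'
#' @param path File path.
#' @return `read_label_mask()` returns an integer matrix;
#'   `write_label_mask()` returns `path` invisibly.
#' @export
read_label_mask <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop_nucleograde("Package 'tiff' is required for mask IO.",
                     "nucleograde_parameter_error")
  }
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_label_mask
#' @param mask Integer label matrix (values < 65536).
#' @export
write_label_mask <- function(mask, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop_nucleograde("Package 'tiff' is required for mask IO.",
                     "nucleograde_parameter_error")
  }
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
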