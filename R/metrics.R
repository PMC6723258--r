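#' Mask intersection-over-union (Jaccard index)
#'
#' @param a,b binary masks given either as logical matrices of a common shape
#'   or as integer vectors of linear pixel indices (in which case they are
#'   assumed to refer to the same grid).
#' @return `|a & b| / |a | b|`. Defined as 1 when both masks are empty and 0
#'   when exactly one is empty.
#' @export
mask_iou <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b)))
      stop("mask_iou: masks must share a common grid shape")
    a <- which(a != 0); b <- which(b != 0)
  }
  na <- length(a); nb <- length(b)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  inter <- sum(a %in% b)
  inter / (na + nb - inter)
}

#' Bounding-box intersection-over-union
#'
#' Boxes are half-open `[r0, r1) x [c0, c1)` in pixel units, given as numeric
#' vectors `(r0, c0, r1, c1)`.
#'
#' @param a,b boxes.
#' @return overlap area divided by union area.
#' @export
box_iou <- function(a, b) {
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[3] - b[1]) * (b[4] - b[2])
  if (area_a <= 0 || area_b <= 0) stop("box_iou: zero-area box")
  ih <- min(a[3], b[3]) - max(a[1], b[1])
  iw <- min(a[4], b[4]) - max(a[2], b[2])
  if (ih <= 0 || iw <= 0) return(0)
  inter <- ih * iw
  inter / (area_a + area_b - inter)
}

# Pairwise IoU matrix between a label set and a prediction set.
pairwise_iou <- function(s_l, s_p, mode = c("mask", "box")) {
  mode <- match.arg(mode)
  nl <- length(s_l$masks); np <- length(s_p$masks)
  iou <- matrix(0, nl, np)
  if (nl == 0 || np == 0) return(iou)
  for (j in seq_len(np)) {
    bj <- s_p$boxes[j, ]
    for (i in seq_len(nl)) {
      bi <- s_l$boxes[i, ]
      # well-separated boxes imply disjoint masks (1 px margin: prediction
      # masks may overflow fractional boxes by less than a pixel)
      if (min(bi[3], bj[3]) <= max(bi[1], bj[1]) - 1 ||
          min(bi[4], bj[4]) <= max(bi[2], bj[2]) - 1) next
      iou[i, j] <- if (mode == "box") box_iou(bi, bj) else
        mask_iou(s_l$masks[[i]], s_p$masks[[j]])
    }
  }
  iou
}

#' Match predicted instances to labelled instances at an IoU threshold
#'
#' Greedy one-to-one matching: predictions are visited in descending score
#' order and each claims the highest-IoU unclaimed label, provided the IoU
#' strictly exceeds `t_iou`. Unmatched predictions are false positives,
#' unmatched labels false negatives.
#'
#' @param s_l labelled `instance_mask_set`.
#' @param s_p predicted `instance_mask_set` (scores optional; unscored
#'   predictions are visited in input order).
#' @param t_iou IoU threshold in (0, 1); a pair matches only if IoU > `t_iou`.
#' @param mode `"mask"` (pixel IoU) or `"box"` (bounding-box IoU).
#' @return a `match_result` with elements `t_iou`, `pairs` (matrix with columns
#'   `label`, `pred`, `iou`), `fp_indices`, `fn_indices`, and counts `tp`,
#'   `fp`, `fn`.
#' @export
match_instances <- function(s_l, s_p, t_iou = 0.5, mode = c("mask", "box")) {
  mode <- match.arg(mode)
  if (!is.numeric(t_iou) || t_iou <= 0 || t_iou >= 1)
    stop("match_instances: t_iou must lie strictly inside (0, 1)")
  nl <- length(s_l$masks); np <- length(s_p$masks)
  iou <- pairwise_iou(s_l, s_p, mode)
  ord <- if (is.null(s_p$scores)) seq_len(np) else
    order(s_p$scores, decreasing = TRUE)
  claimed <- logical(nl)
  pairs <- matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("label", "pred", "iou")))
  for (j in ord) {
    if (nl == 0) break
    cand <- iou[, j]
    cand[claimed] <- -Inf
    i <- which.max(cand)
    if (length(i) && cand[i] > t_iou) {
      claimed[i] <- TRUE
      pairs <- rbind(pairs, c(i, j, iou[i, j]))
    }
  }
  tp <- nrow(pairs)
  structure(list(
    t_iou = t_iou, pairs = pairs,
    fp_indices = setdiff(seq_len(np), pairs[, "pred"]),
    fn_indices = which(!claimed),
    tp = tp, fp = np - tp, fn = nl - tp), class = "match_result")
}

#' Precision and recall of a match result
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`. Degenerate 0/0
#' ratios are defined as 1 (an empty prediction set against an empty label set
#' is vacuously perfect), so empty frames do not poison averages.
#'
#' @param m a `match_result`.
#' @return named numeric vector `(precision, recall)`.
#' @export
precision_recall <- function(m) {
  stopifnot(inherits(m, "match_result"))
  p <- if (m$tp + m$fp == 0) 1 else m$tp / (m$tp + m$fp)
  r <- if (m$tp + m$fn == 0) 1 else m$tp / (m$tp + m$fn)
  c(precision = p, recall = r)
}

#' Precision-recall curve over a prediction-score sweep
#'
#' For each score threshold `T_s`, predictions scoring below `T_s` are removed,
#' the remainder re-matched against the labels, and one (precision, recall)
#' point recorded. Thresholds default to the sorted distinct prediction scores,
#' so every point retains at least one prediction.
#'
#' @inheritParams match_instances
#' @param thresholds numeric vector of score thresholds; default the sorted
#'   unique scores of `s_p`.
#' @return a `pr_curve`: a data.frame with columns `t_s`, `precision`,
#'   `recall`, plus attributes `t_iou` and `mode`.
#' @export
pr_curve <- function(s_l, s_p, t_iou = 0.5, mode = c("mask", "box"),
                     thresholds = NULL) {
  mode <- match.arg(mode)
  if (is.null(s_p$scores))
    stop("pr_curve: the prediction set must carry scores")
  if (is.null(thresholds)) thresholds <- sort(unique(s_p$scores))
  pts <- vapply(thresholds, function(ts) {
    keep <- which(s_p$scores >= ts)
    precision_recall(match_instances(s_l, mask_set_subset(s_p, keep),
                                     t_iou, mode))
  }, numeric(2))
  out <- data.frame(t_s = thresholds,
                    precision = pts["precision", ],
                    recall = pts["recall", ])
  attr(out, "t_iou") <- t_iou
  attr(out, "mode") <- mode
  class(out) <- c("pr_curve", "data.frame")
  out
}

# AP of one image: running-max (right-continuous) interpolated precision
# averaged over a fixed grid of M = 101 recall levels; precision is 0 at
# recall levels the predictions never reach. Fixed levels make AP provably
# non-increasing in the matching threshold.
ap_recall_levels <- seq(0, 1, by = 0.01)

ap_one_image <- function(s_l, s_p, t_iou, mode) {
  if (length(s_p$masks) == 0)
    return(if (length(s_l$masks) == 0) 1 else 0)
  curve <- pr_curve(s_l, s_p, t_iou, mode)
  interp <- vapply(ap_recall_levels, function(r) {
    ok <- curve$recall >= r
    if (any(ok)) max(curve$precision[ok]) else 0
  }, numeric(1))
  mean(interp)
}

#' Per-image-averaged average precision
#'
#' Each image's AP is the mean of its interpolated precision over a fixed
#' grid of 101 recall evaluation levels (0 to 1 in steps of 0.01); precision
#' is interpolated right-continuously (running maximum over score-threshold
#' points with recall at least the evaluation level) and is 0 at levels the
#' predictions never reach. The reported value is the arithmetic mean of
#' per-image APs. An image with neither labels nor predictions contributes
#' AP = 1 by convention.
#'
#' @param images list of `list(labels = <instance_mask_set>, preds = <scored
#'   instance_mask_set>)` pairs.
#' @param t_iou IoU threshold used for matching.
#' @param mode `"mask"` or `"box"`.
#' @return an `ap_result`: list with `per_image_ap`, `mean_ap`, `t_iou`, `mode`.
#' @export
average_precision <- function(images, t_iou = 0.5, mode = c("mask", "box")) {
  mode <- match.arg(mode)
  if (length(images) < 1) stop("average_precision: need at least one image")
  per <- vapply(images, function(im)
    ap_one_image(im$labels, im$preds, t_iou, mode), numeric(1))
  structure(list(per_image_ap = per, mean_ap = mean(per),
                 t_iou = t_iou, mode = mode), class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("<ap_result: mean AP %.4f over %d image(s), T_iou %.2f, %s mode>\n",
              x$mean_ap, length(x$per_image_ap), x$t_iou, x$mode))
  invisible(x)
}

#' Evaluate detections over a grid of IoU thresholds
#'
#' Computes the per-image-averaged AP for every combination of IoU threshold
#' and matching mode (boxes and masks), plus the PR curve at each threshold.
#'
#' @inheritParams average_precision
#' @param t_iou_grid numeric vector of IoU thresholds (default 0.3 to 0.7 in
#'   steps of 0.05).
#' @param modes character vector, subset of `c("box", "mask")`.
#' @return an `eval_report`: list with `ap` (data.frame `t_iou`, `mode`, `ap`)
#'   and `pr` (named list of per-threshold pooled `pr_curve`s).
#' @export
evaluate_suite <- function(images, t_iou_grid = seq(0.3, 0.7, by = 0.05),
                           modes = c("box", "mask")) {
  modes <- match.arg(modes, c("box", "mask"), several.ok = TRUE)
  grid <- expand.grid(t_iou = t_iou_grid, mode = modes,
                      stringsAsFactors = FALSE)
  grid$ap <- mapply(function(t, m) average_precision(images, t, m)$mean_ap,
                    grid$t_iou, grid$mode)
  pr <- list()
  for (m in modes) for (t in t_iou_grid) {
    cur <- lapply(images, function(im) {
      if (length(im$preds$masks) == 0) return(NULL)
      pr_curve(im$labels, im$preds, t, m)
    })
    cur <- Filter(Negate(is.null), cur)
    key <- sprintf("%s@%.2f", m, t)
    pr[[key]] <- if (length(cur)) do.call(rbind, cur) else NULL
  }
  structure(list(ap = grid, pr = pr), class = "eval_report")
}

#' Mean matched-pair mask IoU against a golden annotation set
#'
#' Matches predicted instances to expert ("golden") instances frame by frame
#' (mask IoU, threshold `t_iou`) and summarises the matched-pair IoUs.
#'
#' @param golden,predicted lists of `instance_mask_set`, aligned one-to-one.
#' @param t_iou matching threshold (default 0.5).
#' @return named numeric vector `(mean, sd, n_pairs)`.
#' @export
mean_mask_iou <- function(golden, predicted, t_iou = 0.5) {
  stopifnot(length(golden) == length(predicted))
  ious <- unlist(lapply(seq_along(golden), function(i) {
    m <- match_instances(golden[[i]], predicted[[i]], t_iou, "mask")
    m$pairs[, "iou"]
  }))
  if (length(ious) == 0) stop("mean_mask_iou: zero matched pairs")
  c(mean = mean(ious), sd = stats::sd(ious), n_pairs = length(ious))
}
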