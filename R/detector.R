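#' Anchor configuration
#'
#' Anchors are predefined candidate boxes: for each size scale `s` an `s x s`
#' box plus two aspect-ratio variants of (approximately) equal area, placed on
#' a grid whose step defaults to half the anchor side, so neighbouring anchors
#' of the same scale overlap.
#'
#' @param scales anchor side lengths in pixels (default `c(8, 16, 32, 64,
#'   128)`; the largest must cover the largest expected object).
#' @param aspect_ratios height:width ratios (default 1:2, 1:1, 2:1 given as
#'   `c(0.5, 1, 2)`).
#' @param step_fraction placement step as a fraction of the anchor side
#'   (default 0.5).
#' @return an `anchor_config`.
#' @export
anchor_config <- function(scales = c(8, 16, 32, 64, 128),
                          aspect_ratios = c(0.5, 1, 2),
                          step_fraction = 0.5) {
  stopifnot(all(scales > 0), all(aspect_ratios > 0), step_fraction > 0)
  structure(list(scales = sort(as.numeric(scales)),
                 aspect_ratios = as.numeric(aspect_ratios),
                 step_fraction = as.numeric(step_fraction)),
            class = "anchor_config")
}

#' Enumerate anchors over an image
#'
#' For each scale, `s x s` placements start at the image origin and advance by
#' `step_fraction * s`, with the last placement shifted to stay interior; each
#' position carries one anchor per aspect ratio (`h = s / sqrt(r)`,
#' `w = s * sqrt(r)`, area ~ s^2), clipped to the image bounds.
#'
#' @param cfg an [anchor_config()].
#' @param image_size (H, W) in pixels.
#' @return data.frame with columns `r0`, `c0`, `r1`, `c1`, `scale`, `ratio`.
#' @export
generate_anchors <- function(cfg, image_size) {
  H <- image_size[1]; W <- image_size[2]
  if (min(H, W) < max(cfg$scales))
    stop("generate_anchors: image smaller than the largest anchor")
  out <- list()
  for (s in cfg$scales) {
    step <- s * cfg$step_fraction
    pr <- seq(0, H - s, by = step); pc <- seq(0, W - s, by = step)
    cen_r <- rep(pr + s / 2, times = length(pc))
    cen_c <- rep(pc + s / 2, each = length(pr))
    for (r in cfg$aspect_ratios) {
      h <- s / sqrt(r); w <- s * sqrt(r)
      out[[length(out) + 1]] <- data.frame(
        r0 = pmax(cen_r - h / 2, 0), c0 = pmax(cen_c - w / 2, 0),
        r1 = pmin(cen_r + h / 2, H), c1 = pmin(cen_c + w / 2, W),
        scale = s, ratio = r)
    }
  }
  do.call(rbind, out)
}

# Vectorized IoU between two box matrices (n x 4, half-open r0,c0,r1,c1).
box_iou_matrix <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  if (n == 0 || m == 0) return(matrix(0, n, m))
  ih <- outer(A[, 3], B[, 3], pmin) - outer(A[, 1], B[, 1], pmax)
  iw <- outer(A[, 4], B[, 4], pmin) - outer(A[, 2], B[, 2], pmax)
  inter <- pmax(ih, 0) * pmax(iw, 0)
  aA <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  aB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  inter / (outer(aA, aB, "+") - inter)
}

#' Greedy non-max suppression
#'
#' Boxes are visited in descending score order; a box is suppressed iff its
#' IoU with an already-kept box exceeds `iou_threshold`.
#'
#' @param boxes n x 4 matrix of half-open boxes `(r0, c0, r1, c1)`.
#' @param scores numeric vector of length n.
#' @param iou_threshold suppression threshold.
#' @return kept indices, in descending-score order.
#' @export
nms <- function(boxes, scores, iou_threshold = 0.5) {
  boxes <- matrix(boxes, ncol = 4)
  stopifnot(nrow(boxes) == length(scores))
  if (nrow(boxes) == 0) return(integer(0))
  ord <- order(scores, decreasing = TRUE)
  iou <- box_iou_matrix(boxes, boxes)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0 || all(iou[i, keep] <= iou_threshold))
      keep <- c(keep, i)
  }
  keep
}

#' Training configuration of the compact detector
#'
#' The defaults describe a small residual backbone with pyramid features,
#' trainable on one CPU, using three anchor scales suited to 128 x 128 patches
#' with 20-44 px nuclei. The alignment sizes, mask-head shape and score
#' threshold default to the reference operating point (7 x 7 detection
#' alignment, 14 x 14 mask alignment with a 28 x 28 float output, score
#' threshold 0.9) and are configurable.
#'
#' @param anchor_scales anchor sides in px; one pyramid level per scale, each
#'   level's stride = scale / 2 (the half-anchor-size scanning step).
#' @param aspect_ratios anchor height:width ratios.
#' @param base_channels channels of the first backbone stage (doubling per
#'   stage, capped at 64).
#' @param fpn_channels channels of every pyramid level.
#' @param roi_align_detect,roi_align_mask RoI alignment sizes.
#' @param mask_channels channels of the mask head's convolutions.
#' @param head_fc width of the two fully connected head layers.
#' @param score_threshold prediction-score cutoff at inference (default 0.9).
#' @param nms_iou final detection NMS threshold.
#' @param rpn_nms_iou proposal NMS threshold.
#' @param proposals_kept proposals kept after NMS per patch.
#' @param pos_iou,neg_iou anchor-to-truth IoU thresholds defining positive and
#'   negative anchors (argmax anchors per truth are always positive).
#' @param epochs_rpn,epochs_heads training epochs of the two phases.
#' @param lr Adam learning rate.
#' @param seed root seed for initialization, shuffling and sampling.
#' @return a `train_config`.
#' @export
train_config <- function(anchor_scales = c(16, 32, 64),
                         aspect_ratios = c(0.5, 1, 2),
                         base_channels = 16, fpn_channels = 32,
                         roi_align_detect = 7, roi_align_mask = 14,
                         mask_channels = 64, head_fc = 256,
                         score_threshold = 0.9, nms_iou = 0.3,
                         rpn_nms_iou = 0.7, proposals_kept = 200,
                         pos_iou = 0.7, neg_iou = 0.3,
                         epochs_rpn = 12, epochs_heads = 12, lr = 2e-3,
                         seed = 1L) {
  scales <- sort(as.numeric(anchor_scales))
  strides <- scales / 2
  if (any(strides != 2^round(log2(strides))) ||
      any(diff(round(log2(strides))) != 1))
    stop("train_config: anchor_scales must be consecutive powers of two ",
         "(each pyramid level's stride is half its anchor scale)")
  structure(list(anchor_scales = scales, aspect_ratios = aspect_ratios,
                 base_channels = base_channels, fpn_channels = fpn_channels,
                 roi_align_detect = roi_align_detect,
                 roi_align_mask = roi_align_mask,
                 mask_channels = mask_channels, head_fc = head_fc,
                 score_threshold = score_threshold, nms_iou = nms_iou,
                 rpn_nms_iou = rpn_nms_iou,
                 proposals_kept = proposals_kept,
                 pos_iou = pos_iou, neg_iou = neg_iou,
                 epochs_rpn = epochs_rpn, epochs_heads = epochs_heads,
                 lr = lr, seed = as.integer(seed)),
            class = "train_config")
}

# ---- parameter initialization ---------------------------------------------

backbone_channels <- function(cfg, n_stages)
  pmin(cfg$base_channels * 2^(seq_len(n_stages) - 1), 64)

init_params <- function(cfg) {
  strides <- cfg$anchor_scales / 2
  n_stages <- round(log2(max(strides)))
  ch <- backbone_channels(cfg, n_stages)
  D <- cfg$fpn_channels
  A <- length(cfg$aspect_ratios)
  Cm <- cfg$mask_channels
  p <- list()
  cin <- 1
  for (k in seq_len(n_stages)) {
    p[[sprintf("bb%d_down_W", k)]] <- he_init(9 * cin, ch[k])
    p[[sprintf("bb%d_down_b", k)]] <- numeric(ch[k])
    p[[sprintf("bb%d_res_W", k)]] <- he_init(9 * ch[k], ch[k])
    p[[sprintf("bb%d_res_b", k)]] <- numeric(ch[k])
    cin <- ch[k]
  }
  for (s in strides) {
    k <- round(log2(s))
    p[[sprintf("lat%d_W", k)]] <- he_init(ch[k], D)
    p[[sprintf("lat%d_b", k)]] <- numeric(D)
    p[[sprintf("smooth%d_W", k)]] <- he_init(9 * D, D)
    p[[sprintf("smooth%d_b", k)]] <- numeric(D)
  }
  p$rpn_conv_W <- he_init(9 * D, D); p$rpn_conv_b <- numeric(D)
  p$rpn_obj_W <- he_init(D, A) * 0.1; p$rpn_obj_b <- numeric(A)
  p$rpn_delta_W <- he_init(D, 4 * A) * 0.1; p$rpn_delta_b <- numeric(4 * A)
  nin <- cfg$roi_align_detect^2 * D
  p$head_fc1_W <- he_init(nin, cfg$head_fc); p$head_fc1_b <- numeric(cfg$head_fc)
  p$head_fc2_W <- he_init(cfg$head_fc, cfg$head_fc)
  p$head_fc2_b <- numeric(cfg$head_fc)
  p$head_cls_W <- he_init(cfg$head_fc, 2) * 0.1; p$head_cls_b <- numeric(2)
  p$head_box_W <- he_init(cfg$head_fc, 4) * 0.1; p$head_box_b <- numeric(4)
  p$mask1_W <- he_init(9 * D, Cm); p$mask1_b <- numeric(Cm)
  p$mask2_W <- he_init(9 * Cm, Cm); p$mask2_b <- numeric(Cm)
  p$mask3_W <- he_init(9 * Cm, Cm); p$mask3_b <- numeric(Cm)
  p$mask4_W <- he_init(9 * Cm, Cm); p$mask4_b <- numeric(Cm)
  p$mask_out_W <- he_init(Cm, 1) * 0.1; p$mask_out_b <- numeric(1)
  p
}

# ---- forward graph ---------------------------------------------------------

# Backbone + FPN + RPN on one H x W image (tape-based). Returns node ids for
# the per-level pyramid features and RPN outputs.
forward_rpn <- function(tp, params, img, cfg) {
  leaf <- function(nm) tp_leaf(tp, params[[nm]], nm)
  strides <- cfg$anchor_scales / 2
  n_stages <- round(log2(max(strides)))
  x <- tp_leaf(tp, array(img, c(nrow(img), ncol(img), 1)))
  stages <- list()
  for (k in seq_len(n_stages)) {
    x <- tp_relu(tp, tp_conv2d(tp, x, leaf(sprintf("bb%d_down_W", k)),
                               leaf(sprintf("bb%d_down_b", k)),
                               3, 3, stride = 2L, pad = 1L))
    r <- tp_conv2d(tp, x, leaf(sprintf("bb%d_res_W", k)),
                   leaf(sprintf("bb%d_res_b", k)), 3, 3, stride = 1L, pad = 1L)
    x <- tp_relu(tp, tp_add(tp, x, r))
    stages[[k]] <- x
  }
  lvls <- sort(round(log2(strides)), decreasing = TRUE)  # deepest first
  P <- list()
  for (i in seq_along(lvls)) {
    k <- lvls[i]
    lat <- tp_conv2d(tp, stages[[k]], leaf(sprintf("lat%d_W", k)),
                     leaf(sprintf("lat%d_b", k)), 1, 1)
    P[[as.character(k)]] <- if (i == 1) lat else
      tp_add(tp, lat, tp_upsample2x(tp, P[[as.character(lvls[i - 1])]]))
  }
  out <- list()
  for (k in sort(lvls)) {
    sm <- tp_conv2d(tp, P[[as.character(k)]], leaf(sprintf("smooth%d_W", k)),
                    leaf(sprintf("smooth%d_b", k)), 3, 3, pad = 1L)
    h <- tp_relu(tp, tp_conv2d(tp, sm, leaf("rpn_conv_W"), leaf("rpn_conv_b"),
                               3, 3, pad = 1L))
    out[[length(out) + 1]] <- list(
      stride = 2^k,
      feat = sm,
      obj = tp_conv2d(tp, h, leaf("rpn_obj_W"), leaf("rpn_obj_b"), 1, 1),
      delta = tp_conv2d(tp, h, leaf("rpn_delta_W"), leaf("rpn_delta_b"), 1, 1))
  }
  out
}

# Cell-centred anchor table for pyramid levels; row order matches the column-
# major flattening of the RPN output arrays.
level_anchor_table <- function(cfg, image_size) {
  strides <- cfg$anchor_scales / 2
  A <- length(cfg$aspect_ratios)
  tabs <- list()
  for (li in seq_along(strides)) {
    t <- strides[li]; s <- cfg$anchor_scales[li]
    Hl <- ceiling(image_size[1] / t); Wl <- ceiling(image_size[2] / t)
    i <- rep(seq_len(Hl) - 1L, times = Wl)
    j <- rep(seq_len(Wl) - 1L, each = Hl)
    cen_r <- (i + 0.5) * t; cen_c <- (j + 0.5) * t
    per <- list()
    for (a in seq_len(A)) {
      r <- cfg$aspect_ratios[a]
      h <- s / sqrt(r); w <- s * sqrt(r)
      per[[a]] <- cbind(cen_r - h / 2, cen_c - w / 2,
                        cen_r + h / 2, cen_c + w / 2)
    }
    boxes <- do.call(rbind, per)
    tabs[[li]] <- list(level = li, stride = t, Hl = Hl, Wl = Wl,
                       boxes = boxes,
                       cell = rep(i + j * Hl, A),
                       anchor_var = rep(seq_len(A), each = Hl * Wl))
  }
  tabs
}

encode_boxes <- function(anchors, truths) {
  ah <- anchors[, 3] - anchors[, 1]; aw <- anchors[, 4] - anchors[, 2]
  acy <- (anchors[, 1] + anchors[, 3]) / 2
  acx <- (anchors[, 2] + anchors[, 4]) / 2
  th <- truths[, 3] - truths[, 1]; tw <- truths[, 4] - truths[, 2]
  tcy <- (truths[, 1] + truths[, 3]) / 2
  tcx <- (truths[, 2] + truths[, 4]) / 2
  cbind((tcy - acy) / ah, (tcx - acx) / aw, log(th / ah), log(tw / aw))
}

decode_boxes <- function(anchors, deltas) {
  ah <- anchors[, 3] - anchors[, 1]; aw <- anchors[, 4] - anchors[, 2]
  acy <- (anchors[, 1] + anchors[, 3]) / 2
  acx <- (anchors[, 2] + anchors[, 4]) / 2
  cy <- acy + deltas[, 1] * ah
  cx <- acx + deltas[, 2] * aw
  h <- ah * exp(pmin(pmax(deltas[, 3], -4), 4))
  w <- aw * exp(pmin(pmax(deltas[, 4], -4), 4))
  cbind(cy - h / 2, cx - w / 2, cy + h / 2, cx + w / 2)
}

clip_boxes <- function(boxes, H, W) {
  boxes[, 1] <- pmin(pmax(boxes[, 1], 0), H)
  boxes[, 2] <- pmin(pmax(boxes[, 2], 0), W)
  boxes[, 3] <- pmin(pmax(boxes[, 3], 0), H)
  boxes[, 4] <- pmin(pmax(boxes[, 4], 0), W)
  boxes
}

# Assign anchors to truth boxes: +1 positive, 0 negative, NA ignore.
assign_anchors <- function(anchor_boxes, truth_boxes, cfg, image_size) {
  n <- nrow(anchor_boxes)
  lab <- rep(NA_real_, n)
  matched <- rep(NA_integer_, n)
  inside <- anchor_boxes[, 1] >= -2 & anchor_boxes[, 2] >= -2 &
    anchor_boxes[, 3] <= image_size[1] + 2 &
    anchor_boxes[, 4] <= image_size[2] + 2
  if (is.null(truth_boxes) || nrow(truth_boxes) == 0) {
    lab[inside] <- 0
    return(list(label = lab, matched = matched))
  }
  iou <- box_iou_matrix(anchor_boxes, truth_boxes)
  best <- apply(iou, 1, max)
  lab[inside & best < cfg$neg_iou] <- 0
  pos <- best >= cfg$pos_iou
  # every truth owns its argmax anchor plus near-argmax anchors, so sparse
  # anchor grids still contribute several positives per instance
  for (t in seq_len(ncol(iou))) {
    bt <- max(iou[, t])
    pos[iou[, t] >= max(0.3, 0.85 * bt)] <- TRUE
    pos[which.max(iou[, t])] <- TRUE
  }
  lab[pos] <- 1
  matched[pos] <- apply(iou[pos, , drop = FALSE], 1, which.max)
  list(label = lab, matched = matched)
}

# ---- RoIAlign --------------------------------------------------------------

# Bilinear RoI alignment: `out` x `out` bin centres sampled from a pyramid
# feature map of the given stride. Returns out x out x C array.
roi_align <- function(feat, box, stride, out) {
  d <- dim(feat); H <- d[1]; W <- d[2]; C <- d[3]
  bh <- (box[3] - box[1]) / out; bw <- (box[4] - box[2]) / out
  r <- box[1] / stride - 0.5 + (seq_len(out) - 0.5) * bh / stride
  c <- box[2] / stride - 0.5 + (seq_len(out) - 0.5) * bw / stride
  r <- pmin(pmax(r, 0), H - 1); c <- pmin(pmax(c, 0), W - 1)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  fr <- rep(r - r0, times = out); fc <- rep(c - c0, each = out)
  # linear indices of the four corners for all out^2 samples, shared by all
  # channels through a channel-offset outer sum
  i00 <- rep(r0 + 1, times = out) + rep(c0 * H, each = out)
  i01 <- rep(r0 + 1, times = out) + rep(c1 * H, each = out)
  i10 <- rep(r1 + 1, times = out) + rep(c0 * H, each = out)
  i11 <- rep(r1 + 1, times = out) + rep(c1 * H, each = out)
  off <- rep((seq_len(C) - 1) * (H * W), each = out * out)
  v <- feat[i00 + off] * ((1 - fr) * (1 - fc)) +
    feat[i01 + off] * ((1 - fr) * fc) +
    feat[i10 + off] * (fr * (1 - fc)) +
    feat[i11 + off] * (fr * fc)
  array(v, c(out, out, C))
}

# Pyramid level for an RoI: the level whose anchor scale is closest to the
# RoI's side (sqrt of its area), FPN-style.
roi_level <- function(box, scales) {
  side <- sqrt(max(box[3] - box[1], 1) * max(box[4] - box[2], 1))
  which.min(abs(log(scales) - log(side)))
}
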