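# Training and inference of the compact detect-and-segment model.

# Spike-only global gradient-norm clipping: healthy gradients pass through,
# rare large mask/box gradients are rescaled before Adam sees them.
clip_grads <- function(grads, max_norm = 50) {
  tot <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(tot) && tot > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / tot))
  grads
}

param_groups <- function(params) {
  nms <- names(params)
  head <- grepl("^(head_|mask)", nms)
  list(rpn = nms[!head], heads = nms[head],
       mask = nms[grepl("^mask", nms)])
}

# Plain (no-tape) helpers used at inference time.
conv_plain <- function(x, Wm, b, kh, kw, stride = 1L, pad = 0L) {
  d <- dim(x)
  ii <- im2col_index(d[1], d[2], d[3], kh, kw, stride, pad)
  xp <- pad_array(x, pad)
  out <- sweep(matrix(xp[ii$idx], nrow(ii$idx)) %*% Wm, 2, b, "+")
  array(out, c(ii$H2, ii$W2, ncol(Wm)))
}

relu_plain <- function(x) x * (x > 0)

head_scores_plain <- function(params, roi_feats) {
  h <- relu_plain(sweep(roi_feats %*% params$head_fc1_W, 2,
                        params$head_fc1_b, "+"))
  h <- relu_plain(sweep(h %*% params$head_fc2_W, 2, params$head_fc2_b, "+"))
  logits <- sweep(h %*% params$head_cls_W, 2, params$head_cls_b, "+")
  deltas <- sweep(h %*% params$head_box_W, 2, params$head_box_b, "+")
  zm <- logits - apply(logits, 1, max)
  p <- exp(zm) / rowSums(exp(zm))
  list(score = p[, 2], deltas = deltas)
}

mask_head_plain <- function(params, feat) {
  x <- relu_plain(conv_plain(feat, params$mask1_W, params$mask1_b, 3, 3, pad = 1L))
  x <- relu_plain(conv_plain(x, params$mask2_W, params$mask2_b, 3, 3, pad = 1L))
  d <- dim(x)
  x <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
         drop = FALSE]
  x <- relu_plain(conv_plain(x, params$mask3_W, params$mask3_b, 3, 3, pad = 1L))
  x <- relu_plain(conv_plain(x, params$mask4_W, params$mask4_b, 3, 3, pad = 1L))
  logits <- conv_plain(x, params$mask_out_W, params$mask_out_b, 1, 1)
  1 / (1 + exp(-logits[, , 1]))
}

# Per-level linear indices of the RPN output elements behind each anchor row.
anchor_linear_index <- function(tab) {
  HlWl <- tab$Hl * tab$Wl
  obj <- tab$cell + (tab$anchor_var - 1L) * HlWl + 1L
  delta <- sapply(1:4, function(q)
    tab$cell + ((tab$anchor_var - 1L) * 4L + q - 1L) * HlWl + 1L)
  list(obj = obj, delta = delta)
}

# One RPN optimization step on one patch. Returns loss components.
rpn_step <- function(params, opt, img, truth_boxes, cfg, tabs) {
  tp <- tape_new()
  levels <- forward_rpn(tp, params, img, cfg)
  all_boxes <- do.call(rbind, lapply(tabs, `[[`, "boxes"))
  asg <- assign_anchors(all_boxes, truth_boxes, cfg, dim(img))
  pos <- which(!is.na(asg$label) & asg$label == 1)
  neg <- which(!is.na(asg$label) & asg$label == 0)
  if (length(pos) > 32) pos <- sample(pos, 32)
  n_neg <- min(length(neg), max(length(pos), 8))
  neg <- if (n_neg < length(neg)) sample(neg, n_neg) else neg
  sampled <- c(pos, neg)
  target <- c(rep(1, length(pos)), rep(0, length(neg)))

  offs <- cumsum(c(0, vapply(tabs, function(t) nrow(t$boxes), 1)))
  lin <- lapply(tabs, anchor_linear_index)
  lvl_of <- function(rows) findInterval(rows - 1, offs[-1]) + 1
  gather_obj <- function(rows) {
    ids <- integer(0); ord <- integer(0)
    for (li in seq_along(tabs)) {
      sel <- which(lvl_of(rows) == li)
      if (!length(sel)) next
      within <- rows[sel] - offs[li]
      ids <- c(ids, tp_gather(tp, levels[[li]]$obj, lin[[li]]$obj[within]))
      ord <- c(ord, sel)
    }
    list(node = tp_concat(tp, ids), order = ord)
  }
  g <- gather_obj(sampled)
  obj_loss <- tp_bce_logits(tp, g$node, target[g$order])

  losses <- list(obj_loss)
  box_loss_val <- 0
  if (length(pos) > 0) {
    ids <- list(); tgt <- NULL
    for (li in seq_along(tabs)) {
      sel <- which(lvl_of(pos) == li)
      if (!length(sel)) next
      within <- pos[sel] - offs[li]
      idx <- as.vector(t(lin[[li]]$delta[within, , drop = FALSE]))
      ids[[length(ids) + 1]] <- tp_gather(tp, levels[[li]]$delta, idx)
      tgt <- rbind(tgt, encode_boxes(
        all_boxes[pos[sel], , drop = FALSE],
        truth_boxes[asg$matched[pos[sel]], , drop = FALSE]))
    }
    box_loss <- tp_smooth_l1(tp, tp_concat(tp, unlist(ids)),
                             as.vector(t(tgt)), beta = 1 / 9)
    box_loss_val <- tp_value(tp, box_loss)
    losses <- c(losses, box_loss)
  }
  total <- tp_sum_nodes(tp, unlist(losses))
  grads <- clip_grads(tp_backward(tp, total))
  list(params = adam_step(opt, params, grads),
       obj = tp_value(tp, obj_loss), box = box_loss_val)
}

# Plain forward returning per-level features, objectness and deltas as arrays.
forward_plain <- function(params, img, cfg) {
  tp <- tape_new()
  levels <- forward_rpn(tp, params, img, cfg)
  lapply(levels, function(l) list(
    stride = l$stride,
    feat = tp_value(tp, l$feat),
    obj = tp_value(tp, l$obj),
    delta = tp_value(tp, l$delta)))
}

# Decode RPN outputs into scored proposal boxes.
rpn_proposals <- function(lv, cfg, tabs, image_size, top_k = NULL) {
  scores <- unlist(lapply(seq_along(tabs), function(li) {
    lin <- anchor_linear_index(tabs[[li]])
    as.vector(lv[[li]]$obj)[lin$obj]
  }))
  deltas <- do.call(rbind, lapply(seq_along(tabs), function(li) {
    lin <- anchor_linear_index(tabs[[li]])
    matrix(as.vector(lv[[li]]$delta)[as.vector(t(lin$delta))],
           ncol = 4, byrow = TRUE)
  }))
  all_boxes <- do.call(rbind, lapply(tabs, `[[`, "boxes"))
  scores <- 1 / (1 + exp(-scores))
  ord <- order(scores, decreasing = TRUE)[seq_len(min(600, length(scores)))]
  boxes <- clip_boxes(decode_boxes(all_boxes[ord, , drop = FALSE],
                                   deltas[ord, , drop = FALSE]),
                      image_size[1], image_size[2])
  sc <- scores[ord]
  okb <- (boxes[, 3] - boxes[, 1]) >= 2 & (boxes[, 4] - boxes[, 2]) >= 2
  boxes <- boxes[okb, , drop = FALSE]; sc <- sc[okb]
  keep <- nms(boxes, sc, cfg$rpn_nms_iou)
  keep <- keep[seq_len(min(top_k %||% cfg$proposals_kept, length(keep)))]
  list(boxes = boxes[keep, , drop = FALSE], scores = sc[keep])
}

roi_features <- function(lv, boxes, cfg, out) {
  n <- nrow(boxes)
  D <- cfg$fpn_channels
  res <- array(0, c(n, out * out * D))
  for (i in seq_len(n)) {
    li <- roi_level(boxes[i, ], cfg$anchor_scales)
    res[i, ] <- as.vector(roi_align(lv[[li]]$feat, boxes[i, ],
                                    lv[[li]]$stride, out))
  }
  res
}

# Binary 28 x 28 mask target: the matched instance inside the RoI box.
mask_target <- function(lab_map, box, truth_id, out = 28) {
  bh <- (box[3] - box[1]) / out; bw <- (box[4] - box[2]) / out
  pr <- pmin(pmax(floor(box[1] + (seq_len(out) - 0.5) * bh), 0),
             nrow(lab_map) - 1) + 1
  pc <- pmin(pmax(floor(box[2] + (seq_len(out) - 0.5) * bw), 0),
             ncol(lab_map) - 1) + 1
  matrix(as.numeric(lab_map[pr, pc] == truth_id), out, out)
}

# One optimization step of the detection + mask heads on one patch. The mask
# convolutions get their own optimizer (lower learning rate) because their
# loss surface is steeper than the fully connected heads'.
head_step <- function(params, opt, opt_mask, cache, cfg) {
  truth <- cache$truth_boxes
  # a few random boxes per step keep the background class diverse
  shp <- dim(cache$lab_map)
  rnd <- t(vapply(seq_len(4), function(i) {
    h <- stats::runif(1, 8, 0.6 * shp[1]); w <- stats::runif(1, 8, 0.6 * shp[2])
    r0 <- stats::runif(1, 0, shp[1] - h); c0 <- stats::runif(1, 0, shp[2] - w)
    c(r0, c0, r0 + h, c0 + w)
  }, numeric(4)))
  cand <- rbind(cache$proposals, truth, cache$jitter, rnd)
  n_t <- if (is.null(truth)) 0 else nrow(truth)
  if (n_t > 0) {
    iou <- box_iou_matrix(cand, truth)
    best <- apply(iou, 1, max)
    fg <- which(best >= 0.5); bg <- which(best < 0.5)
    matched <- apply(iou, 1, which.max)
  } else {
    fg <- integer(0); bg <- seq_len(nrow(cand)); matched <- integer(0)
  }
  if (length(fg) > 12) fg <- sample(fg, 12)
  if (length(bg) > 12) bg <- sample(bg, 12)
  rois <- c(fg, bg)
  if (length(rois) == 0) return(list(params = params, cls = NA, box = NA, mask = NA))
  boxes <- cand[rois, , drop = FALSE]
  cls_target <- c(rep(2L, length(fg)), rep(1L, length(bg)))  # 2 = nucleus

  feats <- roi_features(cache$lv, boxes, cfg, cfg$roi_align_detect)
  tp <- tape_new()
  leaf <- function(nm) tp_leaf(tp, params[[nm]], nm)
  x <- tp_leaf(tp, feats)
  h <- tp_relu(tp, tp_fc(tp, x, leaf("head_fc1_W"), leaf("head_fc1_b")))
  h <- tp_relu(tp, tp_fc(tp, h, leaf("head_fc2_W"), leaf("head_fc2_b")))
  cls <- tp_fc(tp, h, leaf("head_cls_W"), leaf("head_cls_b"))
  cls_loss <- tp_softmax_ce(tp, cls, cls_target)
  losses <- list(cls_loss)
  box_val <- NA; mask_val <- NA

  if (length(fg) > 0) {
    box <- tp_fc(tp, h, leaf("head_box_W"), leaf("head_box_b"))
    fg_rows <- seq_along(fg)
    idx <- as.vector(vapply(fg_rows, function(r)
      r + (0:3) * length(rois), numeric(4)))
    tgt <- encode_boxes(boxes[fg_rows, , drop = FALSE],
                        truth[matched[fg], , drop = FALSE])
    box_loss <- tp_smooth_l1(tp, tp_gather(tp, box, idx),
                             as.vector(t(tgt)), beta = 1)
    box_val <- tp_value(tp, box_loss)
    losses <- c(losses, box_loss)

    ml <- list()
    for (k in seq_len(min(4, length(fg)))) {
      b <- boxes[k, ]
      li <- roi_level(b, cfg$anchor_scales)
      mf <- roi_align(cache$lv[[li]]$feat, b, cache$lv[[li]]$stride,
                      cfg$roi_align_mask)
      mx <- tp_leaf(tp, mf)
      mx <- tp_relu(tp, tp_conv2d(tp, mx, leaf("mask1_W"), leaf("mask1_b"),
                                  3, 3, pad = 1L))
      mx <- tp_relu(tp, tp_conv2d(tp, mx, leaf("mask2_W"), leaf("mask2_b"),
                                  3, 3, pad = 1L))
      mx <- tp_upsample2x(tp, mx)
      mx <- tp_relu(tp, tp_conv2d(tp, mx, leaf("mask3_W"), leaf("mask3_b"),
                                  3, 3, pad = 1L))
      mx <- tp_relu(tp, tp_conv2d(tp, mx, leaf("mask4_W"), leaf("mask4_b"),
                                  3, 3, pad = 1L))
      mx <- tp_conv2d(tp, mx, leaf("mask_out_W"), leaf("mask_out_b"), 1, 1)
      tgtm <- mask_target(cache$lab_map, b, matched[fg[k]],
                          2 * cfg$roi_align_mask)
      ml[[k]] <- tp_bce_logits(tp, mx, as.vector(tgtm))
    }
    mask_loss <- tp_scale(tp, tp_sum_nodes(tp, unlist(ml)), 1 / length(ml))
    mask_val <- tp_value(tp, mask_loss)
    losses <- c(losses, mask_loss)
  }
  total <- tp_sum_nodes(tp, unlist(losses))
  grads <- clip_grads(tp_backward(tp, total))
  is_mask <- grepl("^mask", names(grads))
  params <- adam_step(opt, params, grads[!is_mask])
  if (any(is_mask)) params <- adam_step(opt_mask, params, grads[is_mask])
  list(params = params,
       cls = tp_value(tp, cls_loss), box = box_val, mask = mask_val)
}

#' Train the compact detect-and-segment model
#'
#' Two-phase alternating optimization: first the backbone, pyramid and region
#' proposal network are trained with objectness cross-entropy plus smooth-L1
#' anchor-box regression; then the detection head (softmax classification +
#' smooth-L1 box refinement) and the fully convolutional mask head (binary
#' cross-entropy, positive regions only) are trained on RoI-aligned features
#' from the frozen pyramid. All five loss components are traced per epoch.
#' Fully deterministic given `cfg$seed`.
#'
#' @param patches list of `list(image = <matrix>, labels =
#'   <instance_mask_set>)`; images must share a common shape divisible by the
#'   largest pyramid stride. Labels may be empty on individual patches.
#' @param cfg a [train_config()].
#' @return a `nucseg_model`: list with `params`, `cfg` and `trace` (data.frame
#'   of per-epoch mean losses).
#' @export
train_detector <- function(patches, cfg = train_config()) {
  stopifnot(length(patches) >= 1)
  shp <- dim(patches[[1]]$image)
  ms <- max(cfg$anchor_scales) / 2
  for (p in patches) {
    if (!all(dim(p$image) == shp))
      stop("train_detector: all patches must share one shape")
    if (!all(p$labels$shape == shp))
      stop("train_detector: image/label shape mismatch")
  }
  if (any(shp %% ms != 0))
    stop("train_detector: patch shape must be divisible by the largest ",
         "pyramid stride (", ms, ")")
  n_inst <- vapply(patches, function(p) length(p$labels$masks), 1L)
  if (all(n_inst == 0))
    stop("train_detector: every label set is empty; nothing to learn")

  with_seed(cfg$seed, {
    params <- init_params(cfg)
    tabs <- level_anchor_table(cfg, shp)
    groups <- param_groups(params)
    trace <- list()

    opt_a <- adam_new(params[groups$rpn], lr = cfg$lr)
    for (ep in seq_len(cfg$epochs_rpn)) {
      if (ep > 0.7 * cfg$epochs_rpn) opt_a$lr <- cfg$lr * 0.3
      ord <- sample(length(patches))
      obj <- box <- numeric(0)
      for (i in ord) {
        p <- patches[[i]]
        tb <- if (length(p$labels$masks)) p$labels$boxes else NULL
        st <- rpn_step(params, opt_a, normalize_minmax(p$image), tb, cfg, tabs)
        params <- st$params
        obj <- c(obj, st$obj); box <- c(box, st$box)
      }
      trace[[length(trace) + 1]] <- data.frame(
        epoch = ep, phase = "rpn", rpn_obj = mean(obj), rpn_box = mean(box),
        cls = NA, box = NA, mask = NA,
        total = mean(obj) + mean(box))
    }

    # cache frozen features, proposals and mask targets per patch
    caches <- lapply(patches, function(p) {
      img <- normalize_minmax(p$image)
      lv <- forward_plain(params, img, cfg)
      pr <- rpn_proposals(lv, cfg, tabs, shp)
      tb <- if (length(p$labels$masks)) p$labels$boxes else NULL
      jit <- NULL
      if (!is.null(tb)) {
        jit <- tb + matrix(stats::rnorm(length(tb), 0, 2), nrow(tb), 4)
        jit <- clip_boxes(jit, shp[1], shp[2])
        ok <- (jit[, 3] - jit[, 1]) >= 2 & (jit[, 4] - jit[, 2]) >= 2
        jit <- jit[ok, , drop = FALSE]
      }
      list(lv = lv, proposals = pr$boxes, truth_boxes = tb, jitter = jit,
           lab_map = as_label_map(p$labels))
    })

    opt_b <- adam_new(params[setdiff(groups$heads, groups$mask)],
                      lr = cfg$lr / 2)
    opt_m <- adam_new(params[groups$mask], lr = cfg$lr / 5)
    for (ep in seq_len(cfg$epochs_heads)) {
      if (ep > 0.7 * cfg$epochs_heads) {
        opt_b$lr <- cfg$lr * 0.1
        opt_m$lr <- cfg$lr * 0.04
      }
      ord <- sample(length(patches))
      cl <- bx <- mk <- numeric(0)
      for (i in ord) {
        st <- head_step(params, opt_b, opt_m, caches[[i]], cfg)
        params <- st$params
        cl <- c(cl, st$cls); bx <- c(bx, st$box); mk <- c(mk, st$mask)
      }
      trace[[length(trace) + 1]] <- data.frame(
        epoch = cfg$epochs_rpn + ep, phase = "heads",
        rpn_obj = NA, rpn_box = NA,
        cls = mean(cl, na.rm = TRUE), box = mean(bx, na.rm = TRUE),
        mask = mean(mk, na.rm = TRUE),
        total = mean(cl, na.rm = TRUE) + mean(bx, na.rm = TRUE) +
          mean(mk, na.rm = TRUE))
    }

    structure(list(params = params, cfg = cfg,
                   trace = do.call(rbind, trace)),
              class = "nucseg_model")
  })
}

#' @export
print.nucseg_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1))
  cat(sprintf("<nucseg_model: %d parameters, %d anchor scale(s), trained %d epochs>\n",
              np, length(x$cfg$anchor_scales), nrow(x$trace)))
  invisible(x)
}

#' Detect and segment nuclei in one phase-contrast patch
#'
#' Runs the pyramid + region-proposal forward pass, scores proposals with the
#' detection head, discards detections below `score_threshold`, refines the
#' surviving boxes, applies non-max suppression and attaches a 28 x 28 float
#' mask per detection.
#'
#' @param model a trained [train_detector()] model.
#' @param img phase-contrast patch (numeric matrix); padded internally if its
#'   shape is not divisible by the largest pyramid stride.
#' @param score_threshold prediction-score cutoff (default from the model
#'   config, 0.9).
#' @return list of [detection()] objects in descending score order.
#' @export
predict_detections <- function(model, img,
                               score_threshold = model$cfg$score_threshold) {
  cfg <- model$cfg
  x <- normalize_minmax(img)
  ms <- max(cfg$anchor_scales) / 2
  H <- nrow(x); W <- ncol(x)
  H2 <- as.integer(ceiling(H / ms) * ms); W2 <- as.integer(ceiling(W / ms) * ms)
  if (H2 != H || W2 != W) {
    xp <- matrix(0, H2, W2); xp[seq_len(H), seq_len(W)] <- x
    x <- xp
  }
  lv <- forward_plain(model$params, x, cfg)
  tabs <- level_anchor_table(cfg, c(H2, W2))
  pr <- rpn_proposals(lv, cfg, tabs, c(H, W))
  if (nrow(pr$boxes) == 0) return(list())
  feats <- roi_features(lv, pr$boxes, cfg, cfg$roi_align_detect)
  hs <- head_scores_plain(model$params, feats)
  keep <- which(hs$score >= score_threshold)
  if (length(keep) == 0) return(list())
  boxes <- clip_boxes(decode_boxes(pr$boxes[keep, , drop = FALSE],
                                   hs$deltas[keep, , drop = FALSE]), H, W)
  sc <- hs$score[keep]
  ok <- (boxes[, 3] - boxes[, 1]) >= 2 & (boxes[, 4] - boxes[, 2]) >= 2
  boxes <- boxes[ok, , drop = FALSE]; sc <- sc[ok]
  if (nrow(boxes) == 0) return(list())
  kept <- nms(boxes, sc, cfg$nms_iou)
  kept <- kept[seq_len(min(100, length(kept)))]
  lapply(kept, function(i) {
    b <- boxes[i, ]
    li <- roi_level(b, cfg$anchor_scales)
    mf <- roi_align(lv[[li]]$feat, b, lv[[li]]$stride, cfg$roi_align_mask)
    soft <- mask_head_plain(model$params, mf)
    detection(b, sc[i], soft)
  })
}

#' Serialize a trained model to disk
#' @param model a `nucseg_model`.
#' @param path output file.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' Read a model written by [write_model()]
#' @param path model file.
#' @return a `nucseg_model`.
#' @export
read_model <- function(path) readRDS(path)
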