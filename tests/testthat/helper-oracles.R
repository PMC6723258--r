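# Independent reference implementations used as test oracles. These are kept
# deliberately naive (enumeration, exhaustive search) and share no code with
# the package internals they check.

# Exhaustive one-to-one matching: maximum number of (label, prediction) pairs
# with IoU > t among all assignments (labels and predictions <= 10).
oracle_max_matching <- function(iou, t) {
  nl <- nrow(iou); np <- ncol(iou)
  if (nl == 0 || np == 0) return(0L)
  ok <- iou > t
  best <- 0L
  recurse <- function(l, used) {
    if (l > nl) return(0L)
    res <- recurse(l + 1, used)            # leave label l unmatched
    for (p in seq_len(np)) {
      if (!used[p] && ok[l, p]) {
        used2 <- used; used2[p] <- TRUE
        res <- max(res, 1L + recurse(l + 1, used2))
      }
    }
    res
  }
  recurse(1L, rep(FALSE, np))
}

# Pixel-set IoU computed naively from logical matrices.
oracle_mask_iou <- function(a, b) {
  i <- sum(a & b); u <- sum(a | b)
  if (u == 0) 1 else i / u
}

# Brute-force per-image AP: every distinct score threshold, exhaustive
# matching, running-max precision interpolation at 101 fixed recall levels.
oracle_ap_image <- function(labels_mats, preds_mats, scores, t_iou) {
  if (length(preds_mats) == 0)
    return(if (length(labels_mats) == 0) 1 else 0)
  iou_all <- matrix(0, length(labels_mats), length(preds_mats))
  for (i in seq_along(labels_mats)) for (j in seq_along(preds_mats))
    iou_all[i, j] <- oracle_mask_iou(labels_mats[[i]], preds_mats[[j]])
  thr <- sort(unique(scores))
  prec <- rec <- numeric(length(thr))
  for (k in seq_along(thr)) {
    keep <- which(scores >= thr[k])
    tp <- oracle_max_matching(iou_all[, keep, drop = FALSE], t_iou)
    fp <- length(keep) - tp
    fn <- length(labels_mats) - tp
    prec[k] <- if (tp + fp == 0) 1 else tp / (tp + fp)
    rec[k] <- if (tp + fn == 0) 1 else tp / (tp + fn)
  }
  rlev <- seq(0, 1, by = 0.01)
  mean(vapply(rlev, function(r) {
    ok <- rec >= r
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1)))
}

# Exhaustive Otsu threshold: argmax of between-class variance over the 256
# histogram bin edges.
oracle_otsu_threshold <- function(x, levels = 256) {
  br <- seq(0, 1, length.out = levels + 1)
  h <- hist(x, breaks = br, plot = FALSE)$counts
  centers <- (br[-1] + br[-(levels + 1)]) / 2
  n <- sum(h); best <- -1; bt <- 0
  for (k in seq_len(levels - 1)) {
    w0 <- sum(h[1:k]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:k] * centers[1:k]) / w0
    m1 <- sum(h[(k + 1):levels] * centers[(k + 1):levels]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; bt <- br[k + 1] }
  }
  bt
}

# Greedy NMS re-implemented directly from its definition.
oracle_nms <- function(boxes, scores, t) {
  ord <- order(scores, decreasing = TRUE)
  kept <- integer(0)
  biou <- function(a, b) {
    ih <- min(a[3], b[3]) - max(a[1], b[1])
    iw <- min(a[4], b[4]) - max(a[2], b[2])
    if (ih <= 0 || iw <= 0) return(0)
    i <- ih * iw
    i / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - i)
  }
  for (i in ord) {
    sup <- FALSE
    for (k in kept) if (biou(boxes[i, ], boxes[k, ]) > t) { sup <- TRUE; break }
    if (!sup) kept <- c(kept, i)
  }
  kept
}

# Random small instance scenes: a few blob masks on a tiny grid plus scored
# predictions that are jittered copies (some dropped, some spurious), shaped
# like realistic detector output.
random_eval_scene <- function(seed, grid = 48, max_inst = 6) {
  set.seed(seed)
  n <- sample(0:max_inst, 1)
  mk_blob <- function(cr, cc, rad) {
    r <- matrix(seq_len(grid), grid, grid)
    c <- t(r)
    (r - cr)^2 + (c - cc)^2 <= rad^2
  }
  labels <- list()
  centers <- NULL
  for (i in seq_len(n)) {
    for (try in 1:50) {
      cr <- runif(1, 8, grid - 8); cc <- runif(1, 8, grid - 8)
      if (is.null(centers) ||
          min(sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2)) > 10) break
    }
    centers <- rbind(centers, c(cr, cc))
    labels[[i]] <- mk_blob(cr, cc, runif(1, 3.5, 6))
  }
  preds <- list(); scores <- numeric(0)
  for (i in seq_along(labels)) {
    if (runif(1) < 0.85) {   # detected, jittered
      preds[[length(preds) + 1]] <-
        mk_blob(centers[i, 1] + rnorm(1, 0, 1.5),
                centers[i, 2] + rnorm(1, 0, 1.5), runif(1, 3.5, 6))
      scores <- c(scores, runif(1, 0.5, 1))
    }
  }
  for (k in seq_len(rpois(1, 0.7))) {  # spurious
    preds[[length(preds) + 1]] <-
      mk_blob(runif(1, 8, grid - 8), runif(1, 8, grid - 8), runif(1, 3, 5))
    scores <- c(scores, runif(1, 0.05, 0.6))
  }
  keep <- vapply(preds, any, TRUE)
  preds <- preds[keep]; scores <- scores[keep]
  labels <- labels[vapply(labels, any, TRUE)]
  list(labels = labels, preds = preds, scores = scores, grid = grid)
}

scene_to_sets <- function(sc) {
  lab <- instance_mask_set(c(sc$grid, sc$grid), lapply(sc$labels, which))
  pred <- if (length(sc$preds))
    instance_mask_set(c(sc$grid, sc$grid), lapply(sc$preds, which), sc$scores)
  else instance_mask_set(c(sc$grid, sc$grid), list())
  list(labels = lab, preds = pred)
}
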