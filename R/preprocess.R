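#' Upsample an image by a factor of 2
#'
#' Bilinear interpolation with the align-corners convention: the output grid
#' maps linearly onto the input grid so corner samples coincide and affine
#' intensity ramps are reproduced exactly. Label maps must use
#' `method = "nearest"` so instance identities are never blended.
#'
#' @param img numeric matrix (intensity image or integer label map).
#' @param method `"bilinear"` (images) or `"nearest"` (label maps).
#' @return matrix of shape `(2H, 2W)`.
#' @export
upsample2x <- function(img, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot_image(img)
  H <- nrow(img); W <- ncol(img)
  rr <- if (H == 1) rep(0, 2) else seq(0, H - 1, length.out = 2 * H)
  cc <- if (W == 1) rep(0, 2) else seq(0, W - 1, length.out = 2 * W)
  if (method == "nearest") {
    out <- img[round(rr) + 1, round(cc) + 1, drop = FALSE]
    storage.mode(out) <- storage.mode(img)
    return(out)
  }
  grid_r <- matrix(rr, 2 * H, 2 * W)
  grid_c <- matrix(rep(cc, each = 2 * H), 2 * H, 2 * W)
  matrix(bilinear_sample(img, grid_r, grid_c), 2 * H, 2 * W)
}

#' Tile a frame into fixed-size patches
#'
#' Row-major grid of patch origins with the given stride; when the frame size
#' is not an exact multiple, the last origin in each dimension is shifted so
#' the final patch ends exactly at the frame edge (patches may then overlap).
#'
#' @param frame_shape integer (H, W) of the (upsampled) frame, or a matrix
#'   whose dimensions are used.
#' @param patch_size patch side length in pixels (default 512).
#' @param stride step between patch origins in pixels (default `patch_size`).
#' @return a `patch_grid`: list with `frame_shape`, `patch_size`, `stride` and
#'   `origins` (n x 2 matrix of 0-based (row, col) top-left corners).
#' @export
tile_patches <- function(frame_shape, patch_size = 512, stride = patch_size) {
  if (is.matrix(frame_shape)) frame_shape <- dim(frame_shape)
  frame_shape <- as.integer(frame_shape)
  if (stride <= 0) stop("tile_patches: stride must be positive")
  if (any(frame_shape < patch_size))
    stop("tile_patches: patch_size exceeds the frame size")
  starts <- function(L) {
    s <- seq(0L, L - patch_size, by = as.integer(stride))
    if (s[length(s)] != L - patch_size) s <- c(s, L - patch_size)
    s
  }
  sr <- starts(frame_shape[1]); sc <- starts(frame_shape[2])
  origins <- cbind(rep(sr, each = length(sc)), rep(sc, times = length(sr)))
  colnames(origins) <- c("r0", "c0")
  structure(list(frame_shape = frame_shape,
                 patch_size = as.integer(patch_size),
                 stride = as.integer(stride), origins = origins),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid: %d patch(es) of %d px, stride %d, frame %d x %d>\n",
              nrow(x$origins), x$patch_size, x$stride,
              x$frame_shape[1], x$frame_shape[2]))
  invisible(x)
}

#' Extract one patch from a frame
#' @param img frame matrix.
#' @param origin 0-based (row, col) of the patch top-left corner.
#' @param patch_size patch side length.
#' @return `patch_size` x `patch_size` matrix.
#' @export
extract_patch <- function(img, origin, patch_size) {
  img[origin[1] + seq_len(patch_size), origin[2] + seq_len(patch_size),
      drop = FALSE]
}

#' Restrict instance labels to a patch
#'
#' Instances clipped by the patch border are kept only if at least
#' `keep_fraction` of their area lies inside the patch; coordinates are
#' re-expressed relative to the patch origin.
#'
#' @param labels an [instance_mask_set()] in frame coordinates.
#' @param origin 0-based patch top-left corner.
#' @param patch_size patch side length.
#' @param keep_fraction minimum inside-area fraction (default 0.5).
#' @return an `instance_mask_set` on the patch grid.
#' @export
crop_labels_to_patch <- function(labels, origin, patch_size,
                                 keep_fraction = 0.5) {
  H <- labels$shape[1]
  masks <- list()
  for (px in labels$masks) {
    r <- (px - 1L) %% H - origin[1]       # 0-based patch row
    c <- (px - 1L) %/% H - origin[2]
    inside <- r >= 0 & r < patch_size & c >= 0 & c < patch_size
    if (sum(inside) == 0 || sum(inside) / length(px) < keep_fraction) next
    masks[[length(masks) + 1]] <-
      as.integer(c[inside] * patch_size + r[inside] + 1L)
  }
  instance_mask_set(c(patch_size, patch_size), masks)
}

#' One predicted instance
#'
#' @param box half-open pixel box `(r0, c0, r1, c1)`, 0-based.
#' @param score prediction score in `[0, 1]`.
#' @param soft_mask float mask in `[0, 1]` (28 x 28 by default) covering the
#'   box; materialized to pixels by [detection_mask()].
#' @return a `detection`.
#' @export
detection <- function(box, score, soft_mask = NULL) {
  box <- as.numeric(box)
  if ((box[3] - box[1]) <= 0 || (box[4] - box[2]) <= 0)
    stop("detection: box area must be positive")
  stopifnot(score >= 0, score <= 1)
  if (!is.null(soft_mask))
    stopifnot(min(soft_mask) >= -1e-9, max(soft_mask) <= 1 + 1e-9)
  structure(list(box = box, score = as.numeric(score), soft_mask = soft_mask),
            class = "detection")
}

#' Materialize a detection's soft mask as pixel indices on a frame grid
#'
#' The soft mask is resized to the detection box with bilinear weights and
#' thresholded.
#'
#' @param det a [detection()].
#' @param shape frame (H, W).
#' @param threshold binarization threshold on the float mask (default 0.5).
#' @return integer vector of linear pixel indices (possibly empty).
#' @export
detection_mask <- function(det, shape, threshold = 0.5) {
  b <- det$box
  r0 <- max(0, floor(b[1])); r1 <- min(shape[1], ceiling(b[3]))
  c0 <- max(0, floor(b[2])); c1 <- min(shape[2], ceiling(b[4]))
  if (r1 <= r0 || c1 <= c0 || is.null(det$soft_mask)) return(integer(0))
  mh <- nrow(det$soft_mask); mw <- ncol(det$soft_mask)
  rows <- (seq(r0, r1 - 1) + 0.5 - b[1]) / (b[3] - b[1]) * mh - 0.5
  cols <- (seq(c0, c1 - 1) + 0.5 - b[2]) / (b[4] - b[2]) * mw - 0.5
  gr <- matrix(rows, length(rows), length(cols))
  gc <- matrix(rep(cols, each = length(rows)), length(rows), length(cols))
  vals <- bilinear_sample(det$soft_mask, gr, gc)
  on <- which(matrix(vals, length(rows), length(cols)) > threshold)
  if (length(on) == 0) return(integer(0))
  pr <- (on - 1L) %% length(rows) + r0      # 0-based frame rows
  pc <- (on - 1L) %/% length(rows) + c0
  as.integer(pc * shape[1] + pr + 1L)
}

#' Convert detections to a scored instance mask set
#'
#' The returned set keeps the detections' own (refined, clipped) boxes rather
#' than re-deriving boxes from the binarized masks, so box-mode evaluation
#' scores the detector's localization and mask-mode evaluation its
#' segmentation, independently.
#'
#' @param dets list of [detection()].
#' @param shape frame (H, W).
#' @param threshold soft-mask binarization threshold.
#' @return an [instance_mask_set()] with scores; detections whose binarized
#'   mask is empty fall back to their (rounded) box as the mask.
#' @export
detections_to_mask_set <- function(dets, shape, threshold = 0.5) {
  masks <- list(); scores <- numeric(0); boxes <- NULL
  for (d in dets) {
    px <- detection_mask(d, shape, threshold)
    if (length(px) == 0) {
      b <- round(d$box)
      rs <- max(0, b[1]):(min(shape[1], b[3]) - 1)
      cs <- max(0, b[2]):(min(shape[2], b[4]) - 1)
      if (length(rs) == 0 || length(cs) == 0) next
      px <- as.integer(outer(rs + 1, cs * shape[1], "+"))
    }
    masks[[length(masks) + 1]] <- px
    scores <- c(scores, d$score)
    boxes <- rbind(boxes, pmin(pmax(d$box, 0), c(shape, shape)))
  }
  ms <- instance_mask_set(shape, masks, if (length(scores)) scores else NULL)
  if (!is.null(boxes)) {
    colnames(boxes) <- c("r0", "c0", "r1", "c1")
    ms$boxes <- boxes
  }
  ms
}

#' Stitch per-patch detections back to frame coordinates
#'
#' Boxes and masks are translated by their patch origin; duplicates across
#' overlapping patches are removed by score-ranked non-max suppression on
#' boxes. Optionally rescales coordinates by 1/2 back to the raw (pre-
#' upsampling) frame.
#'
#' @param grid a [tile_patches()] grid.
#' @param per_patch list (aligned with `grid$origins`) of lists of
#'   [detection()] in patch coordinates.
#' @param nms_iou IoU above which the lower-scored duplicate is dropped.
#' @param rescale coordinate scale applied after translation (1 = stay in the
#'   upsampled frame, 0.5 = back to the raw frame).
#' @return list of [detection()] in frame coordinates, descending score.
#' @export
stitch_detections <- function(grid, per_patch, nms_iou = 0.5, rescale = 1) {
  stopifnot(inherits(grid, "patch_grid"),
            length(per_patch) == nrow(grid$origins))
  all_dets <- list()
  for (i in seq_along(per_patch)) {
    o <- grid$origins[i, ]
    for (d in per_patch[[i]]) {
      if (any(d$box < -1e-9) || any(d$box[c(1, 3)] > grid$patch_size + 1e-9) ||
          any(d$box[c(2, 4)] > grid$patch_size + 1e-9))
        stop("stitch_detections: detection box outside its patch bounds")
      b <- (d$box + c(o[1], o[2], o[1], o[2])) * rescale
      all_dets[[length(all_dets) + 1]] <- detection(b, d$score, d$soft_mask)
    }
  }
  if (length(all_dets) == 0) return(all_dets)
  boxes <- do.call(rbind, lapply(all_dets, `[[`, "box"))
  scores <- vapply(all_dets, `[[`, numeric(1), "score")
  keep <- nms(boxes, scores, nms_iou)
  all_dets[keep]
}
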