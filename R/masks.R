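#' Instance mask sets
#'
#' An `instance_mask_set` holds a collection of per-instance binary masks over a
#' common image grid, together with the tight axis-aligned bounding box of each
#' mask and optional per-instance confidence scores. It is the common currency
#' between the label generator (labelled sets), the detector (predicted sets)
#' and the evaluation metrics.
#'
#' Masks are stored as integer vectors of 1-based linear pixel indices
#' (column-major, as R matrices are laid out). Boxes are half-open pixel boxes
#' `[r0, r1) x [c0, c1)` in 0-based row/column coordinates, stored as rows
#' `(r0, c0, r1, c1)`.
#'
#' @param shape integer (H, W) of the common grid.
#' @param masks list of integer vectors of linear pixel indices, one per
#'   instance; every mask must be non-empty.
#' @param scores optional numeric vector in `[0, 1]`, one score per instance.
#' @return an object of class `instance_mask_set` with elements `shape`,
#'   `masks`, `boxes` (n x 4 matrix) and `scores` (numeric or `NULL`).
#' @export
instance_mask_set <- function(shape, masks = list(), scores = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2, all(shape > 0))
  masks <- lapply(masks, function(m) sort(unique(as.integer(m))))
  if (any(vapply(masks, length, 1L) == 0L))
    stop("instance_mask_set: every mask must be non-empty")
  npix <- prod(shape)
  for (m in masks)
    if (length(m) && (m[1] < 1L || m[length(m)] > npix))
      stop("instance_mask_set: mask pixel index out of bounds")
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(masks))
    if (length(scores) && (min(scores) < 0 || max(scores) > 1))
      stop("instance_mask_set: scores must lie in [0, 1]")
  }
  structure(
    list(shape = shape, masks = masks,
         boxes = mask_boxes(masks, shape), scores = scores),
    class = "instance_mask_set")
}

#' @export
length.instance_mask_set <- function(x) length(x$masks)

#' @export
print.instance_mask_set <- function(x, ...) {
  cat(sprintf("<instance_mask_set: %d instance(s) on a %d x %d grid%s>\n",
              length(x$masks), x$shape[1], x$shape[2],
              if (is.null(x$scores)) "" else ", scored"))
  invisible(x)
}

# Tight half-open boxes (r0, c0, r1, c1), 0-based, for a list of pixel-index masks.
mask_boxes <- function(masks, shape) {
  H <- shape[1]
  out <- matrix(0, nrow = length(masks), ncol = 4,
                dimnames = list(NULL, c("r0", "c0", "r1", "c1")))
  for (i in seq_along(masks)) {
    r <- (masks[[i]] - 1L) %% H        # 0-based row
    c <- (masks[[i]] - 1L) %/% H       # 0-based col
    out[i, ] <- c(min(r), min(c), max(r) + 1L, max(c) + 1L)
  }
  out
}

#' Convert an instance mask set to an integer label map
#'
#' Background is 0; instance `k` is written as value `k`. When masks overlap
#' (predictions may), later instances overwrite earlier ones.
#'
#' @param x an `instance_mask_set`.
#' @return an integer matrix of the set's grid shape.
#' @export
as_label_map <- function(x) {
  stopifnot(inherits(x, "instance_mask_set"))
  lab <- matrix(0L, x$shape[1], x$shape[2])
  for (i in seq_along(x$masks)) lab[x$masks[[i]]] <- i
  lab
}

#' Build an instance mask set from an integer label map
#'
#' @param lab integer matrix; 0 is background, each positive value one instance.
#' @param scores optional scores aligned with the sorted unique positive labels.
#' @return an `instance_mask_set`.
#' @export
mask_set_from_label_map <- function(lab, scores = NULL) {
  ids <- sort(unique(lab[lab > 0]))
  masks <- lapply(ids, function(k) which(lab == k))
  instance_mask_set(dim(lab), masks, scores)
}

# Logical matrix for one instance (used by tests and mask resampling).
mask_as_matrix <- function(x, i) {
  m <- matrix(FALSE, x$shape[1], x$shape[2])
  m[x$masks[[i]]] <- TRUE
  m
}

# Subset instances, keeping boxes/scores aligned. Boxes are carried over
# rather than recomputed: prediction sets may carry detector boxes that are
# not the tight bounds of their binarized masks.
mask_set_subset <- function(x, idx) {
  out <- instance_mask_set(x$shape, x$masks[idx],
                           if (is.null(x$scores)) NULL else x$scores[idx])
  out$boxes <- x$boxes[idx, , drop = FALSE]
  out
}
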