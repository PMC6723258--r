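#' Parameters of the blob-detection label generator
#'
#' @param erosion_degree number of single-pixel erosions (`E`) applied to each
#'   generated instance mask to counteract the fluorescence halo.
#' @param diameter_range expected full nucleus diameter range in pixels; used
#'   to derive the default LoG sigma range.
#' @param log_sigma_range (min, max) LoG standard deviations in pixels;
#'   defaults to `diameter_range / (2 * sqrt(2))` (a blob of radius r peaks at
#'   sigma = r / sqrt(2)).
#' @param n_sigma number of sigma levels (geometric spacing).
#' @param log_threshold minimum scale-normalized LoG response for a seed, on
#'   min-max normalized images.
#' @param min_instance_area instances below this pixel area are dropped after
#'   erosion (and foreground specks below it are ignored).
#' @param structuring_element `"disk"` (radius-1 city-block disk, a 3x3 cross)
#'   or `"square"` (3x3 box), applied `erosion_degree` times.
#' @return a `blob_params` list.
#' @export
blob_params <- function(erosion_degree = 4, diameter_range = c(20, 60),
                        log_sigma_range = diameter_range / (2 * sqrt(2)),
                        n_sigma = 6, log_threshold = 0.05,
                        min_instance_area = 25,
                        structuring_element = c("disk", "square")) {
  structuring_element <- match.arg(structuring_element)
  stopifnot(erosion_degree >= 0, log_sigma_range[1] <= log_sigma_range[2],
            min_instance_area >= 1, n_sigma >= 1, log_threshold >= 0)
  structure(list(erosion_degree = as.integer(erosion_degree),
                 diameter_range = as.numeric(diameter_range),
                 log_sigma_range = as.numeric(log_sigma_range),
                 n_sigma = as.integer(n_sigma),
                 log_threshold = as.numeric(log_threshold),
                 min_instance_area = as.numeric(min_instance_area),
                 structuring_element = structuring_element),
            class = "blob_params")
}

#' Min-max normalize an image to [0, 1]
#'
#' `(img - min) / (max - min)`; a constant image maps to all zeros (background
#' semantics, avoids division by zero).
#'
#' @param img numeric matrix with finite values.
#' @return numeric matrix with range inside `[0, 1]`.
#' @export
normalize_minmax <- function(img) {
  stopifnot_image(img)
  bad <- sum(!is.finite(img))
  if (bad > 0)
    stop(sprintf("normalize_minmax: %d non-finite pixel(s)", bad))
  lo <- min(img); hi <- max(img)
  if (hi == lo) return(matrix(0, nrow(img), ncol(img)))
  (img - lo) / (hi - lo)
}

#' Otsu foreground binarization
#'
#' Thresholds a `[0, 1]`-normalized image at the value maximizing between-class
#' variance over a 256-bin histogram; pixels strictly above the threshold are
#' foreground. A constant image yields an all-background mask.
#'
#' @param img numeric matrix with values in `[0, 1]`.
#' @return logical matrix (`TRUE` = foreground).
#' @export
binarize_otsu <- function(img) {
  stopifnot_image(img)
  if (min(img) < 0 || max(img) > 1)
    stop("binarize_otsu: image must be normalized to [0, 1]")
  if (max(img) == min(img)) return(matrix(FALSE, nrow(img), ncol(img)))
  thr <- EBImage::otsu(img, range = c(0, 1), levels = 256)
  img > thr
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so labels
# touching diagonally are merged afterwards via a label-adjacency graph.
label_components <- function(bw) {
  lab <- EBImage::imageData(EBImage::bwlabel(bw))
  n <- max(lab)
  if (n <= 1) return(matrix(as.integer(lab), nrow(bw), ncol(bw)))
  H <- nrow(lab); W <- ncol(lab)
  edges <- NULL
  for (sh in list(c(1, 1), c(1, -1))) {
    a <- lab[seq_len(H - 1), , drop = FALSE]
    b <- lab[seq_len(H - 1) + 1, , drop = FALSE]
    if (sh[2] == 1) { a <- a[, seq_len(W - 1)]; b <- b[, seq_len(W - 1) + 1] }
    else           { a <- a[, seq_len(W - 1) + 1]; b <- b[, seq_len(W - 1)] }
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) edges <- rbind(edges, cbind(a[sel], b[sel]))
  }
  if (is.null(edges)) return(matrix(as.integer(lab), H, W))
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out <- matrix(0L, H, W)
  pos <- lab > 0
  out[pos] <- as.integer(comp[lab[pos]])
  # renumber 1..k
  ids <- sort(unique(out[out > 0]))
  matrix(match(out, ids, nomatch = 1L) * (out > 0), H, W)
}

# Scale-normalized LoG blob seeds inside one component.
# Returns a matrix (row, col, sigma, response), 1-based pixel coords.
log_seeds <- function(intensity, comp_px, params) {
  H <- nrow(intensity); W <- ncol(intensity)
  r <- (comp_px - 1L) %% H + 1L; c <- (comp_px - 1L) %/% H + 1L
  sigmas <- exp(seq(log(params$log_sigma_range[1]),
                    log(params$log_sigma_range[2]),
                    length.out = params$n_sigma))
  # crop with margin wide enough for the largest usable Gaussian kernel
  pad <- ceiling(3 * max(sigmas)) + 2
  r0 <- max(1, min(r) - pad); r1 <- min(H, max(r) + pad)
  c0 <- max(1, min(c) - pad); c1 <- min(W, max(c) + pad)
  crop <- intensity[r0:r1, c0:c1]
  incomp <- matrix(FALSE, nrow(crop), ncol(crop))
  incomp[cbind(r - r0 + 1L, c - c0 + 1L)] <- TRUE

  usable <- sigmas[2 * ceiling(3 * sigmas) + 1 <= min(dim(crop))]
  if (length(usable) == 0) return(NULL)
  resp <- lapply(usable, function(s)
    -s^2 * laplacian(gauss_blur(crop, s)))

  peaks <- NULL
  for (k in seq_along(usable)) {
    m <- resp[[k]]
    is_peak <- m >= params$log_threshold & incomp & local_max8(m)
    if (k > 1) is_peak <- is_peak & m >= resp[[k - 1]]
    if (k < length(usable)) is_peak <- is_peak & m >= resp[[k + 1]]
    idx <- which(is_peak)
    if (length(idx))
      peaks <- rbind(peaks, cbind((idx - 1L) %% nrow(m) + r0,
                                  (idx - 1L) %/% nrow(m) + c0,
                                  usable[k], m[idx]))
  }
  if (is.null(peaks)) return(NULL)
  prune_blob_overlaps(peaks, overlap = 0.5)
}

# Overlap pruning: blobs are circles of radius sqrt(2) * sigma; when two
# circles overlap by more than `overlap` of the smaller one, the weaker goes.
prune_blob_overlaps <- function(peaks, overlap = 0.5) {
  ord <- order(peaks[, 4], decreasing = TRUE)
  peaks <- peaks[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    if (i == nrow(peaks)) break
    for (j in seq(i + 1, nrow(peaks))) {
      if (!keep[j]) next
      ri <- sqrt(2) * peaks[i, 3]; rj <- sqrt(2) * peaks[j, 3]
      d <- sqrt(sum((peaks[i, 1:2] - peaks[j, 1:2])^2))
      if (d >= ri + rj) next
      if (circle_overlap_area(ri, rj, d) / (pi * min(ri, rj)^2) > overlap)
        keep[j] <- FALSE
    }
  }
  peaks[keep, , drop = FALSE]
}

circle_overlap_area <- function(r1, r2, d) {
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  if (d >= r1 + r2) return(0)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  tri <- 0.5 * sqrt(pmax(0, (-d + r1 + r2) * (d + r1 - r2) *
                           (d - r1 + r2) * (d + r1 + r2)))
  a1 + a2 - tri
}

# 4-neighbour Laplacian with replicated borders.
laplacian <- function(m) {
  H <- nrow(m); W <- ncol(m)
  m[c(1, seq_len(H - 1)), ] + m[c(seq_len(H - 1) + 1, H), ] +
    m[, c(1, seq_len(W - 1))] + m[, c(seq_len(W - 1) + 1, W)] - 4 * m
}

# Strict-enough 8-neighbour local maximum test (>= all neighbours).
local_max8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(-Inf, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m
  out <- matrix(TRUE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out & m >= p[2:(H + 1) + dr, 2:(W + 1) + dc]
  }
  out
}

# Marker-based watershed on the negative Euclidean distance transform of a
# binary mask, seeded at the given (row, col) markers. Bucket-queue flooding:
# distance levels are processed from the ridge tops (largest distance) down;
# within a level, labels propagate breadth-first, each unlabeled pixel taking
# the label of its highest neighbour.
marker_watershed <- function(mask, seeds) {
  H <- nrow(mask); W <- ncol(mask)
  dist <- EBImage::imageData(EBImage::distmap(mask))
  labels <- matrix(0L, H, W)
  labels[cbind(seeds[, 1], seeds[, 2])] <- seq_len(nrow(seeds))
  lev <- floor(dist)
  for (l in seq(max(lev), 0)) {
    eligible <- mask & lev >= l
    repeat {
      front <- propagate_once(labels, dist, eligible)
      if (is.null(front)) break
      labels <- front
    }
  }
  labels
}

# One vectorized 8-neighbour propagation step; returns NULL at fixed point.
propagate_once <- function(labels, dist, eligible) {
  H <- nrow(labels); W <- ncol(labels)
  padl <- matrix(0L, H + 2, W + 2); padl[2:(H + 1), 2:(W + 1)] <- labels
  padd <- matrix(-Inf, H + 2, W + 2); padd[2:(H + 1), 2:(W + 1)] <- dist
  best_d <- matrix(-Inf, H, W); best_l <- matrix(0L, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nl <- padl[2:(H + 1) + dr, 2:(W + 1) + dc]
    nd <- padd[2:(H + 1) + dr, 2:(W + 1) + dc]
    upd <- nl > 0L & nd > best_d
    best_d[upd] <- nd[upd]; best_l[upd] <- nl[upd]
  }
  target <- eligible & labels == 0L & best_l > 0L
  if (!any(target)) return(NULL)
  labels[target] <- best_l[target]
  labels
}

#' Split one foreground component into individual nuclei
#'
#' Runs scale-normalized LoG blob detection on the intensity image restricted
#' to the component; with k >= 2 seeds the component is partitioned by a
#' marker-based watershed on its negative distance transform. With fewer than
#' two seeds the whole component is returned as a single instance.
#'
#' @param component integer vector of linear pixel indices of one 8-connected
#'   foreground component (or a logical matrix).
#' @param intensity the normalized intensity image the component came from.
#' @param params a [blob_params()].
#' @return list of integer index vectors; disjoint, union = component.
#' @export
split_component <- function(component, intensity, params = blob_params()) {
  stopifnot_image(intensity)
  if (is.matrix(component)) component <- which(component != 0)
  component <- as.integer(component)
  seeds <- log_seeds(intensity, component, params)
  if (is.null(seeds) || nrow(seeds) < 2) return(list(component))
  H <- nrow(intensity); W <- ncol(intensity)
  r <- (component - 1L) %% H + 1L; c <- (component - 1L) %/% H + 1L
  r0 <- min(r); c0 <- min(c)
  mh <- max(r) - r0 + 3L; mw <- max(c) - c0 + 3L   # 1 px border
  mask <- matrix(FALSE, mh, mw)
  mask[cbind(r - r0 + 2L, c - c0 + 2L)] <- TRUE
  sl <- cbind(seeds[, 1] - r0 + 2L, seeds[, 2] - c0 + 2L)
  lab <- marker_watershed(mask, sl)
  # any pixels untouched by flooding (flat zero-distance corners) join the
  # nearest seed so the outputs exactly tile the component
  miss <- which(mask & lab == 0L)
  if (length(miss)) {
    mr <- (miss - 1L) %% mh + 1L; mc <- (miss - 1L) %/% mh + 1L
    d2 <- outer(mr, sl[, 1], "-")^2 + outer(mc, sl[, 2], "-")^2
    lab[miss] <- max.col(-d2)
  }
  lapply(seq_len(nrow(seeds)), function(k) {
    px <- which(lab == k)
    pr <- (px - 1L) %% mh + 1L; pc <- (px - 1L) %/% mh + 1L
    as.integer((pc + c0 - 3L) * H + (pr + r0 - 2L))
  })
}

erosion_kernel <- function(structuring_element) {
  if (structuring_element == "disk")
    matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
  else matrix(1, 3, 3)
}

#' Erode every instance mask independently
#'
#' Each mask is eroded `params$erosion_degree` times by the structuring
#' element; instances eroded to emptiness or below `params$min_instance_area`
#' are dropped and bounding boxes recomputed. With `erosion_degree = 0` the
#' set is returned unchanged.
#'
#' @param labels an [instance_mask_set()] with pairwise disjoint masks.
#' @param params a [blob_params()].
#' @return an `instance_mask_set`.
#' @export
erode_instances <- function(labels, params = blob_params()) {
  E <- params$erosion_degree
  if (E == 0 || length(labels$masks) == 0) return(labels)
  kern <- erosion_kernel(params$structuring_element)
  H <- labels$shape[1]
  out <- list()
  for (i in seq_along(labels$masks)) {
    px <- labels$masks[[i]]
    r <- (px - 1L) %% H + 1L; c <- (px - 1L) %/% H + 1L
    r0 <- min(r); c0 <- min(c)
    m <- matrix(0, max(r) - r0 + 3L, max(c) - c0 + 3L)
    m[cbind(r - r0 + 2L, c - c0 + 2L)] <- 1
    for (e in seq_len(E)) m <- EBImage::imageData(EBImage::erode(m, kern))
    px2 <- which(m > 0)
    if (length(px2) < max(1, params$min_instance_area)) next
    mh <- nrow(m)
    pr <- (px2 - 1L) %% mh + 1L; pc <- (px2 - 1L) %/% mh + 1L
    out[[length(out) + 1]] <- as.integer((pc + c0 - 3L) * H + (pr + r0 - 2L))
  }
  instance_mask_set(labels$shape, out)
}

# Pipeline up to (not including) erosion; shared by generate_labels and the
# erosion sweep so the expensive LoG/watershed work is done once per frame.
generate_labels_raw <- function(fluor, params, split = TRUE) {
  norm <- normalize_minmax(fluor)
  bw <- binarize_otsu(norm)
  lab <- label_components(bw)
  n <- max(lab)
  masks <- list()
  for (k in seq_len(n)) {
    px <- which(lab == k)
    if (length(px) < params$min_instance_area) next
    pieces <- if (split) split_component(px, norm, params) else list(px)
    masks <- c(masks, pieces)
  }
  instance_mask_set(dim(fluor), masks)
}

#' Generate instance-mask training labels from a fluorescence frame
#'
#' The full blob-detection pipeline: min-max normalization, Otsu foreground
#' binarization, per-component LoG seeding with marker-based watershed
#' splitting, then controlled per-instance erosion.
#'
#' @param fluor raw fluorescence frame (numeric matrix).
#' @param params a [blob_params()].
#' @return an [instance_mask_set()] of pairwise disjoint instance masks.
#' @export
generate_labels <- function(fluor, params = blob_params()) {
  erode_instances(generate_labels_raw(fluor, params), params)
}

#' Sweep the erosion degree against golden annotation masks
#'
#' For every erosion degree in `e_values`, generates labels from each
#' fluorescence frame, matches them to the golden instance masks and reports
#' the mean matched-pair mask IoU. An Otsu-only baseline (no instance
#' splitting, no erosion) is included. The best erosion degree (argmax of
#' mean IoU) is attached as attribute `best_e`.
#'
#' @param fluor_frames list of fluorescence frames.
#' @param golden list of golden [instance_mask_set()], aligned with frames.
#' @param e_values integer erosion degrees to try.
#' @param params a [blob_params()]; its own `erosion_degree` is ignored.
#' @param match_t_iou IoU threshold used to pair generated and golden
#'   instances before averaging (low by default so shrunken masks still pair).
#' @return data.frame with columns `method`, `erosion`, `mean_iou`, `n_pairs`;
#'   attribute `best_e` holds the argmax erosion degree.
#' @export
erosion_sweep <- function(fluor_frames, golden, e_values = c(0, 2, 4, 6),
                          params = blob_params(), match_t_iou = 0.1) {
  stopifnot(length(fluor_frames) == length(golden))
  if (length(golden) == 0 || all(vapply(golden, function(g)
    length(g$masks), 1L) == 0))
    stop("erosion_sweep: empty golden set")
  raw <- lapply(fluor_frames, generate_labels_raw, params = params)
  otsu_only <- lapply(fluor_frames, generate_labels_raw, params = params,
                      split = FALSE)
  score <- function(sets) {
    ious <- unlist(lapply(seq_along(sets), function(i) {
      m <- match_instances(golden[[i]], sets[[i]], match_t_iou, "mask")
      m$pairs[, "iou"]
    }))
    c(mean_iou = if (length(ious)) mean(ious) else 0, n_pairs = length(ious))
  }
  rows <- list()
  s <- score(otsu_only)
  rows[[1]] <- data.frame(method = "otsu", erosion = NA_integer_,
                          mean_iou = s[1], n_pairs = s[2])
  for (E in e_values) {
    p <- params; p$erosion_degree <- as.integer(E)
    s <- score(lapply(raw, erode_instances, params = p))
    rows[[length(rows) + 1]] <- data.frame(
      method = sprintf("E%d", E), erosion = as.integer(E),
      mean_iou = s[1], n_pairs = s[2])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  eroded <- out[!is.na(out$erosion), ]
  attr(out, "best_e") <- eroded$erosion[which.max(eroded$mean_iou)]
  out
}
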