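# Minimal reverse-mode autodiff over dense arrays, sized for the compact
# detector: a tape of nodes, each with a value and a backward closure.
# Convolutions are im2col + BLAS matmul; gradients w.r.t. inputs use a
# rowsum-based col2im scatter. Only the ops the detector needs exist.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp
}

tp_push <- function(tp, value, parents = integer(0), backfn = NULL,
                    extra = NULL) {
  force(value); force(parents); force(backfn)
  id <- length(tp$nodes) + 1L
  tp$nodes[[id]] <- list(value = value, parents = parents, backfn = backfn,
                         extra = extra)
  id
}

tp_value <- function(tp, id) {
  # force `id` before touching tp$nodes: evaluating a lazily passed op call
  # may itself append nodes to the tape
  force(id)
  tp$nodes[[id]]$value
}

# Leaf input; `name` non-NULL marks a trainable parameter whose gradient is
# collected by tp_backward.
tp_leaf <- function(tp, value, name = NULL) {
  id <- tp_push(tp, value)
  tp$nodes[[id]]$param_name <- name
  id
}

# Backward pass from a scalar loss node; returns named list of parameter grads.
tp_backward <- function(tp, loss_id) {
  n <- length(tp$nodes)
  grads <- vector("list", n)
  grads[[loss_id]] <- 1
  out <- list()
  for (id in seq(n, 1)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tp$nodes[[id]]
    if (!is.null(node$param_name))
      out[[node$param_name]] <- g
    if (is.null(node$backfn)) next
    pg <- node$backfn(g)
    for (k in seq_along(node$parents)) {
      p <- node$parents[k]
      if (is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
    grads[id] <- list(NULL)   # free without shifting list indices
  }
  out
}

# ---- im2col machinery ------------------------------------------------------

# Cache of index maps keyed by geometry; lives for the session.
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(H, W, C, kh, kw, stride, pad) {
  key <- paste(H, W, C, kh, kw, stride, pad, sep = "_")
  got <- .im2col_cache[[key]]
  if (!is.null(got)) return(got)
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  H2 <- (Hp - kh) %/% stride + 1L; W2 <- (Wp - kw) %/% stride + 1L
  oi <- rep(seq_len(H2) - 1L, times = W2) * stride      # padded row offset
  oj <- rep(seq_len(W2) - 1L, each = H2) * stride
  cols <- matrix(0L, H2 * W2, kh * kw * C)
  k <- 1L
  for (ch in seq_len(C) - 1L) for (dj in seq_len(kw) - 1L)
    for (di in seq_len(kh) - 1L) {
      cols[, k] <- (oi + di) + (oj + dj) * Hp + ch * (Hp * Wp) + 1L
      k <- k + 1L
    }
  # col2im scatter plan: positions of `cols` sorted by target element, with
  # segment boundaries, so gradients accumulate via one cumsum pass
  ord <- order(as.vector(cols))
  sorted <- as.vector(cols)[ord]
  ends <- c(which(diff(sorted) != 0), length(sorted))
  res <- list(idx = cols, H2 = H2, W2 = W2, Hp = Hp, Wp = Wp,
              ord = ord, ends = ends, uvals = sorted[ends])
  .im2col_cache[[key]] <- res
  res
}

pad_array <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

# conv2d: x is H x W x Cin, weight (kh*kw*Cin) x Cout, bias length Cout.
tp_conv2d <- function(tp, x_id, w_id, b_id, kh, kw, stride = 1L, pad = 0L) {
  x <- tp_value(tp, x_id); Wm <- tp_value(tp, w_id); b <- tp_value(tp, b_id)
  d <- dim(x); C <- d[3]; Cout <- ncol(Wm)
  ii <- im2col_index(d[1], d[2], C, kh, kw, stride, pad)
  xp <- pad_array(x, pad)
  col <- xp[ii$idx]
  dim(col) <- dim(ii$idx)
  out <- col %*% Wm
  out <- out + rep(b, each = nrow(out))
  val <- out
  dim(val) <- c(ii$H2, ii$W2, Cout)
  backfn <- function(g) {
    D <- g
    dim(D) <- c(ii$H2 * ii$W2, Cout)
    dW <- crossprod(col, D)
    db <- colSums(D)
    dcol <- D %*% t(Wm)
    cs <- cumsum(as.vector(dcol)[ii$ord])
    sums <- cs[ii$ends] - c(0, cs[ii$ends[-length(ii$ends)]])
    dxp <- numeric(ii$Hp * ii$Wp * C)
    dxp[ii$uvals] <- sums
    dxp <- array(dxp, c(ii$Hp, ii$Wp, C))
    dx <- if (pad > 0)
      dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , drop = FALSE]
    else dxp
    list(array(dx, d), dW, db)
  }
  tp_push(tp, val, c(x_id, w_id, b_id), backfn)
}

tp_relu <- function(tp, x_id) {
  x <- tp_value(tp, x_id)
  pos <- x > 0
  tp_push(tp, x * pos, x_id, function(g) list(g * pos))
}

tp_add <- function(tp, a_id, b_id) {
  tp_push(tp, tp_value(tp, a_id) + tp_value(tp, b_id), c(a_id, b_id),
          function(g) list(g, g))
}

# Nearest-neighbour x2 upsampling of H x W x C (backward: 2x2 block sums).
tp_upsample2x <- function(tp, x_id) {
  x <- tp_value(tp, x_id); d <- dim(x)
  ri <- rep(seq_len(d[1]), each = 2); ci <- rep(seq_len(d[2]), each = 2)
  val <- x[ri, ci, , drop = FALSE]
  backfn <- function(g) {
    g1 <- g[seq(1, 2 * d[1], 2), , , drop = FALSE] +
      g[seq(2, 2 * d[1], 2), , , drop = FALSE]
    list(g1[, seq(1, 2 * d[2], 2), , drop = FALSE] +
           g1[, seq(2, 2 * d[2], 2), , drop = FALSE])
  }
  tp_push(tp, val, x_id, backfn)
}

# Fully connected on a batch matrix (n x in) %*% W (in x out) + b.
tp_fc <- function(tp, x_id, w_id, b_id) {
  x <- tp_value(tp, x_id); Wm <- tp_value(tp, w_id); b <- tp_value(tp, b_id)
  val <- sweep(x %*% Wm, 2, b, "+")
  backfn <- function(g) {
    g <- matrix(g, nrow(x), ncol(Wm))
    list(g %*% t(Wm), crossprod(x, g), colSums(g))
  }
  tp_push(tp, val, c(x_id, w_id, b_id), backfn)
}

# Gather elements by linear index (backward scatters into zeros).
tp_gather <- function(tp, x_id, idx) {
  x <- tp_value(tp, x_id)
  backfn <- function(g) {
    dx <- array(0, dim(x) %||% length(x))
    dx[idx] <- g
    list(dx)
  }
  tp_push(tp, x[idx], x_id, backfn)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable binary cross-entropy with logits; mean over elements.
tp_bce_logits <- function(tp, z_id, target) {
  z <- tp_value(tp, z_id)
  n <- length(z)
  loss <- sum(pmax(z, 0) - z * target + log1p(exp(-abs(z)))) / n
  backfn <- function(g) list(g * (1 / (1 + exp(-z)) - target) / n)
  tp_push(tp, loss, z_id, backfn)
}

# Softmax cross-entropy over rows of an n x K logit matrix; mean over rows.
tp_softmax_ce <- function(tp, z_id, classes) {
  z <- tp_value(tp, z_id)
  n <- nrow(z)
  zm <- z - apply(z, 1, max)
  p <- exp(zm) / rowSums(exp(zm))
  loss <- -mean(log(pmax(p[cbind(seq_len(n), classes)], 1e-12)))
  backfn <- function(g) {
    d <- p
    d[cbind(seq_len(n), classes)] <- d[cbind(seq_len(n), classes)] - 1
    list(g * d / n)
  }
  tp_push(tp, loss, z_id, backfn)
}

# Smooth L1 (Huber) loss, mean over elements.
tp_smooth_l1 <- function(tp, x_id, target, beta = 1) {
  x <- tp_value(tp, x_id)
  d <- x - target
  n <- length(d)
  a <- abs(d)
  loss <- sum(ifelse(a < beta, 0.5 * d^2 / beta, a - 0.5 * beta)) / n
  backfn <- function(g) list(g * pmin(pmax(d / beta, -1), 1) / n)
  tp_push(tp, loss, x_id, backfn)
}

# Concatenate vector-valued nodes (backward splits the gradient).
tp_concat <- function(tp, ids) {
  vals <- lapply(ids, function(i) as.vector(tp_value(tp, i)))
  lens <- vapply(vals, length, 1L)
  ends <- cumsum(lens)
  backfn <- function(g) {
    lapply(seq_along(ids), function(k)
      g[seq(ends[k] - lens[k] + 1, ends[k])])
  }
  tp_push(tp, unlist(vals), ids, backfn)
}

tp_scale <- function(tp, x_id, s) {
  tp_push(tp, tp_value(tp, x_id) * s, x_id, function(g) list(g * s))
}

tp_sum_nodes <- function(tp, ids) {
  val <- sum(vapply(ids, function(i) tp_value(tp, i), numeric(1)))
  tp_push(tp, val, ids, function(g) rep(list(g), length(ids)))
}

# ---- parameter init and Adam ----------------------------------------------

he_init <- function(nin, nout, shape = NULL) {
  v <- stats::rnorm(nin * nout, 0, sqrt(2 / nin))
  if (is.null(shape)) matrix(v, nin, nout) else array(v, shape)
}

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

adam_step <- function(st, params, grads) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  corr <- st$lr * sqrt(1 - b2^st$t) / (1 - b1^st$t)
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      corr * st$m[[nm]] / (sqrt(st$v[[nm]]) + st$eps)
  }
  params
}
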