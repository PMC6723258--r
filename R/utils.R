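# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All randomness in the package flows through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a per-item child seed from a root seed; stays inside 32-bit range.
child_seed <- function(root, i) {
  as.integer((as.numeric(root) * 7919 + as.numeric(i) * 104729) %%
               .Machine$integer.max)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Sample `img` (matrix) at fractional 0-based (row, col) coordinates with
# bilinear weights; coordinates outside the grid are clamped to the border.
bilinear_sample <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  r <- pmin(pmax(r, 0), H - 1); c <- pmin(pmax(c, 0), W - 1)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- r0 + 1 + c0 * H; i01 <- r0 + 1 + c1 * H
  i10 <- r1 + 1 + c0 * H; i11 <- r1 + 1 + c1 * H
  img[i00] * (1 - fr) * (1 - fc) + img[i01] * (1 - fr) * fc +
    img[i10] * fr * (1 - fc) + img[i11] * fr * fc
}

# Gaussian blur via EBImage; thin wrapper so callers stay matrix-in/matrix-out.
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  as.matrix(EBImage::gblur(img, sigma = sigma))
}

stopifnot_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("%s must be a numeric matrix", arg))
}
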