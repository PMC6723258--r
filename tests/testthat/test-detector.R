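make_patches <- function(seeds) {
  lapply(seeds, function(s) {
    sc <- simulate_scene(patch_scene_config(seed = s))
    list(image = sc$phase, labels = sc$truth)
  })
}

test_that("anchor enumeration follows the scale/ratio/step definitions", {
  one <- generate_anchors(anchor_config(scales = 128), c(128, 128))
  expect_equal(nrow(one), 3)                      # one position, three ratios
  sq <- one[one$ratio == 1, ]
  expect_equal(c(sq$r1 - sq$r0, sq$c1 - sq$c0), c(128, 128))

  a8 <- generate_anchors(anchor_config(scales = 8), c(64, 64))
  sq8 <- a8[a8$ratio == 1, ][1, ]
  expect_equal((sq8$r1 - sq8$r0) * (sq8$c1 - sq8$c0), 64)  # 8 x 8 box

  # closed-form placement count: floor((L - s)/step) + 1 per dimension
  for (s in c(32, 64, 128)) {
    g <- generate_anchors(anchor_config(scales = s), c(512, 512))
    per_dim <- floor((512 - s) / (s / 2)) + 1
    expect_equal(nrow(g), 3 * per_dim^2)
  }
  expect_error(generate_anchors(anchor_config(), c(64, 64)), "smaller")
})

test_that("anchor coverage of the synthetic size range matches the geometry
           of 2x-spaced scales", {
  # with scales doubling and step = half the anchor side, the best anchor IoU
  # for a square object at the geometric mean of two scales is ~0.5 at best;
  # the guaranteed floor is lower. Enumerate random truth boxes at 40-120 px
  # (the 20-60 px nucleus range after x2 upsampling).
  A <- as.matrix(generate_anchors(anchor_config(), c(512, 512))[, 1:4])
  set.seed(123)
  mx <- replicate(800, {
    d1 <- runif(1, 40, 120); d2 <- d1 * runif(1, 0.8, 1)
    r0 <- runif(1, 0, 512 - d1); c0 <- runif(1, 0, 512 - d2)
    b <- c(r0, c0, r0 + d1, c0 + d2)
    ih <- pmin(A[, 3], b[3]) - pmax(A[, 1], b[1])
    iw <- pmin(A[, 4], b[4]) - pmax(A[, 2], b[2])
    i <- pmax(ih, 0) * pmax(iw, 0)
    max(i / ((A[, 3] - A[, 1]) * (A[, 4] - A[, 2]) +
               (b[3] - b[1]) * (b[4] - b[2]) - i))
  })
  expect_gt(min(mx), 0.35)        # every box is coarsely covered
  expect_gt(mean(mx >= 0.5), 0.75)  # most boxes have a >= 0.5 anchor
})

test_that("greedy NMS matches its brute-force definition", {
  expect_equal(nms(matrix(c(0, 0, 10, 10), 1, 4), 0.7), 1)
  two <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10))
  expect_equal(nms(two, c(0.9, 0.8), 0.5), 1)
  set.seed(5)
  for (rep in 1:10) {
    n <- 20
    boxes <- t(replicate(n, {
      r0 <- runif(1, 0, 80); c0 <- runif(1, 0, 80)
      c(r0, c0, r0 + runif(1, 5, 30), c0 + runif(1, 5, 30))
    }))
    scores <- runif(n)
    expect_equal(nms(boxes, scores, 0.4), oracle_nms(boxes, scores, 0.4))
  }
})

test_that("training validates its inputs", {
  p <- make_patches(1)
  empty <- list(image = p[[1]]$image,
                labels = instance_mask_set(dim(p[[1]]$image), list()))
  expect_error(train_detector(list(empty), train_config(seed = 1)),
               "nothing to learn")
  mismatch <- list(image = p[[1]]$image,
                   labels = instance_mask_set(c(64, 64), list(1:30)))
  expect_error(train_detector(list(mismatch)), "shape mismatch")
  expect_error(train_config(anchor_scales = c(16, 64)), "consecutive")
})

test_that("training is deterministic and its losses decrease", {
  patches <- make_patches(c(3, 4))
  cfg <- train_config(epochs_rpn = 4, epochs_heads = 3, seed = 11)
  m1 <- train_detector(patches, cfg)
  m2 <- train_detector(patches, cfg)
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$params, m2$params)
  rpn <- m1$trace[m1$trace$phase == "rpn", ]
  expect_lt(rpn$total[nrow(rpn)], rpn$total[1])
  d1 <- predict_detections(m1, patches[[1]]$image, score_threshold = 0.3)
  d2 <- predict_detections(m2, patches[[1]]$image, score_threshold = 0.3)
  expect_identical(d1, d2)
})

test_that("models round-trip through serialization with identical predictions", {
  patches <- make_patches(5)
  m <- train_detector(patches, train_config(epochs_rpn = 3, epochs_heads = 2,
                                            seed = 2))
  path <- tempfile(fileext = ".rds")
  write_model(m, path)
  m2 <- read_model(path)
  img <- patches[[1]]$image
  expect_identical(predict_detections(m, img, 0.5),
                   predict_detections(m2, img, 0.5))
})

test_that("detection counts are monotone in the score threshold", {
  patches <- make_patches(6)
  m <- train_detector(patches, train_config(epochs_rpn = 3, epochs_heads = 2,
                                            seed = 3))
  img <- patches[[1]]$image
  n_lo <- length(predict_detections(m, img, score_threshold = 0.5))
  n_hi <- length(predict_detections(m, img, score_threshold = 0.95))
  expect_lte(n_hi, n_lo)
  expect_length(predict_detections(m, img, score_threshold = 1 + 1e-9), 0)
})
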