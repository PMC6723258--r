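test_that("x2 upsampling reproduces corners, constants and affine ramps", {
  const <- matrix(3.5, 4, 5)
  up <- upsample2x(const)
  expect_equal(dim(up), c(8, 10))
  expect_true(all(abs(up - 3.5) < 1e-12))

  tiny <- matrix(c(1, 3, 2, 8), 2, 2)
  up2 <- upsample2x(tiny)
  expect_equal(up2[1, 1], tiny[1, 1]); expect_equal(up2[4, 4], tiny[2, 2])
  expect_equal(up2[1, 4], tiny[1, 2]); expect_equal(up2[4, 1], tiny[2, 1])

  # bilinear interpolation reproduces affine intensity functions exactly
  r <- matrix(seq_len(8), 8, 6); c <- t(matrix(seq_len(6), 6, 8))
  ramp <- 0.3 * r + 0.1 * c - 0.2
  up3 <- upsample2x(ramp)
  rr <- matrix(seq(1, 8, length.out = 16), 16, 12)
  cc <- t(matrix(seq(1, 6, length.out = 12), 12, 16))
  expect_equal(up3, 0.3 * rr + 0.1 * cc - 0.2, tolerance = 1e-12)

  # label maps go through nearest-neighbour: no new ids appear
  lab <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
  upl <- upsample2x(lab, method = "nearest")
  expect_setequal(unique(as.vector(upl)), unique(as.vector(lab)))
  expect_type(upl[1, 1], "integer")
})

test_that("patch tiling covers frames with the edge-shift rule", {
  g1 <- tile_patches(c(512, 512), 512, 512)
  expect_equal(nrow(g1$origins), 1)
  expect_equal(unname(g1$origins[1, ]), c(0, 0))

  g2 <- tile_patches(c(4096, 4096), 512, 512)
  expect_equal(nrow(g2$origins), 64)

  g3 <- tile_patches(c(600, 600), 512, 512)
  expect_equal(nrow(g3$origins), 4)
  expect_setequal(unique(g3$origins[, "r0"]), c(0, 88))

  # coverage: every pixel inside at least one patch
  cov <- matrix(0L, 600, 600)
  for (i in seq_len(nrow(g3$origins))) {
    o <- g3$origins[i, ]
    cov[o[1] + 1:512, o[2] + 1:512] <- 1L
  }
  expect_true(all(cov == 1L))

  expect_error(tile_patches(c(600, 600), 512, 0), "stride")
  expect_error(tile_patches(c(100, 100), 512), "exceeds")
})

test_that("label cropping keeps instances by inside-area fraction", {
  ms <- instance_mask_set(c(20, 20),
                          list(c(1, 2, 21, 22),      # rows 0-1, cols 0-1
                               which(matrix(seq_len(400), 20, 20) > 380)))
  crop <- crop_labels_to_patch(ms, c(0, 0), 10)
  expect_equal(length(crop$masks), 1)  # second instance fully outside
  expect_equal(crop$shape, c(10L, 10L))

  # an instance straddling the border: kept iff >= 50% inside
  straddle <- instance_mask_set(c(20, 20), list(c(181, 182, 201, 202)))
  # cols 9 and 10 (0-based); patch cols 0-9 contain half
  kept <- crop_labels_to_patch(straddle, c(0, 0), 10, keep_fraction = 0.5)
  expect_equal(length(kept$masks), 1)
  gone <- crop_labels_to_patch(straddle, c(0, 0), 10, keep_fraction = 0.6)
  expect_equal(length(gone$masks), 0)
})

test_that("stitching translates, deduplicates and stays idempotent", {
  grid <- tile_patches(c(600, 600), 512, 512)
  soft <- matrix(0.9, 28, 28)
  d1 <- detection(c(10, 10, 40, 40), 0.9, soft)
  per <- list(list(d1), list(), list(), list())
  out <- stitch_detections(grid, per, nms_iou = 0.5)
  expect_length(out, 1)
  expect_equal(out[[1]]$box, c(10, 10, 40, 40))

  # same object seen in two overlapping patches: higher score survives
  d_in_p4 <- detection(c(10 - 88, 10 - 88, 40 - 88, 40 - 88) + 88, 0.7, soft)
  per2 <- list(list(d1), list(), list(), list(detection(c(2, 2, 32, 32) - 90 + 88,
                                                        0.7, soft)))
  # patch 4 origin (88, 88); its detection lands at (86, 86, 116, 116)? build
  # an exact duplicate instead: frame box (100,100,130,130) via both patches
  pa <- detection(c(100, 100, 130, 130), 0.95, soft)        # patch 1 (0,0)
  pb <- detection(c(12, 12, 42, 42), 0.60, soft)            # patch 4 (88,88)
  out2 <- stitch_detections(grid, list(list(pa), list(), list(), list(pb)),
                            nms_iou = 0.5)
  expect_length(out2, 1)
  expect_equal(out2[[1]]$score, 0.95)

  # disjoint detections all survive, ordered by descending score
  pc_ <- detection(c(200, 200, 230, 230), 0.5, soft)
  out3 <- stitch_detections(grid, list(list(pa, pc_), list(), list(), list()),
                            nms_iou = 0.5)
  expect_length(out3, 2)
  expect_equal(vapply(out3, `[[`, numeric(1), "score"), c(0.95, 0.5))

  # idempotence: stitching the stitched output through a trivial grid
  g0 <- tile_patches(c(600, 600), 600, 600)
  out4 <- stitch_detections(g0, list(out2), nms_iou = 0.5)
  expect_equal(out4, out2)

  # rescaling halves coordinates back to the raw frame
  outr <- stitch_detections(grid, list(list(pa), list(), list(), list()),
                            rescale = 0.5)
  expect_equal(outr[[1]]$box, c(50, 50, 65, 65))

  bad <- detection(c(-5, 0, 30, 30), 0.5, soft)
  expect_error(stitch_detections(grid, list(list(bad), list(), list(), list())),
               "outside its patch")
})

test_that("a truth instance detected with its exact mask stitches back to the
           identical mask", {
  shape <- c(600, 600)
  grid <- tile_patches(shape, 512, 512)
  # truth: a 20x20 square fully inside patch 4 (origin 88,88)
  r <- matrix(seq_len(600), 600, 600); c <- t(r)
  truth <- r >= 301 & r <= 320 & c >= 301 & c <= 320
  # its box in patch-4 coordinates (0-based, half-open)
  box_patch <- c(300 - 88, 300 - 88, 320 - 88, 320 - 88)
  det <- detection(box_patch, 0.9, matrix(1, 28, 28))
  stitched <- stitch_detections(grid, list(list(), list(), list(), list(det)))
  px <- detection_mask(stitched[[1]], shape)
  expect_setequal(px, which(truth))
})
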