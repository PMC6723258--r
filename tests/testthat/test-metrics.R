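ms_from <- function(shape, ...) instance_mask_set(shape, list(...))

test_that("mask IoU follows the Jaccard definition with empty-set conventions", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  b <- matrix(FALSE, 4, 4); b[1:2, 2:3] <- TRUE
  expect_equal(mask_iou(a, a), 1)
  expect_equal(mask_iou(a, b), 1 / 3)   # 2 px overlap, 6 px union
  expect_equal(mask_iou(a, !a & FALSE), 0)
  expect_equal(mask_iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_error(mask_iou(a, matrix(TRUE, 3, 3)), "common grid")
  # symmetry and bounds on random masks
  set.seed(4)
  for (i in 1:20) {
    x <- matrix(runif(36) < 0.4, 6, 6); y <- matrix(runif(36) < 0.4, 6, 6)
    expect_equal(mask_iou(x, y), mask_iou(y, x))
    expect_gte(mask_iou(x, y), 0); expect_lte(mask_iou(x, y), 1)
    expect_equal(mask_iou(x, y), oracle_mask_iou(x, y))
  }
})

test_that("box IoU handles half-open boxes and degenerate input", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 1, 2, 3)), 1 / 3)
  expect_equal(box_iou(c(0, 0, 2, 2), c(5, 5, 7, 7)), 0)
  expect_error(box_iou(c(0, 0, 0, 2), c(0, 0, 2, 2)), "zero-area")
})

test_that("instance matching is one-to-one with exact TP/FP/FN bookkeeping", {
  s <- ms_from(c(6, 6), c(1, 2, 7, 8), c(29, 30, 35, 36))
  m <- match_instances(s, s, t_iou = 0.5)
  expect_equal(m$tp, 2); expect_equal(m$fp, 0); expect_equal(m$fn, 0)

  empty <- instance_mask_set(c(6, 6), list())
  m2 <- match_instances(s, empty, t_iou = 0.5)
  expect_equal(m2$tp, 0); expect_equal(m2$fn, 2)

  # two predictions over one label: one TP, one FP
  s_l <- ms_from(c(6, 6), c(1, 2, 7, 8))
  s_p <- instance_mask_set(c(6, 6), list(c(1, 2, 7, 8), c(1, 2, 7)),
                           scores = c(0.9, 0.8))
  m3 <- match_instances(s_l, s_p, t_iou = 0.5)
  expect_equal(m3$tp, 1); expect_equal(m3$fp, 1)
  expect_equal(unname(m3$pairs[1, "pred"]), 1)  # higher-scored pairing wins

  expect_error(match_instances(s, s, t_iou = 0), "inside \\(0, 1\\)")
  expect_error(match_instances(s, s, t_iou = 1), "inside \\(0, 1\\)")
})

test_that("matching conserves counts on random scenes", {
  for (seed in 1:25) {
    sc <- random_eval_scene(seed)
    sets <- scene_to_sets(sc)
    for (t in c(0.3, 0.5, 0.7)) {
      m <- match_instances(sets$labels, sets$preds, t)
      expect_equal(m$tp + m$fn, length(sets$labels$masks))
      expect_equal(m$tp + m$fp, length(sets$preds$masks))
      for (iou in m$pairs[, "iou"]) expect_gt(iou, t)
      expect_equal(anyDuplicated(m$pairs[, "label"]), 0)
      expect_equal(anyDuplicated(m$pairs[, "pred"]), 0)
    }
  }
})

test_that("precision and recall substitute into their definitions", {
  m <- structure(list(tp = 2, fp = 1, fn = 1), class = "match_result")
  expect_equal(unname(precision_recall(m)), c(2 / 3, 2 / 3))
  m0 <- structure(list(tp = 0, fp = 0, fn = 0), class = "match_result")
  expect_equal(unname(precision_recall(m0)), c(1, 1))
  m1 <- structure(list(tp = 0, fp = 3, fn = 0), class = "match_result")
  expect_equal(unname(precision_recall(m1))[1], 0)
})

test_that("PR curves sweep the score threshold with non-increasing recall", {
  s_l <- ms_from(c(8, 8), c(1, 2, 9, 10), c(37, 38, 45, 46))
  s_p <- instance_mask_set(c(8, 8), s_l$masks, scores = c(0.99, 0.99))
  cur <- pr_curve(s_l, s_p, t_iou = 0.5, thresholds = c(0.2, 0.5, 0.9))
  expect_true(all(cur$precision == 1) && all(cur$recall == 1))

  for (seed in 1:10) {
    sets <- scene_to_sets(random_eval_scene(seed + 100))
    if (length(sets$preds$masks) == 0) next
    cur <- pr_curve(sets$labels, sets$preds, 0.5)
    expect_true(all(diff(cur$recall) <= 1e-12))
  }
  expect_error(pr_curve(s_l, ms_from(c(8, 8), 1), 0.5), "scores")
})

test_that("average precision matches trivial cases and handles empties", {
  s_l <- ms_from(c(8, 8), c(1, 2, 9, 10), c(37, 38, 45, 46))
  perfect <- instance_mask_set(c(8, 8), s_l$masks, scores = c(0.9, 0.8))
  expect_equal(average_precision(list(list(labels = s_l, preds = perfect)),
                                 0.5)$mean_ap, 1)
  off <- instance_mask_set(c(8, 8), list(c(25, 26)), scores = 0.9)
  expect_equal(average_precision(list(list(labels = s_l, preds = off)),
                                 0.5)$mean_ap, 0)
  both_empty <- list(labels = instance_mask_set(c(8, 8), list()),
                     preds = instance_mask_set(c(8, 8), list()))
  expect_equal(average_precision(list(both_empty), 0.5)$mean_ap, 1)
  expect_error(average_precision(list(), 0.5), "at least one")
})

test_that("AP equals the brute-force oracle on random small scenes", {
  for (seed in 1:20) {
    sc <- random_eval_scene(seed + 300)
    sets <- scene_to_sets(sc)
    got <- average_precision(list(sets), 0.5, "mask")$mean_ap
    want <- oracle_ap_image(sc$labels, sc$preds, sc$scores, 0.5)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the evaluation suite reports AP non-increasing in the threshold", {
  images <- lapply(1:8, function(s) scene_to_sets(random_eval_scene(s + 40)))
  rep <- evaluate_suite(images)
  for (m in unique(rep$ap$mode)) {
    aps <- rep$ap$ap[rep$ap$mode == m][order(rep$ap$t_iou[rep$ap$mode == m])]
    expect_true(all(diff(aps) <= 1e-12))
  }
  perfect <- lapply(1:3, function(s) {
    sets <- scene_to_sets(random_eval_scene(s))
    preds <- sets$labels
    preds$scores <- rep(0.95, length(preds$masks))
    list(labels = sets$labels, preds = preds)
  })
  rep2 <- evaluate_suite(perfect)
  expect_true(all(rep2$ap$ap == 1))
})

test_that("golden-set mean mask IoU summarises matched pairs", {
  s <- ms_from(c(8, 8), c(1, 2, 9, 10), c(37, 38, 45, 46))
  expect_equal(unname(mean_mask_iou(list(s), list(s))[1:2]), c(1, 0))
  # two constructed pairs with known IoUs 0.6 and 1.0
  g <- ms_from(c(10, 10), 1:10, 51:60)
  p <- ms_from(c(10, 10), c(3:10, 11, 12), 51:60)
  got <- mean_mask_iou(list(g), list(p))
  iou1 <- 8 / 12
  expect_equal(unname(got["mean"]), mean(c(iou1, 1)))
  expect_equal(unname(got["sd"]), sd(c(iou1, 1)))
  empty <- instance_mask_set(c(8, 8), list())
  expect_error(mean_mask_iou(list(s), list(empty)), "zero matched")
})
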