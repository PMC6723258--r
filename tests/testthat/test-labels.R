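test_that("min-max normalization maps linearly with stated conventions", {
  img <- matrix(c(10, 15, 20, 12), 2, 2)
  norm <- normalize_minmax(img)
  expect_equal(norm[2, 1], 0.5)
  expect_equal(range(norm), c(0, 1))
  expect_equal(normalize_minmax(matrix(7, 3, 3)), matrix(0, 3, 3))
  already <- matrix(seq(0, 1, length.out = 9), 3, 3)
  expect_equal(normalize_minmax(already), already)
  bad <- matrix(c(1, NA, Inf, 0), 2, 2)
  expect_error(normalize_minmax(bad), "2 non-finite")
})

test_that("Otsu binarization separates bimodal images and matches the
           exhaustive between-class-variance oracle", {
  img <- matrix(c(rep(0.1, 60), rep(0.9, 40)), 10, 10)
  fg <- binarize_otsu(img)
  expect_identical(fg, img > 0.5)
  expect_false(any(binarize_otsu(matrix(0.4, 5, 5))))
  set.seed(21)
  for (i in 1:100) {
    n1 <- sample(30:120, 1)
    x <- pmin(pmax(c(rnorm(n1, 0.3, 0.07), rnorm(150 - n1, 0.75, 0.07)),
                   0), 1)
    img <- matrix(x, 10, 15)
    expect_identical(binarize_otsu(img), img > oracle_otsu_threshold(img),
                     label = sprintf("otsu oracle, draw %d", i))
  }
})

test_that("split_component leaves isolated blobs whole and splits bridged pairs", {
  # one Gaussian blob
  g <- matrix(0, 64, 64)
  r <- matrix(seq_len(64), 64, 64); c <- t(r)
  g <- 0.9 * exp(-((r - 32)^2 + (c - 32)^2) / (2 * 8^2))
  comp <- which(g > 0.2)
  parts <- split_component(comp, g, blob_params(diameter_range = c(16, 40)))
  expect_length(parts, 1)
  expect_setequal(parts[[1]], comp)

  # two same-size blobs bridged into one component
  g2 <- 0.9 * exp(-((r - 32)^2 + (c - 20)^2) / (2 * 7^2)) +
    0.9 * exp(-((r - 32)^2 + (c - 45)^2) / (2 * 7^2))
  comp2 <- which(g2 > 0.15)
  parts2 <- split_component(comp2, g2, blob_params(diameter_range = c(16, 40)))
  expect_length(parts2, 2)
  # partition: pieces tile the component exactly
  expect_setequal(unlist(parts2), comp2)
  expect_equal(anyDuplicated(unlist(parts2)), 0)
  # centroids within 2 px of the true centers
  cents <- t(vapply(parts2, function(px) {
    c(mean((px - 1) %% 64 + 1), mean((px - 1) %/% 64 + 1))
  }, numeric(2)))
  cents <- cents[order(cents[, 2]), ]
  expect_lt(max(abs(cents - rbind(c(32, 20), c(32, 45)))), 2)
})

test_that("per-instance erosion matches a distance-transform oracle and drops
           annihilated instances", {
  # radius-10 disk: erosion by a city-block unit disk E times keeps exactly
  # the pixels whose Manhattan distance to the background exceeds E
  r <- matrix(seq_len(41), 41, 41); c <- t(r)
  disk <- (r - 21)^2 + (c - 21)^2 <= 10^2
  ms <- instance_mask_set(c(41, 41), list(which(disk)))
  p4 <- blob_params(erosion_degree = 4, min_instance_area = 1)
  got <- erode_instances(ms, p4)
  dist <- matrix(0, 41, 41)
  for (i in seq_len(41)) for (j in seq_len(41)) {
    if (!disk[i, j]) next
    bg <- which(!disk)
    dist[i, j] <- min(abs((bg - 1) %% 41 + 1 - i) + abs((bg - 1) %/% 41 + 1 - j))
  }
  expect_setequal(got$masks[[1]], which(dist > 4))

  expect_identical(erode_instances(ms, blob_params(erosion_degree = 0)), ms)
  gone <- erode_instances(ms, blob_params(erosion_degree = 12,
                                          min_instance_area = 1))
  expect_length(gone$masks, 0)
})

test_that("foreground area and instance count are non-increasing in E", {
  sc <- simulate_scene(scene_config(image_size = c(256, 256),
                                    nanowell_size = 256, seed = 31,
                                    n_nuclei = c(3, 3)))
  p <- blob_params(erosion_degree = 0)
  raw <- generate_labels(sc$fluor, p)
  prev_area <- Inf; prev_n <- Inf
  for (E in c(0, 2, 4, 6, 10)) {
    pe <- blob_params(erosion_degree = E)
    lab <- erode_instances(raw, pe)
    area <- sum(vapply(lab$masks, length, 1L))
    expect_lte(area, prev_area)
    expect_lte(length(lab$masks), prev_n)
    prev_area <- area; prev_n <- length(lab$masks)
  }
})

test_that("generate_labels recovers well-separated nuclei and returns empty
           sets on blank frames", {
  blank <- matrix(stats::rnorm(128 * 128, 0.1, 0.01), 128, 128)
  expect_length(generate_labels(pmax(blank, 0))$masks, 0)

  sc <- simulate_scene(scene_config(seed = 41, touching_fraction = 0))
  p <- blob_params(erosion_degree = 2)
  labs <- generate_labels(sc$fluor, p)
  expect_equal(length(labs$masks), length(sc$truth$masks))
  m <- match_instances(sc$truth, labs, t_iou = 0.5, mode = "mask")
  expect_equal(m$tp, length(sc$truth$masks))
  expect_true(all(m$pairs[, "iou"] >= 0.8))
  # outputs pairwise disjoint
  expect_equal(anyDuplicated(unlist(labs$masks)), 0)
})

test_that("the erosion sweep reports the Otsu baseline and an interior best E", {
  scenes <- simulate_scenes(3, scene_config(image_size = c(256, 256),
                                            nanowell_size = 128,
                                            diameter_range = c(20, 40),
                                            touching_fraction = 0),
                            seed = 77)
  sw <- erosion_sweep(lapply(scenes, `[[`, "fluor"),
                      lapply(scenes, `[[`, "truth"),
                      e_values = c(0, 2, 4),
                      params = blob_params(diameter_range = c(20, 40)))
  expect_equal(sw$method[1], "otsu")
  expect_setequal(sw$erosion[-1], c(0, 2, 4))
  best <- attr(sw, "best_e")
  expect_true(best %in% c(0, 2, 4))
  expect_equal(sw$mean_iou[which(sw$erosion == best)], max(sw$mean_iou[-1]))
  expect_error(erosion_sweep(list(), list()), "empty golden")
})
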