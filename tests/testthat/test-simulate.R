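test_that("scenes are deterministic functions of their config", {
  cfg <- scene_config(seed = 17)
  a <- simulate_scene(cfg); b <- simulate_scene(cfg)
  expect_identical(a$fluor, b$fluor)
  expect_identical(a$phase, b$phase)
  expect_identical(a$truth$masks, b$truth$masks)
  # a different seed changes the pixels
  c <- simulate_scene(scene_config(seed = 18))
  expect_false(identical(a$fluor, c$fluor))
})

test_that("an empty configuration yields a background-only scene", {
  sc <- simulate_scene(scene_config(n_nuclei = c(0, 0), seed = 1))
  expect_equal(length(sc$truth$masks), 0)
  expect_equal(dim(sc$fluor), dim(sc$phase))
  expect_lt(diff(range(sc$fluor)), 0.25)   # noise only, no bright nuclei
})

test_that("rendered truth boxes respect the configured diameter range", {
  sides <- c()
  for (s in 1:4) {
    sc <- simulate_scene(scene_config(seed = s, n_nuclei = c(3, 3)))
    b <- sc$truth$boxes
    sides <- c(sides, pmax(b[, 3] - b[, 1], b[, 4] - b[, 2]))
  }
  expect_gte(length(sides), 40)
  expect_true(all(sides >= 20 & sides <= 60))
})

test_that("scene structure invariants hold", {
  sc <- simulate_scene(scene_config(seed = 5, touching_fraction = 1))
  expect_equal(length(sc$truth$masks), nrow(sc$nuclei))
  expect_true(all(vapply(sc$truth$masks, length, 1L) > 0))
  expect_equal(dim(sc$fluor), dim(sc$phase))
  expect_true(min(sc$fluor) >= 0 && max(sc$fluor) <= 1)
  # masks pairwise disjoint even with touching pairs forced on
  all_px <- unlist(sc$truth$masks)
  expect_equal(anyDuplicated(all_px), 0)
})

test_that("fluorescence footprints strictly contain the truth when halo > 0", {
  sc <- simulate_scene(scene_config(seed = 9, fluor_halo = 3,
                                    touching_fraction = 0))
  fg <- binarize_otsu(normalize_minmax(sc$fluor))
  for (px in sc$truth$masks) {
    expect_true(all(fg[px]))                      # truth inside footprint
  }
  expect_gt(sum(fg), length(unlist(sc$truth$masks)))  # strictly larger
})

test_that("impossible placements raise an informative error", {
  expect_error(simulate_scene(scene_config(image_size = c(64, 64),
                                           nanowell_size = 64,
                                           diameter_range = c(50, 60),
                                           seed = 1)),
               "nanowell_size")
  expect_error(scene_config(touching_fraction = 1.4), "\\[0, 1\\]")
})

test_that("datasets round-trip through TIFF + manifest", {
  scenes <- simulate_scenes(2, scene_config(image_size = c(256, 256),
                                            nanowell_size = 128,
                                            diameter_range = c(20, 40)),
                            seed = 3)
  d <- tempfile()
  man <- write_dataset(scenes, d)
  expect_equal(man$n_scenes, 2)
  expect_length(list.files(d, pattern = "\\.tif$"), 6)  # 3 per scene
  back <- read_dataset(d)
  expect_equal(back$scenes[[1]]$truth$masks, scenes[[1]]$truth$masks)
  expect_lt(max(abs(back$scenes[[1]]$fluor - scenes[[1]]$fluor)), 1 / 65535)
  # refuse to clobber without the flag
  expect_error(write_dataset(scenes, d), "overwrite")
  expect_silent(write_dataset(scenes, d, overwrite = TRUE))
  # empty list -> empty manifest, no images
  d2 <- tempfile()
  man2 <- write_dataset(list(), d2)
  expect_equal(man2$n_scenes, 0)
  expect_length(list.files(d2, pattern = "\\.tif$"), 0)
})
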