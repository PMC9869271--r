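test_that("density levels partition counts with half-open bins", {
  expect_equal(assign_density_level(39), 1)
  expect_equal(assign_density_level(0), 1)
  expect_equal(assign_density_level(40), 2)
  expect_equal(assign_density_level(79), 2)
  expect_equal(assign_density_level(80), 3)
  expect_equal(assign_density_level(200), 3)
  # brute force: every count in 0..200 falls in exactly one bin
  lv <- assign_density_level(0:200)
  expect_true(all(lv %in% 1:3))
  expect_equal(lv, sort(lv))  # monotone in count
  expect_error(assign_density_level(-1), ">= 0")
})

test_that("scenes are deterministic and reflect their config", {
  cfg <- scene_config(spot_count = 39, seed = 77)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_equal(a$density_level, 1)
  expect_equal(generate_scene(scene_config(spot_count = 85,
                                           seed = 1))$density_level, 3)
  empty <- generate_scene(scene_config(spot_count = 0, seed = 1))
  expect_equal(sum(empty$mask), 0)
  expect_equal(empty$count, 0)
})

test_that("mask components equal the ground-truth count across seeds", {
  for (seed in 1:20) {
    n <- sample(5:60, 1)
    sc <- generate_scene(scene_config(width = 120, height = 120,
                                      spot_count = n, seed = seed))
    expect_equal(nrow(label_components(sc$mask, 8)$regions), n)
    expect_equal(sc$count, n)
  }
})

test_that("veins mark the image but never the mask", {
  base <- scene_config(spot_count = 15, vein_count = 0, seed = 31)
  veined <- scene_config(spot_count = 15, vein_count = 4, seed = 31)
  a <- generate_scene(base)
  b <- generate_scene(veined)
  expect_identical(a$mask, b$mask)          # mask depends only on spots
  expect_false(identical(a$image, b$image)) # image does not
})

test_that("impossible densities fail with the achievable maximum named", {
  expect_error(
    generate_scene(scene_config(width = 30, height = 30, spot_count = 500,
                                seed = 1)),
    "achieved maximum")
})

test_that("flip augmentation quadruples scenes and preserves mask structure", {
  scenes <- lapply(1:9, function(s)
    generate_scene(scene_config(spot_count = 10 + s, seed = s)))
  aug <- augment_flips(scenes)
  expect_length(aug, 36)
  one <- augment_flips(scenes[[1]])
  expect_length(one, 4)
  for (v in one) {
    expect_equal(sum(v$mask), sum(scenes[[1]]$mask))
    expect_equal(nrow(label_components(v$mask, 8)$regions),
                 scenes[[1]]$count)
  }
  # the four variants are distinct rasters for a generic scene
  keys <- vapply(one, function(s) paste(s$mask, collapse = ""), character(1))
  expect_equal(length(unique(keys)), 4)
  # applying the op twice gives 16 scenes but only 4 distinct rasters
  twice <- augment_flips(one)
  expect_length(twice, 16)
  keys2 <- vapply(twice, function(s) paste(s$mask, collapse = ""),
                  character(1))
  expect_equal(length(unique(keys2)), 4)
  expect_setequal(unique(keys2), unique(keys))
  expect_error(augment_flips(list()), "non-empty")
})

test_that("tile sets draw counts from the requested density stratum", {
  ts <- generate_tile_set(6, density_level = 2, size = 100, seed = 5)
  expect_length(ts$x, 6)
  expect_true(all(ts$counts >= 40 & ts$counts < 80))
  expect_true(all(vapply(ts$scenes, function(s) s$density_level,
                         integer(1)) == 2))
  # deterministic under the same seed
  ts2 <- generate_tile_set(6, density_level = 2, size = 100, seed = 5)
  expect_identical(ts$y, ts2$y)
})
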