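test_that("component labeling matches adjacency definitions", {
  expect_equal(nrow(label_components(matrix(0L, 10, 10))$regions), 0)
  # two diagonally touching pixels
  m <- matrix(0L, 5, 5)
  m[2, 2] <- 1L; m[3, 3] <- 1L
  expect_equal(nrow(label_components(m, 8)$regions), 1)
  expect_equal(nrow(label_components(m, 4)$regions), 2)
  expect_error(label_components(m, 6), "4 or 8")
  expect_error(label_components(m + 1L), "binary")
})

test_that("labeling agrees with a flood-fill oracle on random masks", {
  set.seed(21)
  for (rep in 1:50) {
    m <- random_mask(64, 64, runif(1, 0.2, 0.6))
    for (conn in c(4, 8)) {
      rs <- label_components(m, conn)
      oracle <- floodfill_labels(m, conn)
      expect_equal(max(oracle), nrow(rs$regions))
      # same partition: labels must be a relabeling of each other
      fg <- m == 1
      expect_true(all(tapply(rs$labels[fg], oracle[fg],
                             function(v) length(unique(v))) == 1))
    }
  }
  # region table invariants on one case
  m <- random_mask(40, 40, 0.4, seed = 3)
  rs <- label_components(m, 8)
  expect_equal(sum(rs$regions$area), sum(m))
  expect_equal(rs$regions$region_id, seq_len(nrow(rs$regions)))
})

test_that("labeling agrees with EBImage where available", {
  skip_if_not_installed("EBImage")
  set.seed(9)
  for (rep in 1:5) {
    m <- random_mask(48, 48, 0.35)
    ours <- nrow(label_components(m, 4)$regions)
    theirs <- max(EBImage::bwlabel(m))
    expect_equal(ours, theirs)
  }
})

test_that("morphological closing obeys the morphology laws", {
  m <- random_mask(30, 30, 0.3, seed = 7)
  expect_identical(morphological_close(m, 0), m)
  c1 <- morphological_close(m, 1)
  expect_identical(morphological_close(c1, 1), c1)  # idempotent
  expect_true(all(c1[m == 1] == 1))                 # extensive
  # two glands 1 px apart merge under radius-1 closing (the adhesion
  # failure mode of closing-based post-filtering)
  m2 <- matrix(0L, 11, 11)
  m2[4:6, 3:4] <- 1L
  m2[4:6, 6:7] <- 1L   # gap of one column
  expect_equal(nrow(label_components(m2, 8)$regions), 2)
  closed <- morphological_close(m2, 1)
  expect_equal(nrow(label_components(closed, 8)$regions), 1)
})

test_that("area filtering keeps exactly the in-range regions", {
  m <- matrix(0L, 12, 20)
  m[2, 2] <- 1L                   # area 1
  m[5, 2:4] <- 1L                 # area 3
  m[8:9, 10:12] <- 1L             # area 6 (as 5 would need care) -> areas 1,3,6
  rs <- label_components(m, 8)
  expect_setequal(rs$regions$area, c(1, 3, 6))
  kept <- filter_regions(rs, filter_config(min_area = 2, closing_radius = 0))
  expect_setequal(kept$regions$area, c(3, 6))
  expect_equal(kept$regions$region_id, seq_len(2))
  expect_equal(sum(kept$labels > 0), 9)
  # min_area 1 is the identity; everything filtered leaves an empty set
  expect_equal(nrow(filter_regions(rs, filter_config(1, closing_radius = 0))$regions), 3)
  m1 <- matrix(0L, 5, 5); m1[1, 1] <- 1L; m1[3, 3] <- 1L
  rs1 <- label_components(m1, 8)
  expect_equal(nrow(filter_regions(rs1,
    filter_config(min_area = 2, closing_radius = 0))$regions), 0)
})

test_that("count_glands counts filtered connected domains", {
  expect_equal(count_glands(matrix(0L, 20, 20)), 0)
  sc <- generate_scene(scene_config(width = 120, height = 120,
                                    spot_count = 40, seed = 5))
  cfg <- filter_config(min_area = 2, closing_radius = 0)
  expect_equal(count_glands(sc$mask, cfg), 40)
  # ten spots plus seven single-pixel specks: specks are filtered out
  sc2 <- generate_scene(scene_config(width = 80, height = 80,
                                     spot_count = 10,
                                     spot_radius_range = c(2, 3), seed = 8))
  m <- sc2$mask
  empty <- which(m == 0)
  set.seed(4)
  specks <- 0
  for (p in sample(empty, 500)) {
    if (specks == 7) break
    ij <- arrayInd(p, dim(m))
    i <- ij[1]; j <- ij[2]
    ni <- max(1, i - 1):min(80, i + 1)
    nj <- max(1, j - 1):min(80, j + 1)
    if (all(m[ni, nj] == 0)) { m[i, j] <- 1L; specks <- specks + 1 }
  }
  expect_equal(specks, 7)
  expect_equal(count_glands(m, filter_config(min_area = 1,
                                             closing_radius = 0)), 17)
  expect_equal(count_glands(m, cfg), 10)
})

test_that("count is flip-invariant and monotone in min_area", {
  sc <- generate_scene(scene_config(width = 100, height = 100,
                                    spot_count = 25, seed = 12))
  cfg <- filter_config(min_area = 2, closing_radius = 0)
  n0 <- count_glands(sc$mask, cfg)
  expect_equal(count_glands(sc$mask[nrow(sc$mask):1, ], cfg), n0)
  expect_equal(count_glands(sc$mask[, ncol(sc$mask):1], cfg), n0)
  counts <- sapply(c(1, 2, 5, 10, 20), function(a)
    count_glands(sc$mask, filter_config(min_area = a, closing_radius = 0)))
  expect_true(all(diff(counts) <= 0))
})
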