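test_that("rasterization follows the pixel-center even-odd convention", {
  doc <- annotation_doc(10, 10, list())
  expect_equal(sum(rasterize_annotation(doc)), 0)
  # a 2x2 axis-aligned square: exactly the 4 pixels whose centers it covers
  sq <- annotation_doc(10, 10, list(list(
    label = "gland", points = rbind(c(3, 3), c(5, 3), c(5, 5), c(3, 5)))))
  m <- rasterize_annotation(sq)
  expect_equal(sum(m), 4)
  expect_equal(which(m == 1, arr.ind = TRUE)[, "row"], c(4, 5, 4, 5),
               ignore_attr = TRUE)
  # two disjoint polygons -> two components
  two <- annotation_doc(20, 20, list(
    list(label = "a", points = rbind(c(1, 1), c(4, 1), c(4, 4), c(1, 4))),
    list(label = "b", points = rbind(c(10, 10), c(15, 10), c(15, 15),
                                     c(10, 15)))))
  expect_equal(nrow(label_components(rasterize_annotation(two), 8)$regions), 2)
  expect_error(annotation_doc(10, 10, list(list(
    label = "bad", points = rbind(c(1, 1), c(2, 2))))), "polygon 1")
})

test_that("scanline fill agrees with a brute-force point-in-polygon oracle", {
  set.seed(41)
  for (rep in 1:8) {
    # random star-shaped polygon around a centre
    k <- sample(3:8, 1)
    ang <- sort(runif(k, 0, 2 * pi))
    r <- runif(k, 2, 9)
    pts <- cbind(10 + r * cos(ang), 10 + r * sin(ang))
    pts <- pmin(pmax(pts, 0), 20)
    doc <- annotation_doc(20, 20, list(list(label = "g", points = pts)))
    expect_identical(rasterize_annotation(doc), pip_rasterize(pts, 20, 20))
  }
})

test_that("mask -> rectangle polygons -> rasterize round-trips", {
  set.seed(17)
  for (rep in 1:5) {
    shapes <- lapply(1:3, function(i) {
      x0 <- sample(0:20, 1); y0 <- sample(0:20, 1)
      w <- sample(2:8, 1); h <- sample(2:8, 1)
      list(label = "g", points = rbind(c(x0, y0), c(x0 + w, y0),
                                       c(x0 + w, y0 + h), c(x0, y0 + h)))
    })
    ref <- matrix(0L, 30, 30)
    for (s in shapes) {
      p <- s$points
      ref[(p[1, 2] + 1):p[3, 2], (p[1, 1] + 1):p[3, 1]] <- 1L
    }
    doc <- annotation_doc(30, 30, shapes)
    expect_identical(rasterize_annotation(doc), ref)
  }
})

test_that("LabelMe JSON round-trips through disk", {
  doc <- annotation_doc(50, 40, list(
    list(label = "gland", points = rbind(c(5, 5), c(9, 5), c(7, 9)))))
  path <- withr::local_tempfile(fileext = ".json")
  write_labelme(doc, path)
  back <- read_labelme(path)
  expect_equal(back$width, 50)
  expect_equal(back$height, 40)
  expect_equal(back$shapes[[1]]$points, doc$shapes[[1]]$points)
  expect_equal(back$shapes[[1]]$label, "gland")
})

test_that("dataset splits are sized, disjoint and reproducible", {
  sp <- split_dataset(seq_len(6912), 0.8, seed = 1)
  expect_length(sp$train, 5529)
  expect_length(sp$validation, 1383)
  sp10 <- split_dataset(seq_len(10), 0.8, seed = 2)
  expect_length(sp10$train, 8)
  expect_length(sp10$validation, 2)
  expect_identical(split_dataset(letters, 0.8, seed = 9),
                   split_dataset(letters, 0.8, seed = 9))
  for (seed in 1:10) {
    sp <- split_dataset(seq_len(101), 0.7, seed = seed)
    expect_length(intersect(sp$train, sp$validation), 0)
    expect_setequal(c(sp$train, sp$validation), seq_len(101))
  }
  expect_error(split_dataset(list(1), 0.8), "at least 2")
  expect_error(split_dataset(1:10, 1.2), "fraction")
})

test_that("images and masks round-trip through PNG and BMP", {
  img <- generate_scene(scene_config(width = 40, height = 30,
                                     spot_count = 5, seed = 3))$image
  png_path <- withr::local_tempfile(fileext = ".png")
  bmp_path <- withr::local_tempfile(fileext = ".bmp")
  write_image(img, png_path)
  write_image(img, bmp_path)
  # 8-bit quantisation on both routes
  expect_lt(max(abs(read_image(png_path) - img)), 1 / 254)
  expect_lt(max(abs(read_image(bmp_path) - img)), 1 / 254)
  m <- random_mask(30, 40, 0.3, seed = 5)
  mp <- withr::local_tempfile(fileext = ".png")
  write_mask(m, mp)
  expect_identical(read_mask(mp), m + 0L)
  expect_error(read_image("x.tiff"), "unsupported")
})

test_that("scene sets are written with a consistent manifest", {
  dir <- withr::local_tempdir()
  scenes <- lapply(1:3, function(s)
    generate_scene(scene_config(width = 60, height = 60, spot_count = 8,
                                seed = s)))
  man <- write_scene_set(scenes, dir, prefix = "sc")
  expect_equal(nrow(man), 3)
  expect_true(all(file.exists(man$image_path)))
  expect_true(all(file.exists(man$mask_path)))
  expect_equal(man$count, rep(8, 3))
  back <- read_mask(man$mask_path[2])
  expect_identical(back, scenes[[2]]$mask + 0L)
})
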