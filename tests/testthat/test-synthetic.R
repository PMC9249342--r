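test_that("fixed per-class counts yield exactly that many boxes", {
  spec <- scene_spec(
    image_size = 256,
    classes = list(
      cell_class_spec("rbc", count = c(3, 3), radius = c(14, 18),
                      color = c(0.85, 0.5, 0.5)),
      cell_class_spec("wbc", count = c(1, 1), radius = c(40, 46),
                      color = c(0.45, 0.35, 0.7), max_iou = 0.6),
      cell_class_spec("platelet", count = c(2, 2), radius = c(3, 8),
                      color = c(0.5, 0.2, 0.55), max_iou = 0.2)
    ),
    seed = 3
  )
  sc <- generate_scene(spec)
  expect_equal(nrow(sc$boxes), 6)
  expect_equal(as.integer(table(sc$boxes$class)[c("rbc", "wbc", "platelet")]),
               c(3, 1, 2))
})

test_that("the same seed reproduces the scene bit for bit", {
  s1 <- generate_scene(tiny_spec(), seed = 99)
  s2 <- generate_scene(tiny_spec(), seed = 99)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$boxes, s2$boxes)
  s3 <- generate_scene(tiny_spec(), seed = 100)
  expect_false(identical(s1$image, s3$image))
})

test_that("platelet-like radii up to 12 px keep all boxes in the small band", {
  spec <- scene_spec(
    classes = list(cell_class_spec("platelet", count = c(4, 4),
                                   radius = c(3, 12),
                                   color = c(0.5, 0.2, 0.55), max_iou = 0.2)),
    seed = 5
  )
  areas <- unlist(lapply(1:20, function(i) generate_scene(spec, seed = i)$boxes$area))
  expect_true(all(areas > 0))
  expect_true(all(areas < 1024))
})

test_that("scene boxes always lie inside the image", {
  for (seed in 1:10) {
    sc <- generate_scene(tiny_spec(), seed = seed)
    expect_true(all(sc$boxes$x_min >= 0 & sc$boxes$y_min >= 0))
    expect_true(all(sc$boxes$x_max <= 96 & sc$boxes$y_max <= 96))
    expect_true(all(sc$boxes$area > 0))
  }
})

test_that("the manifest census matches a brute-force recount of annotation areas", {
  ds <- generate_dataset(tiny_spec(seed = 13), 12)
  areas <- ds$annotations$area
  expect_equal(ds$manifest$census$small, sum(areas < 1024))
  expect_equal(ds$manifest$census$medium, sum(areas >= 1024 & areas <= 9216))
  expect_equal(ds$manifest$census$large, sum(areas > 9216))
})

test_that("datasets round-trip through the COCO directory layout", {
  dir1 <- withr::local_tempdir()
  ds <- generate_dataset(tiny_spec(seed = 21), 4, out_dir = dir1)
  expect_length(list.files(dir1, pattern = "\\.png$"), 4)
  back <- read_dataset(dir1)
  expect_equal(back$categories, ds$categories)
  expect_equal(back$annotations[c("image_id", "category_id")],
               ds$annotations[c("image_id", "category_id")])
  expect_equal(as.matrix(back$annotations[c("x_min", "y_min", "x_max", "y_max")]),
               as.matrix(ds$annotations[c("x_min", "y_min", "x_max", "y_max")]),
               tolerance = 1e-12)
  # PNG quantises to 8/16 bit; pixel values must agree to that precision
  expect_lt(max(abs(back$images[[1]] - ds$images[[1]])), 1 / 255)
})

test_that("two runs with the same spec and seed write identical JSON", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  generate_dataset(tiny_spec(seed = 8), 3, out_dir = dir1)
  generate_dataset(tiny_spec(seed = 8), 3, out_dir = dir2)
  expect_identical(readLines(file.path(dir1, "annotations.json")),
                   readLines(file.path(dir2, "annotations.json")))
})

test_that("detection results round-trip through COCO results JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  dets <- box_tbl(c(1, 5), c(2, 6), c(11, 25), c(12, 30)) |>
    dplyr::mutate(image_id = c(1L, 2L), category_id = c(1L, 3L),
                  score = c(0.9, 0.4))
  write_detections(dets, path)
  back <- read_detections(path)
  expect_equal(back$score, dets$score)
  expect_equal(back$x_max, dets$x_max)
})
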