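gt_one <- function(box, image_id = 1L, category_id = 1L) {
  box_tbl(box[1], box[2], box[3], box[4],
          image_id = image_id, category_id = category_id)
}

det_one <- function(box, score, image_id = 1L, category_id = 1L) {
  box_tbl(box[1], box[2], box[3], box[4],
          image_id = image_id, category_id = category_id, score = score)
}

test_that("size bands follow the printed area boundaries", {
  expect_equal(assign_size_band(900), "small")
  expect_equal(assign_size_band(1024), "medium")
  expect_equal(assign_size_band(9216), "medium")
  expect_equal(assign_size_band(9217), "large")
  expect_equal(assign_size_band(10000), "large")
  expect_error(assign_size_band(0), "positive")
  expect_error(assign_size_band(-5), "positive")
})

test_that("perfect detections score mAP 1 and no detections score 0", {
  set.seed(3)
  gts <- dplyr::bind_rows(lapply(1:4, function(i) {
    b <- random_boxes(3, size = 200, min_side = 10, max_side = 60)
    box_tbl(b[, 1], b[, 2], b[, 3], b[, 4], image_id = i,
            category_id = sample(1:2, 3, TRUE))
  }))
  perfect <- dplyr::mutate(gts, score = 1)
  ev <- evaluate_detections(perfect, gts)
  expect_equal(ev$map, 1)
  ev0 <- evaluate_detections(NULL, gts)
  expect_equal(ev0$map, 0)
})

test_that("a single detection at IoU 0.6 scores AP 1 up to 0.60 and 0 above", {
  gt <- gt_one(c(0, 0, 10, 10))
  # width 6 overlapping box: IoU = 60/100... construct IoU 0.6 exactly:
  # intersection 15x10 = 6? Use box (0,0,6,10): inter 60, union 100 -> 0.6
  det <- det_one(c(0, 0, 6, 10), score = 0.8)
  ev <- evaluate_detections(det, gt)
  per <- ev$by_iou
  expect_equal(per$ap[per$iou_threshold <= 0.6], rep(1, 3))
  expect_equal(per$ap[per$iou_threshold > 0.6], rep(0, 7))
  expect_equal(ev$map, 0.3)
})

test_that("bands with no ground truths have undefined AP, not zero", {
  gt <- gt_one(c(0, 0, 10, 10)) # small only
  ev <- evaluate_detections(det_one(c(0, 0, 10, 10), 0.9), gt)
  expect_equal(ev$ap_small, 1)
  expect_true(is.na(ev$ap_medium))
  expect_true(is.na(ev$ap_large))
})

test_that("detections matching out-of-band ground truths are ignored, not false positives", {
  # one small gt and one large gt; the large-band evaluation must not punish
  # the detection that matches the small gt
  gts <- dplyr::bind_rows(gt_one(c(0, 0, 10, 10)), gt_one(c(50, 50, 150, 150)))
  dets <- dplyr::bind_rows(det_one(c(0, 0, 10, 10), 0.95),
                           det_one(c(50, 50, 150, 150), 0.90))
  ev <- evaluate_detections(dets, gts)
  expect_equal(ev$ap_small, 1)
  expect_equal(ev$ap_large, 1)
  expect_equal(ev$map, 1)
})

test_that("shuffling detection rows never changes any AP", {
  set.seed(31)
  for (rep in 1:5) {
    gts <- dplyr::bind_rows(lapply(1:3, function(i) {
      b <- random_boxes(4, size = 150, min_side = 8, max_side = 50)
      box_tbl(b[, 1], b[, 2], b[, 3], b[, 4], image_id = i,
              category_id = sample(1:2, 4, TRUE))
    }))
    dets <- dplyr::bind_rows(lapply(1:3, function(i) {
      b <- random_boxes(6, size = 150, min_side = 8, max_side = 50)
      box_tbl(b[, 1], b[, 2], b[, 3], b[, 4], image_id = i,
              category_id = sample(1:2, 6, TRUE),
              score = round(runif(6), 1)) # deliberate score ties
    }))
    e1 <- evaluate_detections(dets, gts)
    e2 <- evaluate_detections(dets[sample(nrow(dets)), ], gts)
    expect_equal(e1$by_class_band, e2$by_class_band)
  }
})

test_that("single-class all-area AP agrees with an independent greedy oracle", {
  set.seed(37)
  for (rep in 1:25) {
    n_img <- sample(1:3, 1)
    gts <- dplyr::bind_rows(lapply(seq_len(n_img), function(i) {
      b <- random_boxes(sample(1:5, 1), size = 120, min_side = 5, max_side = 60)
      box_tbl(b[, 1], b[, 2], b[, 3], b[, 4], image_id = i, category_id = 1L)
    }))
    dets <- dplyr::bind_rows(lapply(seq_len(n_img), function(i) {
      nd <- sample(0:6, 1)
      if (nd == 0) return(NULL)
      b <- random_boxes(nd, size = 120, min_side = 5, max_side = 60)
      # mix random boxes with jittered copies of ground truths
      g <- gts[gts$image_id == i, ]
      if (nrow(g) && runif(1) < 0.8) {
        j <- sample(nrow(g), min(nd, nrow(g)))
        b[seq_along(j), ] <- as.matrix(g[j, c("x_min", "y_min", "x_max", "y_max")]) +
          matrix(runif(4 * length(j), -4, 4), ncol = 4)
        b[, 3] <- pmax(b[, 3], b[, 1] + 1)
        b[, 4] <- pmax(b[, 4], b[, 2] + 1)
      }
      box_tbl(b[, 1], b[, 2], b[, 3], b[, 4], image_id = i, category_id = 1L,
              score = runif(nd))
    }))
    ev <- evaluate_detections(dets, gts)
    all_band <- ev$by_class_band[ev$by_class_band$band == "all", ]
    for (t in c(0.5, 0.75, 0.95)) {
      expect_equal(all_band$ap[all_band$iou_threshold == t],
                   oracle_ap_single_class(dets, gts, t),
                   tolerance = 1e-6)
    }
  }
})

test_that("eval results serialise to JSON with tidy/glance accessors", {
  gt <- gt_one(c(0, 0, 10, 10))
  ev <- evaluate_detections(det_one(c(0, 0, 10, 10), 0.9), gt)
  g <- glance(ev)
  expect_equal(g$map, 1)
  expect_true(all(c("category_id", "band", "iou_threshold", "ap") %in%
                    names(tidy(ev))))
  path <- withr::local_tempfile(fileext = ".json")
  write_eval(ev, path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$map, 1)
})
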