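# Independent reference implementations used as oracles. These are written
# from the definitions, deliberately avoiding the package's code paths.

# IoU of two single boxes, scalar arithmetic only.
oracle_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  aa <- (a[3] - a[1]) * (a[4] - a[2])
  ab <- (b[3] - b[1]) * (b[4] - b[2])
  if (inter == 0) 0 else inter / (aa + ab - inter)
}

# O(n^2) greedy NMS, index bookkeeping via explicit loops.
oracle_nms <- function(boxes, scores, thr) {
  ord <- order(-scores, boxes[, 1], boxes[, 2], boxes[, 3], boxes[, 4])
  alive <- rep(TRUE, nrow(boxes))
  keep <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    for (j in ord) {
      if (j == i || !alive[j]) next
      if (oracle_iou(boxes[i, ], boxes[j, ]) > thr) alive[j] <- FALSE
    }
    alive[i] <- FALSE
  }
  keep
}

# Exhaustive pairwise-IoU anchor labelling.
oracle_match <- function(anchors, gts, fg_iou, bg_iou) {
  n <- nrow(anchors)
  if (nrow(gts) == 0) {
    return(list(label = rep("background", n), gt_index = rep(NA_integer_, n)))
  }
  iou <- matrix(0, n, nrow(gts))
  for (i in seq_len(n)) {
    for (g in seq_len(nrow(gts))) iou[i, g] <- oracle_iou(anchors[i, ], gts[g, ])
  }
  label <- rep("ignore", n)
  gt_index <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    m <- max(iou[i, ])
    if (m >= fg_iou) {
      label[i] <- "foreground"
      gt_index[i] <- which.max(iou[i, ])
    } else if (m < bg_iou) {
      label[i] <- "background"
    }
  }
  for (g in seq_len(nrow(gts))) {
    bm <- max(iou[, g])
    if (bm > 0) {
      for (i in which(abs(iou[, g] - bm) <= 1e-7)) {
        label[i] <- "foreground"
        gt_index[i] <- g
      }
    }
  }
  list(label = label, gt_index = gt_index)
}

# Reference unweighted Faster-R-CNN-style loss, coded directly from the
# definition: mean CE over classification samples, mean smooth-L1 (summed
# over 4 coords) over regression samples, total with lambda.
oracle_ce_one <- function(logits, label) {
  p <- exp(logits) / sum(exp(logits))
  -log(p[label])
}

oracle_sl1_one <- function(pred, target) {
  s <- 0
  for (c in 1:4) {
    d <- pred[c] - target[c]
    s <- s + if (abs(d) < 1) 0.5 * d^2 else abs(d) - 0.5
  }
  s
}

oracle_baseline_loss <- function(rpn_cls, rpn_reg, roi_cls, roi_reg, lambda = 1) {
  comp <- function(cls) {
    if (nrow(cls) == 0) return(0)
    v <- vapply(seq_len(nrow(cls)),
                function(i) oracle_ce_one(cls$logits[i, ], cls$label[i]),
                numeric(1))
    mean(v)
  }
  regc <- function(reg) {
    if (nrow(reg) == 0) return(0)
    v <- vapply(seq_len(nrow(reg)),
                function(i) oracle_sl1_one(reg$pred_deltas[i, ],
                                           reg$target_deltas[i, ]),
                numeric(1))
    mean(v)
  }
  c1 <- comp(rpn_cls); r1 <- regc(rpn_reg)
  c2 <- comp(roi_cls); r2 <- regc(roi_reg)
  list(cls_rpn = c1, reg_rpn = r1, cls_roi = c2, reg_roi = r2,
       total = c1 + lambda * r1 + c2 + lambda * r2)
}

# Independent COCO-style AP for a single class over all areas: greedy
# score-ordered matching per image, each ground truth used once, 101-point
# interpolation. No ignore handling (callers use in-band-only instances).
oracle_ap_single_class <- function(dets, gts, threshold) {
  n_pos <- nrow(gts)
  if (n_pos == 0) return(NA_real_)
  if (nrow(dets) == 0) return(0)
  ord <- order(-dets$score, dets$image_id, dets$x_min, dets$y_min,
               dets$x_max, dets$y_max)
  dets <- dets[ord, , drop = FALSE]
  used <- rep(FALSE, nrow(gts))
  tp <- logical(nrow(dets))
  for (d in seq_len(nrow(dets))) {
    best <- threshold - 1e-10
    m <- 0
    for (g in seq_len(nrow(gts))) {
      if (used[g] || gts$image_id[g] != dets$image_id[d]) next
      v <- oracle_iou(as.numeric(dets[d, c("x_min", "y_min", "x_max", "y_max")]),
                      as.numeric(gts[g, c("x_min", "y_min", "x_max", "y_max")]))
      if (v >= best) {
        best <- v
        m <- g
      }
    }
    if (m > 0) {
      used[m] <- TRUE
      tp[d] <- TRUE
    }
  }
  ctp <- cumsum(tp)
  recall <- ctp / n_pos
  precision <- ctp / seq_along(tp)
  ap <- 0
  for (r in seq(0, 1, 0.01)) {
    idx <- which(recall >= r)
    ap <- ap + if (length(idx)) max(precision[min(idx):length(precision)]) else 0
  }
  ap / 101
}

# Random boxes fully inside a square image.
random_boxes <- function(n, size = 100, min_side = 2, max_side = 40) {
  w <- runif(n, min_side, max_side)
  h <- runif(n, min_side, max_side)
  x <- runif(n, 0, size - w)
  y <- runif(n, 0, size - h)
  unname(cbind(x, y, x + w, y + h))
}

# Random classification / regression sample sets for loss tests.
random_cls_set <- function(n, k = 3, with_boxes = TRUE) {
  if (n == 0) return(cls_samples(matrix(0, 0, k), integer(0), logical(0)))
  fg <- runif(n) < 0.6
  if (!any(fg)) fg[1] <- TRUE
  b <- matrix(NA_real_, n, 4)
  b[fg, ] <- random_boxes(sum(fg))
  cls_samples(matrix(rnorm(n * k), n, k), sample.int(k, n, replace = TRUE),
              fg, if (with_boxes) b else NULL)
}

random_reg_set <- function(n) {
  if (n == 0) {
    return(reg_samples(matrix(0, 0, 4), matrix(0, 0, 4), matrix(0, 0, 4)))
  }
  reg_samples(matrix(rnorm(n * 4), n, 4), matrix(rnorm(n * 4), n, 4),
              random_boxes(n))
}
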