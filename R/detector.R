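#' Configuration of the desk-scale two-stage detector
#'
#' A deliberately small Faster-R-CNN-style detector: a three-layer
#' convolutional backbone producing a single feature map at stride 4, a
#' region proposal network (RPN) head, and an ROI head with 7x7 average
#' region pooling and one hidden fully connected layer. Sized for 128x128
#' images so that training runs in minutes on one CPU.
#'
#' @param image_size Side length of (square) input images, pixels.
#' @param anchor_sizes Anchor base sizes in pixels (geometric mean of width
#'   and height).
#' @param anchor_aspect_ratios Width/height ratios of the anchors.
#' @param rpn_fg_iou,rpn_bg_iou Anchor-matching IoU thresholds: anchors with
#'   best IoU at or above `rpn_fg_iou` are foreground, below `rpn_bg_iou`
#'   background, in between ignored. Each object's best anchor is always
#'   forced foreground.
#' @param roi_fg_iou Proposal-matching foreground threshold for the ROI head.
#' @param rpn_batch,roi_batch Per-image minibatch sizes of the two stages.
#' @param rpn_fg_fraction,roi_fg_fraction Target foreground fraction in each
#'   minibatch.
#' @param rpn_pre_nms,rpn_post_nms,rpn_nms_iou Proposal filtering: top-k by
#'   objectness before NMS, boxes kept after NMS, and the NMS IoU.
#' @param nms_iou,score_threshold Inference-time class-wise NMS IoU and
#'   minimum detection score.
#' @param channels Channel widths of the three backbone convolutions.
#' @param rpn_channels RPN hidden convolution width.
#' @param fc_dim ROI head hidden width.
#' @param roi_pool_bins Region pooling output is `bins x bins` per channel.
#' @param lr,momentum,lr_step,lr_gamma SGD with momentum; the learning rate
#'   is multiplied by `lr_gamma` every `lr_step` epochs.
#' @param grad_clip Global L2 gradient-norm clip.
#' @param seed Integer seed controlling initialisation and sampling.
#' @return A `plb_detector_config` list.
#' @export
detector_config <- function(image_size = 128,
                            anchor_sizes = c(10, 14, 20, 32, 48, 112),
                            anchor_aspect_ratios = c(0.75, 1, 1.5),
                            rpn_fg_iou = 0.7, rpn_bg_iou = 0.3, roi_fg_iou = 0.5,
                            rpn_batch = 256, rpn_fg_fraction = 0.5,
                            roi_batch = 64, roi_fg_fraction = 0.5,
                            rpn_pre_nms = 1024, rpn_post_nms = 64, rpn_nms_iou = 0.7,
                            nms_iou = 0.5, score_threshold = 0.05,
                            channels = c(8, 16, 32), rpn_channels = 32,
                            fc_dim = 128, roi_pool_bins = 7,
                            lr = 0.01, momentum = 0.9, lr_step = 6, lr_gamma = 0.3,
                            grad_clip = 5, seed = 1) {
  stopifnot(
    rpn_bg_iou >= 0, rpn_bg_iou < rpn_fg_iou, rpn_fg_iou <= 1,
    roi_fg_iou > 0, roi_fg_iou <= 1,
    rpn_fg_fraction > 0, rpn_fg_fraction < 1,
    roi_fg_fraction > 0, roi_fg_fraction < 1,
    image_size %% 4 == 0, length(channels) == 3
  )
  structure(as.list(environment()), class = "plb_detector_config")
}

# Anchor boxes, one per (position, shape); positions are column-major over
# the (Hf, Wf) feature grid so anchor q = (p - 1) * A + a aligns with the
# reshaped head outputs.
generate_anchors <- function(config) {
  hf <- config$image_size / 4L
  stride <- 4
  ij <- expand.grid(i = seq_len(hf), j = seq_len(hf))
  cy <- (ij$i - 0.5) * stride
  cx <- (ij$j - 0.5) * stride
  shapes <- expand.grid(ratio = config$anchor_aspect_ratios,
                        size = config$anchor_sizes)
  w <- shapes$size * sqrt(shapes$ratio)
  h <- shapes$size / sqrt(shapes$ratio)
  a <- nrow(shapes)
  n <- length(cx) * a
  idx_pos <- rep(seq_along(cx), each = a)
  idx_shape <- rep(seq_len(a), times = length(cx))
  cbind(
    cx[idx_pos] - w[idx_shape] / 2, cy[idx_pos] - h[idx_shape] / 2,
    cx[idx_pos] + w[idx_shape] / 2, cy[idx_pos] + h[idx_shape] / 2
  )
}

#' Match anchors (or proposals) to ground-truth boxes
#'
#' Anchors whose best IoU with any ground truth reaches `fg_iou` become
#' foreground; those strictly below `bg_iou` background; the rest are
#' ignored. When `force_best` is set, each ground truth's highest-IoU
#' anchor(s) are additionally forced foreground so every object is
#' trainable, however small.
#'
#' @param anchors,gts Box tibbles or 4-column matrices.
#' @param fg_iou,bg_iou Matching thresholds, `0 <= bg_iou <= fg_iou <= 1`.
#' @param force_best Force each ground truth's best anchor foreground.
#' @return A tibble with one row per anchor: `label`
#'   (`"foreground"`/`"background"`/`"ignore"`), `gt_index` (NA for
#'   non-foreground) and `max_iou`.
#' @export
match_anchors <- function(anchors, gts, fg_iou = 0.7, bg_iou = 0.3,
                          force_best = TRUE) {
  a <- as_box_matrix(anchors)
  n <- nrow(a)
  if (n == 0) rlang::abort("match_anchors needs a non-empty anchor set")
  g <- if (is.null(gts)) matrix(0, 0, 4) else as_box_matrix(gts)
  if (nrow(g) == 0) {
    return(tibble::tibble(label = rep("background", n),
                          gt_index = rep(NA_integer_, n),
                          max_iou = rep(0, n)))
  }
  iou <- box_iou(a, g)
  best_gt <- max.col(iou, ties.method = "first")
  mx <- iou[cbind(seq_len(n), best_gt)]
  label <- rep("ignore", n)
  label[mx < bg_iou] <- "background"
  label[mx >= fg_iou] <- "foreground"
  gt_index <- ifelse(label == "foreground", best_gt, NA_integer_)
  if (force_best) {
    for (k in seq_len(ncol(iou))) {
      bm <- max(iou[, k])
      if (bm > 0) {
        hit <- which(iou[, k] >= bm - 1e-7)
        label[hit] <- "foreground"
        gt_index[hit] <- k
      }
    }
  }
  tibble::tibble(label = label, gt_index = as.integer(gt_index), max_iou = mx)
}

sample_minibatch <- function(labels, batch, fg_fraction) {
  fg <- which(labels == "foreground")
  bg <- which(labels == "background")
  n_fg <- min(length(fg), round(batch * fg_fraction))
  if (length(fg) > n_fg) fg <- sample(fg, n_fg)
  n_bg <- min(length(bg), batch - length(fg))
  if (length(bg) > n_bg) bg <- sample(bg, n_bg)
  list(fg = fg, bg = bg)
}

init_detector_params <- function(config, n_classes) {
  a <- length(config$anchor_sizes) * length(config$anchor_aspect_ratios)
  ch <- config$channels
  pool_dim <- config$roi_pool_bins^2 * ch[3]
  list(
    conv1 = conv_param(3, 3, ch[1]),
    conv2 = conv_param(3, ch[1], ch[2]),
    conv3 = conv_param(3, ch[2], ch[3]),
    rpn_conv = conv_param(3, ch[3], config$rpn_channels),
    rpn_cls = fc_param(config$rpn_channels, 2 * a, sd = 0.01),
    rpn_reg = fc_param(config$rpn_channels, 4 * a, sd = 0.01),
    fc1 = fc_param(pool_dim, config$fc_dim),
    roi_cls = fc_param(config$fc_dim, n_classes + 1, sd = 0.01),
    roi_reg = fc_param(config$fc_dim, 4, sd = 0.01)
  )
}

# (P, A*d) head output -> (P*A, d) per-anchor rows, and its inverse.
reshape_heads <- function(m, a, d) {
  p <- nrow(m)
  out <- matrix(0, p * a, d)
  for (k in seq_len(a)) {
    out[seq(k, p * a, by = a), ] <- m[, ((k - 1) * d + 1):(k * d)]
  }
  out
}

unshape_heads <- function(g, a, d) {
  p <- nrow(g) / a
  out <- matrix(0, p, a * d)
  for (k in seq_len(a)) {
    out[, ((k - 1) * d + 1):(k * d)] <- g[seq(k, p * a, by = a), , drop = FALSE]
  }
  out
}

backbone_forward <- function(x, params) {
  c1 <- conv_fw(x, params$conv1, stride = 2L); f1 <- relu(c1$out)
  c2 <- conv_fw(f1, params$conv2, stride = 2L); f2 <- relu(c2$out)
  c3 <- conv_fw(f2, params$conv3, stride = 1L); f3 <- relu(c3$out)
  cr <- conv_fw(f3, params$rpn_conv, stride = 1L); r <- relu(cr$out)
  hf <- dim(f3)[1]
  rmat <- matrix(r, hf * hf, dim(r)[3])
  a <- ncol(params$rpn_cls$w) / 2
  list(
    x = x, c1 = c1, f1 = f1, c2 = c2, f2 = f2, c3 = c3, f3 = f3,
    cr = cr, r = r, rmat = rmat, hf = hf,
    rpn_logits = reshape_heads(fc_fw(rmat, params$rpn_cls), a, 2),
    rpn_deltas = reshape_heads(fc_fw(rmat, params$rpn_reg), a, 4)
  )
}

# Gradients through RPN heads and backbone given per-anchor logit/delta
# gradients (full-length matrices, zero rows for unsampled anchors) and the
# ROI contribution to the shared feature map.
backbone_backward <- function(fw, params, d_logits, d_deltas, dfeat3_roi) {
  a <- ncol(params$rpn_cls$w) / 2
  g_cls <- fc_bw(fw$rmat, params$rpn_cls, unshape_heads(d_logits, a, 2))
  g_reg <- fc_bw(fw$rmat, params$rpn_reg, unshape_heads(d_deltas, a, 4))
  drmat <- g_cls$dx + g_reg$dx
  dr <- array(drmat, dim(fw$r))
  g_rpnc <- conv_bw(fw$cr, dim(fw$f3), params$rpn_conv,
                    relu_bw(fw$cr$out, dr), stride = 1L)
  dfeat3 <- g_rpnc$dx
  if (!is.null(dfeat3_roi)) dfeat3 <- dfeat3 + dfeat3_roi
  g3 <- conv_bw(fw$c3, dim(fw$f2), params$conv3,
                relu_bw(fw$c3$out, dfeat3), stride = 1L)
  g2 <- conv_bw(fw$c2, dim(fw$f1), params$conv2,
                relu_bw(fw$c2$out, g3$dx), stride = 2L)
  g1 <- conv_bw(fw$c1, dim(fw$x), params$conv1,
                relu_bw(fw$c1$out, g2$dx), stride = 2L, skip_dx = TRUE)
  list(
    conv1 = list(w = g1$dw, b = g1$db),
    conv2 = list(w = g2$dw, b = g2$db),
    conv3 = list(w = g3$dw, b = g3$db),
    rpn_conv = list(w = g_rpnc$dw, b = g_rpnc$db),
    rpn_cls = list(w = g_cls$dw, b = g_cls$db),
    rpn_reg = list(w = g_reg$dw, b = g_reg$db)
  )
}

roi_forward <- function(f3, rois, params, config) {
  pooled <- cpp_roi_pool_forward(f3, rois, 4, config$roi_pool_bins)
  hp <- fc_fw(pooled, params$fc1)
  h <- relu(hp)
  list(pooled = pooled, hp = hp, h = h,
       cls_logits = fc_fw(h, params$roi_cls),
       reg_deltas = fc_fw(h, params$roi_reg))
}

roi_backward <- function(fw_roi, rois, params, config, d_cls, d_reg, feat_dim) {
  g_cls <- fc_bw(fw_roi$h, params$roi_cls, d_cls)
  g_reg <- fc_bw(fw_roi$h, params$roi_reg, d_reg)
  g_fc1 <- fc_bw(fw_roi$pooled, params$fc1, relu_bw(fw_roi$hp, g_cls$dx + g_reg$dx))
  dfeat3 <- cpp_roi_pool_backward(feat_dim[1], feat_dim[2], feat_dim[3],
                                  rois, 4, config$roi_pool_bins, g_fc1$dx)
  list(grads = list(fc1 = list(w = g_fc1$dw, b = g_fc1$db),
                    roi_cls = list(w = g_cls$dw, b = g_cls$db),
                    roi_reg = list(w = g_reg$dw, b = g_reg$db)),
       dfeat3 = dfeat3)
}

gen_proposals <- function(anchors, fw, config, gts = NULL) {
  score <- fw$rpn_logits[, 2] - fw$rpn_logits[, 1]
  boxes <- cpp_decode_clip(anchors, fw$rpn_deltas, config$image_size, 4, 1e-3)
  wide <- (boxes[, 3] - boxes[, 1] >= 2) & (boxes[, 4] - boxes[, 2] >= 2)
  boxes <- boxes[wide, , drop = FALSE]
  score <- score[wide]
  top <- order(-score)[seq_len(min(config$rpn_pre_nms, length(score)))]
  keep <- nms(boxes[top, , drop = FALSE], score[top],
              config$rpn_nms_iou, config$rpn_post_nms)
  props <- boxes[top[keep], , drop = FALSE]
  if (!is.null(gts) && nrow(gts) > 0) props <- rbind(props, as_box_matrix(gts))
  props
}

# One optimisation step on a single image. Returns the loss breakdown and
# parameter gradients.
detector_step <- function(image, gt_boxes, gt_classes, params, anchors,
                          config, loss_config, n_classes, rpn_match = NULL) {
  fw <- backbone_forward(image, params)
  sz <- config$image_size
  gts <- if (length(gt_classes)) gt_boxes else matrix(0, 0, 4)
  predict_source <- loss_config$weight_config$size_source == "predict_box"

  ## ----- RPN stage -----
  m <- if (is.null(rpn_match)) {
    match_anchors(anchors, gts, config$rpn_fg_iou, config$rpn_bg_iou)
  } else rpn_match
  samp <- sample_minibatch(m$label, config$rpn_batch, config$rpn_fg_fraction)
  s_idx <- c(samp$fg, samp$bg)
  fg_idx <- samp$fg
  rpn_labels <- c(rep(2L, length(samp$fg)), rep(1L, length(samp$bg)))
  size_box_rpn <- matrix(NA_real_, length(s_idx), 4)
  if (length(fg_idx)) {
    decoded_fg <- cpp_decode_clip(anchors[fg_idx, , drop = FALSE],
                                  fw$rpn_deltas[fg_idx, , drop = FALSE],
                                  sz, 4, 1e-3)
    matched_fg <- gts[m$gt_index[fg_idx], , drop = FALSE]
    size_box_rpn[seq_along(fg_idx), ] <- if (predict_source) decoded_fg else matched_fg
  }
  rpn_cls_s <- cls_samples(fw$rpn_logits[s_idx, , drop = FALSE], rpn_labels,
                           rpn_labels == 2L, size_box_rpn)
  if (length(fg_idx)) {
    rpn_targets <- encode_deltas(anchors[fg_idx, , drop = FALSE], matched_fg)
    rpn_reg_s <- reg_samples(fw$rpn_deltas[fg_idx, , drop = FALSE], rpn_targets,
                             if (predict_source) decoded_fg else matched_fg)
  } else {
    rpn_reg_s <- empty_reg_samples()
  }

  ## ----- ROI stage -----
  props <- gen_proposals(anchors, fw, config, gts)
  mp <- match_anchors(props, gts, config$roi_fg_iou, config$roi_fg_iou,
                      force_best = FALSE)
  samp_roi <- sample_minibatch(mp$label, config$roi_batch, config$roi_fg_fraction)
  roi_idx <- c(samp_roi$fg, samp_roi$bg)
  rois <- props[roi_idx, , drop = FALSE]
  n_fg_roi <- length(samp_roi$fg)
  roi_labels <- rep(1L, length(roi_idx))
  if (n_fg_roi) {
    roi_gt <- mp$gt_index[samp_roi$fg]
    roi_labels[seq_len(n_fg_roi)] <- gt_classes[roi_gt] + 1L
  }
  fw_roi <- roi_forward(fw$f3, rois, params, config)
  size_box_roi <- matrix(NA_real_, length(roi_idx), 4)
  if (n_fg_roi) {
    fg_rows <- seq_len(n_fg_roi)
    decoded_roi <- cpp_decode_clip(rois[fg_rows, , drop = FALSE],
                                   fw_roi$reg_deltas[fg_rows, , drop = FALSE],
                                   sz, 4, 1e-3)
    matched_roi <- gts[roi_gt, , drop = FALSE]
    size_box_roi[fg_rows, ] <- if (predict_source) decoded_roi else matched_roi
    roi_targets <- encode_deltas(rois[fg_rows, , drop = FALSE], matched_roi)
    roi_reg_s <- reg_samples(fw_roi$reg_deltas[fg_rows, , drop = FALSE],
                             roi_targets,
                             if (predict_source) decoded_roi else matched_roi)
  } else {
    roi_reg_s <- empty_reg_samples()
  }
  roi_cls_s <- cls_samples(fw_roi$cls_logits, roi_labels,
                           roi_labels > 1L, size_box_roi)

  ## ----- losses and gradients -----
  breakdown <- suppressWarnings(
    total_loss(rpn_cls_s, rpn_reg_s, roi_cls_s, roi_reg_s, loss_config)
  )
  w <- attr(breakdown, "weights")
  lam <- loss_config$lambda_balance

  d_logits_full <- matrix(0, nrow(fw$rpn_logits), 2)
  if (!is.null(w$cls_rpn) && length(s_idx)) {
    probs <- softmax_rows(fw$rpn_logits[s_idx, , drop = FALSE])
    onehot <- matrix(0, length(s_idx), 2)
    onehot[cbind(seq_along(s_idx), rpn_labels)] <- 1
    d_logits_full[s_idx, ] <- w$cls_rpn * (probs - onehot) / length(s_idx)
  }
  d_deltas_full <- matrix(0, nrow(fw$rpn_deltas), 4)
  if (!is.null(w$reg_rpn) && length(fg_idx)) {
    gr <- smooth_l1_grad(fw$rpn_deltas[fg_idx, , drop = FALSE] - rpn_targets)
    d_deltas_full[fg_idx, ] <- lam * (w$reg_rpn / length(fg_idx)) * gr
  }

  d_roi_cls <- matrix(0, length(roi_idx), n_classes + 1)
  if (!is.null(w$cls_roi) && length(roi_idx)) {
    probs <- softmax_rows(fw_roi$cls_logits)
    onehot <- matrix(0, length(roi_idx), n_classes + 1)
    onehot[cbind(seq_along(roi_idx), roi_labels)] <- 1
    d_roi_cls <- w$cls_roi * (probs - onehot) / length(roi_idx)
  }
  d_roi_reg <- matrix(0, length(roi_idx), 4)
  if (!is.null(w$reg_roi) && n_fg_roi) {
    gr <- smooth_l1_grad(fw_roi$reg_deltas[seq_len(n_fg_roi), , drop = FALSE] - roi_targets)
    d_roi_reg[seq_len(n_fg_roi), ] <- lam * (w$reg_roi / n_fg_roi) * gr
  }

  roi_bw <- roi_backward(fw_roi, rois, params, config, d_roi_cls, d_roi_reg,
                         dim(fw$f3))
  grads <- c(
    backbone_backward(fw, params, d_logits_full, d_deltas_full, roi_bw$dfeat3),
    roi_bw$grads
  )
  list(breakdown = breakdown, grads = grads, weights = w)
}

dataset_gt <- function(dataset) {
  ann <- dataset$annotations
  lapply(seq_along(dataset$images), function(i) {
    rows <- ann[ann$image_id == i, , drop = FALSE]
    list(boxes = as_box_matrix(rows), classes = rows$category_id)
  })
}

#' Train the desk-scale two-stage detector
#'
#' Runs SGD with momentum over single-image steps: anchors are matched and
#' sampled, RPN proposals feed the ROI head, and the four-component loss —
#' with any combination of the PLB switches — drives hand-written
#' backpropagation. Training is deterministic given the seed.
#'
#' @param dataset A dataset as returned by [generate_dataset()] (or any list
#'   with `images`, `annotations`, `categories` in the same layout).
#' @param config A [detector_config()].
#' @param loss_config A [plb_loss_config()].
#' @param epochs Number of passes over the dataset.
#' @param eval_data Optional held-out dataset evaluated after every
#'   `eval_every` epochs (and after the last).
#' @param eval_every Epoch interval for evaluation; `NULL` evaluates only at
#'   the end when `eval_data` is given.
#' @param log_path Optional path for a JSON-lines per-step training log.
#' @param verbose Print per-epoch mean losses.
#' @return A `plb_detector` object: trained parameters, configs, category
#'   table, per-step `history` tibble (losses and PLB weight statistics) and
#'   optional `eval_history`.
#' @export
train_detector <- function(dataset, config = detector_config(),
                           loss_config = plb_loss_config(), epochs = 10,
                           eval_data = NULL, eval_every = NULL,
                           log_path = NULL, verbose = FALSE) {
  stopifnot(length(dataset$images) > 0)
  n_classes <- nrow(dataset$categories)
  gt <- dataset_gt(dataset)
  anchors <- generate_anchors(config)
  # anchors and ground truths are fixed, so RPN matching is image-static
  rpn_matches <- lapply(gt, function(g) {
    match_anchors(anchors, g$boxes, config$rpn_fg_iou, config$rpn_bg_iou)
  })
  con <- if (!is.null(log_path)) file(log_path, open = "wt") else NULL
  on.exit(if (!is.null(con)) close(con))

  hist_cols <- c("epoch", "step", "image_id", "cls_rpn", "reg_rpn", "cls_roi",
                 "reg_roi", "total", "w_mean_cls_rpn", "w_mean_reg_rpn",
                 "w_mean_cls_roi", "w_mean_reg_roi")
  history <- matrix(NA_real_, epochs * length(dataset$images), length(hist_cols),
                    dimnames = list(NULL, hist_cols))
  eval_history <- list()
  step <- 0L
  with_seed(config$seed, {
    params <- init_detector_params(config, n_classes)
    velocity <- zero_like(params)
    for (epoch in seq_len(epochs)) {
      lr <- config$lr * config$lr_gamma^((epoch - 1) %/% config$lr_step)
      ord <- sample(length(dataset$images))
      for (i in ord) {
        step <- step + 1L
        res <- detector_step(dataset$images[[i]], gt[[i]]$boxes, gt[[i]]$classes,
                             params, anchors, config, loss_config, n_classes,
                             rpn_match = rpn_matches[[i]])
        if (!is.finite(res$breakdown$total)) {
          rlang::abort(sprintf(
            "training diverged at epoch %d step %d (total loss %g); lower lr or grad_clip",
            epoch, step, res$breakdown$total))
        }
        grads <- clip_gradients(res$grads, config$grad_clip)
        upd <- sgd_update(params, grads, velocity, lr, config$momentum)
        params <- upd$params
        velocity <- upd$velocity
        wstats <- vapply(res$weights[c("cls_rpn", "reg_rpn", "cls_roi", "reg_roi")],
                         function(w) if (is.null(w)) NA_real_ else mean(w),
                         numeric(1))
        history[step, ] <- c(epoch, step, i, res$breakdown$cls_rpn,
                             res$breakdown$reg_rpn, res$breakdown$cls_roi,
                             res$breakdown$reg_roi, res$breakdown$total, wstats)
        if (!is.null(con)) {
          writeLines(jsonlite::toJSON(as.list(history[step, ]),
                                      auto_unbox = TRUE, digits = NA), con)
        }
      }
      if (verbose) {
        ep <- tibble::as_tibble(history[(step - length(ord) + 1):step, , drop = FALSE])
        message(sprintf("epoch %d: total %.4f (cls_rpn %.4f reg_rpn %.4f cls_roi %.4f reg_roi %.4f)",
                        epoch, mean(ep$total), mean(ep$cls_rpn), mean(ep$reg_rpn),
                        mean(ep$cls_roi), mean(ep$reg_roi)))
      }
      do_eval <- !is.null(eval_data) &&
        (if (is.null(eval_every)) epoch == epochs else
           (epoch %% eval_every == 0 || epoch == epochs))
      if (do_eval) {
        model_now <- new_plb_detector(params, config, loss_config,
                                      dataset$categories, NULL, NULL, anchors)
        ev <- evaluate_model(model_now, eval_data)
        eval_history[[length(eval_history) + 1]] <-
          dplyr::bind_cols(tibble::tibble(epoch = epoch), glance(ev))
      }
    }
  })
  new_plb_detector(params, config, loss_config, dataset$categories,
                   tibble::as_tibble(history),
                   if (length(eval_history)) dplyr::bind_rows(eval_history) else NULL,
                   anchors)
}

new_plb_detector <- function(params, config, loss_config, categories, history,
                             eval_history, anchors) {
  structure(
    list(params = params, config = config, loss_config = loss_config,
         categories = categories, history = history,
         eval_history = eval_history, anchors = anchors),
    class = "plb_detector"
  )
}

#' @export
print.plb_detector <- function(x, ...) {
  n_par <- sum(vapply(unlist(x$params, recursive = FALSE), length, numeric(1)))
  cat(sprintf("<plb_detector> %d parameters, %d classes\n",
              n_par, nrow(x$categories)))
  sw <- c("plb1c", "plb1b", "plb2c", "plb2b")
  on <- sw[vapply(sw, function(s) isTRUE(x$loss_config[[s]]), logical(1))]
  cat("PLB switches:", if (length(on)) paste(on, collapse = ", ") else "none (baseline)", "\n")
  if (!is.null(x$history)) {
    cat(sprintf("trained %d steps, final total loss %.4f\n",
                nrow(x$history), mean(utils::tail(x$history$total, 20))))
  }
  invisible(x)
}

#' Run inference on one image
#'
#' Forward pass, proposal generation, ROI scoring, score thresholding and
#' class-wise greedy NMS.
#'
#' @param model A trained [train_detector()] object.
#' @param image An `image_size x image_size x 3` array in `[0, 1]`.
#' @param score_threshold,nms_iou Override the config values.
#' @param max_dets Keep at most this many detections.
#' @return A tibble of detections: box columns, `category_id`, `class`,
#'   `score`, sorted by decreasing score.
#' @export
predict_boxes <- function(model, image, score_threshold = NULL, nms_iou = NULL,
                          max_dets = 100) {
  config <- model$config
  if (is.null(score_threshold)) score_threshold <- config$score_threshold
  if (is.null(nms_iou)) nms_iou <- config$nms_iou
  fw <- backbone_forward(image, model$params)
  props <- gen_proposals(model$anchors, fw, config)
  empty <- box_tbl(numeric(0), numeric(0), numeric(0), numeric(0),
                   category_id = integer(0), class = character(0),
                   score = numeric(0))
  if (nrow(props) == 0) return(empty)
  fw_roi <- roi_forward(fw$f3, props, model$params, config)
  probs <- softmax_rows(fw_roi$cls_logits)
  boxes <- as_box_matrix(decode_deltas(props, fw_roi$reg_deltas,
                                       config$image_size, config$image_size))
  out <- list()
  for (k in seq_len(nrow(model$categories))) {
    sc <- probs[, k + 1]
    sel <- which(sc >= score_threshold)
    if (!length(sel)) next
    keep <- nms(boxes[sel, , drop = FALSE], sc[sel], nms_iou)
    kept <- sel[keep]
    out[[k]] <- box_tbl(boxes[kept, 1], boxes[kept, 2], boxes[kept, 3],
                        boxes[kept, 4],
                        category_id = model$categories$id[k],
                        class = model$categories$name[k],
                        score = sc[kept])
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out) |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    utils::head(max_dets)
}

#' Detections for every image of a dataset
#'
#' @param model A trained detector.
#' @param dataset A dataset in [generate_dataset()] layout.
#' @param ... Passed to [predict_boxes()].
#' @return A detections tibble with an `image_id` column.
#' @export
predict_dataset <- function(model, dataset, ...) {
  purrr::map_dfr(seq_along(dataset$images), function(i) {
    d <- predict_boxes(model, dataset$images[[i]], ...)
    if (nrow(d)) dplyr::mutate(d, image_id = i, .before = 1) else NULL
  })
}

#' Evaluate a trained detector on a dataset
#'
#' @param model A trained detector.
#' @param dataset A dataset in [generate_dataset()] layout.
#' @param ... Passed to [predict_boxes()].
#' @return A `plb_eval` object (see [evaluate_detections()]).
#' @export
evaluate_model <- function(model, dataset, ...) {
  dets <- predict_dataset(model, dataset, ...)
  evaluate_detections(dets, dataset$annotations)
}

#' Save / load a trained detector
#'
#' Checkpoints are plain RDS files.
#'
#' @param model A `plb_detector`.
#' @param path File path.
#' @return `save_detector()` returns `path` invisibly; `load_detector()` the
#'   model.
#' @export
save_detector <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  readRDS(path)
}
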