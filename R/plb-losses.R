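#' Loss configuration for a PLB-weighted two-stage detector
#'
#' The total training loss has four components: RPN (coarse-grained,
#' object-vs-background) classification, RPN box regression, ROI
#' (fine-grained, per-category) classification and ROI box regression. Each
#' can independently be switched to its pixel-level-balanced form:
#'
#' * `plb1c` — PLB in the RPN classification loss
#' * `plb1b` — PLB in the RPN box-regression loss
#' * `plb2c` — PLB in the ROI classification loss
#' * `plb2b` — PLB in the ROI box-regression loss
#'
#' With all switches off every weight is 1 and the total reduces to the
#' ordinary Faster-R-CNN-style loss. `lambda_balance` multiplies the two
#' regression components relative to the classification components.
#'
#' @param plb1c,plb1b,plb2c,plb2b Logical switches, one per loss component.
#' @param lambda_balance Classification/localisation trade-off (default 1).
#' @param weight_config A [plb_weight_config()].
#' @return A `plb_loss_config` list.
#' @export
plb_loss_config <- function(plb1c = FALSE, plb1b = FALSE, plb2c = FALSE,
                            plb2b = FALSE, lambda_balance = 1,
                            weight_config = plb_weight_config()) {
  stopifnot(
    is.logical(plb1c), is.logical(plb1b), is.logical(plb2c), is.logical(plb2b),
    is.numeric(lambda_balance), lambda_balance >= 0,
    inherits(weight_config, "plb_weight_config")
  )
  structure(
    list(plb1c = plb1c, plb1b = plb1b, plb2c = plb2c, plb2b = plb2b,
         lambda_balance = as.numeric(lambda_balance),
         weight_config = weight_config),
    class = "plb_loss_config"
  )
}

#' Assemble classification samples for a loss term
#'
#' @param logits An `n x k` matrix of unnormalised class scores.
#' @param label Integer vector of true class indices (1-based; for the RPN
#'   term, 1 = background, 2 = object).
#' @param is_foreground Logical vector; background samples carry no box.
#' @param boxes Optional box tibble/matrix row-aligned with the samples; the
#'   box rows of background samples are ignored (may be `NA`). This is the
#'   box whose pixel area represents the sample's size (predicted or matched
#'   ground-truth box, per the weight configuration upstream).
#' @return A tibble with a matrix column `logits` plus `label`,
#'   `is_foreground` and the four box columns.
#' @export
cls_samples <- function(logits, label, is_foreground, boxes = NULL) {
  logits <- rbind(logits)
  n <- nrow(logits)
  stopifnot(length(label) == n, length(is_foreground) == n)
  if (is.null(boxes)) {
    b <- matrix(NA_real_, n, 4)
  } else {
    b <- if (is.matrix(boxes)) boxes else unname(as.matrix(boxes[box_cols]))
  }
  tibble::tibble(
    logits = logits, label = as.integer(label),
    is_foreground = as.logical(is_foreground),
    x_min = b[, 1], y_min = b[, 2], x_max = b[, 3], y_max = b[, 4]
  )
}

#' Assemble box-regression samples for a loss term
#'
#' Only foreground (object-matched) samples regress boxes, so every row
#' carries a decoded box and a target.
#'
#' @param pred_deltas,target_deltas `n x 4` matrices of predicted and target
#'   `(dx, dy, dw, dh)` offsets.
#' @param boxes Box tibble/matrix of the decoded predicted boxes (or matched
#'   ground-truth boxes, per the weight configuration upstream).
#' @return A tibble with matrix columns `pred_deltas`, `target_deltas` and
#'   the four box columns.
#' @export
reg_samples <- function(pred_deltas, target_deltas, boxes) {
  pred_deltas <- rbind(pred_deltas)
  target_deltas <- rbind(target_deltas)
  n <- nrow(pred_deltas)
  stopifnot(nrow(target_deltas) == n, ncol(pred_deltas) == 4, ncol(target_deltas) == 4)
  b <- if (is.matrix(boxes)) boxes else unname(as.matrix(boxes[box_cols]))
  stopifnot(nrow(b) == n)
  tibble::tibble(
    pred_deltas = pred_deltas, target_deltas = target_deltas,
    x_min = b[, 1], y_min = b[, 2], x_max = b[, 3], y_max = b[, 4]
  )
}

empty_cls_samples <- function(k = 2) {
  cls_samples(matrix(0, 0, k), integer(0), logical(0))
}

empty_reg_samples <- function() {
  reg_samples(matrix(0, 0, 4), matrix(0, 0, 4), matrix(0, 0, 4))
}

#' Per-sample cross-entropy
#'
#' Negative log-softmax of the true class, computed stably via the
#' log-sum-exp trick.
#'
#' @param logits `n x k` matrix.
#' @param label Integer vector of 1-based class indices.
#' @return Numeric vector of per-sample losses.
#' @export
cross_entropy <- function(logits, label) {
  logits <- rbind(logits)
  stopifnot(all(label >= 1), all(label <= ncol(logits)))
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  true_logit <- logits[cbind(seq_len(nrow(logits)), label)]
  lse - true_logit
}

#' Elementwise smooth-L1
#'
#' `0.5 d^2` for `|d| < 1`, otherwise `|d| - 0.5`.
#'
#' @param d Numeric vector/matrix of residuals.
#' @return Same shape as `d`.
#' @export
smooth_l1 <- function(d) {
  ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5)
}

weight_values <- function(weights, n) {
  w <- if (is.data.frame(weights)) weights$weight else as.numeric(weights)
  if (length(w) != n) {
    rlang::abort(sprintf("weight/sample length mismatch: %d weights for %d samples",
                         length(w), n))
  }
  w
}

#' PLB-weighted cross-entropy loss
#'
#' `(1/N) * sum_i w_i * CE(logits_i, label_i)` over the sample set.
#'
#' @param samples A [cls_samples()] tibble.
#' @param weights Numeric vector of per-sample weights, or a [plb_weights()]
#'   tibble; must align with `samples` row for row.
#' @return A single non-negative number (0 for an empty set).
#' @export
weighted_cross_entropy <- function(samples, weights) {
  n <- nrow(samples)
  if (n == 0) return(0)
  w <- weight_values(weights, n)
  mean(w * cross_entropy(samples$logits, samples$label))
}

#' PLB-weighted smooth-L1 loss
#'
#' `(1/N) * sum_i w_i * sum_c smoothL1(pred_ic - target_ic)` over the four
#' box coordinates.
#'
#' @param samples A [reg_samples()] tibble.
#' @param weights As in [weighted_cross_entropy()].
#' @return A single non-negative number (0 for an empty set).
#' @export
weighted_smooth_l1 <- function(samples, weights) {
  n <- nrow(samples)
  if (n == 0) return(0)
  w <- weight_values(weights, n)
  per_sample <- rowSums(smooth_l1(samples$pred_deltas - samples$target_deltas))
  mean(w * per_sample)
}

# Weight vector for one loss component. Classification: background samples
# always weigh 1; PLB statistics (mean, n) run over foreground boxes only.
component_weights <- function(samples, enabled, weight_config, component,
                              regression = FALSE) {
  n <- nrow(samples)
  if (!enabled) return(rep(1, n))
  fg <- if (regression) rep(TRUE, n) else samples$is_foreground
  if (n == 0 || !any(fg)) {
    rlang::warn(sprintf("PLB enabled for %s but no boxes contribute; component set to 0",
                        component))
    return(NULL)
  }
  b <- cbind(samples$x_min, samples$y_min, samples$x_max, samples$y_max)[fg, , drop = FALSE]
  if (anyNA(b)) {
    rlang::abort(sprintf("foreground samples in %s are missing boxes", component))
  }
  w <- rep(1, n)
  w[fg] <- plb_weights(box_area_raw(b), weight_config)$weight
  w
}

#' Total two-stage detection loss with optional PLB weighting
#'
#' Combines the four loss components:
#' `total = cls_rpn + lambda * reg_rpn + cls_roi + lambda * reg_roi`,
#' each component normalised by its own sample count. A component whose PLB
#' switch is enabled has its foreground samples weighted by
#' [plb_weights()] computed over that component's contributing boxes;
#' disabled components use weight 1 everywhere and reproduce the unweighted
#' baseline exactly.
#'
#' If a switch is enabled but the component has no contributing boxes, that
#' component is set to 0 with a warning.
#'
#' @param rpn_cls,roi_cls [cls_samples()] tibbles.
#' @param rpn_reg,roi_reg [reg_samples()] tibbles (foreground only).
#' @param config A [plb_loss_config()].
#' @return A one-row tibble (class `plb_loss_breakdown`) with columns
#'   `cls_rpn`, `reg_rpn`, `cls_roi`, `reg_roi`, `total`. The per-component
#'   weight vectors are attached as `attr(, "weights")`.
#' @export
total_loss <- function(rpn_cls, rpn_reg, roi_cls, roi_reg,
                       config = plb_loss_config()) {
  wc <- config$weight_config
  w1c <- component_weights(rpn_cls, config$plb1c, wc, "cls_rpn")
  w1b <- component_weights(rpn_reg, config$plb1b, wc, "reg_rpn", regression = TRUE)
  w2c <- component_weights(roi_cls, config$plb2c, wc, "cls_roi")
  w2b <- component_weights(roi_reg, config$plb2b, wc, "reg_roi", regression = TRUE)
  cls_rpn <- if (is.null(w1c)) 0 else weighted_cross_entropy(rpn_cls, w1c)
  reg_rpn <- if (is.null(w1b)) 0 else weighted_smooth_l1(rpn_reg, w1b)
  cls_roi <- if (is.null(w2c)) 0 else weighted_cross_entropy(roi_cls, w2c)
  reg_roi <- if (is.null(w2b)) 0 else weighted_smooth_l1(roi_reg, w2b)
  lam <- config$lambda_balance
  out <- tibble::tibble(
    cls_rpn = cls_rpn, reg_rpn = reg_rpn, cls_roi = cls_roi, reg_roi = reg_roi,
    total = cls_rpn + lam * reg_rpn + cls_roi + lam * reg_roi
  )
  attr(out, "weights") <- list(cls_rpn = w1c, reg_rpn = w1b,
                               cls_roi = w2c, reg_roi = w2b)
  class(out) <- c("plb_loss_breakdown", class(out))
  out
}
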