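#' Construct a tibble of axis-aligned boxes
#'
#' Boxes live in a continuous, 0-based image coordinate frame with the origin
#' at the top-left corner and the half-open convention
#' `[x_min, x_max) x [y_min, y_max)`. Areas are therefore plain products of
#' the two extents, in squared pixels.
#'
#' @param x_min,y_min,x_max,y_max Numeric vectors of box corners (pixels).
#' @param ... Further columns passed to [tibble::tibble()] (e.g. `class`,
#'   `score`).
#' @return A tibble with at least the four corner columns.
#' @examples
#' box_tbl(0, 0, 10, 10)
#' @export
box_tbl <- function(x_min, y_min, x_max, y_max, ...) {
  tibble::tibble(
    x_min = as.numeric(x_min), y_min = as.numeric(y_min),
    x_max = as.numeric(x_max), y_max = as.numeric(y_max), ...
  )
}

box_cols <- c("x_min", "y_min", "x_max", "y_max")

#' @keywords internal
#' @noRd
as_box_matrix <- function(boxes) {
  if (is.matrix(boxes)) {
    stopifnot(ncol(boxes) == 4)
    return(unname(boxes))
  }
  if (!all(box_cols %in% names(boxes))) {
    rlang::abort("boxes must have columns x_min, y_min, x_max, y_max")
  }
  unname(as.matrix(boxes[box_cols]))
}

#' Pixel area of boxes
#'
#' @param boxes A tibble with columns `x_min`, `y_min`, `x_max`, `y_max`
#'   (or a 4-column matrix in that order).
#' @return Numeric vector of areas in squared pixels, one per box.
#'   Degenerate boxes (zero or negative extent) raise an error: a box must
#'   contain at least some pixels for its area to act as a size measure.
#' @examples
#' box_area(box_tbl(0, 0, 10, 10)) # 100
#' @export
box_area <- function(boxes) {
  m <- as_box_matrix(boxes)
  w <- m[, 3] - m[, 1]
  h <- m[, 4] - m[, 2]
  if (any(w <= 0) || any(h <= 0)) {
    rlang::abort("degenerate box: x_max must exceed x_min and y_max must exceed y_min")
  }
  w * h
}

# Unchecked area, used internally on clipped predictions where a zero extent
# is legitimate and handled by the epsilon guard downstream.
box_area_raw <- function(m) {
  pmax(m[, 3] - m[, 1], 0) * pmax(m[, 4] - m[, 2], 0)
}

#' Pairwise intersection-over-union
#'
#' @param a,b Box tibbles or 4-column matrices.
#' @return A `nrow(a) x nrow(b)` matrix of IoU values in `[0, 1]`.
#' @examples
#' box_iou(box_tbl(0, 0, 10, 10), box_tbl(5, 5, 15, 15)) # 25 / 175
#' @export
box_iou <- function(a, b) {
  cpp_iou_matrix(as_box_matrix(a), as_box_matrix(b))
}

#' Clip boxes to image bounds
#'
#' @param boxes Box tibble or matrix.
#' @param width,height Image extent in pixels.
#' @param min_size Minimum retained extent per side; boxes collapsed by the
#'   clip are padded to this size inside the image so downstream area
#'   computations stay defined.
#' @return Object of the same shape as `boxes` with clipped corners.
#' @export
clip_boxes <- function(boxes, width, height, min_size = 1e-3) {
  m <- as_box_matrix(boxes)
  m[, 1] <- pmin(pmax(m[, 1], 0), width)
  m[, 2] <- pmin(pmax(m[, 2], 0), height)
  m[, 3] <- pmin(pmax(m[, 3], 0), width)
  m[, 4] <- pmin(pmax(m[, 4], 0), height)
  m[, 3] <- pmax(m[, 3], pmin(m[, 1] + min_size, width))
  m[, 1] <- pmin(m[, 1], m[, 3] - min_size)
  m[, 4] <- pmax(m[, 4], pmin(m[, 2] + min_size, height))
  m[, 2] <- pmin(m[, 2], m[, 4] - min_size)
  if (is.matrix(boxes)) m else {
    out <- boxes
    out[box_cols] <- as.data.frame(m)
    out
  }
}

#' Encode / decode box regression deltas
#'
#' Standard center/size parameterization used by two-stage detectors:
#' `dx = (gcx - acx) / aw`, `dy = (gcy - acy) / ah`, `dw = log(gw / aw)`,
#' `dh = log(gh / ah)`, where `a*` describe the anchor and `g*` the target
#' box. `decode_deltas()` is the exact inverse (before clipping).
#'
#' @param anchors,gt Box tibbles or 4-column matrices, row-aligned.
#' @param deltas An `n x 4` matrix of `(dx, dy, dw, dh)`.
#' @param width,height Optional image extent; when given, decoded boxes are
#'   clipped to the image.
#' @return `encode_deltas()`: an `n x 4` matrix; `decode_deltas()`: a box
#'   tibble.
#' @export
encode_deltas <- function(anchors, gt) {
  a <- as_box_matrix(anchors)
  g <- as_box_matrix(gt)
  aw <- a[, 3] - a[, 1]; ah <- a[, 4] - a[, 2]
  gw <- g[, 3] - g[, 1]; gh <- g[, 4] - g[, 2]
  acx <- a[, 1] + aw / 2; acy <- a[, 2] + ah / 2
  gcx <- g[, 1] + gw / 2; gcy <- g[, 2] + gh / 2
  cbind((gcx - acx) / aw, (gcy - acy) / ah, log(gw / aw), log(gh / ah))
}

#' @rdname encode_deltas
#' @export
decode_deltas <- function(anchors, deltas, width = NULL, height = NULL) {
  a <- as_box_matrix(anchors)
  aw <- a[, 3] - a[, 1]; ah <- a[, 4] - a[, 2]
  acx <- a[, 1] + aw / 2; acy <- a[, 2] + ah / 2
  # clamp log-size deltas so an early, badly scaled prediction cannot
  # overflow to an astronomically large box
  dw <- pmin(deltas[, 3], 4); dh <- pmin(deltas[, 4], 4)
  cx <- acx + deltas[, 1] * aw
  cy <- acy + deltas[, 2] * ah
  w <- aw * exp(dw); h <- ah * exp(dh)
  out <- box_tbl(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  if (!is.null(width)) out <- clip_boxes(out, width, height)
  out
}

#' Greedy non-maximum suppression
#'
#' Suppresses boxes overlapping a higher-scoring kept box by more than
#' `iou_threshold`. Ties in score are broken deterministically by box
#' coordinates so results never depend on input order.
#'
#' @param boxes Box tibble or matrix.
#' @param scores Numeric vector, one score per box.
#' @param iou_threshold Overlap above which a box is suppressed.
#' @param max_keep Maximum number of boxes retained.
#' @return Integer indices (into `boxes`) of the kept boxes, in decreasing
#'   score order.
#' @export
nms <- function(boxes, scores, iou_threshold = 0.5, max_keep = .Machine$integer.max) {
  m <- as_box_matrix(boxes)
  stopifnot(length(scores) == nrow(m))
  if (nrow(m) == 0) return(integer(0))
  ord <- order(-scores, m[, 1], m[, 2], m[, 3], m[, 4])
  keep <- cpp_nms_sorted(m[ord, , drop = FALSE], iou_threshold, max_keep)
  ord[keep]
}
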