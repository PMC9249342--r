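#' Assign object areas to COCO size bands
#'
#' Small objects have area in `(0, 32*32)`, medium in `[32*32, 96*96]`
#' (both boundaries inclusive) and large above `96*96`, with areas measured
#' in pixels on the ground-truth box.
#'
#' @param area Numeric vector of strictly positive areas (px^2).
#' @return Character vector: `"small"`, `"medium"` or `"large"`.
#' @examples
#' assign_size_band(c(900, 1024, 9216, 9217)) # small medium medium large
#' @export
assign_size_band <- function(area) {
  if (any(!is.finite(area)) || any(area <= 0)) {
    rlang::abort("areas must be finite and strictly positive")
  }
  ifelse(area < 1024, "small", ifelse(area <= 9216, "medium", "large"))
}

# Greedy score-ordered matching of one image's detections of one class
# against its ground truths at one IoU threshold. `ignore_g` marks ground
# truths outside the current area band. Returns per-detection match status.
match_greedy <- function(iou, ignore_g, threshold, det_out_of_band) {
  n_d <- nrow(iou); n_g <- ncol(iou)
  g_ord <- order(ignore_g) # non-ignored ground truths first
  gtm <- rep(FALSE, n_g)
  dt_tp <- rep(FALSE, n_d)
  dt_ig <- rep(FALSE, n_d)
  for (d in seq_len(n_d)) {
    best <- threshold - 1e-10
    m <- 0L
    for (g in g_ord) {
      if (gtm[g]) next
      # after a real match is found, never trade it for an ignored gt
      if (m > 0L && !ignore_g[m] && ignore_g[g]) break
      if (iou[d, g] < best) next
      best <- iou[d, g]
      m <- g
    }
    if (m > 0L) {
      gtm[m] <- TRUE
      if (ignore_g[m]) dt_ig[d] <- TRUE else dt_tp[d] <- TRUE
    } else if (det_out_of_band[d]) {
      dt_ig[d] <- TRUE
    }
  }
  list(tp = dt_tp, ignored = dt_ig)
}

# 101-point interpolated average precision.
ap_interpolated <- function(tp, fp, n_positive, recall_points = seq(0, 1, 0.01)) {
  if (n_positive == 0) return(NA_real_)
  if (length(tp) == 0) return(0)
  ctp <- cumsum(tp); cfp <- cumsum(fp)
  recall <- ctp / n_positive
  precision <- ctp / (ctp + cfp)
  for (i in rev(seq_len(length(precision) - 1))) {
    precision[i] <- max(precision[i], precision[i + 1])
  }
  idx <- findInterval(recall_points, recall, left.open = TRUE) + 1
  q <- ifelse(idx <= length(precision), precision[pmin(idx, length(precision))], 0)
  mean(q)
}

#' Size-stratified COCO-protocol detection evaluation
#'
#' Average precision with greedy score-ordered matching at each IoU
#' threshold in `0.50:0.05:0.95`, 101-point interpolated precision, averaged
#' over thresholds and classes. Band APs restrict ground truths to one area
#' band; detections matched to out-of-band ground truths — and unmatched
#' detections whose own box falls outside the band — are ignored (neither
#' true nor false positives), following the COCO area-range rule. A band
#' with no ground truths has undefined (NA) AP, not 0.
#'
#' Detection order never matters: sorting breaks score ties
#' deterministically by image and box coordinates.
#'
#' @param detections Tibble with `image_id`, `category_id`, `score` and box
#'   columns (may have zero rows).
#' @param ground_truths Tibble with `image_id`, `category_id` and box
#'   columns.
#' @param iou_thresholds IoU grid (default `seq(0.5, 0.95, 0.05)`).
#' @param max_dets Per-image, per-class detection cap (default 100).
#' @return A `plb_eval` object: `map`, `ap_small`, `ap_medium`, `ap_large`,
#'   `by_iou` (per-threshold AP over all areas), and the full
#'   `by_class_band` table.
#' @export
evaluate_detections <- function(detections, ground_truths,
                                iou_thresholds = seq(0.5, 0.95, 0.05),
                                max_dets = 100) {
  gt <- dplyr::mutate(ground_truths,
                      area = box_area(ground_truths),
                      band = assign_size_band(.data$area))
  if (is.null(detections) || nrow(detections) == 0) {
    detections <- tibble::tibble(image_id = integer(0), category_id = integer(0),
                                 x_min = numeric(0), y_min = numeric(0),
                                 x_max = numeric(0), y_max = numeric(0),
                                 score = numeric(0))
  }
  det <- detections
  det$det_area <- box_area_raw(as_box_matrix(det))
  det$det_band <- ifelse(det$det_area < 1024, "small",
                         ifelse(det$det_area <= 9216, "medium", "large"))
  det <- det[order(-det$score, det$image_id, det$x_min, det$y_min,
                   det$x_max, det$y_max), , drop = FALSE]
  # per-image, per-class cap
  det <- det |>
    dplyr::group_by(.data$image_id, .data$category_id) |>
    dplyr::slice_head(n = max_dets) |>
    dplyr::ungroup()

  classes <- sort(unique(c(gt$category_id, det$category_id)))
  bands <- c("all", "small", "medium", "large")
  rows <- list()
  for (cls in classes) {
    gt_c <- gt[gt$category_id == cls, , drop = FALSE]
    det_c <- det[det$category_id == cls, , drop = FALSE]
    img_ids <- sort(unique(c(gt_c$image_id, det_c$image_id)))
    per_image <- lapply(img_ids, function(im) {
      g <- gt_c[gt_c$image_id == im, , drop = FALSE]
      d <- det_c[det_c$image_id == im, , drop = FALSE]
      list(g = g, d = d,
           iou = if (nrow(d) && nrow(g))
             box_iou(as_box_matrix(d), as_box_matrix(g))
           else matrix(0, nrow(d), nrow(g)))
    })
    for (band in bands) {
      n_pos <- if (band == "all") nrow(gt_c) else sum(gt_c$band == band)
      for (t in iou_thresholds) {
        score <- c(); tp <- c(); ig <- c()
        key <- list()
        for (pi in per_image) {
          if (nrow(pi$d) == 0) next
          ignore_g <- if (band == "all") rep(FALSE, nrow(pi$g)) else pi$g$band != band
          out_band <- if (band == "all") rep(FALSE, nrow(pi$d)) else pi$d$det_band != band
          mt <- match_greedy(pi$iou, ignore_g, t, out_band)
          score <- c(score, pi$d$score)
          tp <- c(tp, mt$tp)
          ig <- c(ig, mt$ignored)
          key[[length(key) + 1]] <- pi$d[c("image_id", "x_min", "y_min", "x_max", "y_max")]
        }
        if (length(score)) {
          k <- dplyr::bind_rows(key)
          ord <- order(-score, k$image_id, k$x_min, k$y_min, k$x_max, k$y_max)
          keep <- !ig[ord]
          ap <- ap_interpolated(tp[ord][keep], !tp[ord][keep], n_pos)
        } else {
          ap <- ap_interpolated(logical(0), logical(0), n_pos)
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          category_id = cls, band = band, iou_threshold = t,
          ap = ap, n_gt = n_pos
        )
      }
    }
  }
  by_class_band <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(category_id = integer(0), band = character(0),
                   iou_threshold = numeric(0), ap = numeric(0), n_gt = integer(0))
  band_ap <- function(b) {
    v <- by_class_band$ap[by_class_band$band == b]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  by_iou <- by_class_band |>
    dplyr::filter(.data$band == "all") |>
    dplyr::group_by(.data$iou_threshold) |>
    dplyr::summarise(ap = if (all(is.na(.data$ap))) NA_real_ else
      mean(.data$ap, na.rm = TRUE), .groups = "drop")
  structure(
    list(map = band_ap("all"), ap_small = band_ap("small"),
         ap_medium = band_ap("medium"), ap_large = band_ap("large"),
         by_iou = by_iou, by_class_band = by_class_band,
         iou_thresholds = iou_thresholds, max_dets = max_dets),
    class = "plb_eval"
  )
}

#' @export
print.plb_eval <- function(x, ...) {
  cat(sprintf("<plb_eval> IoU %.2f:%.2f\n", min(x$iou_thresholds), max(x$iou_thresholds)))
  cat(sprintf("  mAP %.4f | AP_small %s | AP_medium %s | AP_large %s\n",
              x$map, format_ap(x$ap_small), format_ap(x$ap_medium),
              format_ap(x$ap_large)))
  invisible(x)
}

format_ap <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)

#' Write an evaluation result as JSON
#'
#' @param eval A `plb_eval`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_eval <- function(eval, path) {
  jsonlite::write_json(
    list(map = eval$map, ap_small = eval$ap_small, ap_medium = eval$ap_medium,
         ap_large = eval$ap_large,
         by_iou = eval$by_iou, by_class_band = eval$by_class_band),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
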