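#' Tidy a trained detector's loss history
#'
#' @param x A `plb_detector`.
#' @param ... Unused.
#' @return A long tibble: `epoch`, `step`, `component`, `loss`.
#' @method tidy plb_detector
#' @export
tidy.plb_detector <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(0), step = integer(0),
                          component = character(0), loss = numeric(0)))
  }
  x$history |>
    dplyr::select("epoch", "step", "cls_rpn", "reg_rpn", "cls_roi",
                  "reg_roi", "total") |>
    tidyr::pivot_longer(c("cls_rpn", "reg_rpn", "cls_roi", "reg_roi", "total"),
                        names_to = "component", values_to = "loss")
}

#' One-row summary of a trained detector
#'
#' @param x A `plb_detector`.
#' @param ... Unused.
#' @return Tibble with parameter count, steps trained, enabled PLB switches
#'   and the mean total loss over the final 20 steps.
#' @method glance plb_detector
#' @export
glance.plb_detector <- function(x, ...) {
  sw <- c("plb1c", "plb1b", "plb2c", "plb2b")
  on <- sw[vapply(sw, function(s) isTRUE(x$loss_config[[s]]), logical(1))]
  tibble::tibble(
    n_parameters = sum(vapply(unlist(x$params, recursive = FALSE), length,
                              numeric(1))),
    n_steps = if (is.null(x$history)) NA_integer_ else nrow(x$history),
    plb_switches = if (length(on)) paste(on, collapse = "+") else "none",
    final_loss = if (is.null(x$history)) NA_real_ else
      mean(utils::tail(x$history$total, 20))
  )
}

#' Tidy an evaluation result
#'
#' @param x A `plb_eval`.
#' @param ... Unused.
#' @return The per-class, per-band, per-threshold AP tibble.
#' @method tidy plb_eval
#' @export
tidy.plb_eval <- function(x, ...) {
  x$by_class_band
}

#' One-row summary of an evaluation result
#'
#' @param x A `plb_eval`.
#' @param ... Unused.
#' @return Tibble with `map`, `ap_small`, `ap_medium`, `ap_large`.
#' @method glance plb_eval
#' @export
glance.plb_eval <- function(x, ...) {
  tibble::tibble(map = x$map, ap_small = x$ap_small,
                 ap_medium = x$ap_medium, ap_large = x$ap_large)
}

#' Plot training loss curves
#'
#' @param object A `plb_detector`.
#' @param ... Unused.
#' @return A ggplot of per-component losses over steps (loess-free raw
#'   traces).
#' @method autoplot plb_detector
#' @export
autoplot.plb_detector <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$step, y = .data$loss,
                                 colour = .data$component)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "training step", y = "loss",
                  title = "Two-stage detector training loss") +
    ggplot2::theme_minimal()
}

#' Plot size-stratified APs
#'
#' @param object A `plb_eval`.
#' @param ... Unused.
#' @return A ggplot bar chart of AP per area band.
#' @method autoplot plb_eval
#' @export
autoplot.plb_eval <- function(object, ...) {
  glance(object) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric",
                        values_to = "ap") |>
    dplyr::mutate(metric = factor(.data$metric,
                                  c("map", "ap_small", "ap_medium", "ap_large"))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$metric, y = .data$ap)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "average precision (IoU 0.50:0.95)") +
    ggplot2::theme_minimal()
}

#' Plot a synthetic scene with its bounding boxes
#'
#' @param object A `plb_scene` from [generate_scene()].
#' @param ... Unused.
#' @return A ggplot raster with box overlays coloured by class.
#' @method autoplot plb_scene
#' @export
autoplot.plb_scene <- function(object, ...) {
  img <- object$image
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- expand.grid(y = seq_len(h) - 0.5, x = seq_len(w) - 0.5)
  px$fill <- grDevices::rgb(as.vector(img[, , 1]), as.vector(img[, , 2]),
                            as.vector(img[, , 3]))
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = px,
                         ggplot2::aes(x = .data$x, y = .data$y, fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::geom_rect(
      data = object$boxes,
      ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                   ymin = .data$y_min, ymax = .data$y_max,
                   colour = .data$class),
      fill = NA, linewidth = 0.4
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot an ablation summary
#'
#' @param object A `plb_experiment` from [run_plan()].
#' @param ... Unused.
#' @return A ggplot of per-variant, per-band mean APs with replicate points.
#' @method autoplot plb_experiment
#' @export
autoplot.plb_experiment <- function(object, ...) {
  long <- object$runs |>
    dplyr::filter(.data$status == "ok") |>
    tidyr::pivot_longer(c("map", "ap_small", "ap_medium", "ap_large"),
                        names_to = "metric", values_to = "ap") |>
    dplyr::mutate(metric = factor(.data$metric,
                                  c("map", "ap_small", "ap_medium", "ap_large")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$variant, y = .data$ap)) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "grey70") +
    ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::facet_wrap(~metric, nrow = 1) +
    ggplot2::labs(x = NULL, y = "AP (IoU 0.50:0.95)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
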