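#' Configuration for pixel-level-balancing weights
#'
#' Pixel level balancing (PLB) rescales each detection box's loss
#' contribution by a factor computed from the box's pixel area. The size of
#' a training sample can be represented either by the box the model currently
#' predicts for it (`"predict_box"`, the default) or by the ground-truth box
#' it was matched to (`"matched_labeled_box"`).
#'
#' `area_epsilon` is added to every raw area before any weight computation.
#' Its role is to keep the factor defined when a predicted box collapses to
#' zero area; the default of 1 px^2 is negligible at realistic object sizes.
#'
#' @param size_source Which box supplies a sample's area.
#' @param area_epsilon Non-negative area increment in squared pixels.
#' @return A `plb_weight_config` list.
#' @export
plb_weight_config <- function(size_source = c("predict_box", "matched_labeled_box"),
                              area_epsilon = 1) {
  size_source <- match.arg(size_source)
  if (!is.numeric(area_epsilon) || length(area_epsilon) != 1 || area_epsilon < 0) {
    rlang::abort("area_epsilon must be a single non-negative number")
  }
  structure(
    list(size_source = size_source, area_epsilon = as.numeric(area_epsilon)),
    class = "plb_weight_config"
  )
}

#' Mean box area of a loss term's contributing boxes
#'
#' @param areas Numeric vector of box areas (px^2), one per box contributing
#'   to a loss term; must be non-empty and positive.
#' @return The arithmetic mean area.
#' @examples
#' mean_area(c(100, 300)) # 200
#' @export
mean_area <- function(areas) {
  if (length(areas) == 0) {
    rlang::abort("no boxes contribute to this loss term")
  }
  if (any(!is.finite(areas)) || any(areas <= 0)) {
    rlang::abort("areas must be finite and strictly positive")
  }
  mean(areas)
}

#' Pixel-level-balancing weights
#'
#' Each box contributing to a loss term receives the dimensionless factor
#' \deqn{w_i = \frac{2\,\bar a}{a_i + \bar a}}{w_i = 2*mean(a) / (a_i + mean(a))}
#' where \eqn{a_i} is the box's (epsilon-adjusted) pixel area and
#' \eqn{\bar a} the arithmetic mean over the \eqn{n} contributing boxes.
#' A box of exactly average size keeps weight 1; weights increase towards 2
#' as a box shrinks and decrease towards \eqn{2/(n+1)} as it dominates the
#' batch, so smaller-than-average objects are emphasised during training.
#' Weights are per-step constants: they carry no gradient.
#'
#' @param areas Numeric vector of raw box areas in px^2 (non-negative; the
#'   configured `area_epsilon` is added before the mean and the weights are
#'   computed).
#' @param config A [plb_weight_config()].
#' @return A tibble with columns `area` (raw input), `area_eff`
#'   (epsilon-adjusted) and `weight`. `attr(, "n")` records the batch size.
#' @examples
#' plb_weights(c(100, 300), plb_weight_config(area_epsilon = 0))$weight # 4/3, 4/5
#' @export
plb_weights <- function(areas, config = plb_weight_config()) {
  if (length(areas) == 0) {
    rlang::abort("no boxes contribute to this loss term")
  }
  if (any(!is.finite(areas)) || any(areas < 0)) {
    rlang::abort("box areas must be finite and non-negative")
  }
  eff <- areas + config$area_epsilon
  if (any(eff <= 0)) {
    rlang::abort("epsilon-adjusted areas must be strictly positive; increase area_epsilon")
  }
  m <- mean(eff)
  out <- tibble::tibble(area = areas, area_eff = eff, weight = 2 * m / (eff + m))
  attr(out, "n") <- length(areas)
  out
}
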