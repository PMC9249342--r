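#' Standard ablation variants
#'
#' The unweighted baseline plus the four single-switch variants and the
#' two-switch RPN combination. Additional variants can be supplied to
#' [experiment_plan()] as named [plb_loss_config()]s.
#'
#' @param size_source,area_epsilon Passed to [plb_weight_config()].
#' @return Named list of [plb_loss_config()]s; the baseline is always first.
#' @export
plb_variants <- function(size_source = "predict_box", area_epsilon = 1) {
  wc <- plb_weight_config(size_source, area_epsilon)
  list(
    baseline = plb_loss_config(weight_config = wc),
    PLB1C = plb_loss_config(plb1c = TRUE, weight_config = wc),
    PLB1B = plb_loss_config(plb1b = TRUE, weight_config = wc),
    PLB2C = plb_loss_config(plb2c = TRUE, weight_config = wc),
    PLB2B = plb_loss_config(plb2b = TRUE, weight_config = wc),
    `PLB1C+PLB1B` = plb_loss_config(plb1c = TRUE, plb1b = TRUE, weight_config = wc)
  )
}

#' Plan an ablation experiment
#'
#' @param train_data,eval_data Datasets in [generate_dataset()] layout.
#' @param detector_config A [detector_config()]; its seed is overridden per
#'   replicate.
#' @param variants Named list of [plb_loss_config()]s. Must include a
#'   `baseline` entry (all switches off); one is prepended if missing.
#' @param epochs Training epochs per run.
#' @param seeds Integer vector of replicate seeds.
#' @param out_dir Optional directory for per-run logs, checkpoints and the
#'   report.
#' @return A `plb_experiment_plan` list.
#' @export
experiment_plan <- function(train_data, eval_data,
                            detector_config = plbdetect::detector_config(),
                            variants = plb_variants(),
                            epochs = 10, seeds = 1:3, out_dir = NULL) {
  stopifnot(!is.null(names(variants)), !anyDuplicated(names(variants)))
  if (!"baseline" %in% names(variants)) {
    variants <- c(list(baseline = plb_loss_config(
      weight_config = variants[[1]]$weight_config)), variants)
  }
  structure(
    list(train_data = train_data, eval_data = eval_data,
         detector_config = detector_config, variants = variants,
         epochs = epochs, seeds = seeds, out_dir = out_dir),
    class = "plb_experiment_plan"
  )
}

#' Run an ablation plan
#'
#' Trains one detector per (variant, seed), evaluates each on the held-out
#' data and tabulates size-stratified APs. A variant whose training fails is
#' recorded as failed and the remaining runs continue.
#'
#' @param plan A [experiment_plan()].
#' @param verbose Print progress.
#' @return A `plb_experiment` object with the per-run `runs` tibble
#'   (variant, seed, map, ap_small, ap_medium, ap_large, status) and the
#'   `summary` produced by [report_runs()].
#' @export
run_plan <- function(plan, verbose = FALSE) {
  runs <- list()
  for (vn in names(plan$variants)) {
    for (sd in plan$seeds) {
      if (verbose) message(sprintf("training %s (seed %d)", vn, sd))
      cfg <- plan$detector_config
      cfg$seed <- sd
      log_path <- NULL
      if (!is.null(plan$out_dir)) {
        dir.create(plan$out_dir, recursive = TRUE, showWarnings = FALSE)
        log_path <- file.path(plan$out_dir,
                              sprintf("train_%s_seed%d.jsonl", vn, sd))
      }
      row <- tryCatch({
        model <- train_detector(plan$train_data, cfg, plan$variants[[vn]],
                                epochs = plan$epochs, log_path = log_path)
        if (!is.null(plan$out_dir)) {
          save_detector(model, file.path(
            plan$out_dir, sprintf("model_%s_seed%d.rds", vn, sd)))
        }
        ev <- evaluate_model(model, plan$eval_data)
        tibble::tibble(variant = vn, seed = sd, map = ev$map,
                       ap_small = ev$ap_small, ap_medium = ev$ap_medium,
                       ap_large = ev$ap_large, status = "ok")
      }, error = function(e) {
        tibble::tibble(variant = vn, seed = sd, map = NA_real_,
                       ap_small = NA_real_, ap_medium = NA_real_,
                       ap_large = NA_real_, status = conditionMessage(e))
      })
      runs[[length(runs) + 1]] <- row
    }
  }
  runs <- dplyr::bind_rows(runs)
  out <- structure(list(runs = runs, summary = report_runs(runs),
                        plan = plan),
                   class = "plb_experiment")
  if (!is.null(plan$out_dir)) {
    utils::write.csv(runs, file.path(plan$out_dir, "runs.csv"), row.names = FALSE)
    writeLines(format_report(out$summary), file.path(plan$out_dir, "report.txt"))
  }
  out
}

#' Summarise ablation runs against the baseline
#'
#' A pure function of the per-run results: seed-averaged metrics per variant
#' plus relative deltas `(variant - baseline) / baseline * 100` (percent).
#' Re-running it on the same `runs` tibble reproduces the table exactly.
#'
#' @param runs Tibble as produced by [run_plan()] (`variant`, `seed`, the
#'   four AP columns, `status`).
#' @return Tibble with one row per variant: means, standard deviations and
#'   percentage deltas versus the baseline.
#' @export
report_runs <- function(runs) {
  ok <- dplyr::filter(runs, .data$status == "ok")
  means <- ok |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      dplyr::across(c("map", "ap_small", "ap_medium", "ap_large"),
                    list(mean = ~mean(.x), sd = ~stats::sd(.x))),
      .groups = "drop"
    )
  base <- dplyr::filter(means, .data$variant == "baseline")
  if (nrow(base) != 1) {
    rlang::abort("report_runs needs exactly one successful baseline variant")
  }
  # relative percent delta vs baseline; a zero baseline makes the ratio
  # undefined except for the baseline row itself
  rel <- function(v, b) {
    if (is.na(b) || b == 0) return(ifelse(v == b, 0, NA_real_))
    (v - b) / b * 100
  }
  means |>
    dplyr::mutate(
      map_delta_pct = rel(.data$map_mean, base$map_mean),
      ap_small_delta_pct = rel(.data$ap_small_mean, base$ap_small_mean),
      ap_medium_delta_pct = rel(.data$ap_medium_mean, base$ap_medium_mean),
      ap_large_delta_pct = rel(.data$ap_large_mean, base$ap_large_mean)
    ) |>
    dplyr::arrange(match(.data$variant, unique(runs$variant)))
}

#' Format an ablation summary as a plain-text table
#'
#' Rows mirror the usual presentation of size-stratified ablations: the
#' baseline appears as "Not used" and deltas are percentages relative to it.
#'
#' @param summary Output of [report_runs()].
#' @return Character vector of lines.
#' @export
format_report <- function(summary) {
  fmt_cell <- function(mean, delta) {
    if (is.na(mean)) return("   --  ")
    d <- if (is.na(delta)) "" else sprintf(" (%+.2f%%)", delta)
    sprintf("%.3f%s", mean, d)
  }
  header <- sprintf("%-14s %-18s %-18s %-18s %-18s", "Method", "MAP",
                    "AP_small", "AP_medium", "AP_large")
  lines <- c("Comparison of the PLB variants (IoU = 0.50:0.95)", header,
             strrep("-", nchar(header)))
  for (i in seq_len(nrow(summary))) {
    r <- summary[i, ]
    nm <- if (r$variant == "baseline") "Not used" else r$variant
    lines <- c(lines, sprintf(
      "%-14s %-18s %-18s %-18s %-18s", nm,
      fmt_cell(r$map_mean, r$map_delta_pct),
      fmt_cell(r$ap_small_mean, r$ap_small_delta_pct),
      fmt_cell(r$ap_medium_mean, r$ap_medium_delta_pct),
      fmt_cell(r$ap_large_mean, r$ap_large_delta_pct)
    ))
  }
  lines
}

#' @export
print.plb_experiment <- function(x, ...) {
  cat(format_report(x$summary), sep = "\n")
  invisible(x)
}
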