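#' Grid of candidate delta-beta thresholds
#'
#' Inclusive ascending sequence of candidate |delta-beta| cutoffs, by
#' default 0.05 to 0.50 in steps of 0.05 (5% to 50% methylation change).
#'
#' @param start,stop,step grid limits and increment; `0 < start < stop <=
#'   1`, `step > 0`.
#' @return numeric vector of thresholds.
#' @export
threshold_grid <- function(start = 0.05, stop = 0.50, step = 0.05) {
  if (!(start > 0 && start < stop && stop <= 1 && step > 0)) {
    rlang::abort("threshold grid requires 0 < start < stop <= 1, step > 0",
                 class = "methgain_value_error")
  }
  seq(start, stop, by = step)
}

#' Classify the methylation-expression correlation of a gene
#'
#' A gene whose methylation goes up while its expression goes down (or vice
#' versa) is inversely correlated; strictly matching signs give positive
#' correlation; a zero or missing change on either side is undefined.
#'
#' @param delta_beta signed methylation change(s).
#' @param log_fc signed expression change(s).
#' @return character vector in `{"inverse", "positive", "undefined"}`.
#' @export
classify_correlation <- function(delta_beta, log_fc) {
  s <- sign(delta_beta) * sign(log_fc)
  out <- dplyr::case_when(
    is.na(s) | s == 0 ~ "undefined",
    s < 0 ~ "inverse",
    TRUE ~ "positive")
  out
}

#' Filter records eligible for the threshold-gain analysis
#'
#' Keeps records significant in both modalities (both FDRs strictly below
#' `fdr_cut`, default 0.1 — deliberately not stringent) with a defined
#' correlation class.
#'
#' @param records tibble carrying `meth_fdr`, `expr_fdr` and
#'   `correlation_class` (e.g. from [combine_gene_significances()]).
#' @param fdr_cut eligibility bound in (0, 1].
#' @return the filtered tibble.
#' @export
eligible_records <- function(records, fdr_cut = 0.1) {
  if (!(fdr_cut > 0 && fdr_cut <= 1)) {
    rlang::abort("fdr_cut must lie in (0, 1]",
                 class = "methgain_value_error")
  }
  dplyr::filter(records,
                .data$meth_fdr < fdr_cut,
                .data$expr_fdr < fdr_cut,
                .data$correlation_class != "undefined")
}

#' Inverse-correlation ratio and gain across a threshold grid
#'
#' At each candidate threshold tau the eligible records split into an
#' "above" side (|delta-beta| strictly greater than tau) and a "below"
#' side (the complement). Each side's ratio is its inversely correlated
#' fraction, and the gain is `ratio_above - ratio_below`: a positive gain
#' means strong methylation changes are disproportionately coupled to
#' opposite-direction expression changes. A threshold is marked invalid
#' when either side carries fewer than `min_side` records (ratios from
#' tiny sides are noise).
#'
#' @param records eligible records (see [eligible_records()]).
#' @param grid thresholds from [threshold_grid()].
#' @param min_side minimum records per side for a threshold to be valid.
#' @param dataset_id label carried into the output.
#' @return a `threshold_curve` tibble: `dataset_id`, `tau`, `n_above`,
#'   `n_below`, `ratio_above`, `ratio_below`, `gain`, `valid`.
#' @export
gain_curve <- function(records, grid = threshold_grid(), min_side = 10,
                       dataset_id = "dataset") {
  if (nrow(records) == 0) {
    rlang::abort("no eligible records for the threshold analysis",
                 class = "methgain_input_error")
  }
  adb <- abs(records$delta_beta)
  inv <- records$correlation_class == "inverse"
  rows <- purrr::map(grid, function(tau) {
    above <- adb > tau
    n_a <- sum(above)
    n_b <- sum(!above)
    r_a <- if (n_a > 0) sum(inv[above]) / n_a else NA_real_
    r_b <- if (n_b > 0) sum(inv[!above]) / n_b else NA_real_
    tibble::tibble(tau = tau, n_above = n_a, n_below = n_b,
                   ratio_above = r_a, ratio_below = r_b,
                   gain = r_a - r_b,
                   valid = n_a >= min_side && n_b >= min_side)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, dataset_id = dataset_id, .before = 1)
  class(out) <- c("threshold_curve", class(out))
  attr(out, "min_side") <- min_side
  out
}

bind_curves <- function(curves) {
  if (is.data.frame(curves)) curves <- list(curves)
  dplyr::bind_rows(curves)
}

#' Select the threshold with highest summed inverse-correlation gain
#'
#' Gains from each dataset's curve are linearly added together at each
#' threshold and the threshold with the highest overall gain wins; only
#' thresholds valid in every curve compete, and ties go to the smallest
#' threshold.
#'
#' @param curves one `threshold_curve` or a list of them, sharing a grid.
#' @return object of class `threshold_selection` with elements `tau_opt`,
#'   `pooled` (tibble of tau and pooled gain), `curves`. Supports
#'   [generics::tidy()], [generics::glance()] and `autoplot()`.
#' @export
select_threshold <- function(curves) {
  all_curves <- bind_curves(curves)
  grids <- split(all_curves$tau, all_curves$dataset_id)
  if (length(unique(purrr::map_chr(grids, paste, collapse = ","))) != 1) {
    rlang::abort("curves must share one threshold grid",
                 class = "methgain_input_error")
  }
  pooled <- all_curves |>
    dplyr::group_by(.data$tau) |>
    dplyr::summarise(pooled_gain = sum(.data$gain),
                     valid_all = all(.data$valid), .groups = "drop")
  ok <- dplyr::filter(pooled, .data$valid_all)
  if (nrow(ok) == 0) {
    rlang::abort("no threshold is valid in every dataset",
                 class = "methgain_analysis_error")
  }
  best <- ok |>
    dplyr::filter(.data$pooled_gain == max(.data$pooled_gain)) |>
    dplyr::slice_min(.data$tau, n = 1)
  out <- list(tau_opt = best$tau, pooled = pooled, curves = all_curves)
  class(out) <- "threshold_selection"
  out
}

#' Per-dataset threshold maximising the above-threshold inverse ratio
#'
#' Unlike [select_threshold()], which maximises the above-minus-below gain,
#' this reports for each dataset the threshold whose above side has the
#' highest inverse-correlated fraction — the raw-ratio view of the same
#' curves. The two optima generally differ: the raw ratio keeps rising
#' towards extreme thresholds while the gain peaks where the coupling
#' regime changes.
#'
#' @inheritParams select_threshold
#' @return tibble with `dataset_id`, `tau_ratio_max`, `ratio_above`.
#' @export
ratio_maximiser <- function(curves) {
  bind_curves(curves) |>
    dplyr::filter(.data$valid, !is.na(.data$ratio_above)) |>
    dplyr::group_by(.data$dataset_id) |>
    dplyr::filter(.data$ratio_above == max(.data$ratio_above)) |>
    dplyr::slice_min(.data$tau, n = 1) |>
    dplyr::ungroup() |>
    dplyr::select("dataset_id", tau_ratio_max = "tau", "ratio_above")
}

#' @export
tidy.threshold_selection <- function(x, ...) x$pooled

#' @export
glance.threshold_selection <- function(x, ...) {
  tibble::tibble(
    tau_opt = x$tau_opt,
    max_pooled_gain = max(x$pooled$pooled_gain[x$pooled$valid_all]),
    n_datasets = length(unique(x$curves$dataset_id)))
}

#' @export
print.threshold_selection <- function(x, ...) {
  cat("Threshold selection over", length(unique(x$curves$dataset_id)),
      "dataset(s)\n")
  cat(sprintf("  optimal tau: %.2f (pooled gain %.4f)\n", x$tau_opt,
              max(x$pooled$pooled_gain[x$pooled$valid_all])))
  invisible(x)
}

#' Plot inverse-correlation ratio or gain curves
#'
#' `type = "ratio"` draws the above-threshold inverse-correlated fraction
#' per dataset; `type = "gain"` draws the above-minus-below gain. Invalid
#' thresholds are dropped.
#'
#' @param object a `threshold_curve` tibble (or row-bound curves).
#' @param type which curve to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.threshold_curve <- function(object, type = c("ratio", "gain"),
                                     ...) {
  type <- match.arg(type)
  dat <- dplyr::filter(object, .data$valid)
  if (type == "ratio") {
    ggplot2::ggplot(dat, ggplot2::aes(.data$tau, .data$ratio_above,
                                      colour = .data$dataset_id)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "methylation-change threshold (|delta beta|)",
                    y = "inverse-correlated fraction above threshold",
                    colour = "dataset") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(dat, ggplot2::aes(.data$tau, .data$gain,
                                      colour = .data$dataset_id)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "methylation-change threshold (|delta beta|)",
                    y = "inverse-correlation gain (above - below)",
                    colour = "dataset") +
      ggplot2::theme_minimal()
  }
}

#' @export
autoplot.threshold_selection <- function(object, ...) {
  dat <- dplyr::filter(object$pooled, .data$valid_all)
  ggplot2::ggplot(dat, ggplot2::aes(.data$tau, .data$pooled_gain)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$tau_opt, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "methylation-change threshold (|delta beta|)",
                  y = "summed inverse-correlation gain") +
    ggplot2::theme_minimal()
}
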