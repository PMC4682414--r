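#' Weighted-Z (Stouffer) combination of significance values
#'
#' Combines k significances into one by the weighted Z-method:
#' \deqn{Z_w = \sum_i w_i \Phi^{-1}(1 - p_i) / \sqrt{\sum_i w_i^2}}
#' returning \eqn{1 - \Phi(Z_w)}. With weights \eqn{w_i = \sqrt{n_i}}
#' (square root of each study's sample size) this is the classical
#' sample-size-weighted Stouffer combination. The result is invariant to
#' rescaling all weights by a positive constant, symmetric under permuting
#' the (p, w) pairs, and reduces to the input for a single p-value.
#'
#' Inputs are clamped to `[1e-300, 1 - 1e-16]` before the normal-quantile
#' transform so it stays finite.
#'
#' @param p_values numeric vector of significances in (0, 1].
#' @param weights positive weights, one per p-value; defaults to equal
#'   weights (unweighted Stouffer).
#' @return the combined p-value (scalar).
#' @export
weighted_z_combine <- function(p_values, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(p_values))
  if (length(p_values) < 1) {
    rlang::abort("need at least one p-value", class = "methgain_value_error")
  }
  if (length(weights) != length(p_values)) {
    rlang::abort("p-values and weights must have equal length",
                 class = "methgain_value_error")
  }
  if (any(!is.finite(weights) | weights <= 0)) {
    rlang::abort("weights must be positive and finite",
                 class = "methgain_value_error")
  }
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    rlang::abort("p-values must lie in (0, 1]",
                 class = "methgain_value_error")
  }
  p <- pmin(pmax(p_values, 1e-300), 1 - 1e-16)
  z <- stats::qnorm(p, lower.tail = FALSE)
  zw <- sum(weights * z) / sqrt(sum(weights^2))
  stats::pnorm(zw, lower.tail = FALSE)
}

# vectorised two-study special case used across whole gene tables
weighted_z_pair <- function(p1, p2, w1, w2) {
  p1 <- pmin(pmax(p1, 1e-300), 1 - 1e-16)
  p2 <- pmin(pmax(p2, 1e-300), 1 - 1e-16)
  z1 <- stats::qnorm(p1, lower.tail = FALSE)
  z2 <- stats::qnorm(p2, lower.tail = FALSE)
  stats::pnorm((w1 * z1 + w2 * z2) / sqrt(w1^2 + w2^2), lower.tail = FALSE)
}

#' Combine per-gene methylation and expression significances
#'
#' Joins gene-level methylation records (post region collapse) with
#' gene-level expression records and combines the two significances per
#' gene by [weighted_z_combine()] with weights equal to the square root of
#' each modality's sample size. The combined p-values are then BH-adjusted
#' across genes, and each gene is tagged with its methylation-expression
#' correlation class (see [classify_correlation()]).
#'
#' The inputs are BH FDRs, not raw p-values, when `values = "fdr"` (the
#' default): combining already-adjusted significances is conservative and
#' non-standard, so a warning is emitted once per call unless `quiet =
#' TRUE`. Pass `values = "p"` to combine raw p-values instead.
#'
#' @param meth gene-level methylation tibble from
#'   [collapse_regions_to_genes()].
#' @param expr gene-level expression tibble from
#'   [differential_expression()].
#' @param n_meth,n_expr sample sizes behind each modality (weights are
#'   their square roots).
#' @param values which column to combine: `"fdr"` (default) or `"p"` (uses
#'   `p_value`).
#' @param quiet suppress the FDR-combination warning.
#' @return tibble with columns `gene`, `meth_fdr`, `expr_fdr`,
#'   `combined_p`, `combined_fdr`, `delta_beta`, `log_fc`,
#'   `correlation_class`; genes present in only one modality are attached
#'   as the `unmatched` attribute, not combined.
#' @export
combine_gene_significances <- function(meth, expr, n_meth, n_expr,
                                       values = c("fdr", "p"),
                                       quiet = FALSE) {
  values <- match.arg(values)
  shared <- intersect(meth$gene, expr$gene)
  if (length(shared) == 0) {
    rlang::abort("methylation and expression gene universes do not overlap",
                 class = "methgain_input_error")
  }
  if (values == "fdr" && !quiet) {
    rlang::warn(paste("combining BH-adjusted FDRs rather than raw p-values;",
                      "this is conservative (set values = 'p' to combine",
                      "raw p-values)"),
                class = "methgain_fdr_combination")
  }
  m <- dplyr::select(meth, "gene", meth_sig = dplyr::all_of(
    if (values == "fdr") "fdr" else "p_value"), "delta_beta")
  e <- dplyr::select(expr, "gene", expr_sig = dplyr::all_of(
    if (values == "fdr") "fdr" else "p_value"), "log_fc")
  joined <- dplyr::inner_join(m, e, by = "gene")
  w1 <- sqrt(n_meth)
  w2 <- sqrt(n_expr)
  out <- joined |>
    dplyr::mutate(
      combined_p = weighted_z_pair(.data$meth_sig, .data$expr_sig, w1, w2),
      combined_fdr = bh_adjust(.data$combined_p),
      correlation_class = classify_correlation(.data$delta_beta,
                                               .data$log_fc)) |>
    dplyr::select(gene = "gene", meth_fdr = "meth_sig",
                  expr_fdr = "expr_sig", "combined_p", "combined_fdr",
                  "delta_beta", "log_fc", "correlation_class")
  attr(out, "unmatched") <- list(
    meth_only = setdiff(meth$gene, shared),
    expr_only = setdiff(expr$gene, shared))
  out
}

#' Combine per-key significance tables across batches
#'
#' For keys (genes or enrichment terms) present in every batch table the
#' significances are merged by [weighted_z_combine()] with weights equal to
#' the square root of each batch's sample size; keys missing from any
#' batch are carried through flagged (`in_all_batches = FALSE`) and
#' excluded from combination and ranking.
#'
#' @param tables list (>= 2) of tibbles each holding `key_col` and `p_col`.
#' @param sample_sizes numeric vector of per-batch sample sizes.
#' @param key_col,p_col column names of the key and the significance.
#' @return tibble with `key_col`, per-batch significances, `combined_p`,
#'   `combined_fdr` (BH across combined keys), `in_all_batches`, and
#'   `rank` (ascending combined significance; NA for flagged keys).
#' @export
combine_across_batches <- function(tables, sample_sizes,
                                   key_col = "term", p_col = "p_value") {
  if (length(tables) < 2) {
    rlang::abort("need at least two batch tables to combine",
                 class = "methgain_input_error")
  }
  if (length(sample_sizes) != length(tables) || any(sample_sizes <= 0)) {
    rlang::abort("sample_sizes must be positive, one per table",
                 class = "methgain_input_error")
  }
  slim <- purrr::imap(tables, function(tbl, i) {
    out <- tbl[, c(key_col, p_col)]
    names(out) <- c("key", paste0("p_batch", i))
    out
  })
  merged <- purrr::reduce(slim, dplyr::full_join, by = "key")
  pmat <- as.matrix(merged[, -1, drop = FALSE])
  in_all <- rowSums(is.na(pmat)) == 0
  w <- sqrt(sample_sizes)
  combined <- rep(NA_real_, nrow(merged))
  if (any(in_all)) {
    z <- stats::qnorm(pmin(pmax(pmat[in_all, , drop = FALSE], 1e-300),
                           1 - 1e-16), lower.tail = FALSE)
    zw <- as.vector(z %*% w) / sqrt(sum(w^2))
    combined[in_all] <- stats::pnorm(zw, lower.tail = FALSE)
  }
  out <- merged
  names(out)[1] <- key_col
  out$combined_p <- combined
  out$combined_fdr <- NA_real_
  out$combined_fdr[in_all] <- bh_adjust(combined[in_all])
  out$in_all_batches <- in_all
  out$rank <- NA_integer_
  out$rank[in_all] <- rank(combined[in_all], ties.method = "first")
  dplyr::arrange(tibble::as_tibble(out), !.data$in_all_batches, .data$rank)
}
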