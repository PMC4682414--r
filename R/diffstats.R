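#' Benjamini-Hochberg adjustment with input validation
#'
#' Step-up BH false-discovery-rate adjustment; output order matches input
#' order and every adjusted value is >= its raw value and <= 1.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return numeric vector of BH-adjusted p-values, same order.
#' @export
bh_adjust <- function(p_values) {
  bad <- which(!is.finite(p_values) | p_values <= 0 | p_values > 1)
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("p-values must lie in (0, 1]; offending index: %d (value %s)",
              bad[1], format(p_values[bad[1]])),
      class = "methgain_value_error")
  }
  stats::p.adjust(p_values, method = "BH")
}

check_groups <- function(samples, group_labels) {
  if (is.data.frame(group_labels)) {
    group_labels <- stats::setNames(group_labels$group, group_labels$sample)
  }
  if (!is.null(names(group_labels))) {
    group_labels <- group_labels[samples]
  }
  g <- as.character(group_labels)
  if (length(g) != length(samples) || anyNA(g)) {
    rlang::abort("group labels do not cover every sample column",
                 class = "methgain_input_error")
  }
  if (!all(g %in% c("control", "tumour"))) {
    rlang::abort("group labels must be 'control' or 'tumour'",
                 class = "methgain_input_error")
  }
  if (sum(g == "control") < 2 || sum(g == "tumour") < 2) {
    rlang::abort("each group needs at least 2 samples",
                 class = "methgain_input_error")
  }
  g
}

#' @noRd
#' Row-wise Welch t-test. Degenerate rows (zero variance in both groups)
#' get p = 1 rather than NaN. Returns two-sided p-values floored away from 0.
row_welch_p <- function(x, is_t) {
  n1 <- sum(!is_t)
  n2 <- sum(is_t)
  x1 <- x[, !is_t, drop = FALSE]
  x2 <- x[, is_t, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- pmax(rowSums((x1 - m1)^2) / (n1 - 1), 0)
  v2 <- pmax(rowSums((x2 - m2)^2) / (n2 - 1), 0)
  se2 <- v1 / n1 + v2 / n2
  degen <- se2 <= 0
  tstat <- ifelse(degen, 0, (m2 - m1) / sqrt(pmax(se2, 1e-300)))
  df <- ifelse(degen, 1,
               se2^2 / (pmax((v1 / n1)^2 / (n1 - 1) +
                               (v2 / n2)^2 / (n2 - 1), 1e-300)))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[degen] <- 1
  pmin(pmax(p, 1e-300), 1)
}

#' Region-level differential methylation
#'
#' Per region: delta-beta is the tumour-minus-control difference of mean
#' beta-values (reported on the beta scale); the p-value comes from a Welch
#' t-test on M-values (logit2 of beta, clamped), the standard
#' variance-stabilising transform for array methylation; FDR is BH over all
#' regions.
#'
#' @param beta_matrix regions x samples matrix of beta-values in [0, 1].
#' @param group_labels `control`/`tumour` labels: a named vector, a bare
#'   vector aligned to columns, or a tibble with `sample` and `group`.
#' @param region_map tibble with `region_id`, `gene` linking regions to
#'   genes.
#' @return tibble with columns `region_id`, `gene`, `delta_beta`,
#'   `p_value`, `fdr`.
#' @export
differential_methylation <- function(beta_matrix, group_labels, region_map) {
  g <- check_groups(colnames(beta_matrix), group_labels)
  if (any(beta_matrix < 0 | beta_matrix > 1)) {
    rlang::abort("beta values must lie in [0, 1]",
                 class = "methgain_input_error")
  }
  is_t <- g == "tumour"
  delta <- rowMeans(beta_matrix[, is_t, drop = FALSE]) -
    rowMeans(beta_matrix[, !is_t, drop = FALSE])
  b <- pmin(pmax(beta_matrix, 1e-6), 1 - 1e-6)
  mval <- log2(b / (1 - b))
  p <- row_welch_p(mval, is_t)
  out <- tibble::tibble(region_id = rownames(beta_matrix),
                        delta_beta = unname(delta),
                        p_value = unname(p),
                        fdr = bh_adjust(unname(p)))
  dplyr::relocate(
    dplyr::inner_join(out, region_map, by = "region_id"),
    "region_id", "gene")
}

#' Gene-level differential expression
#'
#' A linear-model stand-in with the table contract downstream stages need:
#' log2 fold change of mean CPM (pseudocount 0.5) and a Welch t-test on
#' log2(CPM + 0.5), BH-corrected across genes. Genes with zero counts
#' everywhere get `log_fc = 0`, `p = 1`.
#'
#' @param count_matrix genes x samples matrix of non-negative integer
#'   counts.
#' @inheritParams differential_methylation
#' @return tibble with columns `gene`, `log_fc`, `p_value`, `fdr`.
#' @export
differential_expression <- function(count_matrix, group_labels) {
  g <- check_groups(colnames(count_matrix), group_labels)
  if (any(count_matrix < 0) || any(count_matrix != floor(count_matrix))) {
    rlang::abort("counts must be non-negative integers",
                 class = "methgain_input_error")
  }
  lib <- colSums(count_matrix)
  if (any(lib == 0)) {
    rlang::abort(sprintf("sample '%s' has zero total counts",
                         colnames(count_matrix)[which(lib == 0)[1]]),
                 class = "methgain_input_error")
  }
  cpm <- sweep(count_matrix, 2, lib, "/") * 1e6
  is_t <- g == "tumour"
  log_fc <- log2((rowMeans(cpm[, is_t, drop = FALSE]) + 0.5) /
                   (rowMeans(cpm[, !is_t, drop = FALSE]) + 0.5))
  p <- row_welch_p(log2(cpm + 0.5), is_t)
  tibble::tibble(gene = rownames(count_matrix),
                 log_fc = unname(log_fc),
                 p_value = unname(p),
                 fdr = bh_adjust(unname(p)))
}

#' Collapse region-level methylation records to one record per gene
#'
#' Keeps, for each gene, the region with the most significant methylation
#' change (minimum FDR). Ties are broken deterministically: larger
#' |delta-beta| first, then lexicographically smallest region id. The
#' operation is idempotent and independent of input row order.
#'
#' @param records tibble of region records (`region_id`, `gene`,
#'   `delta_beta`, `p_value`, `fdr`).
#' @return tibble with one row per gene: `gene`, `best_region`,
#'   `delta_beta`, `p_value`, `fdr`.
#' @export
collapse_regions_to_genes <- function(records) {
  if (nrow(records) == 0) {
    rlang::abort("no region records to collapse",
                 class = "methgain_input_error")
  }
  records |>
    dplyr::arrange(.data$fdr, dplyr::desc(abs(.data$delta_beta)),
                   .data$region_id) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE) |>
    dplyr::transmute(gene = .data$gene, best_region = .data$region_id,
                     delta_beta = .data$delta_beta,
                     p_value = .data$p_value, fdr = .data$fdr) |>
    dplyr::arrange(.data$gene)
}

#' Restrict gene-level methylation records to the expression universe
#'
#' Genes measured by the methylation platform but absent from the
#' expression data cannot be integrated; they are dropped and reported.
#'
#' @param meth_genes tibble of gene-level methylation records with a `gene`
#'   column.
#' @param expr_genes character vector (or tibble with `gene`) of genes
#'   present in the expression data.
#' @return list with `kept` (filtered tibble) and `dropped` (character
#'   vector of excluded genes).
#' @export
restrict_to_expression_universe <- function(meth_genes, expr_genes) {
  if (is.data.frame(expr_genes)) expr_genes <- expr_genes$gene
  keep <- meth_genes$gene %in% expr_genes
  list(kept = meth_genes[keep, , drop = FALSE],
       dropped = meth_genes$gene[!keep])
}
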