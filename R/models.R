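#' The ten declarative gene-selection strategies
#'
#' Each model is a predicate over the integrated gene table (see
#' [combine_gene_significances()]): which significance source must pass
#' `fdr_cut`, an optional |delta-beta| bound, and an optional correlation
#' filter. Shipped defaults:
#'
#' * M1 — differentially expressed genes (`expr_fdr < 0.01`)
#' * M2 — differentially methylated genes (`meth_fdr < 0.01`)
#' * M3 — both differentially expressed and methylated
#' * M4 — significant after combining the two significances
#'   (`combined_fdr < 0.01`)
#' * M5 — |delta-beta| > 0.15 and inversely correlated
#' * M6 — |delta-beta| > 0.15
#' * M7 — combined-significant and |delta-beta| > 0.15
#' * M8 — M7 and inversely correlated
#' * M9 — M7 and positively correlated
#' * M10 — combined-significant and |delta-beta| > 0.40
#'
#' With `blanket_meth_fdr = TRUE`, M5 and M6 additionally require
#' `meth_fdr < fdr_cut` (reading the strategy table's blanket FDR note as
#' applying to the threshold-only models too); the default keeps them as
#' pure delta-beta predicates so the set identities `M7 = M4` \eqn{\cap}
#' `M6` and `M3 = M1` \eqn{\cap} `M2` hold exactly.
#'
#' @param delta_beta_threshold the standard methylation-change bound
#'   (default 0.15; "more than 15% methylation change").
#' @param high_threshold the stringent bound used by M10 (default 0.40).
#' @param fdr_cut significance bound for all models (default 0.01).
#' @param blanket_meth_fdr also require methylation significance in
#'   M5/M6.
#' @return tibble with one row per model: `model_id`, `description`,
#'   `significance_source`, `threshold`, `correlation_filter`, `fdr_cut`.
#' @export
model_specs <- function(delta_beta_threshold = 0.15, high_threshold = 0.40,
                        fdr_cut = 0.01, blanket_meth_fdr = FALSE) {
  thr <- delta_beta_threshold
  m56_sig <- if (blanket_meth_fdr) "meth" else "none"
  tibble::tibble(
    model_id = paste0("M", 1:10),
    description = c(
      "differentially expressed genes",
      "differentially methylated genes",
      "differentially expressed and differentially methylated genes",
      "genes significant after combining methylation and expression",
      "genes above the methylation-change threshold, inversely correlated",
      "genes above the methylation-change threshold",
      "combined-significant genes above the methylation-change threshold",
      "combined-significant, above threshold, inversely correlated",
      "combined-significant, above threshold, positively correlated",
      "combined-significant genes above the stringent threshold"),
    significance_source = c("expr", "meth", "both", "combined",
                            m56_sig, m56_sig, "combined", "combined",
                            "combined", "combined"),
    threshold = c(NA, NA, NA, NA, thr, thr, thr, thr, thr, high_threshold),
    correlation_filter = c("any", "any", "any", "any", "inverse", "any",
                           "any", "inverse", "positive", "any"),
    fdr_cut = fdr_cut)
}

#' Apply one selection strategy to an integrated gene table
#'
#' @param table integrated gene tibble with `gene`, `meth_fdr`,
#'   `expr_fdr`, `combined_fdr`, `delta_beta`, `correlation_class`.
#' @param spec one row of [model_specs()] (or a model id, resolved against
#'   `specs`).
#' @param specs the spec table to resolve ids against.
#' @return object of class `gene_set`: list with `model_id`, `genes`
#'   (character vector) and `provenance` (record counts after each filter
#'   stage).
#' @export
apply_model <- function(table, spec, specs = model_specs()) {
  if (is.character(spec)) {
    spec <- specs[specs$model_id == spec, ]
    if (nrow(spec) != 1) {
      rlang::abort("unknown model id", class = "methgain_config_error")
    }
  }
  needed <- c("gene", "correlation_class",
              switch(spec$significance_source,
                     expr = "expr_fdr", meth = "meth_fdr",
                     both = c("expr_fdr", "meth_fdr"),
                     combined = "combined_fdr", none = character(0)),
              if (!is.na(spec$threshold)) "delta_beta")
  missing_f <- setdiff(needed, names(table))
  if (length(missing_f) > 0) {
    rlang::abort(sprintf("integrated table lacks field(s): %s",
                         paste(missing_f, collapse = ", ")),
                 class = "methgain_config_error")
  }
  prov <- tibble::tibble(stage = "input", n = nrow(table))
  cur <- table
  cut <- spec$fdr_cut
  cur <- switch(spec$significance_source,
                expr = dplyr::filter(cur, .data$expr_fdr < cut),
                meth = dplyr::filter(cur, .data$meth_fdr < cut),
                both = dplyr::filter(cur, .data$expr_fdr < cut,
                                     .data$meth_fdr < cut),
                combined = dplyr::filter(cur, .data$combined_fdr < cut),
                none = cur)
  prov <- dplyr::bind_rows(prov,
                           tibble::tibble(stage = "significance",
                                          n = nrow(cur)))
  if (!is.na(spec$threshold)) {
    cur <- dplyr::filter(cur, abs(.data$delta_beta) > spec$threshold)
    prov <- dplyr::bind_rows(prov,
                             tibble::tibble(stage = "threshold",
                                            n = nrow(cur)))
  }
  if (spec$correlation_filter != "any") {
    cur <- dplyr::filter(cur,
                         .data$correlation_class == spec$correlation_filter)
    prov <- dplyr::bind_rows(prov,
                             tibble::tibble(stage = "correlation",
                                            n = nrow(cur)))
  }
  out <- list(model_id = spec$model_id, genes = sort(unique(cur$gene)),
              provenance = prov)
  class(out) <- "gene_set"
  out
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set %s: %d genes>\n", x$model_id, length(x$genes)))
  invisible(x)
}

#' Run every selection strategy and summarise the resulting sets
#'
#' @inheritParams apply_model
#' @param dataset_id optional label carried into the summary.
#' @return object of class `model_gene_sets`: list with `sets` (named list
#'   of `gene_set`), `sizes` (tibble) and `overlap` (model x model shared
#'   gene counts). Supports [generics::tidy()].
#' @export
run_all_models <- function(table, dataset_id = NULL,
                           specs = model_specs()) {
  sets <- purrr::map(seq_len(nrow(specs)),
                     ~ apply_model(table, specs[.x, ]))
  names(sets) <- specs$model_id
  sizes <- tibble::tibble(
    dataset_id = dataset_id %||% NA_character_,
    model_id = specs$model_id,
    n_genes = purrr::map_int(sets, ~ length(.x$genes)))
  genes <- purrr::map(sets, "genes")
  overlap <- outer(seq_along(genes), seq_along(genes),
                   Vectorize(function(i, j) {
                     length(intersect(genes[[i]], genes[[j]]))
                   }))
  dimnames(overlap) <- list(specs$model_id, specs$model_id)
  out <- list(sets = sets, sizes = sizes, overlap = overlap,
              dataset_id = dataset_id)
  class(out) <- "model_gene_sets"
  out
}

#' @export
tidy.model_gene_sets <- function(x, ...) {
  purrr::map_dfr(x$sets, function(s) {
    tibble::tibble(model_id = s$model_id, gene = s$genes)
  })
}

#' @export
glance.model_gene_sets <- function(x, ...) x$sizes

#' @export
print.model_gene_sets <- function(x, ...) {
  cat("<model_gene_sets>\n")
  print(x$sizes)
  invisible(x)
}

#' Write model gene sets as one-gene-per-line TSVs
#'
#' @param models a `model_gene_sets` object.
#' @param dir output directory.
#' @param stamp optional comment line prefix for provenance.
#' @return `dir`, invisibly.
#' @export
write_gene_sets <- function(models, dir, stamp = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  purrr::walk(models$sets, function(s) {
    path <- file.path(dir, paste0("genes_", s$model_id, ".tsv"))
    hdr <- c(if (!is.null(stamp)) paste0("# ", stamp),
             paste0("# model ", s$model_id, "; stages: ",
                    paste(sprintf("%s=%d", s$provenance$stage,
                                  s$provenance$n), collapse = ", ")))
    writeLines(c(hdr, s$genes), path)
  })
  invisible(dir)
}
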