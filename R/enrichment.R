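#' Gene-set collection with an explicit background universe
#'
#' Harmonises a named list of term member vectors against a background
#' universe (members outside the universe are dropped; terms left empty
#' are removed).
#'
#' @param terms named list of character vectors (term -> member genes).
#' @param universe character vector of background genes.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(terms, universe) {
  universe <- unique(universe)
  harmonised <- purrr::map(terms, ~ intersect(.x, universe))
  keep <- purrr::map_int(harmonised, length) > 0
  if (!all(keep)) {
    rlang::warn(sprintf("%d term(s) had no members in the universe; dropped",
                        sum(!keep)))
  }
  out <- list(terms = harmonised[keep], universe = universe)
  class(out) <- "gene_set_collection"
  out
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection: %d terms, universe of %d genes>\n",
              length(x$terms), length(x$universe)))
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' For each term the p-value is the upper hypergeometric tail
#' \eqn{P(X \ge k)} of drawing `k` term members in a query of size `n`
#' from a universe of size `N` containing `K` term members. P-values are
#' BH-adjusted across terms and rows ranked ascending (ties: smaller raw
#' p, then larger overlap, then lexicographic term id).
#'
#' @param query character vector of genes; genes outside the universe are
#'   dropped with a warning.
#' @param collection a [gene_set_collection()].
#' @return `enrichment_table` tibble: `term`, `overlap`, `term_size`,
#'   `query_size`, `universe_size`, `p_value`, `adjusted_p`, `rank`.
#' @export
ora <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(query)
  outside <- setdiff(query, collection$universe)
  if (length(outside) > 0) {
    rlang::warn(sprintf("%d query gene(s) outside the universe dropped",
                        length(outside)))
    query <- setdiff(query, outside)
  }
  if (length(query) == 0) {
    rlang::abort("query is empty after harmonising with the universe",
                 class = "methgain_input_error")
  }
  n_univ <- length(collection$universe)
  n_query <- length(query)
  rows <- purrr::imap(collection$terms, function(members, id) {
    k <- length(intersect(members, query))
    m <- length(members)
    tibble::tibble(
      term = id, overlap = k, term_size = m, query_size = n_query,
      universe_size = n_univ,
      p_value = stats::phyper(k - 1, m, n_univ - m, n_query,
                              lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(rows)
  out$adjusted_p <- bh_adjust(out$p_value)
  out <- out |>
    dplyr::arrange(.data$adjusted_p, .data$p_value,
                   dplyr::desc(.data$overlap), .data$term) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Count reference terms detected in the top K of a ranking
#'
#' The strategy-comparison metric: how many of a reference list of
#' disease-relevant terms appear at rank <= `k` in an enrichment ranking.
#' Terms absent from the table count as not detected.
#'
#' @param table an `enrichment_table` (or any tibble with `term` and
#'   `rank`).
#' @param reference_terms character vector of reference term ids.
#' @param k rank bound (default 20).
#' @return one-row tibble: `n_detected`, `k`, `n_reference`, `detected`
#'   (list-column of detected term ids).
#' @export
topk_detection <- function(table, reference_terms, k = 20) {
  if (k < 1) {
    rlang::abort("k must be >= 1", class = "methgain_value_error")
  }
  hit <- table$term[!is.na(table$rank) & table$rank <= k]
  detected <- intersect(reference_terms, hit)
  tibble::tibble(n_detected = length(detected), k = k,
                 n_reference = length(reference_terms),
                 detected = list(detected))
}

#' Benchmark all selection strategies across datasets
#'
#' Runs every model on every dataset's integrated gene table, ranks the
#' resulting gene sets against the term collection by [ora()], and scores
#' each (dataset, model) cell by [topk_detection()]. When
#' `combine_batches` names two or more of the datasets, an additional
#' meta-analysis dataset is scored by combining the per-term enrichment
#' p-values across those batches with [combine_across_batches()]
#' (square-root-sample-size weights) and ranking the combined
#' significances.
#'
#' Models whose gene set is empty (or entirely outside the universe) score
#' zero detections.
#'
#' @param datasets named list of integrated gene tibbles.
#' @param collection a [gene_set_collection()].
#' @param reference_terms reference term ids for detection.
#' @param k top-K bound.
#' @param specs model table from [model_specs()].
#' @param combine_batches optional character vector of dataset names to
#'   meta-combine into a `combined` dataset.
#' @param sample_sizes named numeric vector of per-dataset sample sizes
#'   (required when `combine_batches` is given).
#' @return object of class `detection_report`: list with `detection`
#'   (tibble dataset x model x n_detected), `enrichment` (nested list of
#'   enrichment tables), `gene_sets`.
#' @export
benchmark_strategies <- function(datasets, collection, reference_terms,
                                 k = 20, specs = model_specs(),
                                 combine_batches = NULL,
                                 sample_sizes = NULL) {
  if (length(datasets) < 1) {
    rlang::abort("need at least one dataset", class = "methgain_input_error")
  }
  gene_sets <- purrr::imap(datasets, ~ run_all_models(.x, dataset_id = .y,
                                                      specs = specs))
  enr <- purrr::map(gene_sets, function(ms) {
    purrr::map(ms$sets, function(s) {
      if (length(intersect(s$genes, collection$universe)) == 0) {
        return(NULL)
      }
      suppressWarnings(ora(s$genes, collection))
    })
  })
  detection <- purrr::imap_dfr(enr, function(tables, ds) {
    purrr::imap_dfr(tables, function(tbl, model) {
      d <- if (is.null(tbl)) {
        tibble::tibble(n_detected = 0L, k = k,
                       n_reference = length(reference_terms),
                       detected = list(character(0)))
      } else {
        topk_detection(tbl, reference_terms, k)
      }
      dplyr::mutate(d, dataset = ds, model_id = model, .before = 1)
    })
  })
  if (!is.null(combine_batches)) {
    if (length(combine_batches) < 2 ||
        !all(combine_batches %in% names(datasets))) {
      rlang::abort("combine_batches must name >= 2 of the datasets",
                   class = "methgain_input_error")
    }
    if (is.null(sample_sizes)) {
      rlang::abort("sample_sizes required to combine batches",
                   class = "methgain_input_error")
    }
    comb_det <- purrr::map_dfr(specs$model_id, function(model) {
      tabs <- purrr::map(combine_batches, ~ enr[[.x]][[model]])
      if (any(purrr::map_lgl(tabs, is.null))) {
        return(tibble::tibble(dataset = "combined", model_id = model,
                              n_detected = 0L, k = k,
                              n_reference = length(reference_terms),
                              detected = list(character(0))))
      }
      merged <- combine_across_batches(tabs,
                                       sample_sizes[combine_batches],
                                       key_col = "term",
                                       p_col = "p_value")
      dplyr::mutate(topk_detection(merged, reference_terms, k),
                    dataset = "combined", model_id = model, .before = 1)
    })
    detection <- dplyr::bind_rows(detection, comb_det)
  }
  out <- list(detection = detection, enrichment = enr,
              gene_sets = gene_sets, k = k,
              reference_terms = reference_terms)
  class(out) <- "detection_report"
  out
}

#' @export
tidy.detection_report <- function(x, ...) {
  dplyr::select(x$detection, "dataset", "model_id", "n_detected", "k",
                "n_reference")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("<detection_report: top-%d detection of %d reference terms>\n",
              x$k, length(x$reference_terms)))
  wide <- tidyr::pivot_wider(
    dplyr::select(x$detection, "dataset", "model_id", "n_detected"),
    names_from = "dataset", values_from = "n_detected")
  print(wide, n = Inf)
  invisible(x)
}

#' Detection-count heatmap across models and datasets
#'
#' @param object a `detection_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.detection_report <- function(object, ...) {
  dat <- dplyr::mutate(object$detection,
                       model_id = factor(.data$model_id,
                                         levels = paste0("M", 1:10)))
  ggplot2::ggplot(dat, ggplot2::aes(.data$dataset, .data$model_id,
                                    fill = .data$n_detected)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_detected),
                       colour = "white") +
    ggplot2::labs(x = "dataset", y = "strategy",
                  fill = sprintf("terms in top %d", object$k)) +
    ggplot2::theme_minimal()
}
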