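#' Pipeline run configuration
#'
#' Bundles either a simulation config or paths to input tables with the
#' analysis parameters for [run_pipeline()]. Exactly one of `sim` and
#' `input_dir` must be given.
#'
#' @param sim a [simulation_config()] (synthetic run), or NULL.
#' @param input_dir directory of study TSVs written by [write_study()], or
#'   NULL.
#' @param grid threshold grid (see [threshold_grid()]).
#' @param eligibility_fdr FDR bound for threshold-analysis eligibility
#'   (default 0.1).
#' @param model_fdr FDR bound for the selection strategies (default 0.01).
#' @param top_k rank bound of the detection benchmark (default 20).
#' @param threshold_override optional second methylation-change bound; the
#'   combined-significance + threshold strategy is additionally evaluated
#'   at this bound for comparison.
#' @param min_side minimum records per side for a valid threshold.
#' @param unit record unit for the threshold analysis: gene-level
#'   (post-collapse, default) or region-level.
#' @param seed integer seed for the synthetic branch.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = simulation_config(), input_dir = NULL,
                       grid = threshold_grid(), eligibility_fdr = 0.1,
                       model_fdr = 0.01, top_k = 20,
                       threshold_override = NULL, min_side = 10,
                       unit = c("gene", "region"), seed = NULL) {
  if (is.null(sim) == is.null(input_dir)) {
    rlang::abort("exactly one of `sim` and `input_dir` must be provided",
                 class = "methgain_config_error")
  }
  for (f in c("eligibility_fdr", "model_fdr")) {
    v <- get(f)
    if (!(v > 0 && v <= 1)) {
      rlang::abort(sprintf("`%s` must lie in (0, 1]", f),
                   class = "methgain_config_error")
    }
  }
  if (!is.null(sim) && !is.null(seed)) sim$seed <- as.integer(seed)
  out <- list(sim = sim, input_dir = input_dir, grid = grid,
              eligibility_fdr = eligibility_fdr, model_fdr = model_fdr,
              top_k = top_k, threshold_override = threshold_override,
              min_side = min_side, unit = match.arg(unit))
  class(out) <- "run_config"
  out
}

read_study_dir <- function(dir) {
  study <- list(
    beta = read_matrix_tsv(file.path(dir, "beta.tsv")),
    counts = read_matrix_tsv(file.path(dir, "counts.tsv")),
    region_map = readr::read_tsv(file.path(dir, "region_map.tsv"),
                                 show_col_types = FALSE, progress = FALSE),
    samples = readr::read_tsv(file.path(dir, "samples.tsv"),
                              show_col_types = FALSE, progress = FALSE),
    terms = read_gmt(file.path(dir, "terms.gmt")))
  class(study) <- "sim_study"
  study
}

subset_study <- function(study, samples_keep) {
  study$beta <- study$beta[, samples_keep, drop = FALSE]
  study$counts <- study$counts[, samples_keep, drop = FALSE]
  study$samples <- study$samples[study$samples$sample %in% samples_keep, ]
  study
}

#' Differential statistics and integrated gene table for one study
#'
#' Convenience wrapper running the per-dataset stages in order:
#' differential methylation (regions), differential expression (genes),
#' region-to-gene collapse, expression-universe restriction, weighted-Z
#' combination, and eligibility filtering for the threshold analysis.
#'
#' @param study a `sim_study` (or any list with `beta`, `counts`,
#'   `region_map`, `samples`).
#' @param eligibility_fdr FDR bound for threshold-analysis eligibility.
#' @param unit `"gene"` (post-collapse, default) or `"region"`: the record
#'   unit entering the threshold analysis.
#' @return list with `meth`, `expr`, `integrated`, `eligible`, `dropped`,
#'   `n_samples`.
#' @export
integrate_study <- function(study, eligibility_fdr = 0.1,
                            unit = c("gene", "region")) {
  unit <- match.arg(unit)
  meth <- differential_methylation(study$beta, study$samples,
                                   study$region_map)
  expr <- differential_expression(study$counts, study$samples)
  collapsed <- collapse_regions_to_genes(meth)
  restricted <- restrict_to_expression_universe(collapsed, expr$gene)
  n <- nrow(study$samples)
  integrated <- combine_gene_significances(restricted$kept, expr,
                                           n_meth = n, n_expr = n,
                                           quiet = TRUE)
  eligible <- if (unit == "region") {
    pairs <- meth |>
      dplyr::select("region_id", "gene", "delta_beta", meth_fdr = "fdr") |>
      dplyr::inner_join(dplyr::select(expr, "gene", "log_fc",
                                      expr_fdr = "fdr"), by = "gene") |>
      dplyr::mutate(correlation_class = classify_correlation(
        .data$delta_beta, .data$log_fc))
    eligible_records(pairs, eligibility_fdr)
  } else {
    eligible_records(integrated, eligibility_fdr)
  }
  list(meth = meth, expr = expr, integrated = integrated,
       eligible = eligible, dropped = restricted$dropped, n_samples = n)
}

#' Run the full integration pipeline
#'
#' End-to-end orchestration over a multi-batch study (simulated or read
#' from disk): per-dataset differential methylation and expression,
#' region-to-gene collapse, expression-universe restriction, weighted-Z
#' combination, threshold-gain analysis across all datasets (each batch
#' plus the pooled data), the ten selection strategies, hypergeometric
#' enrichment, and the top-K detection benchmark (including the
#' batch-combined meta-analysis dataset). Results are returned and, when
#' `out_dir` is given, written as stamped TSVs with a reproducibility
#' manifest.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return list of class `pipeline_result` with elements `datasets`,
#'   `curves`, `selection`, `ratio_max`, `models`, `report`,
#'   `models_override`, `report_override`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        writeLines(sprintf("stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      }
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)), parent = e)
    })
  }
  log_stage <- function(...) message(sprintf("[methgain] %s", sprintf(...)))

  log_stage("stage: input")
  studies <- stage("input", {
    if (!is.null(config$sim)) {
      simulate_multi_batch(config$sim)
    } else {
      list(batch1 = read_study_dir(config$input_dir))
    }
  })
  datasets <- studies
  if (length(studies) > 1) datasets <- c(studies, list(pooled = pool_studies(studies)))

  log_stage("stage: differential + integration (%d datasets)",
            length(datasets))
  per_ds <- stage("integration", {
    purrr::map(datasets, integrate_study,
               eligibility_fdr = config$eligibility_fdr,
               unit = config$unit)
  })

  log_stage("stage: threshold analysis")
  curves <- stage("threshold", {
    purrr::imap(per_ds, function(d, id) {
      gain_curve(d$eligible, grid = config$grid,
                 min_side = config$min_side, dataset_id = id)
    })
  })
  selection <- stage("threshold", select_threshold(curves))
  ratio_max <- ratio_maximiser(curves)

  log_stage("stage: selection strategies (tau = %.2f)", selection$tau_opt)
  specs <- model_specs(delta_beta_threshold = selection$tau_opt,
                       fdr_cut = config$model_fdr)
  models <- stage("models", {
    purrr::imap(per_ds, ~ run_all_models(.x$integrated, dataset_id = .y,
                                         specs = specs))
  })

  log_stage("stage: enrichment benchmark")
  study0 <- studies[[1]]
  universe <- rownames(study0$counts) %||% per_ds[[1]]$expr$gene
  collection <- gene_set_collection(study0$terms, universe)
  reference <- study0$disease_terms %||% names(study0$terms)[1]
  batch_names <- names(studies)
  sizes <- purrr::map_dbl(per_ds, "n_samples")
  report <- stage("enrichment", {
    benchmark_strategies(purrr::map(per_ds, "integrated"), collection,
                         reference, k = config$top_k, specs = specs,
                         combine_batches = if (length(studies) > 1)
                           batch_names,
                         sample_sizes = sizes)
  })

  models_override <- NULL
  report_override <- NULL
  if (!is.null(config$threshold_override)) {
    log_stage("stage: threshold override (tau = %.2f)",
              config$threshold_override)
    specs_ov <- model_specs(delta_beta_threshold = config$threshold_override,
                            fdr_cut = config$model_fdr)
    models_override <- purrr::imap(per_ds, ~ run_all_models(
      .x$integrated, dataset_id = .y, specs = specs_ov))
    report_override <- benchmark_strategies(
      purrr::map(per_ds, "integrated"), collection, reference,
      k = config$top_k, specs = specs_ov,
      combine_batches = if (length(studies) > 1) batch_names,
      sample_sizes = sizes)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("methgain")),
    seed = if (!is.null(config$sim)) config$sim$seed else NA_integer_,
    config_hash = rlang::hash(config),
    tau_opt = selection$tau_opt,
    datasets = names(per_ds))

  result <- list(datasets = per_ds, curves = curves, selection = selection,
                 ratio_max = ratio_max, models = models, report = report,
                 models_override = models_override,
                 report_override = report_override, manifest = manifest,
                 config = config)
  class(result) <- "pipeline_result"
  if (!is.null(out_dir)) {
    stage("write", write_pipeline_outputs(result, out_dir))
  }
  result
}

#' @noRd
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("methgain seed=%s config_hash=%s",
                   result$manifest$seed, result$manifest$config_hash)
  purrr::iwalk(result$datasets, function(d, id) {
    write_tsv_stamped(d$meth, file.path(out_dir,
                                        sprintf("meth_%s.tsv", id)), stamp)
    write_tsv_stamped(d$expr, file.path(out_dir,
                                        sprintf("expr_%s.tsv", id)), stamp)
    write_tsv_stamped(d$integrated,
                      file.path(out_dir, sprintf("integrated_%s.tsv", id)),
                      stamp)
  })
  write_tsv_stamped(dplyr::bind_rows(result$curves),
                    file.path(out_dir, "threshold_curves.tsv"), stamp)
  write_tsv_stamped(tidy(result$selection),
                    file.path(out_dir, "pooled_gain.tsv"), stamp)
  purrr::iwalk(result$models, function(ms, id) {
    write_gene_sets(ms, file.path(out_dir, paste0("gene_sets_", id)),
                    stamp)
  })
  if (!is.null(result$models_override)) {
    purrr::iwalk(result$models_override, function(ms, id) {
      write_gene_sets(ms, file.path(out_dir,
                                    paste0("gene_sets_override_", id)),
                      stamp)
    })
    write_tsv_stamped(tidy(result$report_override),
                      file.path(out_dir, "detection_report_override.tsv"),
                      stamp)
  }
  write_tsv_stamped(tidy(result$report),
                    file.path(out_dir, "detection_report.tsv"), stamp)
  yaml::write_yaml(result$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<methgain pipeline result>\n")
  cat(sprintf("  datasets: %s\n", paste(names(x$datasets),
                                        collapse = ", ")))
  cat(sprintf("  selected threshold: %.2f\n", x$selection$tau_opt))
  cat(sprintf("  detection (top-%d):\n", x$report$k))
  print(tidy(x$report), n = 5)
  invisible(x)
}

#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(
    tau_opt = x$selection$tau_opt,
    n_datasets = length(x$datasets),
    n_models = nrow(x$models[[1]]$sizes),
    top_k = x$report$k)
}
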