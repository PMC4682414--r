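#' Configuration for a synthetic paired methylation/expression study
#'
#' Builds and validates the parameter set for [simulate_study()] and
#' [simulate_multi_batch()]. The generator plants a coupling structure in
#' which genes whose true methylation change exceeds `tau_star` respond
#' inversely in expression with probability `rho_high`, while genes below
#' the threshold do so with probability `rho_low`; the threshold-gain
#' analysis should then recover `tau_star` from the noisy data alone.
#'
#' Every differentially methylated (DM) gene responds in expression:
#' inversely (log fold change sign opposite to its delta-beta sign) with
#' probability rho, positively otherwise, so the realised inverse fraction
#' among DM genes above `tau_star` converges to `rho_high` (and below, to
#' `rho_low`) and the inverse-correlation gain jumps exactly at
#' `tau_star`.
#'
#' @param n_genes number of genes.
#' @param regions_per_gene_max each gene carries 1..this many methylation
#'   regions (uniform).
#' @param n_control,n_tumour samples per group, per batch.
#' @param n_batches number of batches sharing one truth table.
#' @param tau_star planted coupling threshold on |delta-beta|, in (0,1).
#' @param rho_high,rho_low probability of an inverse expression response for
#'   DM genes above / below `tau_star`.
#' @param frac_dm fraction of genes given a nonzero delta-beta.
#' @param frac_de_only fraction of the remaining genes given an
#'   expression-only effect (no methylation change); background for
#'   single-modality strategies.
#' @param delta_beta_range length-2 numeric, magnitude range for planted
#'   |delta-beta| (uniform draw), within [0,1].
#' @param beta_precision concentration of the beta-distributed array noise
#'   around group means (larger = less noise).
#' @param nb_dispersion negative-binomial overdispersion of counts
#'   (`size = 1/nb_dispersion`).
#' @param logfc_magnitude absolute log2 fold change of responding genes.
#' @param lib_size_range length-2 numeric, per-sample expected library-size
#'   totals (uniform draw).
#' @param n_terms,term_size_range toy gene-set collection shape (GMT).
#' @param n_disease_terms how many terms are "disease" terms whose member
#'   genes receive planted effects at `disease_multiplier` times the base
#'   probability.
#' @param disease_multiplier enrichment of planted effects in disease terms.
#' @param region_jitter_sd sd of the per-region jitter around a gene's
#'   planted delta-beta.
#' @param seed integer seed; every stochastic draw is governed by it.
#' @return a list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              regions_per_gene_max = 4,
                              n_control = 15,
                              n_tumour = 15,
                              n_batches = 2,
                              tau_star = 0.15,
                              rho_high = 0.7,
                              rho_low = 0.4,
                              frac_dm = 0.3,
                              frac_de_only = 0.10,
                              delta_beta_range = c(0.02, 0.5),
                              beta_precision = 100,
                              nb_dispersion = 0.1,
                              logfc_magnitude = 1,
                              lib_size_range = c(0.8e5, 1.2e5),
                              n_terms = 50,
                              term_size_range = c(10, 50),
                              n_disease_terms = 5,
                              disease_multiplier = 3,
                              region_jitter_sd = 0.02,
                              seed = 1L) {
  cfg <- list(
    n_genes = n_genes, regions_per_gene_max = regions_per_gene_max,
    n_control = n_control, n_tumour = n_tumour, n_batches = n_batches,
    tau_star = tau_star, rho_high = rho_high, rho_low = rho_low,
    frac_dm = frac_dm, frac_de_only = frac_de_only,
    delta_beta_range = delta_beta_range, beta_precision = beta_precision,
    nb_dispersion = nb_dispersion, logfc_magnitude = logfc_magnitude,
    lib_size_range = lib_size_range, n_terms = n_terms,
    term_size_range = term_size_range, n_disease_terms = n_disease_terms,
    disease_multiplier = disease_multiplier,
    region_jitter_sd = region_jitter_sd, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

config_abort <- function(field, msg) {
  rlang::abort(sprintf("invalid simulation config: `%s` %s", field, msg),
               class = "methgain_config_error", field = field)
}

validate_sim_config <- function(cfg) {
  count_fields <- c("n_genes", "regions_per_gene_max", "n_control",
                    "n_tumour", "n_batches", "n_terms", "n_disease_terms")
  for (f in count_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 ||
        v != floor(v)) {
      config_abort(f, "must be an integer >= 1")
    }
  }
  for (f in c("rho_high", "rho_low", "frac_dm", "frac_de_only")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      config_abort(f, "must be a probability in [0, 1]")
    }
  }
  if (cfg$rho_low > cfg$rho_high) {
    config_abort("rho_low", "must not exceed rho_high")
  }
  if (!is.numeric(cfg$tau_star) || cfg$tau_star <= 0 || cfg$tau_star >= 1) {
    config_abort("tau_star", "must lie strictly inside (0, 1)")
  }
  dbr <- cfg$delta_beta_range
  if (length(dbr) != 2 || any(dbr < 0) || any(dbr > 1) || dbr[1] > dbr[2]) {
    config_abort("delta_beta_range", "must be an increasing pair in [0, 1]")
  }
  for (f in c("beta_precision", "nb_dispersion", "logfc_magnitude")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      config_abort(f, "must be a positive number")
    }
  }
  lsr <- cfg$lib_size_range
  if (length(lsr) != 2 || any(lsr <= 0) || lsr[1] > lsr[2]) {
    config_abort("lib_size_range", "must be an increasing positive pair")
  }
  if (cfg$region_jitter_sd < 0) {
    config_abort("region_jitter_sd", "must be non-negative")
  }
  invisible(cfg)
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' @noRd
#' Toy GMT-style collection: n_terms terms drawing members from the gene
#' universe; the first n_disease_terms are the planted "disease" terms.
sim_terms <- function(cfg, genes) {
  sizes <- sample(seq(cfg$term_size_range[1], cfg$term_size_range[2]),
                  cfg$n_terms, replace = TRUE)
  terms <- purrr::map(sizes, ~ sort(sample(genes, .x)))
  names(terms) <- sprintf("TERM%03d", seq_len(cfg$n_terms))
  terms
}

#' @noRd
#' Draws the shared design: planted effects, region map, region base means,
#' baseline expression. Shared across batches of one multi-batch study.
sim_design <- function(cfg) {
  genes <- gene_ids(cfg$n_genes)
  terms <- sim_terms(cfg, genes)
  disease_terms <- names(terms)[seq_len(cfg$n_disease_terms)]
  disease_genes <- unique(unlist(terms[disease_terms]))
  in_disease <- genes %in% disease_genes

  # base DM probability solved so the overall DM fraction matches frac_dm
  # while disease-term genes receive effects disease_multiplier times as
  # often; when the disease rate caps at 1 the base rate is re-solved so
  # the overall fraction is preserved
  m <- sum(in_disease)
  p0 <- cfg$frac_dm * cfg$n_genes /
    (cfg$n_genes + (cfg$disease_multiplier - 1) * m)
  p_dis <- min(cfg$disease_multiplier * p0, 1)
  p_base <- if (m < cfg$n_genes) {
    min(max((cfg$frac_dm * cfg$n_genes - m * p_dis) / (cfg$n_genes - m), 0),
        1)
  } else {
    p_dis
  }
  p_dm <- ifelse(in_disease, p_dis, p_base)
  dm <- stats::runif(cfg$n_genes) < p_dm

  db_mag <- ifelse(dm, stats::runif(cfg$n_genes, cfg$delta_beta_range[1],
                                    cfg$delta_beta_range[2]), 0)
  db_sign <- ifelse(stats::runif(cfg$n_genes) < 0.5, -1, 1)
  delta_beta_true <- db_mag * db_sign

  rho <- ifelse(db_mag > cfg$tau_star, cfg$rho_high, cfg$rho_low)
  u <- stats::runif(cfg$n_genes)
  coupling <- ifelse(!dm, "none", ifelse(u < rho, "inverse", "positive"))

  lfc_true <- numeric(cfg$n_genes)
  lfc_true[coupling == "inverse"] <-
    -sign(delta_beta_true[coupling == "inverse"]) * cfg$logfc_magnitude
  lfc_true[coupling == "positive"] <-
    sign(delta_beta_true[coupling == "positive"]) * cfg$logfc_magnitude

  # expression-only background effects on a slice of the unmethylated genes
  de_only <- !dm & stats::runif(cfg$n_genes) < cfg$frac_de_only
  lfc_true[de_only] <- cfg$logfc_magnitude *
    ifelse(stats::runif(sum(de_only)) < 0.5, -1, 1)

  truth <- tibble::tibble(
    gene = genes,
    delta_beta_true = delta_beta_true,
    log_fc_true = lfc_true,
    dm = dm,
    de_only = de_only,
    coupling = coupling,
    above_tau_star = db_mag > cfg$tau_star,
    in_disease_term = in_disease
  )

  n_regions_per_gene <- sample(cfg$regions_per_gene_max, cfg$n_genes,
                               replace = TRUE)
  region_gene <- rep(genes, times = n_regions_per_gene)
  n_reg <- length(region_gene)
  region_id <- sprintf("r%06d", seq_len(n_reg))
  d_reg <- rep(delta_beta_true, times = n_regions_per_gene)
  jitter_on <- rep(dm, times = n_regions_per_gene)
  d_reg <- d_reg + ifelse(jitter_on,
                          stats::rnorm(n_reg, 0, cfg$region_jitter_sd), 0)
  d_reg <- pmax(pmin(d_reg, 0.9), -0.9)
  # base (control) mean placed so both group means stay inside (0.05, 0.95)
  lo <- 0.05 + pmax(-d_reg, 0)
  hi <- 0.95 - pmax(d_reg, 0)
  m0 <- lo + stats::runif(n_reg) * (hi - lo)

  # baseline relative expression, log-normal across genes
  rel_expr <- stats::rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1)
  rel_expr <- rel_expr / sum(rel_expr)

  list(
    cfg = cfg, genes = genes, terms = terms, disease_terms = disease_terms,
    truth = truth,
    region_map = tibble::tibble(region_id = region_id, gene = region_gene),
    region_delta = d_reg, region_base_mean = m0, rel_expr = rel_expr
  )
}

#' @noRd
#' One batch worth of noisy matrices from a shared design.
sim_batch <- function(design, batch) {
  cfg <- design$cfg
  n_c <- cfg$n_control
  n_t <- cfg$n_tumour
  samples <- c(sprintf("b%d_C%02d", batch, seq_len(n_c)),
               sprintf("b%d_T%02d", batch, seq_len(n_t)))
  group <- c(rep("control", n_c), rep("tumour", n_t))

  n_reg <- nrow(design$region_map)
  mu <- cbind(matrix(design$region_base_mean, n_reg, n_c),
              matrix(design$region_base_mean + design$region_delta, n_reg, n_t))
  mu <- pmin(pmax(mu, 1e-3), 1 - 1e-3)
  phi <- cfg$beta_precision
  beta <- matrix(stats::rbeta(length(mu), mu * phi, (1 - mu) * phi),
                 nrow = n_reg,
                 dimnames = list(design$region_map$region_id, samples))

  lib <- stats::runif(n_c + n_t, cfg$lib_size_range[1], cfg$lib_size_range[2])
  fold <- ifelse(group == "tumour", 1, 0)
  mu_counts <- outer(design$rel_expr, lib) *
    2^(outer(design$truth$log_fc_true, fold))
  counts <- matrix(stats::rnbinom(length(mu_counts), mu = mu_counts,
                                  size = 1 / cfg$nb_dispersion),
                   nrow = cfg$n_genes,
                   dimnames = list(design$genes, samples))

  list(beta = beta, counts = counts,
       samples = tibble::tibble(sample = samples, group = group,
                                batch = sprintf("batch%d", batch)))
}

as_sim_study <- function(design, batches) {
  study <- list(
    beta = do.call(cbind, purrr::map(batches, "beta")),
    counts = do.call(cbind, purrr::map(batches, "counts")),
    region_map = design$region_map,
    samples = dplyr::bind_rows(purrr::map(batches, "samples")),
    truth = design$truth,
    terms = design$terms,
    disease_terms = design$disease_terms,
    config = design$cfg
  )
  class(study) <- "sim_study"
  study
}

#' Simulate one paired methylation/expression study
#'
#' Draws a single-batch study (beta-value matrix over regions, count matrix
#' over genes, labels, region-to-gene map, per-gene truth table, toy term
#' collection) under the planted-coupling model described in
#' [simulation_config()]. Deterministic for a fixed `seed`.
#'
#' @param config a [simulation_config()].
#' @return an object of class `sim_study`: list with elements `beta`,
#'   `counts`, `region_map`, `samples`, `truth`, `terms`, `disease_terms`,
#'   `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    design <- sim_design(config)
    as_sim_study(design, list(sim_batch(design, 1L)))
  })
}

#' Simulate a multi-batch study sharing one truth table
#'
#' All batches share the planted effects (the design) but draw independent
#' measurement noise, mirroring two experimental batches of one cohort. A
#' pooled study is the column-concatenation of the batches (see
#' [pool_studies()]).
#'
#' @inheritParams simulate_study
#' @return a named list of `sim_study` objects (`batch1`, `batch2`, ...).
#' @export
simulate_multi_batch <- function(config = simulation_config()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    design <- sim_design(config)
    studies <- purrr::map(seq_len(config$n_batches), function(b) {
      as_sim_study(design, list(sim_batch(design, b)))
    })
    names(studies) <- sprintf("batch%d", seq_len(config$n_batches))
    studies
  })
}

#' Pool studies that share a design by column-concatenation
#'
#' @param studies list of `sim_study` objects from [simulate_multi_batch()].
#' @return a single pooled `sim_study`.
#' @export
pool_studies <- function(studies) {
  stopifnot(length(studies) >= 1)
  pooled <- studies[[1]]
  if (length(studies) > 1) {
    pooled$beta <- do.call(cbind, purrr::map(studies, "beta"))
    pooled$counts <- do.call(cbind, purrr::map(studies, "counts"))
    pooled$samples <- dplyr::bind_rows(purrr::map(studies, "samples"))
  }
  pooled
}

#' Write a simulated study to plain-text files
#'
#' Emits `beta.tsv`, `counts.tsv` (feature id in the first column, sample
#' ids as header), `region_map.tsv`, `samples.tsv`, `truth.tsv`,
#' `terms.gmt` and `config.yaml` under `dir`.
#'
#' @param study a `sim_study`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(study$beta, file.path(dir, "beta.tsv"), "region_id")
  write_matrix_tsv(study$counts, file.path(dir, "counts.tsv"), "gene")
  readr::write_tsv(study$region_map, file.path(dir, "region_map.tsv"))
  readr::write_tsv(study$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(study$truth, file.path(dir, "truth.tsv"))
  write_gmt(study$terms, file.path(dir, "terms.gmt"))
  cfg <- study$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
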