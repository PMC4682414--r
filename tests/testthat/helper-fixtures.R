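# Small shared fixtures, all generated in code.

tiny_config <- function(...) {
  simulation_config(n_genes = 300, n_control = 8, n_tumour = 8,
                    n_terms = 20, term_size_range = c(5, 15),
                    n_disease_terms = 3, seed = 101L, ...)
}

# hand-buildable integrated gene table
toy_integrated <- function(n = 8, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    gene = sprintf("g%02d", seq_len(n)),
    meth_fdr = runif(n),
    expr_fdr = runif(n),
    combined_fdr = runif(n),
    delta_beta = runif(n, -0.6, 0.6),
    log_fc = runif(n, -2, 2),
    correlation_class = classify_correlation(delta_beta, log_fc)))
}

# random integrated table with realistic field ranges for property tests
random_integrated <- function(n = 60, seed = 1) {
  withr::with_seed(seed, {
    db <- runif(n, -0.6, 0.6) * rbinom(n, 1, 0.8)
    lfc <- runif(n, -3, 3) * rbinom(n, 1, 0.8)
    tibble::tibble(
      gene = sprintf("g%03d", seq_len(n)),
      meth_fdr = runif(n)^2,
      expr_fdr = runif(n)^2,
      combined_fdr = runif(n)^2,
      delta_beta = db,
      log_fc = lfc,
      correlation_class = classify_correlation(db, lfc))
  })
}

# independent brute-force BH step-up (sort desc, cumulative min), used as
# the oracle against bh_adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(cummin(p[o] * n / (n:1)), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# exact hypergeometric upper tail by direct enumeration over choose()
hyper_tail_oracle <- function(k, term, universe, query) {
  kk <- k:min(term, query)
  sum(choose(term, kk) * choose(universe - term, query - kk)) /
    choose(universe, query)
}

# brute-force gain computation by explicit per-record enumeration
gain_oracle <- function(records, tau) {
  above <- which(abs(records$delta_beta) > tau)
  below <- setdiff(seq_len(nrow(records)), above)
  ratio <- function(idx) {
    if (length(idx) == 0) return(NA_real_)
    mean(records$correlation_class[idx] == "inverse")
  }
  ratio(above) - ratio(below)
}
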