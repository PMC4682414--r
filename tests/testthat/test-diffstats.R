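test_that("BH adjustment matches hand-derived values and bounds", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  withr::with_seed(11, {
    for (i in 1:20) {
      p <- runif(sample(1:50, 1))
      q <- bh_adjust(p)
      expect_true(all(q >= p & q <= 1))
    }
  })
})

test_that("BH agrees with an independent step-up oracle on random vectors", {
  withr::with_seed(42, {
    for (i in 1:1000) {
      p <- runif(sample(1:40, 1))^sample(1:3, 1)
      p <- pmin(pmax(p, 1e-12), 1)
      expect_equal(bh_adjust(p), bh_oracle(p))
    }
  })
})

test_that("BH rejects p-values outside (0, 1] naming the index", {
  expect_error(bh_adjust(c(0.2, 0, 0.5)), "index: 2",
               class = "methgain_value_error")
  expect_error(bh_adjust(c(0.2, 1.5)), "index: 2",
               class = "methgain_value_error")
})

test_that("null regions give near-zero delta-beta and roughly uniform p", {
  n <- 30
  withr::with_seed(2, {
    m0 <- runif(200, 0.3, 0.7)
    beta <- matrix(rbeta(200 * 2 * n, rep(m0, 2 * n) * 60,
                         (1 - rep(m0, 2 * n)) * 60), nrow = 200)
  })
  colnames(beta) <- c(sprintf("C%02d", 1:n), sprintf("T%02d", 1:n))
  rownames(beta) <- sprintf("r%03d", 1:200)
  map <- tibble::tibble(region_id = rownames(beta),
                        gene = rownames(beta))
  groups <- c(rep("control", n), rep("tumour", n))
  res <- differential_methylation(beta, groups, map)
  expect_lt(max(abs(res$delta_beta)), 0.15)
  expect_lt(abs(mean(res$p_value) - 0.5), 0.08)
  expect_gt(min(res$fdr), 0.05)
})

test_that("a planted methylation difference is detected and matches a permutation oracle", {
  n <- 15
  withr::with_seed(7, {
    ctrl <- rbeta(n, 0.2 * 80, 0.8 * 80)
    tum <- rbeta(n, 0.6 * 80, 0.4 * 80)
    # null filler regions so the FDR correction has a realistic pool
    filler <- matrix(rbeta(50 * 2 * n, 40, 40), nrow = 50)
  })
  beta <- rbind(c(ctrl, tum), filler)
  rownames(beta) <- sprintf("r%03d", seq_len(nrow(beta)))
  colnames(beta) <- c(sprintf("C%02d", 1:n), sprintf("T%02d", 1:n))
  map <- tibble::tibble(region_id = rownames(beta), gene = rownames(beta))
  groups <- c(rep("control", n), rep("tumour", n))
  res <- differential_methylation(beta, groups, map)
  expect_lt(abs(res$delta_beta[1] - 0.4), 0.08)
  expect_lt(res$fdr[1], 0.01)

  # permutation oracle on the planted region's M-values
  b <- pmin(pmax(beta[1, ], 1e-6), 1 - 1e-6)
  mv <- log2(b / (1 - b))
  obs <- abs(mean(mv[groups == "tumour"]) - mean(mv[groups == "control"]))
  withr::with_seed(8, {
    perm <- replicate(10000, {
      g <- sample(groups)
      abs(mean(mv[g == "tumour"]) - mean(mv[g == "control"]))
    })
  })
  p_perm <- (1 + sum(perm >= obs)) / 10001
  # both calls declare the region overwhelmingly significant
  expect_lt(p_perm, 5e-4)
  expect_lt(res$p_value[1], 5e-4)
})

test_that("row-wise Welch p-values match t.test and track a permutation oracle", {
  withr::with_seed(21, {
    for (i in 1:20) {
      n <- sample(8:15, 1)
      x <- matrix(rnorm(2 * n, rep(c(0, runif(1, 0, 1)), each = n),
                        runif(1, 0.5, 1.5)), nrow = 1)
      is_t <- c(rep(FALSE, n), rep(TRUE, n))
      p_pkg <- methgain:::row_welch_p(x, is_t)
      p_ref <- stats::t.test(x[1, is_t], x[1, !is_t])$p.value
      expect_equal(p_pkg, p_ref, tolerance = 1e-10)
    }
  })
  # permutation cross-check on a subset (Welch is approximate; agreement
  # within Monte-Carlo + small-sample error)
  withr::with_seed(22, {
    for (i in 1:10) {
      n <- 12
      x <- matrix(c(rnorm(n), rnorm(n, runif(1, 0, 0.8))), nrow = 1)
      is_t <- c(rep(FALSE, n), rep(TRUE, n))
      p_pkg <- methgain:::row_welch_p(x, is_t)
      obs <- abs(mean(x[1, is_t]) - mean(x[1, !is_t]))
      perm <- replicate(4000, {
        g <- sample(is_t)
        abs(mean(x[1, g]) - mean(x[1, !g]))
      })
      p_perm <- (1 + sum(perm >= obs)) / 4001
      mc_err <- 3 * sqrt(max(p_perm * (1 - p_perm), 2.5e-5) / 4000)
      expect_lt(abs(p_pkg - p_perm), 0.04 + mc_err)
    }
  })
})

test_that("constant regions get the degenerate p = 1, never NaN", {
  beta <- matrix(0.5, nrow = 2, ncol = 8,
                 dimnames = list(c("r1", "r2"),
                                 c(sprintf("C%d", 1:4),
                                   sprintf("T%d", 1:4))))
  map <- tibble::tibble(region_id = c("r1", "r2"), gene = c("g1", "g2"))
  groups <- rep(c("control", "tumour"), each = 4)
  res <- differential_methylation(beta, groups, map)
  expect_equal(res$p_value, c(1, 1))
  expect_false(anyNA(res))
})

test_that("differential methylation validates its inputs", {
  beta <- matrix(0.5, 2, 3, dimnames = list(c("r1", "r2"),
                                            c("a", "b", "c")))
  map <- tibble::tibble(region_id = c("r1", "r2"), gene = c("g1", "g2"))
  expect_error(
    differential_methylation(beta, c("control", "control", "tumour"), map),
    "at least 2", class = "methgain_input_error")
  beta4 <- cbind(beta, d = c(2, 0.5))
  expect_error(
    differential_methylation(beta4,
                             c("control", "control", "tumour", "tumour"),
                             map),
    "0, 1", class = "methgain_input_error")
})

test_that("differential expression recovers a planted two-fold change", {
  n <- 15
  n_genes <- 400
  withr::with_seed(9, {
    base <- rlnorm(n_genes, 5, 1)
    mu <- outer(base, rep(1, 2 * n))
    mu[1, (n + 1):(2 * n)] <- mu[1, (n + 1):(2 * n)] * 2
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 10),
                     nrow = n_genes)
  })
  rownames(counts) <- sprintf("g%04d", seq_len(n_genes))
  colnames(counts) <- c(sprintf("C%02d", 1:n), sprintf("T%02d", 1:n))
  groups <- c(rep("control", n), rep("tumour", n))
  res <- differential_expression(counts, groups)
  expect_lt(abs(res$log_fc[1] - 1), 0.2)
  expect_lt(res$fdr[1], 0.01)
  # null genes: log_fc near zero on average
  expect_lt(abs(mean(res$log_fc[-1])), 0.05)
})

test_that("expression stand-in agrees with a count-model engine on effects", {
  n <- 12
  n_genes <- 300
  withr::with_seed(31, {
    base <- rlnorm(n_genes, 5, 1)
    mu <- outer(base, rep(1, 2 * n))
    mu[1:5, (n + 1):(2 * n)] <- mu[1:5, (n + 1):(2 * n)] *
      rep(c(2, 2, 4, 0.5, 0.25), n)
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 8),
                     nrow = n_genes,
                     dimnames = list(sprintf("g%03d", 1:n_genes),
                                     c(sprintf("C%02d", 1:n),
                                       sprintf("T%02d", 1:n))))
  })
  groups <- c(rep("control", n), rep("tumour", n))
  ours <- differential_expression(counts, groups)

  y <- edgeR::DGEList(counts = counts, group = factor(groups))
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y)
  ref <- edgeR::exactTest(y, pair = c("control", "tumour"))$table

  # same effect-size estimates (within shrinkage/pseudocount differences)
  expect_lt(max(abs(ours$log_fc[1:5] - ref$logFC[1:5])), 0.35)
  expect_gt(cor(ours$log_fc, ref$logFC), 0.95)
  # both engines call the planted genes significant
  expect_true(all(ours$fdr[1:5] < 0.05))
  expect_true(all(p.adjust(ref$PValue, "BH")[1:5] < 0.05))
})

test_that("differential expression degenerate and error rules", {
  counts <- matrix(c(0, 0, 0, 0,
                     5, 6, 7, 8), nrow = 2, byrow = TRUE,
                   dimnames = list(c("gz", "g1"),
                                   c("C1", "C2", "T1", "T2")))
  groups <- c("control", "control", "tumour", "tumour")
  res <- differential_expression(counts, groups)
  expect_equal(res$log_fc[res$gene == "gz"], 0)
  expect_equal(res$p_value[res$gene == "gz"], 1)

  bad <- counts
  bad[, "C1"] <- 0
  expect_error(differential_expression(bad, groups), "C1",
               class = "methgain_input_error")
})

test_that("collapse keeps the most significant region with deterministic ties", {
  rec <- tibble::tibble(
    region_id = c("r1", "r2", "r3", "r4", "r5"),
    gene = c("g1", "g1", "g2", "g3", "g3"),
    delta_beta = c(0.2, -0.5, 0.1, 0.3, -0.3),
    p_value = c(0.01, 0.0005, 0.2, 0.05, 0.05),
    fdr = c(0.02, 0.001, 0.5, 0.1, 0.1))
  out <- collapse_regions_to_genes(rec)
  expect_equal(nrow(out), 3)
  expect_equal(out$best_region[out$gene == "g1"], "r2")
  expect_equal(out$best_region[out$gene == "g2"], "r3")
  # g3: tied fdr, tied |delta_beta| -> lexicographically smallest region
  expect_equal(out$best_region[out$gene == "g3"], "r4")

  # single record passes through
  one <- collapse_regions_to_genes(rec[1, ])
  expect_equal(one$best_region, "r1")

  # idempotent and order-independent
  shuffled <- rec[c(4, 2, 5, 1, 3), ]
  expect_equal(collapse_regions_to_genes(shuffled), out)
  again <- out |>
    dplyr::rename(region_id = best_region) |>
    collapse_regions_to_genes()
  expect_equal(again, out)
})

test_that("collapse emits exactly one row per gene on a large synthetic table", {
  s <- simulate_study(tiny_config())
  meth <- differential_methylation(s$beta, s$samples, s$region_map)
  out <- collapse_regions_to_genes(meth)
  expect_equal(nrow(out), length(unique(s$region_map$gene)))
  expect_false(anyDuplicated(out$gene) > 0)
})

test_that("expression-universe restriction drops and reports missing genes", {
  meth <- tibble::tibble(gene = c("A", "B", "PLEC1"), fdr = c(0.1, 0.2, 0.3))
  res <- restrict_to_expression_universe(meth, c("A", "B"))
  expect_equal(res$kept$gene, c("A", "B"))
  expect_equal(res$dropped, "PLEC1")

  disjoint <- restrict_to_expression_universe(meth, c("X", "Y"))
  expect_equal(nrow(disjoint$kept), 0)
  expect_setequal(disjoint$dropped, meth$gene)

  subset_case <- restrict_to_expression_universe(meth,
                                                 c("A", "B", "PLEC1", "Z"))
  expect_equal(subset_case$kept, meth)
  expect_length(subset_case$dropped, 0)
})
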