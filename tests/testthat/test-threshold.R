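test_that("correlation classification follows the sign rule", {
  expect_equal(classify_correlation(0.20, -1.3), "inverse")
  expect_equal(classify_correlation(-0.20, 0.8), "inverse")
  expect_equal(classify_correlation(0.20, 0.8), "positive")
  expect_equal(classify_correlation(-0.20, -0.8), "positive")
  expect_equal(classify_correlation(0, 1.2), "undefined")
  expect_equal(classify_correlation(0.3, 0), "undefined")
  expect_equal(classify_correlation(NA, 1), "undefined")
  # vectorised
  expect_equal(classify_correlation(c(0.1, -0.1, 0), c(-1, -1, -1)),
               c("inverse", "positive", "undefined"))
})

test_that("threshold grid validates its limits", {
  expect_equal(threshold_grid(), seq(0.05, 0.5, 0.05))
  expect_equal(threshold_grid(0.1, 0.3, 0.1), c(0.1, 0.2, 0.3))
  expect_error(threshold_grid(0, 0.5), class = "methgain_value_error")
  expect_error(threshold_grid(0.5, 0.1), class = "methgain_value_error")
})

test_that("eligibility requires both significances and a defined class", {
  rec <- tibble::tibble(
    gene = sprintf("g%d", 1:4),
    meth_fdr = c(0.05, 0.05, 0.2, 0.01),
    expr_fdr = c(0.2, 0.01, 0.01, 0.02),
    delta_beta = c(0.3, 0.3, 0.3, 0),
    log_fc = c(1, -1, -1, -1),
    correlation_class = classify_correlation(c(0.3, 0.3, 0.3, 0),
                                             c(1, -1, -1, -1)))
  out <- eligible_records(rec)
  expect_equal(out$gene, "g2")  # g1: expr too weak; g3: meth; g4: undefined
  expect_equal(eligible_records(rec[2, ]), rec[2, ])
  expect_equal(nrow(eligible_records(rec[0, ])), 0)
  expect_error(eligible_records(rec, fdr_cut = 0),
               class = "methgain_value_error")
})

toy_records <- function() {
  # 10 records, 4 above tau = 0.15 of which 3 inverse; 6 below, 2 inverse
  tibble::tibble(
    gene = sprintf("g%02d", 1:10),
    meth_fdr = 0.01, expr_fdr = 0.01,
    delta_beta = c(0.3, -0.4, 0.2, 0.25, 0.1, -0.05, 0.12, 0.08, 0.14,
                   -0.1),
    log_fc = c(-1, 1, -2, 1.5, -1, -1, 1, 1, 2, 1),
    correlation_class = c("inverse", "inverse", "inverse", "positive",
                          "inverse", "positive", "positive", "positive",
                          "positive", "inverse"))
}

test_that("gain curve matches the hand-enumerated toy example", {
  cur <- gain_curve(toy_records(), grid = 0.15, min_side = 1)
  expect_equal(cur$n_above, 4L)
  expect_equal(cur$n_below, 6L)
  expect_equal(cur$ratio_above, 0.75)
  expect_equal(cur$ratio_below, 1 / 3)
  expect_equal(cur$gain, 0.75 - 1 / 3)
})

test_that("gain curve agrees exactly with brute-force enumeration on a 12-record table", {
  withr::with_seed(13, {
    rec <- tibble::tibble(
      gene = sprintf("g%02d", 1:12),
      meth_fdr = 0.01, expr_fdr = 0.01,
      delta_beta = round(runif(12, -0.55, 0.55), 3),
      log_fc = round(runif(12, -2, 2), 2))
    rec$correlation_class <- classify_correlation(rec$delta_beta,
                                                  rec$log_fc)
    rec <- rec[rec$correlation_class != "undefined", ]
  })
  grid <- threshold_grid()
  cur <- gain_curve(rec, grid = grid, min_side = 1)
  for (i in seq_along(grid)) {
    expect_identical(cur$gain[i], gain_oracle(rec, grid[i]))
    expect_identical(cur$n_above[i] + cur$n_below[i], nrow(rec))
  }
})

test_that("degenerate gain-curve cases", {
  rec <- toy_records()
  rec$correlation_class <- "inverse"
  cur <- gain_curve(rec, grid = c(0.15, 0.2), min_side = 1)
  expect_equal(cur$gain, c(0, 0))  # both ratios are 1 everywhere

  # every |delta beta| above the grid maximum: below side always empty
  rec2 <- toy_records()
  rec2$delta_beta <- rec2$delta_beta + sign(rec2$delta_beta) * 0.6
  cur2 <- gain_curve(rec2, grid = threshold_grid())
  expect_true(all(!cur2$valid))
  expect_true(all(cur2$n_below < 10))

  expect_error(gain_curve(toy_records()[0, ]),
               class = "methgain_input_error")
})

test_that("side counts are conserved and n_above is monotone in tau", {
  s <- simulate_study(tiny_config())
  ds <- integrate_study(s, 0.1)
  cur <- gain_curve(ds$eligible, dataset_id = "t")
  expect_true(all(cur$n_above + cur$n_below == nrow(ds$eligible)))
  expect_true(all(diff(cur$n_above) <= 0))
})

test_that("threshold selection pools gains additively with deterministic ties", {
  mk <- function(id, gains, valid = TRUE) {
    tibble::tibble(dataset_id = id, tau = c(0.1, 0.2, 0.3),
                   n_above = 50, n_below = 50,
                   ratio_above = 0.5, ratio_below = 0.5,
                   gain = gains, valid = valid)
  }
  sel <- select_threshold(list(mk("a", c(0.1, 0.3, 0.2)),
                               mk("b", c(0.2, 0.2, 0.1))))
  expect_equal(sel$pooled$pooled_gain, c(0.3, 0.5, 0.3))
  expect_equal(sel$tau_opt, 0.2)

  # single curve: its own argmax
  sel1 <- select_threshold(mk("a", c(0.1, 0.3, 0.2)))
  expect_equal(sel1$tau_opt, 0.2)

  # ties go to the smallest tau
  sel2 <- select_threshold(mk("a", c(0.3, 0.3, 0.1)))
  expect_equal(sel2$tau_opt, 0.1)

  # thresholds invalid in any curve cannot win
  sel3 <- select_threshold(list(mk("a", c(0.1, 0.9, 0.2),
                                   valid = c(TRUE, FALSE, TRUE)),
                                mk("b", c(0.2, 0.9, 0.1))))
  expect_equal(sel3$tau_opt, 0.1)

  expect_error(select_threshold(mk("a", c(0.1, 0.2, 0.3), valid = FALSE)),
               class = "methgain_analysis_error")
  expect_error(select_threshold(list(mk("a", c(0.1, 0.2, 0.3)),
                                     mk("b", c(0.1, 0.2, 0.3))[1:2, ])),
               class = "methgain_input_error")

  # tidy/glance accessors expose the pooled curve and the optimum
  expect_equal(tidy(sel)$pooled_gain, c(0.3, 0.5, 0.3))
  expect_equal(glance(sel)$tau_opt, 0.2)
  expect_equal(glance(sel)$n_datasets, 2)
})

test_that("ratio maximiser reports the per-dataset argmax of ratio_above", {
  mk <- function(id, ratios) {
    tibble::tibble(dataset_id = id, tau = c(0.1, 0.2, 0.3),
                   n_above = 50, n_below = 50,
                   ratio_above = ratios, ratio_below = 0.4,
                   gain = ratios - 0.4, valid = TRUE)
  }
  out <- ratio_maximiser(list(mk("a", c(0.5, 0.69, 0.6)),
                              mk("b", c(0.4, 0.5, 0.6))))
  expect_equal(out$tau_ratio_max[out$dataset_id == "a"], 0.2)
  # monotone increasing ratio: last tau wins
  expect_equal(out$tau_ratio_max[out$dataset_id == "b"], 0.3)
})

test_that("the raw-ratio optimum sits at or above the gain optimum", {
  # the above-side inverse ratio keeps rising past the coupling
  # change-point, so its argmax should rarely fall below the gain argmax
  hits <- 0
  for (s in 1:20) {
    cfg <- simulation_config(n_genes = 3000, tau_star = 0.15,
                             rho_high = 0.7, rho_low = 0.4, seed = 300 + s)
    out <- threshold_selection_for(cfg)
    tau_gain <- out$selection$tau_opt
    tau_ratio <- out$ratio_max$tau_ratio_max[
      out$ratio_max$dataset_id == "pooled"]
    hits <- hits + (tau_ratio >= tau_gain - 1e-9)
  }
  expect_gte(hits, 16)
})

test_that("curve and selection plots build without error", {
  s <- simulate_study(tiny_config())
  ds <- integrate_study(s, 0.1)
  cur <- gain_curve(ds$eligible, dataset_id = "t", min_side = 3)
  expect_s3_class(ggplot2::autoplot(cur, type = "ratio"), "ggplot")
  expect_s3_class(ggplot2::autoplot(cur, type = "gain"), "ggplot")
  sel <- select_threshold(cur)
  expect_s3_class(ggplot2::autoplot(sel), "ggplot")
})
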