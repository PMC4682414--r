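# methgain

Integration of paired DNA-methylation and gene-expression differential
results, for analysts who have a region-level methylation table (or
beta-value matrix) and a gene-level expression table (or count matrix)
from the same two-group cohort and want to answer two questions:

1. **Which genes are jointly significant?** Per gene, the two
   significances are merged by the weighted Z-method,
   `Z_w = Σ w_i Φ⁻¹(1 − p_i) / √(Σ w_i²)` with `w_i = √n_i` (square root
   of each modality's sample size), then re-adjusted by
   Benjamini–Hochberg across genes.
2. **Is there a methylation-change magnitude worth thresholding on?**
   For every candidate threshold τ in a grid (0.05–0.50), the eligible
   records (both FDRs < 0.1, defined correlation) split into
   `|Δβ| > τ` and the rest; the *gain* is the inversely correlated
   fraction above minus below. Gains are summed across datasets (each
   batch and the pooled samples) and the τ with the highest overall gain
   is selected.

On top of the integrated table the package evaluates ten declarative
gene-selection strategies (expression-only, methylation-only, combined
significance, Δβ thresholds, correlation filters — `model_specs()`),
ranks each strategy's genes against a GMT term collection by
hypergeometric over-representation, and scores strategies by how many
reference pathway terms appear in the top-20 ranking, including a
batch-combined meta-analysis column.

A synthetic-study generator with planted ground truth (a known coupling
threshold `tau_star`, known inverse-response probabilities, known disease
terms) makes the whole pipeline testable end to end without any
downloads; it is first-class, documented code (`simulation_config()`).

## A worked example

```r
library(methgain)

cfg <- simulation_config(n_genes = 1000, seed = 7)   # planted tau* = 0.15
res <- run_pipeline(run_config(sim = cfg))
res$selection
#> Threshold selection over 3 dataset(s)
#>   optimal tau: 0.15 (pooled gain 0.7781)

res$ratio_max
#> # A tibble: 3 × 3
#>   dataset_id tau_ratio_max ratio_above
#>   <chr>              <dbl>       <dbl>
#> 1 batch1              0.35       0.811
#> 2 batch2              0.35       0.817
#> 3 pooled              0.35       0.821

tidy(res$report) |> head(4)
#> # A tibble: 4 × 5
#>   dataset model_id n_detected     k n_reference
#>   <chr>   <chr>         <int> <dbl>       <int>
#> 1 batch1  M1                5    20           5
#> 2 batch1  M2                5    20           5
#> 3 batch1  M3                5    20           5
#> 4 batch1  M4                5    20           5
```

The threshold-gain analysis recovers the planted 0.15 from the noisy
matrices alone, while the per-dataset raw-ratio optimum sits higher
(0.35 in all three datasets) — the above-threshold inverse fraction
keeps creeping up with τ even though the *gain* peaks at the coupling
change-point. The
detection table counts how many of the five planted disease terms each
strategy places in its top-20 enrichment ranking. `autoplot()` methods
draw the ratio curves, gain curves and the detection heatmap;
`run_pipeline(..., out_dir = )` writes every table as a stamped TSV plus
a reproducibility manifest. A thin command-line wrapper ships at
`inst/cli/methgain-cli.R` (`simulate` and `run` subcommands).

See `vignette("methylation-expression-integration")` for the model, the
generator's assumptions, and every numerical design choice.

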