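# Shared machinery for the planted-threshold recovery studies: simulate a
# two-batch study, integrate each batch plus the pooled data, and return
# the threshold-gain selection across the three curves.

threshold_selection_for <- function(cfg) {
  studies <- simulate_multi_batch(cfg)
  datasets <- c(studies, list(pooled = pool_studies(studies)))
  curves <- purrr::imap(datasets, function(st, id) {
    gain_curve(integrate_study(st)$eligible, dataset_id = id)
  })
  list(selection = select_threshold(curves),
       ratio_max = ratio_maximiser(curves),
       curves = curves)
}

recover_tau <- function(tau_star, seed, n_genes = 5000) {
  cfg <- simulation_config(n_genes = n_genes, tau_star = tau_star,
                           rho_high = 0.7, rho_low = 0.4, seed = seed)
  threshold_selection_for(cfg)$selection$tau_opt
}
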