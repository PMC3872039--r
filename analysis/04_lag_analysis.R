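#!/usr/bin/env Rscript
# Lag-distribution analysis: how well the adaptive lag search localizes the
# true interaction lags, what the estimated-lag histogram over gold edges
# looks like, and how hidden co-regulation (two genes fed by one unobserved
# driver at equal lag) creates the characteristic mass at lag zero.
# Writes results/lag_hist_planted.tsv and results/lag_hist_coregulation.tsv.

library(lagnet)

seed <- 20260923
dir.create("results", showWarnings = FALSE)

# recovery rate of a planted 2-step lag over 200 high-signal replicates
hits <- 0
for (k in 1:200) {
  d <- simulate_dataset(sim_config(p = 2, n_edges = 1, hub_fraction = 0,
                                   lag_support = 2, lag_probs = 1,
                                   coef_range = c(0.85, 0.95), n = 45,
                                   seed = seed + k))
  e <- d$gold$edges
  bl <- best_lag(d$series, e$source[1], e$target[1], 6)
  hits <- hits + (abs(bl$lag - 2) <= 1)
}
cat("lag recovery within +/-1 step:", hits / 200, "\n")

# histogram over gold edges, planted lag = 4 steps
h_sum <- NULL
for (k in 1:25) {
  d <- simulate_dataset(sim_config(p = 4, n_edges = 3, hub_fraction = 0,
                                   lag_support = 4, lag_probs = 1,
                                   coef_range = c(0.85, 0.95), n = 45,
                                   seed = seed + 300 + k))
  h <- lag_distribution(lagged_mi_matrix(d$series, 6), d$gold, step = 30)
  h_sum <- if (is.null(h_sum)) h else transform(h_sum,
                                                count = count + h$count)
}
cat("\nestimated-lag histogram (planted lag 4 steps = 120 min):\n")
print(h_sum, row.names = FALSE)
write.table(h_sum, "results/lag_hist_planted.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# co-regulation scenario: presumed interactions between co-regulated genes
h0_sum <- NULL
for (k in 1:25) {
  cfg <- sim_config(p = 4, n_edges = 0, hub_fraction = 0, n_confounders = 2,
                    n = 45, seed = seed + 600 + k)
  sim <- simulate_expression(simulate_network(cfg), cfg)
  pairs <- unique(do.call(rbind, lapply(sim$confounder_pairs,
    function(pr) data.frame(source = pr[1], target = pr[2]))))
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  if (nrow(pairs) == 0) next
  gold <- gold_standard(pairs, sim$series$gene_ids)
  h <- lag_distribution(lagged_mi_matrix(sim$series, 6), gold, step = 30)
  h0_sum <- if (is.null(h0_sum)) h else transform(h0_sum,
                                                  count = count + h$count)
}
cat("\nestimated-lag histogram under hidden co-regulation:\n")
print(h0_sum, row.names = FALSE)
write.table(h0_sum, "results/lag_hist_coregulation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
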