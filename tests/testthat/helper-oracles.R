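# Independent reference implementations used as oracles. These deliberately
# re-derive quantities by brute force, staying independent of the package's
# code paths.

# AUPRC by full prefix enumeration: walk the ranking, record precision and
# recall at every prefix, then average the maximum precision achieving each
# of the P canonical recall levels (unreached levels contribute 0).
oracle_auprc <- function(labels, P) {
  N <- length(labels)
  best_at_level <- rep(0, P)
  tp <- 0
  for (k in seq_len(N)) {
    tp <- tp + labels[k]
    if (labels[k] == 1) {
      prec <- tp / k
      if (prec > best_at_level[tp]) best_at_level[tp] <- prec
    }
  }
  mean(best_at_level)
}

# expected AUPRC of a uniformly random ranking by enumerating every placement
# of the P positive labels among N slots
oracle_random_baseline_enum <- function(N, P) {
  placements <- utils::combn(N, P, simplify = FALSE)
  mean(vapply(placements, function(pos) {
    labels <- rep(0, N)
    labels[pos] <- 1
    oracle_auprc(labels, P)
  }, numeric(1)))
}

# exhaustive mRMR: evaluate u - r for every remaining candidate at each step
# directly from the definition
oracle_mrmr <- function(mi, target) {
  p <- nrow(mi)
  remaining <- setdiff(seq_len(p), target)
  selected <- integer(0)
  out <- rep(NA_real_, p)
  while (length(remaining) > 0) {
    scores <- vapply(remaining, function(j) {
      u <- mi[j, target]
      r <- if (length(selected) == 0) 0 else mean(mi[j, selected])
      u - r
    }, numeric(1))
    best <- remaining[which.max(scores)]
    out[best] <- max(scores)
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  out
}

# brute-force PC skeleton: an edge survives only if every conditioning subset
# of the remaining variables leaves its partial correlation significant
oracle_pc_skeleton <- function(vals, alpha) {
  p <- ncol(vals)
  n <- nrow(vals)
  r <- stats::cor(vals)
  adj <- matrix(TRUE, p, p)
  diag(adj) <- FALSE
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      rest <- setdiff(seq_len(p), c(i, j))
      for (sz in 0:length(rest)) {
        subsets <- if (sz == 0) list(integer(0))
                   else utils::combn(rest, sz, simplify = FALSE)
        for (S in subsets) {
          pc <- lagnet:::pcor_given(r, i, j, S)
          if (lagnet:::fisher_z_pvalue(pc, n - length(S) - 3) > alpha)
            adj[i, j] <- adj[j, i] <- FALSE
        }
      }
    }
  }
  adj
}

# small planted dataset helpers ---------------------------------------------

planted_pair <- function(seed, lag = 2, n = 45, coef = c(0.85, 0.95)) {
  simulate_dataset(sim_config(p = 2, n_edges = 1, hub_fraction = 0,
                              lag_support = lag, lag_probs = 1,
                              coef_range = coef, n = n, seed = seed))
}

fly_dataset <- function(seed, ...) {
  simulate_dataset(dataset_preset("fly", seed = seed, ...))
}
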