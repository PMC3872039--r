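#' Simulation configuration
#'
#' Bundles every knob of the synthetic regulatory-network generator. Defaults
#' describe a small, sparse network with lags of one to two sampling steps,
#' strong regulatory coefficients and moderate process noise -- the regime the
#' benchmarked microarray series are assumed to live in.
#'
#' @param p number of genes.
#' @param n_edges number of directed regulatory edges.
#' @param hub_fraction fraction of genes designated hubs (receive a
#'   disproportionate share of outgoing edges); 0 disables hub bias.
#' @param lag_support,lag_probs distribution of true interaction lags in
#'   steps (support >= 1 unless confounders supply lag-0 structure).
#' @param coef_range magnitude range of regulatory coefficients; signs are
#'   random.
#' @param noise_sd standard deviation of the driving process noise.
#' @param n number of time points on the observation grid.
#' @param step sampling interval in minutes.
#' @param grid one of `"uniform"`, `"fly"` (1 h spacing after ten ~30-min
#'   intervals, mirroring a long developmental series) or `"ecoli"`
#'   (alternating 10/50-min gaps); non-uniform grids exercise the linear
#'   resampling step.
#' @param n_confounders number of hidden co-regulation drivers, each feeding
#'   two observed genes at equal lag (their targets become lag-0 associated
#'   without a direct interaction).
#' @param spectral_radius stability bound for the lagged system (companion
#'   matrix spectral radius), default 0.95.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(p = 10, n_edges = 10, hub_fraction = 0.2,
                       lag_support = c(1, 2), lag_probs = c(0.7, 0.3),
                       coef_range = c(0.6, 0.9), noise_sd = 1.0,
                       n = 45, step = 30, grid = "uniform",
                       n_confounders = 0, spectral_radius = 0.95,
                       seed = 1) {
  stopifnot(p >= 2, n_edges <= p * (p - 1), noise_sd >= 0,
            all(lag_support >= 0), length(lag_support) == length(lag_probs),
            spectral_radius > 0, spectral_radius < 1)
  structure(list(p = p, n_edges = n_edges, hub_fraction = hub_fraction,
                 lag_support = as.integer(lag_support),
                 lag_probs = lag_probs / sum(lag_probs),
                 coef_range = coef_range, noise_sd = noise_sd,
                 n = n, step = step, grid = grid,
                 n_confounders = n_confounders,
                 spectral_radius = spectral_radius, seed = seed),
            class = "sim_config")
}

#' Preset configurations shaped like the three benchmark series
#'
#' `fly`: 45 points at 30 min (a 22 h developmental course), `ecoli`: 32
#' points at 10 min, `yeast`: 25 points at 5 min. Only the grid shape changes
#' between presets; network parameters keep the documented defaults.
#'
#' @param name `"fly"`, `"ecoli"` or `"yeast"`.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
dataset_preset <- function(name, ...) {
  shape <- switch(name,
                  fly = list(n = 45, step = 30),
                  ecoli = list(n = 32, step = 10),
                  yeast = list(n = 25, step = 5),
                  stop("unknown preset: ", name))
  args <- utils::modifyList(shape, list(...))
  do.call(sim_config, args)
}

#' Simulate a directed regulatory network
#'
#' Draws `n_edges` directed edges without self-loops or reciprocal pairs
#' (unless the requested density forces them). When `hub_fraction > 0`, a
#' designated hub set supplies edge sources with probability 0.7, giving hubs
#' a disproportionate out-degree. Each edge gets a coefficient of random sign
#' with magnitude uniform in `coef_range` and a lag drawn from the configured
#' lag distribution.
#'
#' @param config a `sim_config`.
#' @return list with `gold` (a `gold_standard` whose edges carry `lag` in
#'   steps), `coef` (p x p matrix, entry (j, i) = effect of j on i), `lags`
#'   (p x p integer matrix) and `hubs` (character).
#' @export
simulate_network <- function(config) {
  p <- config$p
  ids <- paste0("g", seq_len(p))
  with_seed(config$seed, {
    n_hubs <- round(config$hub_fraction * p)
    hubs <- if (n_hubs > 0) sample(ids, n_hubs) else character(0)
    all_pairs <- expand.grid(source = ids, target = ids,
                             stringsAsFactors = FALSE)
    all_pairs <- all_pairs[all_pairs$source != all_pairs$target, ]
    chosen <- character(0)
    edges <- data.frame(source = character(0), target = character(0))
    guard <- 0L
    allow_reciprocal <- config$n_edges > p * (p - 1) / 2
    while (nrow(edges) < config$n_edges) {
      guard <- guard + 1L
      if (guard > 1e5) stop("infeasible edge count")
      src <- if (length(hubs) > 0 && stats::runif(1) < 0.7)
        sample(hubs, 1) else sample(ids, 1)
      tgt <- sample(setdiff(ids, src), 1)
      key <- paste(src, tgt)
      rev_key <- paste(tgt, src)
      if (key %in% chosen) next
      if (!allow_reciprocal && rev_key %in% chosen) next
      chosen <- c(chosen, key)
      edges <- rbind(edges, data.frame(source = src, target = tgt,
                                       stringsAsFactors = FALSE))
    }
    lags <- config$lag_support[sample.int(length(config$lag_support),
                                          nrow(edges), replace = TRUE,
                                          prob = config$lag_probs)]
    mags <- stats::runif(nrow(edges), config$coef_range[1],
                         config$coef_range[2])
    signs <- sample(c(-1, 1), nrow(edges), replace = TRUE)
    coef <- matrix(0, p, p, dimnames = list(ids, ids))
    lagm <- matrix(0L, p, p, dimnames = list(ids, ids))
    for (e in seq_len(nrow(edges))) {
      coef[edges$source[e], edges$target[e]] <- mags[e] * signs[e]
      lagm[edges$source[e], edges$target[e]] <- lags[e]
    }
    edges$lag <- lags
    list(gold = gold_standard(edges, gene_ids = ids), coef = coef,
         lags = lagm, hubs = hubs)
  })
}

# spectral radius of the companion matrix of the lagged linear system
companion_radius <- function(coef, lags) {
  p <- nrow(coef)
  L <- max(lags, 1)
  comp <- matrix(0, p * L, p * L)
  for (l in seq_len(L)) {
    a_l <- matrix(0, p, p)
    sel <- lags == l
    a_l[sel] <- coef[sel]
    comp[1:p, ((l - 1) * p + 1):(l * p)] <- t(a_l)
  }
  if (L > 1) comp[(p + 1):(p * L), 1:(p * (L - 1))] <- diag(p * (L - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Simulate lagged linear expression dynamics
#'
#' Generates `x_i(t) = sum_edges beta_ji x_j(t - l_ji) + eps_i(t)` with
#' Gaussian process noise, after rescaling the coefficients so the companion
#' matrix spectral radius does not exceed `config$spectral_radius` (the
#' rescaled coefficients are returned). A burn-in of `10 * max lag` steps
#' (at least 20) is discarded. Hidden co-regulation confounders, when
#' requested, are extra unobserved noise processes each feeding two observed
#' genes at equal lag; the fed genes end up associated at lag 0 without any
#' gold edge between them. Non-uniform grid modes simulate on the fine step
#' and then take the nearest fine-step sample for each irregular time stamp,
#' returning an `expression_series` to be re-gridded with
#' [resample_uniform()].
#'
#' @param network output of [simulate_network()].
#' @param config the same `sim_config`.
#' @return list with `series` (a `uniform_series`, or an `expression_series`
#'   for non-uniform grids), `gold`, `coef` (as used, post-rescaling),
#'   `confounder_pairs` and `seed`.
#' @export
simulate_expression <- function(network, config) {
  p <- config$p
  ids <- network$gold$gene_ids
  coef <- network$coef
  lags <- network$lags
  rho <- companion_radius(coef, lags)
  if (rho > config$spectral_radius)
    coef <- coef * (config$spectral_radius / rho)
  L <- max(lags, 1)
  burn <- max(10 * L, 20)
  n_total <- burn + config$n
  edge_idx <- which(coef != 0, arr.ind = TRUE)

  with_seed(child_seed(config$seed, "expr"), {
    conf_pairs <- list()
    n_conf <- config$n_confounders
    conf_targets <- matrix(0L, 0, 2)
    conf_lag <- integer(0)
    if (n_conf > 0) {
      for (c_i in seq_len(n_conf)) {
        pair <- sample(p, 2)
        conf_targets <- rbind(conf_targets, pair)
        conf_lag <- c(conf_lag,
                      config$lag_support[sample.int(length(config$lag_support),
                                                    1,
                                                    prob = config$lag_probs)])
        conf_pairs[[c_i]] <- ids[pair]
      }
    }
    x <- matrix(0, n_total, p)
    z <- if (n_conf > 0) matrix(stats::rnorm(n_total * n_conf), n_total)
         else NULL
    eps <- matrix(stats::rnorm(n_total * p, sd = max(config$noise_sd, 1e-8)),
                  n_total, p)
    for (t in (L + 1):n_total) {
      xt <- eps[t, ]
      if (nrow(edge_idx) > 0) {
        for (e in seq_len(nrow(edge_idx))) {
          j <- edge_idx[e, 1]; i <- edge_idx[e, 2]
          xt[i] <- xt[i] + coef[j, i] * x[t - lags[j, i], j]
        }
      }
      if (n_conf > 0) {
        for (c_i in seq_len(n_conf)) {
          l <- conf_lag[c_i]
          if (t - l >= 1) {
            xt[conf_targets[c_i, 1]] <- xt[conf_targets[c_i, 1]] +
              0.8 * z[t - l, c_i]
            xt[conf_targets[c_i, 2]] <- xt[conf_targets[c_i, 2]] +
              0.8 * z[t - l, c_i]
          }
        }
      }
      if (any(!is.finite(xt))) stop("divergent trajectory")
      x[t, ] <- xt
    }
    obs <- x[(burn + 1):n_total, , drop = FALSE]
    if (max(abs(obs)) > 1e6) stop("divergent trajectory")

    if (config$grid == "uniform") {
      series <- uniform_series(t(obs), step = config$step, start_time = 0,
                               gene_ids = ids)
    } else {
      fine_times <- (seq_len(config$n) - 1) * config$step
      irr <- irregular_grid(config$grid, fine_times)
      idx <- vapply(irr, function(tt) which.min(abs(fine_times - tt)),
                    integer(1))
      series <- expression_series(t(obs[idx, , drop = FALSE]), times = irr,
                                  gene_ids = ids)
    }
    list(series = series, gold = network$gold, coef = coef,
         confounder_pairs = conf_pairs, seed = config$seed)
  })
}

# irregular observation grids patterned on the real series: "fly" has ~30-min
# spacing early then 1 h gaps; "ecoli" alternates 10- and 50-min gaps
irregular_grid <- function(mode, fine_times) {
  span <- max(fine_times)
  if (mode == "fly") {
    t1 <- seq(0, by = 30, length.out = 10)
    t2 <- seq(t1[10] + 60, span, by = 60)
    out <- c(t1, t2)
  } else if (mode == "ecoli") {
    out <- cumsum(c(0, rep(c(10, 50), length.out = 60)))
  } else stop("unknown grid mode: ", mode)
  # the last observation always sits on the grid so resampling spans it
  sort(unique(c(out[out <= span], span)))
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: draws the network, simulates expression, and (for
#' non-uniform grids) resamples to the configured constant step.
#'
#' @param config a `sim_config`.
#' @return list with `series` (always a `uniform_series`), `gold`, `coef`,
#'   `confounder_pairs`, `config`.
#' @export
simulate_dataset <- function(config) {
  net <- simulate_network(config)
  sim <- simulate_expression(net, config)
  series <- sim$series
  if (inherits(series, "expression_series"))
    series <- resample_uniform(series, config$step)
  list(series = series, gold = sim$gold, coef = sim$coef,
       confounder_pairs = sim$confounder_pairs, config = config)
}
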