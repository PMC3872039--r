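#' Lagged mutual-information matrix
#'
#' For every unordered gene pair, runs the adaptive lag search ([best_lag()])
#' over `-l_max .. l_max` and records the maximising lag and its dependence
#' score. Scores are symmetric; lags are antisymmetric (`lags[i, j] > 0`
#' means gene i leads gene j). With `l_max = 0` this reduces exactly to the
#' static mutual-information matrix.
#'
#' @param series a `uniform_series`.
#' @param l_max maximum lag in steps.
#' @param estimator pairwise dependence function (default [gaussian_mi()]).
#' @return a `lag_matrix`.
#' @export
lagged_mi_matrix <- function(series, l_max, estimator = gaussian_mi) {
  p <- nrow(series$values)
  lags <- matrix(0L, p, p)
  scores <- matrix(0, p, p)
  if (p >= 2) {
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        bl <- best_lag(series, i, j, l_max, estimator)
        lags[i, j] <- bl$lag
        lags[j, i] <- -bl$lag
        scores[i, j] <- scores[j, i] <- bl$score
      }
    }
  }
  lag_matrix(lags, scores, series$gene_ids, l_max = max(l_max, 0L))
}

# mRMR forward selection for one target over a symmetric relevance matrix.
# Returns each candidate's mRMR score (u - r, u for the first pick) at the
# moment it is selected.
mrmr_forward <- function(mi, target) {
  p <- nrow(mi)
  candidates <- setdiff(seq_len(p), target)
  selected <- integer(0)
  score_at_selection <- rep(NA_real_, p)
  while (length(candidates) > 0) {
    u <- mi[candidates, target]
    if (length(selected) == 0) {
      r <- rep(0, length(candidates))
    } else {
      r <- rowMeans(mi[candidates, selected, drop = FALSE])
    }
    s <- u - r
    pick <- which.max(s)
    score_at_selection[candidates[pick]] <- s[pick]
    selected <- c(selected, candidates[pick])
    candidates <- candidates[-pick]
  }
  score_at_selection
}

# assign an undirected pair score to directions according to the lag sign:
# lag > 0 means i leads j (i -> j); lag 0 credits both directions
direct_by_lag <- function(pair_scores, lags) {
  p <- nrow(pair_scores)
  out <- matrix(NA_real_, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      s <- pair_scores[i, j]
      if (is.na(s)) next
      l <- lags[i, j]
      if (l > 0) out[i, j] <- s
      else if (l < 0) out[j, i] <- s
      else out[i, j] <- out[j, i] <- s
    }
  }
  out
}

# shift assigned (non-NA) entries so the minimum is 0, then fill NA with 0;
# the shift is monotone so the ranking of assigned edges is unchanged
shift_nonnegative <- function(m) {
  assigned <- !is.na(m)
  if (any(assigned)) {
    lo <- min(m[assigned])
    if (lo < 0) m[assigned] <- m[assigned] - lo
  }
  m[!assigned] <- 0
  diag(m) <- 0
  m
}

#' Time-lagged MRNET scores
#'
#' Minimum-redundancy maximum-relevance network inference over lagged
#' mutual information. For each target gene, all other genes are selected
#' sequentially: the first pick maximises the relevance `u = I(X; Y)` at the
#' pair's best lag, later picks maximise `u - r` with `r` the mean lagged MI
#' between the candidate and the already-selected genes. Each unordered pair
#' scores the maximum of its two mRMR scores (each gene as target), and the
#' estimated lag sign directs the edge (positive lag of X against Y puts the
#' score on X -> Y; lag 0 credits both directions). mRMR scores can be
#' negative, so the assigned scores are shifted by the global minimum --
#' a monotone change that preserves the ranking.
#'
#' @param series a `uniform_series` with at least 3 genes.
#' @param l_max maximum lag in steps.
#' @return a `score_matrix`.
#' @export
tl_mrnet_scores <- function(series, l_max) {
  p <- nrow(series$values)
  if (p < 3) stop("mRMR redundancy needs at least 3 genes")
  lm <- lagged_mi_matrix(series, l_max)
  sel <- vapply(seq_len(p), function(tg) mrmr_forward(lm$scores, tg),
                numeric(p))
  # sel[j, tg] = mRMR score of gene j when tg is the target
  pair <- matrix(NA_real_, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      pair[i, j] <- pair[j, i] <- max(sel[i, j], sel[j, i])
    }
  }
  directed <- direct_by_lag(pair, lm$lags)
  score_matrix(shift_nonnegative(directed), series$gene_ids)
}

#' Time-lagged CLR scores
#'
#' Context-likelihood-of-relatedness scoring over lagged mutual information.
#' Each gene's lagged MI values against all other genes form its background;
#' the z-score of a pair MI against gene x's background is
#' `z_x = max(0, (I - mu_x) / sigma_x)` and the pair score is
#' `sqrt(z_x^2 + z_y^2)`. The estimated lag sign directs the edge as in
#' [tl_mrnet_scores()]. A gene whose background MI is constant gets
#' `sigma = 0` and all its z-scores are defined as 0 (with a warning).
#'
#' @inheritParams tl_mrnet_scores
#' @return a `score_matrix`.
#' @export
tl_clr_scores <- function(series, l_max) {
  p <- nrow(series$values)
  if (p < 3) stop("CLR background needs at least 3 genes")
  lm <- lagged_mi_matrix(series, l_max)
  mi <- lm$scores
  mu <- numeric(p)
  sg <- numeric(p)
  for (g in seq_len(p)) {
    bg <- mi[g, -g]
    mu[g] <- mean(bg)
    sg[g] <- stats::sd(bg)
  }
  if (any(sg == 0))
    warning("constant MI background; z-scores set to 0 for: ",
            paste(series$gene_ids[sg == 0], collapse = ", "))
  zfun <- function(i, val) {
    if (sg[i] == 0) return(0)
    max(0, (val - mu[i]) / sg[i])
  }
  pair <- matrix(NA_real_, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      zi <- zfun(i, mi[i, j])
      zj <- zfun(j, mi[i, j])
      pair[i, j] <- pair[j, i] <- sqrt(zi^2 + zj^2)
    }
  }
  directed <- direct_by_lag(pair, lm$lags)
  score_matrix(shift_nonnegative(directed), series$gene_ids)
}

#' Three-step adaptive-lag scores with DPI pruning
#'
#' A Time-Delay-ARACNE-style procedure. Step 1 estimates each gene's
#' start-of-regulation time as the first time index at which its expression
#' departs from its initial value by more than `theta` standard deviations
#' (genes that never depart get index n), and restricts candidate edges
#' i -> j to pairs with `tau_i <= tau_j`. Step 2 finds, for every candidate,
#' the lag in `0 .. l_max` maximising the copula/kernel mutual information.
#' Step 3 sweeps a threshold grid (by default the deciles of the positive MI
#' values): at each threshold the surviving graph is pruned by the data
#' processing inequality -- in every fully connected triplet the weakest pair
#' is removed if its MI falls below `(1 - dpi_tolerance)` times the second
#' weakest -- and the final score of an edge is the number of thresholded
#' graphs in which it survives.
#'
#' @param series a `uniform_series`.
#' @param l_max maximum lag in steps (default 6).
#' @param threshold_grid MI thresholds; defaults to the deciles of the
#'   positive MI values.
#' @param dpi_tolerance DPI tolerance in `[0, 1)` (default 0.1).
#' @param theta start-of-regulation threshold in standard deviations.
#' @return a `score_matrix` of survival counts.
#' @export
td_aracne_scores <- function(series, l_max = 6, threshold_grid = NULL,
                             dpi_tolerance = 0.1, theta = 1.0) {
  if (l_max < 1) stop("l_max must be >= 1")
  vals <- series$values
  p <- nrow(vals)
  n <- ncol(vals)

  tau <- vapply(seq_len(p), function(i) {
    x <- vals[i, ]
    s <- stats::sd(x)
    if (s == 0) return(n)
    hit <- which(abs(x - x[1]) > theta * s)
    if (length(hit) == 0) n else hit[1]
  }, numeric(1))
  if (length(unique(tau)) == 1)
    warning("no differential-expression ordering; all candidate edges kept")

  mi <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j || tau[i] > tau[j]) next
      bl <- best_lag(series, i, j, l_max, estimator = copula_kde_mi,
                     negative = FALSE)
      mi[i, j] <- bl$score
    }
  }

  pos <- mi[mi > 0]
  if (length(pos) == 0) return(score_matrix(matrix(0, p, p), series$gene_ids))
  if (is.null(threshold_grid))
    threshold_grid <- unname(stats::quantile(pos, probs = seq(0.1, 0.9, 0.1)))

  counts <- dpi_threshold_counts(mi, threshold_grid, dpi_tolerance)
  score_matrix(counts, series$gene_ids)
}

# threshold sweep + DPI pruning over a directed MI matrix: at each threshold
# keep edges at or above it, then in every fully connected triplet (all three
# pairs connected in some direction) remove the weakest pair if its MI is
# below (1 - tol) times the second weakest; DPI decisions are taken on the
# thresholded graph, not cascaded. Returns per-edge survival counts.
dpi_threshold_counts <- function(mi, threshold_grid, dpi_tolerance) {
  p <- nrow(mi)
  counts <- matrix(0, p, p)
  for (th in threshold_grid) {
    keep <- mi >= th & mi > 0
    con <- keep | t(keep)
    strength <- pmax(mi * keep, t(mi * keep))
    if (p >= 3) {
      for (tri in utils::combn(p, 3, simplify = FALSE)) {
        a <- tri[1]; b <- tri[2]; c <- tri[3]
        if (!(con[a, b] && con[a, c] && con[b, c])) next
        s3 <- c(strength[a, b], strength[a, c], strength[b, c])
        o <- order(s3)
        if (s3[o[1]] < (1 - dpi_tolerance) * s3[o[2]]) {
          drop_pair <- list(c(a, b), c(a, c), c(b, c))[[o[1]]]
          keep[drop_pair[1], drop_pair[2]] <- FALSE
          keep[drop_pair[2], drop_pair[1]] <- FALSE
        }
      }
    }
    counts <- counts + keep
  }
  counts
}
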