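#' Shrinkage estimate of the partial correlation matrix
#'
#' Estimates the correlation matrix with analytic shrinkage towards the
#' identity (Schafer-Strimmer): the shrinkage intensity is the ratio of the
#' summed estimated sampling variances of the off-diagonal correlations to the
#' sum of their squares, clipped to `[0, 1]`. Partial correlations are then
#' obtained from the concentration matrix (inverse of the shrunk correlation),
#' `pcor_ij = -omega_ij / sqrt(omega_ii * omega_jj)`, with unit diagonal.
#'
#' @param values numeric matrix, samples in rows, genes in columns; >= 3 rows.
#' @return list with `pcor` (partial correlation matrix, diagonal 1),
#'   `lambda` (shrinkage intensity) and `concentration` (inverse shrunk
#'   correlation matrix).
#' @export
shrinkage_partial_correlation <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values)
  p <- ncol(values)
  if (n < 3) stop("need at least 3 samples")
  if (p < 2) stop("need at least 2 genes")
  xs <- scale(values)           # standardized data
  r <- stats::cor(values)
  # unbiased-ish variance of each empirical correlation via the
  # centered cross-products w_k = xs_i * xs_j
  var_r <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      w <- xs[, i] * xs[, j]
      var_r[i, j] <- var_r[j, i] <- n / (n - 1)^3 * sum((w - mean(w))^2)
    }
  }
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  lambda <- if (denom > 0) sum(var_r[off]) / denom else 1
  lambda <- min(max(lambda, 0), 1)
  r_shrunk <- (1 - lambda) * r
  diag(r_shrunk) <- 1
  omega <- solve(r_shrunk)
  d <- 1 / sqrt(diag(omega))
  pcor <- -omega * outer(d, d)
  diag(pcor) <- 1
  list(pcor = pcor, lambda = lambda, concentration = omega)
}

# two-sided Fisher-z p-value for a (partial) correlation with the given
# effective degrees of freedom (variance of atanh(r) is 1/df)
fisher_z_pvalue <- function(r, df) {
  df <- max(df, 3)
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  z <- atanh(r) * sqrt(df)
  2 * stats::pnorm(-abs(z))
}

#' Shrinkage-GGM scores with partial-variance edge direction
#'
#' Static baseline in the graphical-Gaussian-model tradition: time points are
#' treated as exchangeable samples. Each unordered pair gets a two-sided
#' Fisher-z p-value for its shrunk partial correlation (effective degrees of
#' freedom `n - p - 1`, clipped at 3), and the score `1 - p` is assigned to
#' the direction running from the gene with the larger unexplained-variation
#' ratio (partial variance over variance, i.e. the more exogenous gene) to
#' the one with the smaller; the opposite direction scores 0, and exact ties
#' split the score equally.
#'
#' @param series a `uniform_series` (or any object with a `values`
#'   genes-x-times matrix and `gene_ids`).
#' @return a `score_matrix` (p x p, entry (i,j) = evidence for i -> j).
#' @export
ggm_direct_scores <- function(series) {
  vals <- t(series$values)            # samples x genes
  n <- nrow(vals)
  p <- ncol(vals)
  if (n <= p + 2)
    warning("few samples relative to genes; degrees of freedom clipped")
  fit <- shrinkage_partial_correlation(vals)
  # shrunk covariance-scale concentration: partial variance = 1 / omega_ii
  sds <- apply(vals, 2, stats::sd)
  r_shrunk <- solve(fit$concentration)       # shrunk correlation
  s_shrunk <- r_shrunk * outer(sds, sds)     # shrunk covariance
  omega_cov <- solve(s_shrunk)
  partial_var <- 1 / diag(omega_cov)
  unexplained <- partial_var / diag(s_shrunk)
  df <- n - p - 1
  scores <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      pv <- fisher_z_pvalue(fit$pcor[i, j], df)
      s <- 1 - pv
      if (unexplained[i] > unexplained[j]) {
        scores[i, j] <- s
      } else if (unexplained[j] > unexplained[i]) {
        scores[j, i] <- s
      } else {
        scores[i, j] <- scores[j, i] <- s / 2
      }
    }
  }
  score_matrix(scores, series$gene_ids)
}

# partial correlation of i and j given the conditioning set S, from the
# inverse of the correlation submatrix over {i, j} union S
pcor_given <- function(r, i, j, S) {
  idx <- c(i, j, S)
  sub <- r[idx, idx, drop = FALSE]
  om <- tryCatch(solve(sub), error = function(e) svd_pseudo_inverse(sub))
  -om[1, 2] / sqrt(om[1, 1] * om[2, 2])
}

# small pseudo-inverse fallback for singular conditioning submatrices
svd_pseudo_inverse <- function(m) {
  s <- svd(m)
  pos <- s$d > max(dim(m)) * max(s$d) * .Machine$double.eps
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' One run of the PC edge-removal / orientation algorithm
#'
#' Starts from the complete undirected graph and removes edges whose partial
#' correlation, given conditioning subsets of increasing size drawn from the
#' current neighbourhoods, is non-significant under the Fisher transform at
#' level `alpha`. Removal within one conditioning-set size level is
#' order-independent (all pairs are tested against the graph state at the
#' start of the level). V-structures are then oriented using the recorded
#' separating sets, and Meek's propagation rules applied.
#'
#' @param values samples x genes matrix.
#' @param alpha significance level in (0, 1).
#' @param max_cond maximum conditioning set size (default `p - 2`).
#' @return list with `amat` (p x p: 1 marks i -> j or an undirected edge when
#'   both (i,j) and (j,i) are 1) and `sepset`.
#' @keywords internal
pc_single <- function(values, alpha, max_cond = NULL) {
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(max_cond)) max_cond <- p - 2
  r <- stats::cor(values)
  adj <- matrix(TRUE, p, p)
  diag(adj) <- FALSE
  sepset <- vector("list", p * p)
  dim(sepset) <- c(p, p)
  for (size in 0:max_cond) {
    snapshot <- adj
    changed <- FALSE
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        if (!adj[i, j]) next
        nbrs <- setdiff(which(snapshot[i, ] | snapshot[j, ]), c(i, j))
        if (length(nbrs) < size) next
        subsets <- if (size == 0) list(integer(0))
                   else utils::combn(nbrs, size, simplify = FALSE)
        for (S in subsets) {
          pc <- pcor_given(r, i, j, S)
          pv <- fisher_z_pvalue(pc, n - length(S) - 3)
          if (pv > alpha) {
            adj[i, j] <- adj[j, i] <- FALSE
            sepset[[i, j]] <- sepset[[j, i]] <- S
            changed <- TRUE
            break
          }
        }
      }
    }
    if (!any(adj)) break
  }
  # orient v-structures i -> k <- j when k is not in sepset(i, j)
  amat <- (adj) * 1           # 1 in both directions = undirected
  for (k in seq_len(p)) {
    nb <- which(adj[k, ])
    if (length(nb) < 2) next
    for (pair in utils::combn(nb, 2, simplify = FALSE)) {
      i <- pair[1]; j <- pair[2]
      if (adj[i, j]) next
      if (!(k %in% sepset[[i, j]])) {
        amat[k, i] <- 0
        amat[k, j] <- 0
      }
    }
  }
  amat <- meek_orient(amat)
  list(amat = amat, sepset = sepset)
}

# Meek's rules 1-3 applied to a partially directed adjacency matrix
meek_orient <- function(amat) {
  p <- nrow(amat)
  repeat {
    changed <- FALSE
    directed <- amat == 1 & t(amat) == 0
    undirected <- amat == 1 & t(amat) == 1
    for (b in seq_len(p)) {
      for (c in seq_len(p)) {
        if (!undirected[b, c]) next
        # rule 1: a -> b, a and c non-adjacent  =>  b -> c
        r1 <- any(directed[, b] & amat[, c] == 0 & amat[c, ] == 0 &
                    seq_len(p) != c)
        # rule 2: b -> a -> c with b - c undirected  =>  b -> c
        r2 <- any(directed[b, ] & directed[, c])
        # rule 3: b - a1 -> c, b - a2 -> c, a1/a2 non-adjacent => b -> c
        r3 <- FALSE
        anchors <- which(undirected[b, ] & directed[, c])
        if (length(anchors) >= 2) {
          for (pr in utils::combn(anchors, 2, simplify = FALSE)) {
            if (amat[pr[1], pr[2]] == 0 && amat[pr[2], pr[1]] == 0) {
              r3 <- TRUE
              break
            }
          }
        }
        if (r1 || r2 || r3) {
          amat[c, b] <- 0
          changed <- TRUE
          directed <- amat == 1 & t(amat) == 0
          undirected <- amat == 1 & t(amat) == 1
        }
      }
    }
    if (!changed) break
  }
  amat
}

#' PC-sweep edge scores
#'
#' Runs the PC algorithm once per significance level of a decreasing grid and
#' scores every directed interaction by the fraction of returned networks
#' containing it. An edge left undirected by a run counts for both
#' directions.
#'
#' @param series a `uniform_series`; time points treated as exchangeable
#'   samples (static method).
#' @param alpha_grid decreasing significance levels in (0, 1).
#' @return a `score_matrix`.
#' @export
pc_sweep_scores <- function(series,
                            alpha_grid = c(0.1, 0.05, 0.01, 0.005, 0.001)) {
  if (length(alpha_grid) == 0) stop("alpha grid must be non-empty")
  if (any(alpha_grid <= 0 | alpha_grid >= 1)) stop("alphas must be in (0,1)")
  vals <- t(series$values)
  p <- ncol(vals)
  acc <- matrix(0, p, p)
  for (a in alpha_grid) {
    amat <- pc_single(vals, a)$amat
    acc <- acc + amat
  }
  score_matrix(acc / length(alpha_grid), series$gene_ids)
}
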