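# Lag-one design matrices: targets at times 2..n regressed on all genes at
# times 1..n-1. Predictors AND targets are standardized to zero mean, unit
# variance, so coefficient-based scores are comparable across target genes
# (otherwise high-variance targets attract systematically larger
# coefficients and bias the strongest-direction collapse).
var1_design <- function(series) {
  vals <- t(series$values)                 # time x genes
  n <- nrow(vals)
  if (n < 4) stop("need at least 4 time points for a lag-one fit")
  x <- vals[1:(n - 1), , drop = FALSE]
  y <- vals[2:n, , drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep))
    warning("constant gene(s) dropped from the lag-one design: ",
            paste(rownames(series$values)[!keep], collapse = ", "))
  ysd <- apply(y, 2, stats::sd)
  y <- sweep(y, 2, ifelse(ysd > 0, ysd, 1), "/")
  list(x = scale(x[, keep, drop = FALSE]), y = y, keep = keep,
       gene_ids = series$gene_ids, n_obs = n - 1)
}

# geometric penalty grid from the smallest lambda zeroing every coefficient
# down to lambda_max / ratio
lasso_lambda_grid <- function(x, y, n_points = 100, ratio = 1000) {
  lam_max <- max(abs(crossprod(x, y - mean(y)))) / nrow(x)
  lam_max <- max(lam_max, .Machine$double.eps)
  exp(seq(log(lam_max), log(lam_max / ratio), length.out = n_points))
}

#' L1-path VAR(1) scores
#'
#' Fits, for every target gene, the lag-one lasso regression of the target at
#' time t on all (standardized) genes at time t-1, tracing the regularization
#' path over a 100-point geometric penalty grid from the all-zero solution
#' down to `lambda_max / 1000`. At every grid point where some predictor
#' first becomes non-zero ("enters the model") the whole coefficient vector
#' is recorded, and the score of predictor j for target i is the absolute
#' value of j's mean coefficient over those recorded points. A predictor that
#' never enters the path scores 0.
#'
#' @param series a `uniform_series`.
#' @param n_lambda number of points on the geometric penalty grid.
#' @return a `score_matrix` (entry (j, i): evidence for j -> i).
#' @export
lasso_path_var1_scores <- function(series, n_lambda = 100) {
  d <- var1_design(series)
  p <- length(d$gene_ids)
  scores <- matrix(0, p, p)
  kept <- which(d$keep)
  for (ti in seq_len(p)) {
    yy <- d$y[, ti]
    if (stats::sd(yy) == 0) next
    lam <- lasso_lambda_grid(d$x, yy, n_points = n_lambda)
    fit <- glmnet::glmnet(d$x, yy, family = "gaussian", alpha = 1,
                          lambda = lam, standardize = FALSE, intercept = TRUE)
    beta <- as.matrix(fit$beta)            # predictors x lambda
    lam_used <- fit$lambda
    beta <- beta[, order(-lam_used), drop = FALSE]   # ensure decreasing
    nz <- beta != 0
    entry_idx <- apply(nz, 1, function(z) if (any(z)) which(z)[1] else NA)
    pts <- sort(unique(entry_idx[!is.na(entry_idx)]))
    if (length(pts) == 0) next
    mean_coef <- rowMeans(beta[, pts, drop = FALSE])
    scores[kept, ti] <- abs(mean_coef)
  }
  scores <- score_matrix(scores, d$gene_ids)
  scores
}

#' Hub/leaf-weighted lasso VAR(1) scores
#'
#' Two-stage weighted lasso over the lag-one design. Stage 1 fits a standard
#' lasso at the midpoint of the penalty grid and classifies genes as hubs
#' (outgoing-coefficient L1 row norm above the mean) or leaves. Stage 2
#' refits at every grid penalty with per-predictor penalty weights
#' (`weight_ratio` for hubs, 1 for leaves), so interactions leaving hubs --
#' putative transcription factors -- are penalized less. The score of j -> i
#' is the number of grid fits in which j's coefficient is non-zero.
#'
#' @param series a `uniform_series`.
#' @param weight_ratio hub penalty weight relative to leaves, in (0, 1].
#' @param penalty_grid decreasing lasso penalties; defaults to a 10-point
#'   geometric grid from the data-driven `lambda_max` down to
#'   `lambda_max / 100`.
#' @return a `score_matrix` of non-zero counts.
#' @export
weighted_lasso_var1_scores <- function(series, weight_ratio = 0.5,
                                       penalty_grid = NULL) {
  if (length(penalty_grid) == 0 && !is.null(penalty_grid))
    stop("penalty grid must be non-empty")
  if (weight_ratio <= 0 || weight_ratio > 1)
    stop("weight_ratio must be in (0, 1]")
  d <- var1_design(series)
  p <- length(d$gene_ids)
  kept <- which(d$keep)
  pk <- length(kept)
  if (is.null(penalty_grid)) {
    lam_max <- max(vapply(seq_len(p), function(ti) {
      yy <- d$y[, ti]
      if (stats::sd(yy) == 0) return(0)
      max(abs(crossprod(d$x, yy - mean(yy)))) / nrow(d$x)
    }, numeric(1)))
    lam_max <- max(lam_max, .Machine$double.eps)
    penalty_grid <- exp(seq(log(lam_max), log(lam_max / 100),
                            length.out = 10))
  }
  mid <- penalty_grid[ceiling(length(penalty_grid) / 2)]

  fit_at <- function(lambda, pen_factor) {
    beta <- matrix(0, pk, p)
    for (ti in seq_len(p)) {
      yy <- d$y[, ti]
      if (stats::sd(yy) == 0) next
      fit <- glmnet::glmnet(d$x, yy, family = "gaussian", alpha = 1,
                            lambda = lambda, standardize = FALSE,
                            intercept = TRUE, penalty.factor = pen_factor)
      beta[, ti] <- as.numeric(fit$beta[, 1])
    }
    beta
  }

  beta0 <- fit_at(mid, rep(1, pk))
  row_norm <- rowSums(abs(beta0))
  hubs <- row_norm > mean(row_norm)
  if (all(hubs) || all(!hubs)) {
    warning("hub/leaf classification degenerate; using uniform weights")
    w <- rep(1, pk)
  } else {
    w <- ifelse(hubs, weight_ratio, 1)
  }

  counts <- matrix(0, p, p)
  for (lam in penalty_grid) {
    beta <- fit_at(lam, w)
    counts[kept, ] <- counts[kept, ] + (beta != 0)
  }
  score_matrix(counts, d$gene_ids)
}

#' Two-step first-order conditional-dependence scores
#'
#' Lag-one dynamic-Bayesian-network style scorer. Step 1: for every ordered
#' pair (j -> i) and every conditioning gene k not in \{i, j\}, the target at
#' time t is regressed on genes j and k at time t-1 (plus intercept); the
#' two-sided t-test p-value of j's coefficient is recorded and the step-1
#' score is the maximum of those p-values over k. Edges with step-1 score
#' below `alpha1` are retained. Step 2: each target is regressed jointly on
#' all its retained lagged parents; for every level in `alpha2_grid` a matrix
#' is formed holding the step-2 p-value where it is below the level and 1
#' elsewhere, and the final score is 1 minus the mean of those entries over
#' the grid. Edges not retained in step 1 score exactly 0.
#'
#' @param series a `uniform_series` with at least 5 time points.
#' @param alpha1 step-1 retention threshold (default 0.7).
#' @param alpha2_grid step-2 significance levels.
#' @return a `score_matrix` with values in `[0, 1]`.
#' @export
g1dbn_scores <- function(series, alpha1 = 0.7,
                         alpha2_grid = c(0.9, 0.7, 0.5, 0.3, 0.1)) {
  if (alpha1 <= 0 || alpha1 >= 1) stop("alpha1 must be in (0, 1)")
  if (length(alpha2_grid) == 0) stop("alpha2 grid must be non-empty")
  vals <- t(series$values)
  n <- nrow(vals)
  if (n - 1 < 4) stop("need at least 5 time points")
  p <- ncol(vals)
  x <- vals[1:(n - 1), , drop = FALSE]
  y <- vals[2:n, , drop = FALSE]

  coef_pvalue <- function(xx, yy, col) {
    xx <- cbind(1, xx)
    fit <- stats::lm.fit(xx, yy)
    dfree <- length(yy) - ncol(xx)
    if (dfree <= 0) return(1)
    rss <- sum(fit$residuals^2)
    xtxi <- tryCatch(solve(crossprod(xx)), error = function(e) NULL)
    if (is.null(xtxi)) return(1)
    se <- sqrt(rss / dfree * diag(xtxi))
    tval <- fit$coefficients / se
    2 * stats::pt(-abs(tval[col + 1]), dfree)
  }

  s1 <- matrix(1, p, p)
  for (j in seq_len(p)) {
    for (i in seq_len(p)) {
      if (i == j) next
      others <- setdiff(seq_len(p), c(i, j))
      if (length(others) == 0) {
        s1[j, i] <- coef_pvalue(x[, j, drop = FALSE], y[, i], 1)
        next
      }
      pv <- vapply(others, function(k)
        coef_pvalue(x[, c(j, k), drop = FALSE], y[, i], 1), numeric(1))
      s1[j, i] <- max(pv)
    }
  }

  scores <- matrix(0, p, p)
  for (i in seq_len(p)) {
    parents <- which(s1[, i] < alpha1)
    parents <- setdiff(parents, i)
    if (length(parents) == 0) next
    if (length(parents) > n - 3) {
      warning("parent set pruned by step-1 score for target ",
              series$gene_ids[i])
      parents <- parents[order(s1[parents, i])][1:(n - 3)]
    }
    pv2 <- vapply(seq_along(parents), function(jj)
      coef_pvalue(x[, parents, drop = FALSE], y[, i], jj), numeric(1))
    for (jj in seq_along(parents)) {
      entries <- ifelse(pv2[jj] < alpha2_grid, pv2[jj], 1)
      scores[parents[jj], i] <- 1 - mean(entries)
    }
  }
  score_matrix(scores, series$gene_ids)
}
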