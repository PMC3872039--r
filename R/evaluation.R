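# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library functions stay composable
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a bounded child seed from a master seed and a label (deterministic,
# kept below 2^31 so it is always a valid R integer seed)
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(paste0(label)) * seq_along(utf8ToInt(paste0(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Gold standard of directed regulatory interactions
#'
#' @param edges data frame with character columns `source` and `target`, and
#'   optionally `lag` (true interaction lag, minutes or steps as documented
#'   by the producer).
#' @param gene_ids all gene names in the universe (defaults to the genes
#'   appearing in the edges).
#' @return a `gold_standard` object.
#' @export
gold_standard <- function(edges, gene_ids = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    stopifnot(all(c("source", "target") %in% names(edges)))
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    if (any(edges$source == edges$target)) stop("self-edges are not allowed")
  } else if (!all(c("source", "target") %in% names(edges))) {
    edges <- data.frame(source = character(0), target = character(0),
                        stringsAsFactors = FALSE)
  }
  if (is.null(gene_ids)) gene_ids <- sort(unique(c(edges$source, edges$target)))
  if (nrow(edges) > 0 &&
      !all(c(edges$source, edges$target) %in% gene_ids))
    stop("edge endpoints must be in gene_ids")
  edges <- unique(edges)
  structure(list(gene_ids = gene_ids, edges = edges), class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("gold_standard: %d genes, %d directed edges\n",
              length(x$gene_ids), nrow(x$edges)))
  invisible(x)
}

#' Restrict a gold standard to a gene subset
#' @param gold a `gold_standard`.
#' @param genes character vector of genes to keep.
#' @export
subset_gold <- function(gold, genes) {
  keep <- gold$edges$source %in% genes & gold$edges$target %in% genes
  gold_standard(gold$edges[keep, , drop = FALSE], gene_ids = genes)
}

#' Read / write two-column edge-list TSV
#'
#' Columns: source, target, and optionally a third column holding the true
#' interaction lag in minutes.
#' @param path file path.
#' @export
read_gold_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  gold_standard(tab)
}

#' @rdname read_gold_tsv
#' @param gold a `gold_standard`.
#' @export
write_gold_tsv <- function(gold, path) {
  utils::write.table(gold$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Random subnetwork sampling
#'
#' Draws `count` gene sets of `size` distinct genes uniformly from the gold
#' standard's universe, redrawing any set whose induced subgraph carries no
#' gold edge (the area under the precision-recall curve is undefined without
#' positives). Sets may repeat across draws. Deterministic under `seed`.
#'
#' @param gold a `gold_standard` with at least `size` genes and 1 edge.
#' @param size genes per subnetwork (default 5).
#' @param count number of subnetworks (default 500).
#' @param seed integer seed.
#' @return list of character vectors of gene names.
#' @export
sample_subnetworks <- function(gold, size = 5, count = 500, seed = 1) {
  if (length(gold$gene_ids) < size) stop("not enough genes")
  if (nrow(gold$edges) == 0) stop("gold standard has no edges")
  key <- paste(gold$edges$source, gold$edges$target, sep = "\r")
  with_seed(seed, {
    out <- vector("list", count)
    attempts <- 0L
    k <- 1L
    while (k <= count) {
      attempts <- attempts + 1L
      if (attempts > 1e5) stop("no qualifying subnetwork found")
      genes <- sample(gold$gene_ids, size)
      keep <- gold$edges$source %in% genes & gold$edges$target %in% genes
      if (!any(keep)) next
      out[[k]] <- genes
      k <- k + 1L
    }
    out
  })
}

#' Strongest-direction collapse
#'
#' For every unordered gene pair keeps only the higher-scoring of the two
#' directed candidates (ties keep the direction whose source sorts first),
#' and returns the `p(p-1)/2` surviving candidates ranked by descending
#' score.
#'
#' @param scores a `score_matrix`.
#' @return data frame with columns `source`, `target`, `score`, sorted by
#'   descending score.
#' @export
collapse_directions <- function(scores) {
  ids <- rownames(scores)
  p <- length(ids)
  if (p < 2) stop("need at least 2 genes")
  src <- character(0); tgt <- character(0); sc <- numeric(0)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (scores[i, j] >= scores[j, i]) {
        src <- c(src, ids[i]); tgt <- c(tgt, ids[j]); sc <- c(sc, scores[i, j])
      } else {
        src <- c(src, ids[j]); tgt <- c(tgt, ids[i]); sc <- c(sc, scores[j, i])
      }
    }
  }
  out <- data.frame(source = src, target = tgt, score = sc,
                    stringsAsFactors = FALSE)
  out[order(-out$score), , drop = FALSE]
}

#' Rank all directed candidates without collapsing
#'
#' Alternative candidate definition: every ordered pair is a candidate
#' (`p(p-1)` of them), ranked by descending score.
#' @param scores a `score_matrix`.
#' @export
rank_all_directed <- function(scores) {
  ids <- rownames(scores)
  p <- length(ids)
  idx <- which(row(scores) != col(scores))
  out <- data.frame(source = ids[row(scores)[idx]],
                    target = ids[col(scores)[idx]],
                    score = scores[idx], stringsAsFactors = FALSE)
  out[order(-out$score), , drop = FALSE]
}

# AUPRC of one concrete ordering: (1/P) * sum over achieved recall levels i
# of the maximum precision at that level, which is i / (rank of the i-th
# positive); unreached levels contribute 0
auprc_of_positions <- function(pos_ranks, P) {
  if (P < 1) stop("undefined AUPRC: no positives")
  if (length(pos_ranks) == 0) return(0)
  sum(seq_along(pos_ranks) / sort(pos_ranks)) / P
}

#' Area under the precision-recall curve
#'
#' Candidates are ranked by descending score; walking down the ranking,
#' `precision_k = TP_k / k` and `recall_k = TP_k / P`. Each of the `P` recall
#' levels `i/P` is assigned the maximum precision among ranks achieving it
#' (that maximum sits at the rank where the i-th positive appears), and the
#' AUPRC is the mean of those maxima over all `P` levels. A gold edge absent
#' from the candidate list (e.g. collapsed to the wrong direction) makes its
#' recall level unreachable and contributes 0. Tied scores are handled by
#' averaging over `tie_reps` seeded random orderings within tie groups.
#'
#' @param ranking data frame with `source`, `target`, `score` (e.g. from
#'   [collapse_directions()]).
#' @param gold a `gold_standard` or a data frame of gold edges.
#' @param n_positives total positives `P`; defaults to the number of gold
#'   edges over the ranking's gene set.
#' @param tie_reps random tie orderings to average over (default 100).
#' @param seed seed for the tie orderings.
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(ranking, gold, n_positives = NULL, tie_reps = 100,
                  seed = 1) {
  edges <- if (inherits(gold, "gold_standard")) gold$edges else
    as.data.frame(gold, stringsAsFactors = FALSE)
  genes <- unique(c(ranking$source, ranking$target))
  edges <- unique(edges[edges$source %in% genes & edges$target %in% genes,
                        c("source", "target"), drop = FALSE])
  P <- if (is.null(n_positives)) nrow(edges) else n_positives
  if (P < 1) stop("undefined AUPRC: no positives")
  gold_key <- paste(edges$source, edges$target, sep = "\r")
  cand_key <- paste(ranking$source, ranking$target, sep = "\r")
  is_pos <- cand_key %in% gold_key
  sc <- ranking$score
  ord <- order(-sc)
  sc_sorted <- sc[ord]
  pos_sorted <- is_pos[ord]
  # tie groups that mix positives and negatives need randomization
  grp <- match(sc_sorted, unique(sc_sorted))
  mixed <- vapply(split(pos_sorted, grp),
                  function(v) length(v) > 1 && any(v) && !all(v), logical(1))
  if (!any(mixed)) {
    return(auprc_of_positions(which(pos_sorted), P))
  }
  with_seed(seed, {
    vals <- vapply(seq_len(tie_reps), function(r) {
      perm <- order(grp, stats::runif(length(grp)))
      auprc_of_positions(which(pos_sorted[perm]), P)
    }, numeric(1))
    mean(vals)
  })
}

#' Expected AUPRC of a random ranking
#'
#' `random_baseline` draws `reps` uniformly random orderings of `N`
#' candidates containing `P` positives and averages their AUPRC.
#' `random_baseline_exact` computes the expectation in closed form from the
#' distribution of the rank of the i-th positive (an order statistic of a
#' uniform draw without replacement):
#' `E = (1/P) * sum_i sum_k (i/k) * C(k-1, i-1) * C(N-k, P-i) / C(N, P)`.
#'
#' @param N number of candidates.
#' @param P number of positives, `1 <= P <= N`.
#' @param reps Monte-Carlo replicates (default 1000).
#' @param seed integer seed.
#' @return expected AUPRC; `random_baseline` additionally carries an `"se"`
#'   attribute with the Monte-Carlo standard error.
#' @export
random_baseline <- function(N, P, reps = 1000, seed = 1) {
  if (P > N) stop("P cannot exceed N")
  if (P < 1) stop("P must be at least 1")
  with_seed(seed, {
    vals <- vapply(seq_len(reps), function(r)
      auprc_of_positions(sample(N, P), P), numeric(1))
    structure(mean(vals), se = stats::sd(vals) / sqrt(reps))
  })
}

#' @rdname random_baseline
#' @export
random_baseline_exact <- function(N, P) {
  if (P > N) stop("P cannot exceed N")
  if (P < 1) stop("P must be at least 1")
  total <- lchoose(N, P)
  e <- 0
  for (i in seq_len(P)) {
    k <- i:(N - P + i)
    pr <- exp(lchoose(k - 1, i - 1) + lchoose(N - k, P - i) - total)
    e <- e + sum(i / k * pr)
  }
  e / P
}

#' Expected AUPRC of an uninformative method under the assessment protocol
#'
#' Under strongest-direction collapse a method whose scores carry no signal
#' keeps, for every unordered gene pair, a uniformly random direction: each
#' of the `P` gold edges survives as a candidate with probability 1/2 and the
#' surviving positives land at random ranks among the `N` candidates. The
#' expectation is the binomial mixture
#' `sum_k C(P, k) 2^-P * (k/P) * random_baseline_exact(N, k)`.
#' With `candidates = "all_directed"` no positive can be collapsed away and
#' the value reduces to [random_baseline_exact()].
#'
#' @param N number of ranked candidates.
#' @param P number of gold edges.
#' @param candidates `"collapsed"` or `"all_directed"`.
#' @return expected AUPRC of a random ranking produced by the protocol.
#' @export
protocol_baseline <- function(N, P, candidates = "collapsed") {
  P <- min(P, N)
  if (candidates == "all_directed") return(random_baseline_exact(N, P))
  ks <- seq_len(P)
  wt <- stats::dbinom(ks, P, 0.5)
  sum(wt * ks / P * vapply(ks, function(k) random_baseline_exact(N, k),
                           numeric(1)))
}

#' Pairwise significance of AUPRC differences
#'
#' Compares per-subnetwork AUPRC vectors between every pair of methods with a
#' two-sided t-test: by default a paired test on the per-network differences;
#' alternatively Welch's unequal-variance test. Differences with zero
#' variance give p = 1 with a warning.
#'
#' @param auprc_vectors named list of equal-length numeric vectors (one per
#'   method, >= 10 values).
#' @param mode `"paired"` (default) or `"welch"`.
#' @param level significance level for the flags (default 0.05).
#' @return list with `p_values` (symmetric matrix) and `significant`
#'   (logical matrix at `level`).
#' @export
compare_methods <- function(auprc_vectors, mode = c("paired", "welch"),
                            level = 0.05) {
  mode <- match.arg(mode)
  m <- length(auprc_vectors)
  nm <- names(auprc_vectors)
  if (is.null(nm)) nm <- paste0("method", seq_len(m))
  lens <- lengths(auprc_vectors)
  if (mode == "paired" && length(unique(lens)) != 1)
    stop("paired comparison needs equal-length vectors")
  if (any(lens < 10)) stop("need at least 10 subnetworks per method")
  pmat <- matrix(1, m, m, dimnames = list(nm, nm))
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (b <= a) next
      x <- auprc_vectors[[a]]; y <- auprc_vectors[[b]]
      ok <- stats::complete.cases(x, y)
      x <- x[ok]; y <- y[ok]
      pv <- if (mode == "paired") {
        if (stats::sd(x - y) == 0) {
          warning("zero-variance differences; p set to 1")
          1
        } else stats::t.test(x, y, paired = TRUE)$p.value
      } else {
        if (stats::sd(x) == 0 && stats::sd(y) == 0) {
          warning("zero-variance samples; p set to 1")
          1
        } else stats::t.test(x, y, var.equal = FALSE)$p.value
      }
      pmat[a, b] <- pmat[b, a] <- pv
    }
  }
  list(p_values = pmat, significant = pmat < level & row(pmat) != col(pmat))
}

#' Time-shuffle control
#'
#' Applies one random permutation of the time points (shared across genes),
#' reruns the scoring method and returns the AUPRC of the collapsed ranking.
#' A dynamic method's performance on shuffled data should fall to the random
#' baseline; static methods are permutation-invariant.
#'
#' @param series a `uniform_series`.
#' @param gold a `gold_standard` restricted to the series' genes.
#' @param method function `f(series) -> score_matrix`.
#' @param seed integer seed (also used for tie ordering in the AUPRC).
#' @param permutation optional explicit permutation of `1..n` overriding the
#'   random draw.
#' @return AUPRC of the method on the shuffled series.
#' @export
shuffle_control <- function(series, gold, method, seed = 1,
                            permutation = NULL) {
  n <- ncol(series$values)
  perm <- if (is.null(permutation)) with_seed(seed, sample(n)) else permutation
  shuffled <- series
  shuffled$values <- series$values[, perm, drop = FALSE]
  scores <- method(shuffled)
  auprc(collapse_directions(scores), gold, seed = child_seed(seed, "tie"))
}

#' Distribution of estimated lags over gold edges
#'
#' Tallies the signed lag estimated for every gold edge (positive = the
#' regulator leads its target) across one or more lag matrices, over the
#' support `-l_max .. l_max`.
#'
#' @param lag_matrices a `lag_matrix` or list of them.
#' @param gold a `gold_standard` sharing the gene ids.
#' @param step minutes per step; when given, a `lag_minutes` column is added.
#' @return data frame with `lag_steps`, `count` and optionally `lag_minutes`.
#' @export
lag_distribution <- function(lag_matrices, gold, step = NULL) {
  if (inherits(lag_matrices, "lag_matrix")) lag_matrices <- list(lag_matrices)
  l_max <- max(vapply(lag_matrices, function(m) m$l_max, numeric(1)))
  support <- seq(-l_max, l_max)
  counts <- stats::setNames(rep(0L, length(support)), support)
  for (lm in lag_matrices) {
    for (e in seq_len(nrow(gold$edges))) {
      s <- gold$edges$source[e]
      t <- gold$edges$target[e]
      if (!(s %in% lm$gene_ids) || !(t %in% lm$gene_ids)) next
      l <- lm$lags[s, t]
      counts[as.character(l)] <- counts[as.character(l)] + 1L
    }
  }
  out <- data.frame(lag_steps = support, count = as.integer(counts))
  if (!is.null(step)) out$lag_minutes <- out$lag_steps * step
  out
}

#' Full benchmark of scoring methods over sampled subnetworks
#'
#' Reproduces the assessment protocol: sample gene subnetworks from the gold
#' standard, restrict the series and gold to each, run every method, collapse
#' to the strongest direction (or rank all directed candidates), compute the
#' AUPRC per subnetwork and method, and summarise with per-method means, the
#' exact expected AUPRC of a random ranking, and a pairwise significance
#' matrix. Fully deterministic under `seed`.
#'
#' @param series a `uniform_series` containing all gold genes.
#' @param gold a `gold_standard`.
#' @param methods named list of functions `f(series) -> score_matrix`.
#' @param size,count subnetwork size and number (defaults 5 and 500).
#' @param seed integer master seed.
#' @param candidates `"collapsed"` (default) or `"all_directed"`.
#' @param tie_reps tie-order replicates in the AUPRC.
#' @param compare_mode `"paired"` or `"welch"`.
#' @return a `benchmark_result`: list with `auprc` (subnetworks x methods
#'   matrix), `mean_auprc`, `random_baseline`, `comparison`, `subnetworks`.
#' @export
run_benchmark <- function(series, gold, methods, size = 5, count = 500,
                          seed = 1, candidates = c("collapsed", "all_directed"),
                          tie_reps = 100, compare_mode = "paired") {
  candidates <- match.arg(candidates)
  stopifnot(length(methods) > 0, !is.null(names(methods)))
  subs <- sample_subnetworks(gold, size = size, count = count,
                             seed = child_seed(seed, "subnets"))
  res <- matrix(NA_real_, count, length(methods),
                dimnames = list(NULL, names(methods)))
  baseline <- numeric(count)
  for (k in seq_len(count)) {
    genes <- subs[[k]]
    sub_series <- series
    sub_series$values <- series$values[genes, , drop = FALSE]
    sub_series$gene_ids <- genes
    sub_gold <- subset_gold(gold, genes)
    P <- nrow(sub_gold$edges)
    N <- if (candidates == "collapsed") size * (size - 1) / 2
         else size * (size - 1)
    baseline[k] <- protocol_baseline(N, P, candidates)
    for (m in seq_along(methods)) {
      scores <- tryCatch(methods[[m]](sub_series), error = function(e) NULL)
      if (is.null(scores)) next
      ranking <- if (candidates == "collapsed") collapse_directions(scores)
                 else rank_all_directed(scores)
      res[k, m] <- auprc(ranking, sub_gold, tie_reps = tie_reps,
                         seed = child_seed(seed, paste0("tie", k, "_", m)))
    }
  }
  cmp <- if (length(methods) >= 2 && count >= 10)
    compare_methods(lapply(seq_along(methods), function(m)
      res[, m])  |> stats::setNames(names(methods)), mode = compare_mode)
  else NULL
  structure(list(auprc = res,
                 mean_auprc = colMeans(res, na.rm = TRUE),
                 random_baseline = mean(baseline),
                 comparison = cmp,
                 subnetworks = subs,
                 candidates = candidates,
                 seed = seed),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result: %d subnetworks, %d methods\n",
              nrow(x$auprc), ncol(x$auprc)))
  cat(sprintf("random baseline (expected AUPRC): %.4f\n", x$random_baseline))
  print(round(sort(x$mean_auprc, decreasing = TRUE), 4))
  invisible(x)
}

#' Serialize a benchmark result
#'
#' Writes `<prefix>.json` (means, baseline, p-values, config) and
#' `<prefix>_auprc.tsv` (per-subnetwork AUPRC table).
#' @param result a `benchmark_result`.
#' @param prefix output path prefix.
#' @export
write_benchmark <- function(result, prefix) {
  out <- list(mean_auprc = as.list(result$mean_auprc),
              random_baseline = result$random_baseline,
              candidates = result$candidates,
              seed = result$seed,
              n_subnetworks = nrow(result$auprc))
  if (!is.null(result$comparison)) {
    out$p_values <- result$comparison$p_values
    out$significant <- result$comparison$significant
  }
  jsonlite::write_json(out, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.table(result$auprc, paste0(prefix, "_auprc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
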