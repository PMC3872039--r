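#' Directed interaction score matrix
#'
#' A p x p matrix of non-negative scores where entry (i, j) holds the
#' evidence for the directed interaction i -> j. The diagonal is undefined
#' and fixed at 0; it is excluded from all rankings.
#'
#' @param scores numeric p x p matrix of finite, non-negative values.
#' @param gene_ids character vector of gene names.
#' @return a `score_matrix` object (a matrix with dimnames and a class).
#' @export
score_matrix <- function(scores, gene_ids = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) != ncol(scores)) stop("scores must be square")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (any(scores < 0)) stop("scores must be non-negative")
  if (is.null(gene_ids)) {
    gene_ids <- rownames(scores)
    if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(scores)))
  }
  diag(scores) <- 0
  dimnames(scores) <- list(gene_ids, gene_ids)
  class(scores) <- c("score_matrix", "matrix")
  scores
}

#' Per-pair estimated lags with their dependence scores
#'
#' Holds the signed lag (in steps) estimated for every ordered gene pair,
#' together with the dependence score achieved at that lag. `lags[i, j] > 0`
#' means gene i leads gene j; lags are antisymmetric and scores symmetric by
#' construction when produced by [lagged_mi_matrix()].
#'
#' @param lags integer p x p matrix of signed lags.
#' @param scores numeric p x p matrix of non-negative dependence scores.
#' @param gene_ids character gene names.
#' @param l_max the maximum lag searched.
#' @export
lag_matrix <- function(lags, scores, gene_ids = NULL, l_max = max(abs(lags))) {
  lags <- as.matrix(lags)
  scores <- as.matrix(scores)
  stopifnot(all(dim(lags) == dim(scores)))
  if (any(abs(lags) > l_max)) stop("lag exceeds l_max")
  if (any(scores < 0)) stop("scores must be non-negative")
  if (is.null(gene_ids)) {
    gene_ids <- rownames(scores)
    if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(lags)))
  }
  dimnames(lags) <- dimnames(scores) <- list(gene_ids, gene_ids)
  structure(list(lags = lags, scores = scores, gene_ids = gene_ids,
                 l_max = l_max),
            class = "lag_matrix")
}

#' Read / write score matrices as TSV
#' @param scores a `score_matrix`.
#' @param path file path.
#' @export
write_scores_tsv <- function(scores, path) {
  df <- data.frame(gene = rownames(scores), unclass(scores),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores_tsv
#' @export
read_scores_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  score_matrix(m, gene_ids = as.character(tab[[1]]))
}
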