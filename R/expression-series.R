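#' Expression time series
#'
#' Container for a genes-by-time-points expression matrix with explicit,
#' possibly non-uniform, time stamps in minutes. Rows are genes, columns are
#' observations. Replicate observations at the same time stamp are averaged at
#' construction, so that times are strictly increasing afterwards.
#'
#' @param values numeric matrix, genes in rows, time points in columns.
#' @param times numeric vector of time stamps in minutes, one per column.
#' @param gene_ids character vector of unique gene names; defaults to the
#'   row names of `values` or `g1..gp`.
#' @return An object of class `expression_series` with fields `gene_ids`,
#'   `times` and `values`.
#' @export
expression_series <- function(values, times, gene_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric")
  if (length(times) != ncol(values))
    stop("number of time stamps must equal number of columns")
  if (anyNA(values) || anyNA(times)) stop("missing values are not allowed")
  if (is.null(gene_ids)) {
    gene_ids <- rownames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  }
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")

  ord <- order(times)
  times <- times[ord]
  values <- values[, ord, drop = FALSE]
  if (anyDuplicated(times)) {
    # average replicate samples taken at the same time stamp
    grp <- match(times, unique(times))
    values <- t(apply(values, 1, function(x) tapply(x, grp, mean)))
    times <- unique(times)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")

  rownames(values) <- gene_ids
  colnames(values) <- NULL
  structure(list(gene_ids = gene_ids, times = as.numeric(times),
                 values = values),
            class = "expression_series")
}

#' @export
print.expression_series <- function(x, ...) {
  cat(sprintf("expression_series: %d genes x %d time points, span %g-%g min\n",
              nrow(x$values), ncol(x$values), x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' Uniformly sampled expression series
#'
#' @param values numeric matrix, genes x time points.
#' @param step constant sampling interval in minutes, > 0.
#' @param start_time time stamp of the first column, minutes.
#' @param gene_ids character vector of unique gene names.
#' @return An object of class `uniform_series`; implied time stamps are
#'   `start_time + (k - 1) * step`.
#' @export
uniform_series <- function(values, step, start_time = 0, gene_ids = NULL) {
  values <- as.matrix(values)
  if (step <= 0) stop("step must be positive")
  if (is.null(gene_ids)) {
    gene_ids <- rownames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  }
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  if (anyNA(values)) stop("missing values are not allowed")
  rownames(values) <- gene_ids
  structure(list(gene_ids = gene_ids, step = as.numeric(step),
                 start_time = as.numeric(start_time), values = values),
            class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("uniform_series: %d genes x %d points, step %g min\n",
              nrow(x$values), ncol(x$values), x$step))
  invisible(x)
}

#' Time stamps of a uniform series
#' @param series a `uniform_series`.
#' @return numeric vector of implied time stamps in minutes.
#' @export
series_times <- function(series) {
  series$start_time + (seq_len(ncol(series$values)) - 1) * series$step
}

#' Linear resampling to a constant step
#'
#' Interpolates each gene's trajectory linearly onto a uniform grid anchored at
#' the first observation. The grid ends at the largest `start + k * step` not
#' exceeding the last observation, so a 22 h span resampled at 30 min yields 45
#' points. No extrapolation is performed. Observations that fall exactly on the
#' grid are reproduced.
#'
#' @param series an `expression_series`.
#' @param step target sampling interval in minutes.
#' @return A `uniform_series`.
#' @export
resample_uniform <- function(series, step) {
  stopifnot(inherits(series, "expression_series"))
  if (step <= 0) stop("step must be positive")
  times <- series$times
  if (length(times) < 2) stop("need at least 2 time points")
  span <- times[length(times)] - times[1]
  if (step > span) stop("degenerate grid: step exceeds the observed span")
  grid <- seq(times[1], times[length(times)] + step / 2, by = step)
  grid <- grid[grid <= times[length(times)] + step * 1e-9]
  vals <- t(apply(series$values, 1, function(x)
    stats::approx(times, x, xout = grid, method = "linear")$y))
  uniform_series(vals, step = step, start_time = times[1],
                 gene_ids = series$gene_ids)
}

#' Lag-aligned paired samples for two genes
#'
#' Returns the `n - |lag|` paired observations `(x, y)` with `y` the target at
#' times `t` and `x` the source at times `t - lag`: a positive lag means the
#' source leads the target. This is the effective-sample-size contract of all
#' lagged dependence estimates: at maximum lag `l_max` only `n - l_max` pairs
#' remain.
#'
#' @param series a `uniform_series`.
#' @param source,target gene names or indices.
#' @param lag signed integer lag in steps, `|lag| < n`.
#' @return list with numeric vectors `x` and `y` of length `n - |lag|`.
#' @export
lagged_pairs <- function(series, source, target, lag) {
  stopifnot(inherits(series, "uniform_series"))
  n <- ncol(series$values)
  lag <- as.integer(lag)
  if (abs(lag) >= n) stop("no overlap: |lag| must be smaller than n")
  xs <- series$values[source, ]
  ys <- series$values[target, ]
  if (lag >= 0) {
    idx_y <- (1 + lag):n
    idx_x <- 1:(n - lag)
  } else {
    idx_y <- 1:(n + lag)
    idx_x <- (1 - lag):n
  }
  list(x = unname(xs[idx_x]), y = unname(ys[idx_y]))
}

#' Read / write the tab-separated expression format
#'
#' The on-disk format is a UTF-8 TSV whose first column holds gene ids and
#' whose header row holds numeric time stamps in minutes.
#'
#' @param path file path.
#' @return `read_series_tsv` returns an `expression_series`.
#' @export
read_series_tsv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  times <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(times)) stop("header must hold numeric times in minutes")
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 0,
                           check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  expression_series(vals, times, gene_ids = as.character(tab[[1]]))
}

#' @rdname read_series_tsv
#' @param series an `expression_series` or `uniform_series`.
#' @export
write_series_tsv <- function(series, path) {
  times <- if (inherits(series, "uniform_series")) series_times(series)
           else series$times
  df <- data.frame(gene = series$gene_ids, series$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", format(times, trim = TRUE, scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
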