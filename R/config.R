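#' Benchmark run configuration with JSON round-trip
#'
#' Captures everything needed to reproduce a benchmark run: input paths or a
#' preset name, the method list with per-method parameters (the adaptive-lag
#' default `l_max` grid is 6, 12, 18 steps), subnetwork sampling settings,
#' the candidate mode and one master seed from which all substream seeds are
#' derived. `save_run_config()` / `load_run_config()` round-trip exactly.
#'
#' @param preset preset name (`"fly"`, `"ecoli"`, `"yeast"`) or `NULL` when
#'   `series_path`/`gold_path` are given.
#' @param series_path,gold_path input TSV paths (optional with a preset).
#' @param methods named list: method name -> list of parameters (e.g.
#'   `list(tl_clr = list(l_max = 6))`).
#' @param size,count subnetwork size and count.
#' @param candidates `"collapsed"` or `"all_directed"`.
#' @param seed master integer seed.
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(preset = NULL, series_path = NULL, gold_path = NULL,
                       methods = default_method_set(),
                       size = 5, count = 500,
                       candidates = "collapsed", seed = 1,
                       out_dir = "results") {
  structure(list(preset = preset, series_path = series_path,
                 gold_path = gold_path, methods = methods, size = size,
                 count = count, candidates = candidates, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
save_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  do.call(run_config, raw)
}

#' Default assessed method set
#'
#' The standard roster: two static baselines, three fixed-lag methods and the
#' adaptive-lag methods at `l_max` 6 (the adaptive-lag grid 6/12/18 is swept
#' by the analysis scripts).
#' @param l_max adaptive-lag maximum lag in steps.
#' @return named list of parameter lists, keyed by method name.
#' @export
default_method_set <- function(l_max = 6) {
  list(ggm = list(),
       pc = list(),
       var1_lasso = list(),
       var1_weighted = list(),
       g1dbn = list(),
       tl_mrnet = list(l_max = l_max),
       tl_clr = list(l_max = l_max),
       td_aracne = list(l_max = l_max))
}

#' Instantiate scoring functions from a configured method list
#'
#' Maps method names to the package's scoring operations with the configured
#' parameters bound, ready for [run_benchmark()].
#' @param methods named list as in [run_config()].
#' @return named list of functions `f(series) -> score_matrix`.
#' @export
build_methods <- function(methods) {
  registry <- list(
    ggm = ggm_direct_scores,
    pc = pc_sweep_scores,
    var1_lasso = lasso_path_var1_scores,
    var1_weighted = weighted_lasso_var1_scores,
    g1dbn = g1dbn_scores,
    tl_mrnet = tl_mrnet_scores,
    tl_clr = tl_clr_scores,
    td_aracne = td_aracne_scores)
  out <- list()
  for (nm in names(methods)) {
    base <- sub("_lmax[0-9]+$", "", nm)
    if (!base %in% names(registry)) stop("unknown method name: ", nm)
    fn <- registry[[base]]
    params <- methods[[nm]]
    out[[nm]] <- local({
      f <- fn; pr <- params
      function(series) do.call(f, c(list(series), pr))
    })
  }
  out
}
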