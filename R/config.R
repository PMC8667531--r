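#' Default run configuration
#'
#' One flat list of every tunable in the workflow, serializable to JSON
#' and reloadable to an identical run. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults.
#' @return A `RunConfig` list.
#' @export
cider_config <- function(...) {
  defaults <- list(
    seed = 1L,
    scale_factor = 1e4,        # log-normalization
    min_genes = 500L,          # cell filter
    n_hvgs = 2000L,
    n_pcs = 10L,
    snn_k = 20L,
    resolution = 0.4,
    premerge_threshold = 0.9,
    downsample = 40L,          # per-cluster draws (recommended 35-50)
    background_cap = 10L,
    detection_frac = 0.05,     # gene set for signatures
    cut_height = 0.55,
    edge_threshold = 0,
    covariates = character(0),
    n_workers = 1L,
    # evaluation
    min_cells = 15L,
    min_cluster_size = 75L,
    n_splits = 20L,
    perplexity = 30,
    # markers
    lfc_min = 1,
    adjp_max = 0.05
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop_cider("cider_config_error", "unknown configuration keys: ",
               paste(unknown, collapse = ", "))
  structure(modifyList(defaults, overrides), class = "RunConfig")
}

#' Write / read a run configuration as JSON
#' @param cfg a `RunConfig`; `path` file path.
#' @return `path` (write) or the `RunConfig` (read).
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "RunConfig"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$covariates <- as.character(raw$covariates %||% character(0))
  do.call(cider_config, raw)
}
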