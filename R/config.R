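# Run configuration: which coefficients to search with, the top-n committee
# size, the retrieval cutoff, and the voting basis.

#' Screening run configuration
#'
#' @param coefficients character vector of coefficient ids (see
#'   [coefficient_info()]) or `"all"` for the canonical eleven.
#' @param topn number of top retrieved structures forming the voter committee;
#'   the study design uses 10, 20, 50 or 100, but any positive integer works.
#' @param cutoff_percent retrieval cutoff for recall, as a percentage of the
#'   database (default 5).
#' @param voting_basis `"rank"` (default; voters are the union of the per-
#'   coefficient top-n structures, scored by the rank position each coefficient
#'   assigns them) or `"value"` (voters are positions 1..topn, scored by
#'   min-max-normalized similarity values). See [build_voting_profile()].
#' @param ef_percent enrichment-factor cutoff percentage (default 1).
#' @param bedroc_alpha BEDROC early-recognition parameter (default 20).
#' @param seed integer seed for any stochastic step.
#' @return a `run_config` list.
#' @export
run_config <- function(coefficients = "all", topn = 100L, cutoff_percent = 5,
                       voting_basis = c("rank", "value"), ef_percent = 1,
                       bedroc_alpha = 20, seed = 1L) {
  voting_basis <- match.arg(voting_basis)
  if (identical(coefficients, "all")) coefficients <- coefficient_ids()
  unknown <- setdiff(coefficients, coefficient_ids())
  if (length(unknown) > 0L)
    stop("unsupported coefficient id: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(coefficients)) stop("duplicated coefficient id")
  topn <- as.integer(topn)
  if (is.na(topn) || topn < 1L) stop("topn must be a positive integer")
  if (!is.numeric(cutoff_percent) || cutoff_percent <= 0 || cutoff_percent > 100)
    stop("cutoff_percent must lie in (0, 100]")
  if (!is.numeric(ef_percent) || ef_percent <= 0 || ef_percent > 100)
    stop("ef_percent must lie in (0, 100]")
  if (!is.numeric(bedroc_alpha) || bedroc_alpha <= 0)
    stop("bedroc_alpha must be positive")
  out <- list(coefficients = coefficients, topn = topn,
              cutoff_percent = cutoff_percent, voting_basis = voting_basis,
              ef_percent = ef_percent, bedroc_alpha = bedroc_alpha,
              seed = as.integer(seed))
  class(out) <- "run_config"
  out
}

#' Read a run configuration from YAML or JSON
#'
#' Recognized keys mirror the [run_config()] arguments; absent keys keep their
#' defaults. Values supplied through `...` override file values (the CLI uses
#' this for flag overrides).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file
#' @param ... overrides, e.g. `topn = 50`
#' @return a `run_config`
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json: ", path)
  if (!is.list(vals)) stop("malformed config file: ", path)
  over <- list(...)
  vals[names(over)] <- over
  keep <- intersect(names(vals), names(formals(run_config)))
  dropped <- setdiff(names(vals), keep)
  if (length(dropped) > 0L)
    warning("ignoring unknown config keys: ", paste(dropped, collapse = ", "))
  if (!is.null(vals$coefficients)) vals$coefficients <- unlist(vals$coefficients)
  do.call(run_config, vals[keep])
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config\n")
  cat("  coefficients:", paste(x$coefficients, collapse = ", "), "\n")
  cat(sprintf("  topn: %d  cutoff: %g%%  basis: %s\n",
              x$topn, x$cutoff_percent, x$voting_basis))
  cat(sprintf("  EF cutoff: %g%%  BEDROC alpha: %g  seed: %d\n",
              x$ef_percent, x$bedroc_alpha, x$seed))
  invisible(x)
}
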