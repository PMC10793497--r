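# Schema of the YAML run configuration: three blocks, every field with a
# default. Unknown keys are rejected so typos fail loudly.
config_schema <- function() {
  list(
    scenario = list(ve = NULL, p_n = NULL, lambda_i = 0.001, lambda_n = 0.002,
                    tau = 100, alpha = 0.025, power = 0.8, theta = 0),
    execution = list(reps = 1000L, seed = 1L, out = NULL),
    method = list(design = "tnd", test = "score", delta = 0.5,
                  sample_size_method = "score", n = NULL)
  )
}

resolve_config <- function(cfg) {
  schema <- config_schema()
  bad_blocks <- setdiff(names(cfg), names(schema))
  if (length(bad_blocks))
    stop("unknown config block(s): ", paste(bad_blocks, collapse = ", "),
         call. = FALSE)
  out <- schema
  for (block in names(schema)) {
    given <- cfg[[block]]
    if (is.null(given)) next
    bad <- setdiff(names(given), names(schema[[block]]))
    if (length(bad))
      stop(sprintf("unknown key(s) in `%s`: %s", block,
                   paste(bad, collapse = ", ")), call. = FALSE)
    out[[block]][names(given)] <- given
  }
  if (is.null(out$scenario$ve) || is.null(out$scenario$p_n))
    stop("`scenario.ve` and `scenario.p_n` are required", call. = FALSE)
  # validate through the constructors
  sc <- out$scenario
  design_inputs(sc$ve, sc$p_n, sc$lambda_i, sc$lambda_n, sc$tau,
                sc$alpha, sc$power, sc$theta)
  if (!out$method$design %in% c("tnd", "cct"))
    stop("`method.design` must be \"tnd\" or \"cct\"", call. = FALSE)
  if (!out$method$test %in% c("score", "wald", "cc_wald", "hybrid"))
    stop("`method.test` must be one of score, wald, cc_wald, hybrid",
         call. = FALSE)
  structure(out, class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML file with up to three blocks — `scenario` (the design
#' parameters), `execution` (`reps`, `seed`, `out`) and `method` (study
#' design, test, continuity correction, sample-size method) — fills
#' defaults for anything omitted, and validates every field. Unknown keys
#' are an error. `scenario.ve` and `scenario.p_n` are required.
#'
#' @param path Path to a YAML file.
#' @return A `"run_config"` list with all defaults resolved.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  resolve_config(yaml::read_yaml(path))
}

#' Write a resolved configuration to YAML
#'
#' Counterpart of [load_config()]; the written file round-trips losslessly.
#'
#' @param config A `"run_config"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write result rows with a reproducibility sidecar
#'
#' Writes a data frame of results as CSV (stable column order, full
#' precision, no row names) and a JSON sidecar `<path>.json` recording the
#' resolved configuration, the seed, the package version and a timestamp.
#' Identical inputs and seed produce a byte-identical CSV; only the
#' sidecar carries the timestamp.
#'
#' @param rows A data frame (may have zero rows; the header is still
#'   written).
#' @param path Output CSV path.
#' @param config Optional `"run_config"` (or any list) stored in the
#'   sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path, config = NULL) {
  stopifnot(is.data.frame(rows))
  tryCatch(
    utils::write.csv(rows, path, row.names = FALSE),
    error = function(e) stop("failed to write results to ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  sidecar <- list(
    config = if (!is.null(config)) unclass(config),
    package_version = as.character(utils::packageVersion("tnddesign")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
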