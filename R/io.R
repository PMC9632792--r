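#' Write / read a connectivity snapshot (MatrixMarket)
#'
#' Connectivity matrices are stored as MatrixMarket sparse coordinate files
#' (1-based indices), the standard interchange format for sparse binary
#' matrices.
#'
#' @param W Binary connectivity matrix.
#' @param path Output file path (conventionally `.mtx`).
#' @return `write_connectivity` returns `path` invisibly;
#'   `read_connectivity` returns a base binary matrix.
#' @export
write_connectivity <- function(W, path) {
  Matrix::writeMM(methods::as(Matrix::Matrix(W, sparse = TRUE),
                              "generalMatrix"), path)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  if (!file.exists(path)) stop("read_connectivity: no such file: ", path)
  header <- readLines(path, n = 1)
  if (!startsWith(header, "%%MatrixMarket"))
    stop("read_connectivity: ", path,
         " line 1: missing '%%MatrixMarket' header")
  m <- tryCatch(Matrix::readMM(path), error = function(e)
    stop("read_connectivity: failed to parse ", path, ": ",
         conditionMessage(e)))
  as.matrix(m) * 1
}

#' Write a metrics table as CSV
#'
#' Numeric columns are written with 9 significant digits so re-runs of the
#' same manifest reproduce the file byte-for-byte.
#'
#' @param metrics A data frame / tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  out <- as.data.frame(lapply(metrics, function(col)
    if (is.double(col)) signif(col, 9) else col))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export pool levels alongside GC degrees
#'
#' @param W Binary connectivity matrix.
#' @param state A [resource_state()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pool_state <- function(W, state, path) {
  write_metrics(tibble::tibble(gc_index = seq_along(state$p), p = state$p,
                               degree = colSums(W)), path)
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file with up to three blocks — `params` (network/plasticity
#' parameters), `resource` (resource-pool parameters) and `protocol`
#' (protocol name and its arguments) — validates it, and fills every
#' unspecified parameter with its default. Unknown keys are rejected with a
#' message listing them.
#'
#' @param path Path to a YAML file. An empty file yields all defaults.
#' @return List with elements `params` ([model_params()]), `resource`
#'   ([resource_params()]) and `protocol` (list or `NULL`).
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  bad <- setdiff(names(cfg), c("params", "resource", "protocol"))
  if (length(bad))
    stop("load_config: unknown top-level keys: ", paste(bad, collapse = ", "))
  check_keys <- function(given, allowed, block) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop("load_config: unknown keys in '", block, "': ",
           paste(bad, collapse = ", "))
  }
  check_keys(cfg$params, names(formals(model_params)), "params")
  check_keys(cfg$resource, names(formals(resource_params)), "resource")
  params <- do.call(model_params, cfg$params %||% list())
  resource <- do.call(resource_params, cfg$resource %||% list())
  list(params = params, resource = resource, protocol = cfg$protocol)
}

#' Run manifest
#'
#' Captures everything needed to reproduce a run — seed, full parameter dump,
#' package version, and the planned output inventory — as a JSON file written
#' before any stochastic step.
#'
#' @param seed Integer seed of the run.
#' @param params A [model_params()] object.
#' @param resource Optional [resource_params()].
#' @param outputs Character vector of planned output files.
#' @param path Output JSON path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(seed, params, resource = NULL,
                           outputs = character(), path) {
  manifest <- list(
    seed = seed,
    params = unclass(params),
    resource = if (!is.null(resource)) unclass(resource),
    version = as.character(utils::packageVersion("spinesim")),
    outputs = outputs,
    config_hash = digest_params(params, resource))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Stable content hash of the parameter dump (no external digest dependency:
# serialize deterministically and fold into hex).
digest_params <- function(params, resource = NULL) {
  txt <- paste(utils::capture.output(utils::str(list(params = unclass(params),
                                                     resource = if (!is.null(resource)) unclass(resource)),
                                                digits.d = 15)),
               collapse = "\n")
  raw <- utf8ToInt(txt)
  h <- 5381
  for (b in raw) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}
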