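# NetworkConfig <-> YAML/JSON files. Every architectural field is a key.

#' Write a network configuration to a YAML or JSON file
#'
#' @param config a [NetworkConfig-class].
#' @param path output file; format chosen by extension (.yaml/.yml or
#'   .json).
#' @return \code{path}, invisibly.
#' @export
writeNetworkConfig <- function(config, path) {
  validObject(config)
  x <- .configToList(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a network configuration from a YAML or JSON file
#'
#' @param path file written by [writeNetworkConfig()] (or by hand with
#'   the same keys).
#' @return a [NetworkConfig-class].
#' @export
readNetworkConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  .configFromList(x)
}
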