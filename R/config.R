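#' Read a pipeline configuration file
#'
#' Reads a YAML (or JSON) configuration with the blocks the pipeline
#' understands: `io` (`ligand_resnames`, `frame_spacing_ns`), `protocol`
#' (fields of [protocol_config()]), `synth` (fields of [toy_system_spec()]
#' or [receptor_spec()]) and `ml` (fields of [ensemble_config()]). Missing
#' blocks default to empty lists; unknown keys in a block are rejected by
#' the constructor they are forwarded to.
#'
#' @param path Path to a YAML/JSON file.
#' @return A list with elements `io`, `protocol`, `synth`, `ml`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (block in c("io", "protocol", "synth", "ml")) {
    if (is.null(cfg[[block]])) cfg[[block]] <- list()
  }
  cfg
}

#' Build a protocol configuration from a config list
#'
#' @param cfg A list as returned by [read_config()].
#' @export
protocol_config_from <- function(cfg) {
  do.call(protocol_config, cfg$protocol)
}

#' Build an ensemble configuration from a config list
#'
#' @param cfg A list as returned by [read_config()].
#' @export
ensemble_config_from <- function(cfg) {
  do.call(ensemble_config, cfg$ml)
}
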