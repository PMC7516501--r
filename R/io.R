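#' Write a JSON run manifest
#'
#' Every command-line run records a manifest next to its outputs: the seed,
#' the configuration used, the package version and the wall-clock runtime,
#' so any output can be reproduced bit-for-bit from its manifest.
#'
#' @param path output path for the JSON file.
#' @param seed integer seed of the run (may be `NULL`).
#' @param config named list of configuration values.
#' @param runtime elapsed seconds.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(path, seed, config, runtime = NA_real_) {
  manifest <- list(
    seed = seed,
    config = config,
    package = "pyinar",
    version = as.character(utils::packageVersion("pyinar")),
    r_version = as.character(getRversion()),
    runtime_seconds = runtime,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
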