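# Run manifests: self-contained provenance records written next to every
# file the tools emit.

#' Build a run manifest
#'
#' @param command short name of the operation performed.
#' @param params named list of resolved parameter values.
#' @param seed RNG seed used, or `NULL` for deterministic runs.
#' @param inputs,outputs character vectors of file paths; existing files
#'   are fingerprinted with MD5.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(command, params = list(), seed = NULL,
                         inputs = character(), outputs = character()) {
  digest <- function(paths) {
    paths <- paths[file.exists(paths)]
    if (length(paths) == 0L) return(list())
    as.list(tools::md5sum(paths))
  }
  structure(
    list(command = command,
         package = "fexupbpk",
         version = as.character(utils::packageVersion("fexupbpk")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed,
         params = params,
         inputs = digest(inputs),
         outputs = digest(outputs)),
    class = "run_manifest")
}

#' Write a run manifest as YAML
#'
#' @param manifest a `run_manifest`.
#' @param path output path (conventionally `<output>.manifest.yaml`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}
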