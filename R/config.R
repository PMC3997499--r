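## Key-value run configuration shared by the command-line helpers.

#' Read a YAML run configuration
#'
#' Maps a flat key-value file onto the option constructors: keys under
#' `gb:` go to [gbOptions()], `sasa:` to [sasaOptions()] and
#' `thresholds:` to [spotThresholds()]; omitted keys keep their
#' defaults.
#'
#' @param path YAML file (may be `NULL` for all defaults).
#' @return list with elements `gb`, `sasa`, `thresholds`.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  gb <- do.call(gbOptions, cfg$gb %||% list())
  sasa <- do.call(sasaOptions, cfg$sasa %||% list())
  thr <- do.call(spotThresholds, cfg$thresholds %||% list())
  list(gb = gb, sasa = sasa, thresholds = thr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
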