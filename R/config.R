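#' Load an adaptation configuration from YAML or JSON
#'
#' The file must mirror [adaptation_config()] field for field; unknown keys
#' are an error (they usually indicate a typo in an experiment config).
#'
#' @param path path to a `.yaml`/`.yml` (or JSON, which YAML subsumes) file.
#' @return An `adaptation_config` object.
#' @export
read_adaptation_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop_invalid("config file must contain a mapping.")
  known <- names(formals(adaptation_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop_invalid(sprintf(
      "unknown config key(s): %s. Known keys: %s.",
      paste(unknown, collapse = ", "), paste(known, collapse = ", ")
    ))
  }
  do.call(adaptation_config, cfg)
}
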