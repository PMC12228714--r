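the_defaults <- new.env(parent = emptyenv())

#' Packaged pipeline defaults
#'
#' Reads (and caches) the packaged `defaults.yaml`: the default calibration
#' constants, segmentation parameters (k = 5, brightness threshold,
#' min-max scaling, background handling), dynamics settings, and the
#' normalized regression coefficients relating each NO feature to the
#' healing day and percent re-epithelialization.
#'
#' @return a nested list mirroring the YAML structure.
#' @export
wf_defaults <- function() {
  if (is.null(the_defaults$cfg)) {
    path <- system.file("extdata", "defaults.yaml", package = "woundfluor",
                        mustWork = TRUE)
    the_defaults$cfg <- yaml::read_yaml(path)
  }
  the_defaults$cfg
}

#' Read a pipeline configuration file
#'
#' Loads a user YAML configuration and fills every unset field from
#' [wf_defaults()] (shallow-merged section by section).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return a configuration list with sections `calibration`,
#'   `segmentation`, `dynamics`, `regression`, `zstack`.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- wf_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(sprintf("config file '%s' does not exist.", path), class = "wf_io_error")
    }
    user <- yaml::read_yaml(path)
    for (section in names(user)) {
      cfg[[section]] <- utils::modifyList(cfg[[section]] %||% list(),
                                          user[[section]])
    }
  }
  cfg
}
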