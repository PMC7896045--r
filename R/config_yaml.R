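#' Load an experiment configuration from YAML
#'
#' The YAML file holds [experiment_config()] arguments verbatim, e.g.
#' `methods: [WSI_GMP]`, a `corpus:` mapping, `k:`, `seed:` and
#' `output_dir:`.
#'
#' @param path YAML file path.
#' @return an [experiment_config()].
#' @export
experiment_config_from_yaml <- function(path) {
  args <- yaml::read_yaml(path)
  args$methods <- as.character(args$methods)
  if (!is.null(args$fractions)) args$fractions <- as.numeric(args$fractions)
  do.call(experiment_config, args)
}
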