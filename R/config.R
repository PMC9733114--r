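# Flat YAML serialization of the generator configuration, used by the
# command-line pipeline; every simulation run writes its resolved config
# next to its outputs for provenance.

#' Read a generator configuration from YAML
#'
#' The file holds the fields of [population_config()]: a `regions` list
#' (each with `label`, `urban_share`, `eas_per_stratum`, `hh_per_ea`,
#' `baseline`) and scalar keys `beta_urban`, `beta_wealth`,
#' `beta_education`, `icc`, `n_assets`, `asset_strength`, `eligibility`,
#' `hh_size_dispersion`, `seed`. Missing scalar keys take the
#' [population_config()] defaults.
#'
#' @param path YAML file path.
#' @return A [population_config()].
#' @export
read_population_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$regions)) stop("config lacks a 'regions' entry")
  regions <- do.call(rbind, lapply(y$regions, function(r)
    data.frame(label = r$label, urban_share = r$urban_share,
               eas_per_stratum = r$eas_per_stratum,
               hh_per_ea = r$hh_per_ea, baseline = r$baseline)))
  args <- y[setdiff(names(y), "regions")]
  args <- args[names(args) %in% names(formals(population_config))]
  do.call(population_config, c(list(regions = regions), args))
}

#' Write a generator configuration to YAML
#'
#' @param config A [population_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_population_config <- function(config, path) {
  y <- unclass(config)
  y$regions <- lapply(seq_len(nrow(config$regions)), function(i)
    as.list(config$regions[i, ]))
  yaml::write_yaml(y, path)
  invisible(path)
}
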