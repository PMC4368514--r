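#' Serialise a model configuration to YAML
#'
#' Writes every parameter needed to rebuild the model — variant, loci,
#' lattice geometry, the full rate table, Bcd gradient/activation and
#' initial-profile blocks — so a saved configuration reproduces runs
#' bit-for-bit (deterministic) or distributionally (stochastic, given the
#' seed recorded by the caller).
#'
#' @param model an `hbkr_model`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "hbkr_model"))
  lat <- model$network$lattice
  cfg <- list(
    variant = model$variant,
    loci = model$loci,
    lattice = list(n_ap = lat$n_ap, n_dv = lat$n_dv, h_um = lat$h_um,
                   ap_min = lat$ap_min, ap_max = lat$ap_max),
    rates = unclass(model$network$rates)[names(model$network$rates)],
    bcd = unclass(model$network$bcd),
    initial_conditions = unclass(model$init)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Rebuild a model from a YAML configuration
#'
#' @param path YAML file written by [write_model_config()].
#' @return an `hbkr_model`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("variant", "loci", "lattice", "rates", "bcd", "initial_conditions")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config missing key '", miss[1], "'")
  lat <- do.call(lattice_config, cfg$lattice)
  rates <- do.call(rate_table, cfg$rates)
  bcd <- do.call(bcd_params, cfg$bcd)
  init <- do.call(initial_profile_params, cfg$initial_conditions)
  hb_kr_model(cfg$variant, lattice = lat, rates = rates, init = init,
              bcd = bcd, loci = cfg$loci)
}

#' Validate a model configuration file
#'
#' @param path YAML configuration.
#' @return TRUE on success; otherwise an error naming the first offending
#'   key.
#' @export
validate_config <- function(path) {
  invisible(read_model_config(path))
  TRUE
}
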