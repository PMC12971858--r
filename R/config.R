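#' Read and write flat configuration files
#'
#' Kinetic parameter sets and latent-distribution specifications round-trip
#' through flat key-value YAML or JSON files (chosen by file extension),
#' using the same field names as [kinetic_params()] and
#' [latent_distribution()].
#'
#' @param params A [kinetic_params()].
#' @param dist A [latent_distribution()].
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @name config_io
NULL

read_flat_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config: unsupported extension '", ext, "' (use yaml or json)")
  }
}

write_flat_config <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("config: unsupported extension '", ext, "' (use yaml or json)")
  }
  invisible(path)
}

#' @rdname config_io
#' @export
write_params_config <- function(params, path) {
  stopifnot(inherits(params, "kinetic_params"))
  write_flat_config(unclass(params), path)
}

#' @rdname config_io
#' @export
read_params_config <- function(path) {
  cfg <- read_flat_config(path)
  do.call(kinetic_params, cfg[names(cfg) %in% names(formals(kinetic_params))])
}

#' @rdname config_io
#' @export
write_distribution_config <- function(dist, path) {
  stopifnot(inherits(dist, "latent_distribution"))
  write_flat_config(list(family = dist$family, tau_0 = dist$tau_0,
                         rsd_tau = dist$rsd_tau, tau_min = dist$tau_min), path)
}

#' @rdname config_io
#' @export
read_distribution_config <- function(path) {
  cfg <- read_flat_config(path)
  latent_distribution(cfg$family, cfg$tau_0, cfg$rsd_tau,
                      if (is.null(cfg$tau_min)) 0 else cfg$tau_min)
}
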