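#' Default run configuration
#'
#' Full configuration tree for a pipeline run, with every parameter at its
#' documented default. Sections: `habitat` (levels, spacings), `simulation`
#' (all [sim_params()] fields plus a `seed`), `analysis` (scales,
#' whether to include the whole-array scale), `nullmodel` (iterations,
#' resampling mode, seed) and `synthetic` (the [synth_config()] fields).
#'
#' @return nested named list
#' @export
default_config <- function() {
  sp <- unclass(sim_params())
  sc <- unclass(synth_config())
  sc$seed <- NULL
  list(
    habitat = list(levels = 4L, spacings = default_spacings(4L)),
    simulation = c(sp, list(seed = 1L)),
    analysis = list(scales = c(1L, 3L, 9L, 27L),
                    include_top_scale = FALSE),
    nullmodel = list(n_iter = 10000L, mode = "cell", seed = 1L),
    synthetic = sc
  )
}

#' Read a run configuration file
#'
#' Reads a YAML configuration and merges it over [default_config()]. Every
#' key is optional; unknown keys are rejected so that typos fail loudly
#' instead of being silently ignored.
#'
#' @param path YAML file path; `NULL` returns the defaults
#' @return nested named list (the full, merged configuration)
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  merge_config(cfg, user, "")
}

merge_config <- function(base, user, where) {
  if (!is.list(user)) stop(sprintf("config section '%s' must be a mapping",
                                   where))
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s)%s: %s",
                 if (nzchar(where)) paste0(" in '", where, "'") else "",
                 paste(unknown, collapse = ", ")))
  }
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(where, if (nzchar(where)) ".", nm))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Write a metadata sidecar for an output file
#'
#' Records the package version, timestamp, seed and full parameter echo as
#' JSON next to a data file, so every output is traceable to its
#' configuration.
#'
#' @param path path of the data file (the sidecar gets `.meta.json`
#'   appended)
#' @param params list of parameters to echo
#' @param seed the seed used
#' @return the sidecar path, invisibly
#' @export
write_run_metadata <- function(path, params, seed = NULL) {
  meta <- list(
    package = "scalepp",
    version = as.character(utils::packageVersion("scalepp")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = params
  )
  out <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, out, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(out)
}
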