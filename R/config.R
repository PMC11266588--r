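#' Read and write run configuration
#'
#' A plain-text YAML configuration carrying every exposed tunable of the
#' pipeline (segmentation iterations, window size, seed-circle radius,
#' level-set weights, filter and enhancement parameters).  Unknown keys are
#' rejected so that typos cannot silently fall back to defaults.  A
#' two-column parameter/value spreadsheet (`.xlsx`, the segmentation
#' parameter sheet convention) or an equivalent `.csv` is accepted as an
#' alternative source.
#'
#' @param path A `.yaml`/`.yml` file, or a `.xlsx`/`.csv` parameter/value
#'   table.
#' @return A named list of class `run_config` with elements `lgdf`
#'   ([lgdf_params()]), `filter` ([filter_params()]) and `enhance`
#'   ([enhancement_params()]).
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext %in% c("xlsx", "csv")) {
    tbl <- if (ext == "csv") readr::read_csv(path, show_col_types = FALSE)
           else {
             if (!requireNamespace("readxl", quietly = TRUE))
               abort("reading .xlsx requires the readxl package")
             readxl::read_excel(path)
           }
    names(tbl) <- tolower(names(tbl))
    if (!all(c("parameter", "value") %in% names(tbl))) {
      abort("parameter sheet needs 'parameter' and 'value' columns")
    }
    setNames(as.list(as.numeric(tbl$value)), tolower(tbl$parameter))
  } else {
    abort(sprintf("unsupported config format '.%s'", ext))
  }
  build_run_config(raw)
}

.config_keys <- list(
  lgdf = c("kernel_sigma", "kernel_radius", "epsilon", "nu", "mu", "dt",
           "iterations", "seed_radius", "c0", "var_floor"),
  filter = c("sigma_r", "sigma_s", "window", "median_kernel"),
  enhance = c("alpha", "beta", "gamma_offset", "smooth_sigma_x", "b_min",
              "clahe_clip", "clahe_tiles", "crop_threshold")
)

build_run_config <- function(raw) {
  known <- c(unlist(.config_keys), "verbosity")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  pick <- function(keys) raw[intersect(keys, names(raw))]
  lg <- pick(setdiff(.config_keys$lgdf, "seed_radius"))
  lgdf <- do.call(lgdf_params, lg)
  if (!is.null(raw$seed_radius)) lgdf$seed_radius <- raw$seed_radius
  structure(list(
    lgdf = lgdf,
    filter = do.call(filter_params, pick(.config_keys$filter)),
    enhance = do.call(enhancement_params, pick(.config_keys$enhance)),
    verbosity = raw$verbosity %||% 1
  ), class = "run_config")
}

#' @rdname read_run_config
#' @param config A `run_config` (or the parameter lists to assemble into
#'   one).
#' @export
write_run_config <- function(config, path) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config")
  flat <- c(
    config$lgdf[setdiff(.config_keys$lgdf, "seed_radius")],
    list(seed_radius = config$lgdf$seed_radius),
    config$filter[.config_keys$filter],
    config$enhance[.config_keys$enhance],
    list(verbosity = config$verbosity)
  )
  flat <- flat[!vapply(flat, is.null, logical(1))]
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Default run configuration
#' @rdname read_run_config
#' @export
default_run_config <- function() build_run_config(list())
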