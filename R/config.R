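#' The package's model constants as one configuration record
#'
#' All numeric conventions live in a single record: the fixed left-branch
#' width, the standard reference CSF, the AUC integration interval and grid
#' density, the sensitivity floor behind the semisaturation rule, the default
#' protocol timing, the HRF basis constants, the coarse grid, and the
#' inclusion threshold. The record round-trips through JSON or YAML, so a run
#' can be reproduced from its serialized configuration alone.
#'
#' @param ... Named overrides of individual entries.
#' @return A named list of class `ncsf_config`.
#' @examples
#' ncsf_config()$standard_csf
#' @export
ncsf_config <- function(...) {
  base <- list(
    width_l = 0.68,
    standard_csf = list(cs_p = 166, sf_p = 2.5, width_l = 0.68, width_r = 1.28),
    auc_interval = c(0.5, 18),
    auc_points = 200,
    sensitivity_floor = 1e-6,
    contrast_range = c(0.25, 80),
    contrast_lower_divisor = 4,
    tr = 1.5,
    sf_set = c(0.5, 1, 3, 6, 12, 18),
    block_s = 18,
    blank_s = 15,
    order_seed = 42,
    hrf = list(coef_canonical = 1, coef_derivative = 1, coef_dispersion = 0,
               peak_s = 6, undershoot_s = 16, ratio = 6, duration_s = 32),
    grid = list(sf_p = c(0.25, 18, 12), cs_p = c(5, 500, 10),
                width_r = c(0.3, 3, 8), slope_crf = c(0.5, 8, 6)),
    r2_threshold = 30,
    noise_scales = c(0.4, 0.7, 1.1),
    n_reps = 100,
    michelson_to_rms = FALSE
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(base))
  if (length(bad) > 0) abort(sprintf("unknown configuration entries: %s", paste(bad, collapse = ", ")))
  structure(modifyList(base, overrides), class = "ncsf_config")
}

#' Serialize and restore a configuration
#'
#' JSON (`.json`) or YAML (`.yaml`/`.yml`) by file extension.
#'
#' @param config An [ncsf_config()].
#' @param path Output/input path.
#' @return `write_ncsf_config()` returns `path` invisibly;
#'   `read_ncsf_config()` returns an `ncsf_config`.
#' @export
write_ncsf_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    rlang::check_installed("yaml", reason = "to write YAML configurations")
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_ncsf_config
#' @export
read_ncsf_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    rlang::check_installed("yaml", reason = "to read YAML configurations")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(ncsf_config, raw)
}
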