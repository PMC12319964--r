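#' Tidy a voxelwise fit table
#'
#' Pivots an [fit_dataset()] result into one row per (unit, parameter), the
#' long form convenient for grouped summaries and plotting.
#'
#' @param x An `ncsf_fit` tibble.
#' @param parameters Columns to pivot.
#' @param ... Unused, for generic consistency.
#' @return A tibble with columns `unit_id`, `parameter`, `estimate`, `r2`,
#'   `included`.
#' @export
tidy.ncsf_fit <- function(x, parameters = c("sf_p", "cs_p", "width_r",
                                            "slope_crf", "amplitude",
                                            "baseline", "auc_normalized"),
                          ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(dplyr::all_of(parameters), names_to = "parameter",
                        values_to = "estimate") |>
    dplyr::select(dplyr::all_of(c("unit_id", "parameter", "estimate", "r2",
                                  "included")))
}

#' One-row summary of a voxelwise fit table
#'
#' @param x An `ncsf_fit` tibble.
#' @param ... Unused.
#' @return A one-row tibble: unit counts, inclusion counts at the threshold,
#'   median and maximum variance explained, and convergence rate of the fine
#'   stage.
#' @export
glance.ncsf_fit <- function(x, ...) {
  tibble::tibble(
    n_units = nrow(x),
    n_included = sum(x$included, na.rm = TRUE),
    r2_threshold = attr(x, "r2_threshold") %||% NA_real_,
    median_r2 = median(x$r2, na.rm = TRUE),
    max_r2 = max(x$r2, na.rm = TRUE),
    prop_converged = mean(x$converged, na.rm = TRUE)
  )
}
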