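#' Plot contrast sensitivity functions
#'
#' Sensitivity versus spatial frequency on log-log axes for one or more CSFs,
#' the standard way these curves are drawn.
#'
#' @param ... Named [csf_params()] or [ncsf_model()] objects (names label the
#'   curves).
#' @param sf_range Spatial-frequency range in cycles/degree.
#' @param n Curve resolution.
#' @return A ggplot object.
#' @examples
#' plot_csf(standard = standard_csf(),
#'          green = csf_params(150, 1, 1.3))
#' @export
plot_csf <- function(..., sf_range = c(0.25, 36), n = 200) {
  models <- list(...)
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- paste0("csf_", seq_along(models))
  }
  sf <- logspace(sf_range[1], sf_range[2], n)
  df <- purrr::imap_dfr(models, function(m, nm) {
    if (inherits(m, "ncsf_params")) m <- m$csf
    tibble::tibble(model = nm, sf = sf,
                   sensitivity = csf_sensitivity(m, sf))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$sf, .data$sensitivity,
                                   color = .data$model)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "spatial frequency (c/deg)",
                  y = "contrast sensitivity (100 / threshold %)",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ncsf_design <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$onset_s, .data$contrast_pct,
                                   fill = factor(.data$sf_cpd))) +
    ggplot2::geom_col(width = attr(object, "tr")) +
    ggplot2::labs(x = "time (s)", y = "Michelson contrast (%)",
                  fill = "SF (c/deg)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ncsf_prediction <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object), c("drive", "bold"),
    names_to = "component", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$onset_s, .data$value,
                                   color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "signal (% change)", color = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ncsf_fit <- function(object, ...) {
  df <- tibble::as_tibble(object)
  thr <- attr(object, "r2_threshold") %||% 30
  ggplot2::ggplot(df, ggplot2::aes(.data$r2, fill = .data$included)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::geom_vline(xintercept = thr, linetype = 2) +
    ggplot2::labs(x = "variance explained (%)", y = "units",
                  fill = sprintf("r2 > %g%%", thr)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ncsf_recovery <- function(object, ...) {
  df <- tibble::as_tibble(object)
  x_var <- if ("category" %in% names(df)) "category" else if ("noise_scale" %in% names(df)) "noise_scale" else "truth"
  p <- ggplot2::ggplot(df, ggplot2::aes(factor(.data[[x_var]]), .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q25, ymax = .data$q75)) +
    ggplot2::labs(x = x_var, y = "recovered value (median, IQR)") +
    ggplot2::theme_minimal()
  if ("truth_value" %in% names(df)) {
    p <- p + ggplot2::geom_hline(ggplot2::aes(yintercept = .data$truth_value),
                                 linetype = 2, color = "grey40")
  }
  facets <- intersect(c("truth", "parameter"), names(df))
  if (length(facets) > 0) {
    p <- p + ggplot2::facet_wrap(facets, scales = "free_y")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
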