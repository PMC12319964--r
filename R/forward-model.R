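#' Two-gamma hemodynamic response basis
#'
#' Specification of the hemodynamic response function (HRF) as a weighted sum
#' of the canonical double-gamma response, its temporal derivative, and its
#' dispersion derivative. The default weights (1, 1, 0) add the temporal
#' derivative to the canonical shape and omit the dispersion term; the HRF is
#' held fixed during model fitting. The canonical is
#' \deqn{g(t) = \Gamma(t; \alpha_1, 1) - \Gamma(t; \alpha_2, 1) / r}
#' with peak delay `peak_s` (= \eqn{\alpha_1}, mode at `peak_s - 1` s),
#' undershoot delay `undershoot_s`, and peak/undershoot ratio `ratio`. The
#' temporal derivative is a finite difference of `g` over `deriv_dt` seconds;
#' the dispersion derivative is a central finite difference with respect to
#' the dispersion (time-scaling) parameter.
#'
#' @param coef_canonical,coef_derivative,coef_dispersion Basis weights
#'   (defaults 1, 1, 0).
#' @param peak_s Shape of the peak gamma (default 6; the canonical then peaks
#'   at 5 s).
#' @param undershoot_s Shape of the undershoot gamma (default 16).
#' @param ratio Peak-to-undershoot amplitude ratio (default 6).
#' @param duration_s Kernel support in seconds (default 32).
#' @param deriv_dt Time step of the derivative finite differences (default 0.1 s).
#' @return An object of class `ncsf_hrf`.
#' @examples
#' hrf_spec() # the fixed HRF used throughout
#' @export
hrf_spec <- function(coef_canonical = 1, coef_derivative = 1,
                     coef_dispersion = 0, peak_s = 6, undershoot_s = 16,
                     ratio = 6, duration_s = 32, deriv_dt = 0.1) {
  stop_not_positive(peak_s, "peak_s")
  stop_not_positive(undershoot_s, "undershoot_s")
  stop_not_positive(ratio, "ratio")
  stop_not_positive(duration_s, "duration_s")
  structure(
    list(
      coef_canonical = coef_canonical, coef_derivative = coef_derivative,
      coef_dispersion = coef_dispersion, peak_s = peak_s,
      undershoot_s = undershoot_s, ratio = ratio, duration_s = duration_s,
      deriv_dt = deriv_dt
    ),
    class = "ncsf_hrf"
  )
}

#' @export
print.ncsf_hrf <- function(x, ...) {
  cat(sprintf(
    "<ncsf_hrf> coefficients (canonical, derivative, dispersion) = (%g, %g, %g); peak %g s, undershoot %g s, ratio %g, support %g s\n",
    x$coef_canonical, x$coef_derivative, x$coef_dispersion,
    x$peak_s, x$undershoot_s, x$ratio, x$duration_s
  ))
  invisible(x)
}

# continuous double-gamma; `dispersion` scales time
double_gamma <- function(t, peak_s, undershoot_s, ratio, dispersion = 1) {
  dgamma(t / dispersion, shape = peak_s, rate = 1) -
    dgamma(t / dispersion, shape = undershoot_s, rate = 1) / ratio
}

#' Sample the HRF kernel on the volume grid
#'
#' Evaluates the weighted two-gamma basis of an [hrf_spec()] at multiples of
#' the repetition time, over the kernel support. The kernel is normalized so
#' the canonical component has unit peak, keeping predicted amplitudes
#' interpretable in percent signal change. All-zero coefficients give an
#' all-zero kernel.
#'
#' @param hrf An `ncsf_hrf` object.
#' @param tr Repetition time in seconds (> 0).
#' @return Numeric vector of kernel samples at `t = 0, tr, 2 tr, ...`.
#' @examples
#' k <- hrf_kernel(hrf_spec(coef_derivative = 0), tr = 0.1)
#' (which.max(k) - 1) * 0.1 # canonical peak near 5 s
#' @export
hrf_kernel <- function(hrf, tr) {
  if (!inherits(hrf, "ncsf_hrf")) abort("`hrf` must be an `ncsf_hrf` object.")
  stop_not_positive(tr, "tr")
  t <- seq(0, hrf$duration_s, by = tr)
  g <- function(tt, disp = 1) {
    double_gamma(tt, hrf$peak_s, hrf$undershoot_s, hrf$ratio, disp)
  }
  canonical <- g(t)
  dt <- hrf$deriv_dt
  derivative <- (g(t) - g(t - dt)) / dt
  dd <- 0.01
  dispersion <- (g(t, 1 + dd) - g(t, 1 - dd)) / (2 * dd)
  kernel <- hrf$coef_canonical * canonical +
    hrf$coef_derivative * derivative +
    hrf$coef_dispersion * dispersion
  peak <- max(abs(canonical))
  if (peak > 0) kernel <- kernel / peak
  kernel
}

# causal linear convolution truncated to length(x); zero-padded past
convolve_causal <- function(x, kernel) {
  n <- length(x)
  full <- stats::convolve(x, rev(kernel), type = "open")
  full[seq_len(n)]
}

# lower-triangular Toeplitz matrix T with (T %*% drive)[t] = sum_k kernel[k] drive[t-k+1];
# used to convolve many candidate drives in one matrix product
convolution_matrix <- function(kernel, n) {
  k <- length(kernel)
  out <- matrix(0, n, n)
  for (j in seq_len(n)) {
    i <- j:min(n, j + k - 1)
    out[i, j] <- kernel[seq_along(i)]
  }
  out
}

# per-volume neural drive of a model under a design (blanks -> 0)
neural_drive <- function(params, design) {
  drive <- numeric(nrow(design))
  on <- design$contrast_pct > 0
  if (any(on)) {
    drive[on] <- ncsf_response(params, design$sf_cpd[on], design$contrast_pct[on])
  }
  drive
}

#' Predict a BOLD time series from an nCSF model
#'
#' The forward model: the per-volume neural drive is the nCSF response to the
#' grating shown in that volume (zero during mean-luminance blanks); the
#' drive is convolved with the HRF kernel (causal, zero-padded before the run
#' start, truncated to the run length) and the baseline is added.
#'
#' @param params An [ncsf_model()] object.
#' @param design An `ncsf_design` from [build_design()] or [read_design()].
#' @param hrf An [hrf_spec()] (default: the fixed canonical + derivative HRF).
#' @return A tibble of class `ncsf_prediction` with columns `volume`,
#'   `onset_s`, `drive` (pre-hemodynamic response) and `bold` (percent signal
#'   change); attributes carry the generating parameters, design metadata and
#'   HRF.
#' @examples
#' d <- build_design()
#' m <- ncsf_model(cs_p = 150, sf_p = 1, width_r = 1.3, slope_crf = 3)
#' p <- predict_timeseries(m, d)
#' head(p)
#' @export
predict_timeseries <- function(params, design, hrf = hrf_spec()) {
  if (!inherits(params, "ncsf_params")) abort("`params` must be an `ncsf_params` object.")
  tr <- attr(design, "tr")
  if (is.null(tr)) abort("`design` carries no repetition time; build it with `build_design()` or `read_design()`.")
  kernel <- hrf_kernel(hrf, tr)
  drive <- neural_drive(params, design)
  bold <- params$baseline + convolve_causal(drive, kernel)
  structure(
    tibble::tibble(
      volume = design$volume,
      onset_s = design$onset_s,
      drive = drive,
      bold = bold
    ),
    params = params, tr = tr, hrf = hrf,
    class = c("ncsf_prediction", class(tibble::tibble()))
  )
}
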