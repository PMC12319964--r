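#' Contrast sensitivity function parameters
#'
#' Construct the parameter set of the asymmetric log-parabolic contrast
#' sensitivity function (CSF). Sensitivity is defined as 100 divided by the
#' contrast threshold in percent, so a sensitivity of 200 corresponds to a
#' 0.5% contrast threshold. In log10 sensitivity versus log10 spatial
#' frequency the curve is a parabola with its apex at (`sf_p`, `cs_p`) and
#' separate fall-off rates for the two branches; a larger width means a
#' *faster* drop in sensitivity, i.e. a narrower curve.
#'
#' @param cs_p Peak contrast sensitivity (dimensionless, > 0).
#' @param sf_p Peak spatial frequency in cycles/degree (> 0).
#' @param width_r Fall-off rate of the right (high spatial frequency) branch,
#'   in log10 units (> 0).
#' @param width_l Fall-off rate of the left branch. Fixed at 0.68 by default;
#'   low spatial frequencies are poorly constrained by typical stimulus
#'   protocols, so this branch is conventionally not fitted.
#' @return An object of class `csf_params`.
#' @examples
#' standard_csf()
#' csf_params(cs_p = 150, sf_p = 1, width_r = 1.3)
#' @export
csf_params <- function(cs_p, sf_p, width_r, width_l = 0.68) {
  stop_not_positive(cs_p, "cs_p")
  stop_not_positive(sf_p, "sf_p")
  stop_not_positive(width_r, "width_r")
  stop_not_positive(width_l, "width_l")
  structure(
    list(cs_p = cs_p, sf_p = sf_p, width_r = width_r, width_l = width_l),
    class = "csf_params"
  )
}

#' @export
print.csf_params <- function(x, ...) {
  cat(sprintf(
    "<csf_params> cs_p = %g, sf_p = %g c/deg, width_r = %g, width_l = %g\n",
    x$cs_p, x$sf_p, x$width_r, x$width_l
  ))
  invisible(x)
}

#' The standard reference CSF
#'
#' The healthy-control reference CSF (peak sensitivity 166 at 2.5 c/deg,
#' left/right fall-off 0.68/1.28) used to normalize the area under the curve
#' and to anchor the default per-frequency contrast sampling grid.
#'
#' @return A [csf_params] object.
#' @export
standard_csf <- function() {
  csf_params(cs_p = 166, sf_p = 2.5, width_r = 1.28, width_l = 0.68)
}

#' Evaluate the asymmetric log-parabolic CSF
#'
#' Contrast sensitivity at one or more spatial frequencies. All parameters are
#' given in linear units; internally the parabola lives in log10-log10 space:
#' \deqn{f(SF) = 10^{\log_{10} CS_p - (\log_{10} SF - \log_{10} SF_p)^2 \, w^2}}
#' with \eqn{w = width_L} for \eqn{SF < SF_p} and \eqn{w = width_R} otherwise.
#' The curve is continuous at the peak and attains its maximum `cs_p` exactly
#' at `sf_p`.
#'
#' @param params A [csf_params] object.
#' @param sf Spatial frequencies in cycles/degree (all > 0); vectorized.
#' @return Numeric vector of sensitivities, same length as `sf`.
#' @examples
#' csf_sensitivity(standard_csf(), c(0.5, 2.5, 18))
#' @export
csf_sensitivity <- function(params, sf) {
  if (!inherits(params, "csf_params")) abort("`params` must be a `csf_params` object.")
  if (!is.numeric(sf) || length(sf) == 0L || any(!is.finite(sf)) || any(sf <= 0)) {
    abort("`sf` must be positive and finite (cycles/degree).")
  }
  w <- ifelse(sf < params$sf_p, params$width_l, params$width_r)
  10^(log10(params$cs_p) - (log10(sf) - log10(params$sf_p))^2 * w^2)
}

#' Naka-Rushton contrast response function
#'
#' Response as a function of stimulus contrast,
#' \deqn{R(C) = a \, C^q / (C^q + Q^q),}
#' a saturating sigmoid on a log-contrast axis. `Q` is the semisaturation
#' contrast (the response is `a/2` at `C = Q`), `q` the slope of the rising
#' limb, and `a` the saturated amplitude. The response is 0 at zero contrast
#' and approaches (never reaches) `a`.
#'
#' @param contrast Contrast in percent (>= 0); vectorized.
#' @param q Slope exponent (> 0).
#' @param Q Semisaturation contrast in percent (> 0); vectorized or scalar.
#' @param a Response amplitude (> 0), in percent signal change at saturation.
#' @return Numeric vector of responses.
#' @examples
#' crf_response(contrast = 10, q = 3, Q = 10) # a/2
#' @export
crf_response <- function(contrast, q, Q, a = 1) {
  if (!is.numeric(contrast) || any(!is.finite(contrast)) || any(contrast < 0)) {
    abort("`contrast` must be finite and >= 0 (percent).")
  }
  stop_not_positive(q, "q")
  if (any(Q <= 0)) abort("`Q` must be > 0.")
  stop_not_positive(a, "a")
  cq <- contrast^q
  out <- a * cq / (cq + Q^q)
  out[contrast == 0] <- 0 # avoid 0/0 when q underflows cq and Qq together
  out
}

#' Semisaturation contrast implied by a CSF
#'
#' Maps contrast sensitivity at a spatial frequency to the semisaturation
#' contrast `Q` of the contrast response function. The default rule is
#' `Q(sf) = 100 / f(sf)`: since sensitivity is 100 / threshold-contrast, `Q`
#' is the CSF-implied threshold contrast at that frequency, so the response
#' reaches half its amplitude exactly at the behavioral threshold. Sensitivity
#' is floored at a small positive epsilon before division to keep `Q` finite
#' far from the peak; floored evaluations are flagged via the
#' `"floored"` attribute.
#'
#' @param params A [csf_params] object.
#' @param sf Spatial frequencies in cycles/degree (> 0); vectorized.
#' @param floor Sensitivity floor (default 1e-6).
#' @return Numeric vector of semisaturation contrasts (percent), with
#'   attribute `floored` (logical vector) when any evaluation was clamped.
#' @export
semisaturation_from_csf <- function(params, sf, floor = 1e-6) {
  sens <- csf_sensitivity(params, sf)
  clamped <- sens < floor
  q50 <- 100 / pmax(sens, floor)
  if (any(clamped)) attr(q50, "floored") <- clamped
  q50
}

#' Full nCSF voxel model
#'
#' Bundle the CSF, the contrast response function and an additive baseline
#' into one voxel model. The semisaturation contrast of the CRF is derived
#' from the CSF through a pluggable rule (default: the CSF-implied threshold,
#' see [semisaturation_from_csf()]).
#'
#' @param cs_p,sf_p,width_r,width_l CSF parameters, see [csf_params()].
#' @param slope_crf Naka-Rushton slope exponent (> 0).
#' @param amplitude Response amplitude in percent signal change (> 0).
#' @param baseline Additive offset in percent signal change.
#' @param q_rule Function `(csf_params, sf) -> Q` mapping the CSF to the
#'   semisaturation contrast.
#' @return An object of class `ncsf_params`.
#' @examples
#' ncsf_model(cs_p = 150, sf_p = 1, width_r = 1.3, slope_crf = 3)
#' @export
ncsf_model <- function(cs_p, sf_p, width_r, slope_crf,
                       amplitude = 1, baseline = 0, width_l = 0.68,
                       q_rule = semisaturation_from_csf) {
  stop_not_positive(slope_crf, "slope_crf")
  stop_not_positive(amplitude, "amplitude")
  stop_not_scalar(baseline, "baseline")
  structure(
    list(
      csf = csf_params(cs_p, sf_p, width_r, width_l),
      slope_crf = slope_crf,
      amplitude = amplitude,
      baseline = baseline,
      q_rule = q_rule
    ),
    class = "ncsf_params"
  )
}

#' @export
print.ncsf_params <- function(x, ...) {
  cat(sprintf(
    "<ncsf_params> cs_p = %g, sf_p = %g c/deg, width_r = %g, slope_crf = %g, amplitude = %g, baseline = %g\n",
    x$csf$cs_p, x$csf$sf_p, x$csf$width_r, x$slope_crf, x$amplitude, x$baseline
  ))
  invisible(x)
}

#' Neural response of the nCSF model to a grating
#'
#' Composes the CSF-implied semisaturation contrast with the Naka-Rushton
#' response: the pre-hemodynamic neural drive of a voxel viewing a grating of
#' a given spatial frequency and contrast. Zero contrast yields zero response.
#'
#' @param params An [ncsf_model()] object.
#' @param sf Spatial frequency in cycles/degree (> 0); vectorized.
#' @param contrast Contrast in percent (>= 0); vectorized (recycled against `sf`).
#' @return Numeric vector of responses in percent signal change (before
#'   convolution with the hemodynamic response; excludes the baseline).
#' @examples
#' m <- ncsf_model(cs_p = 100, sf_p = 2, width_r = 1, slope_crf = 3)
#' ncsf_response(m, sf = 2, contrast = c(0, 1, 80))
#' @export
ncsf_response <- function(params, sf, contrast) {
  if (!inherits(params, "ncsf_params")) abort("`params` must be an `ncsf_params` object.")
  q50 <- params$q_rule(params$csf, sf)
  crf_response(contrast, q = params$slope_crf, Q = as.numeric(q50),
               a = params$amplitude)
}

#' Normalized area under the log CSF
#'
#' Summary metric of the full CSF: the area under max(0, log10 sensitivity)
#' over log10 spatial frequency on `[sf_lo, sf_hi]`, expressed as a percent of
#' the same area for the standard reference CSF ([standard_csf()]). Clamping
#' log sensitivity at zero counts only the area above the sensitivity = 1
#' axis, keeping the metric nonnegative. Integration uses the trapezoid rule
#' on `n` log-spaced points; the integrand is smooth, so 200 points put the
#' quadrature error well below reporting precision.
#'
#' @param params A [csf_params] object (or an [ncsf_model()], whose CSF part
#'   is used).
#' @param sf_lo,sf_hi Integration interval in cycles/degree, default 0.5-18
#'   (the stimulus range).
#' @param n Number of quadrature points (default 200).
#' @param reference Reference CSF defining 100%, default [standard_csf()].
#' @return A one-row tibble with columns `auc_raw` (log-sensitivity x log-SF
#'   units), `auc_reference`, and `auc_normalized` (percent).
#' @examples
#' auc_normalized(standard_csf())$auc_normalized # exactly 100
#' @export
auc_normalized <- function(params, sf_lo = 0.5, sf_hi = 18, n = 200,
                           reference = standard_csf()) {
  if (inherits(params, "ncsf_params")) params <- params$csf
  stop_not_positive(sf_lo, "sf_lo")
  stop_not_positive(sf_hi, "sf_hi")
  if (sf_hi <= sf_lo) abort("`sf_hi` must exceed `sf_lo`.")
  raw <- auc_log_csf(params, sf_lo, sf_hi, n)
  ref <- auc_log_csf(reference, sf_lo, sf_hi, n)
  tibble::tibble(
    auc_raw = raw,
    auc_reference = ref,
    auc_normalized = 100 * raw / ref
  )
}

# trapezoid integral of clamped log10 sensitivity over log10 sf
auc_log_csf <- function(params, sf_lo, sf_hi, n) {
  x <- seq(log10(sf_lo), log10(sf_hi), length.out = n)
  y <- pmax(0, log10(csf_sensitivity(params, 10^x)))
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
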