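# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# the default 321 s protocol (deterministic)
default_design <- function() {
  if (is.null(.fixtures$design)) .fixtures$design <- build_design()
  .fixtures$design
}

# a coarse grid small enough for exhaustive cross-checks
small_grid <- function() {
  fit_grid(
    sf_p = c(0.5, 1, 2),
    cs_p = c(50, 100, 150),
    width_r = c(0.7, 1, 1.3),
    slope_crf = c(1.5, 3, 6)
  )
}

# the two ground-truth validation models
green_model <- function() ncsf_model(cs_p = 150, sf_p = 1, width_r = 1.3, slope_crf = 3)
red_model <- function() ncsf_model(cs_p = 100, sf_p = 2, width_r = 1, slope_crf = 3)

# noiseless BOLD prediction of a model under the default protocol
noiseless_bold <- function(model) predict_timeseries(model, default_design())$bold
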