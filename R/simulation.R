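#' Configuration of the parameter-recovery simulation
#'
#' Describes a ground-truth recovery experiment: a set of known nCSF models,
#' a set of noise scales, and a replicate count. The default ground truths
#' are the two validation models — "green" (peak sensitivity 150 at 1 c/deg,
#' right width 1.3) and "red" (peak sensitivity 100 at 2 c/deg, right width
#' 1) — each with CRF slope 3, unit amplitude and zero baseline. Each
#' synthetic voxel is the noiseless forward prediction, normalized to unit
#' standard deviation, plus standard-normal noise multiplied by a scale
#' factor (defaults 0.4, 0.7, 1.1), so the scales read as noise-to-signal
#' ratios. 100 replicates per (truth, scale) condition by default.
#'
#' @param truths Named list of [ncsf_model()] ground truths.
#' @param noise_scales Numeric vector of noise standard deviations relative
#'   to the unit-variance signal.
#' @param n_reps Replicates per condition (default 100).
#' @param seed Master seed; per-replicate noise streams are derived
#'   deterministically from it and the (truth, scale, replicate) indices.
#' @param design Stimulus design (default [build_design()]).
#' @param hrf HRF specification (default [hrf_spec()]).
#' @param normalize How the noiseless prediction is normalized before noise is
#'   added: `"sd"` (default, unit standard deviation), `"peak"` (unit maximum
#'   absolute amplitude), or `"none"`.
#' @return An object of class `ncsf_sim_config`.
#' @export
simulation_config <- function(
    truths = list(
      green = ncsf_model(cs_p = 150, sf_p = 1, width_r = 1.3, slope_crf = 3),
      red = ncsf_model(cs_p = 100, sf_p = 2, width_r = 1, slope_crf = 3)
    ),
    noise_scales = c(0.4, 0.7, 1.1),
    n_reps = 100, seed = 1,
    design = build_design(), hrf = hrf_spec(),
    normalize = c("sd", "peak", "none")) {
  if (n_reps < 1) abort("`n_reps` must be >= 1.")
  if (any(noise_scales < 0)) abort("`noise_scales` must be >= 0.")
  if (is.null(names(truths)) || any(names(truths) == "")) {
    names(truths) <- paste0("truth_", seq_along(truths))
  }
  structure(
    list(truths = truths, noise_scales = noise_scales, n_reps = n_reps,
         seed = seed, design = design, hrf = hrf,
         normalize = match.arg(normalize)),
    class = "ncsf_sim_config"
  )
}

#' Generate synthetic voxels from known ground truths
#'
#' For every (truth, noise scale) condition, the noiseless BOLD prediction of
#' the ground-truth model is computed once, scaled to unit standard
#' deviation, and `n_reps` noisy replicates are drawn by adding
#' standard-normal noise times the scale factor. Replicate noise streams are
#' seeded from the master seed and the condition/replicate indices, so the
#' same configuration always reproduces the same dataset and individual
#' voxels can be regenerated in isolation.
#'
#' @param config An [simulation_config()] object.
#' @return A list of class `ncsf_simulation`: `ts` (voxels x volumes matrix),
#'   `voxels` (tibble with `unit_id`, `truth`, `noise_scale`, `rep`),
#'   `config`.
#' @export
simulate_voxels <- function(config) {
  if (!inherits(config, "ncsf_sim_config")) abort("`config` must come from `simulation_config()`.")
  design <- config$design
  n_vol <- nrow(design)
  meta <- tidyr::expand_grid(
    truth = names(config$truths),
    noise_scale = config$noise_scales,
    rep = seq_len(config$n_reps)
  )
  signals <- lapply(config$truths, function(m) {
    bold <- predict_timeseries(m, design, config$hrf)$bold
    s <- switch(config$normalize %||% "sd",
                sd = sd(bold), peak = max(abs(bold)), none = 1)
    if (s == 0) abort("ground-truth prediction has zero variance; check the model and design.")
    bold / s
  })
  ts <- matrix(NA_real_, nrow(meta), n_vol)
  for (i in seq_len(nrow(meta))) {
    ti <- match(meta$truth[i], names(config$truths))
    si <- match(meta$noise_scale[i], config$noise_scales)
    sub_seed <- derive_seed(config$seed, ti, si, meta$rep[i])
    noise <- with_seed(sub_seed, rnorm(n_vol))
    ts[i, ] <- signals[[ti]] + meta$noise_scale[i] * noise
  }
  meta$unit_id <- sprintf("%s_s%g_r%03d", meta$truth, meta$noise_scale, meta$rep)
  rownames(ts) <- meta$unit_id
  structure(
    list(ts = ts, voxels = meta[c("unit_id", "truth", "noise_scale", "rep")],
         config = config),
    class = "ncsf_simulation"
  )
}

#' @export
print.ncsf_simulation <- function(x, ...) {
  cat(sprintf(
    "<ncsf_simulation> %d synthetic voxels x %d volumes (%d truths x %d noise scales x %d reps, seed %d)\n",
    nrow(x$ts), ncol(x$ts), length(x$config$truths),
    length(x$config$noise_scales), x$config$n_reps, x$config$seed
  ))
  invisible(x)
}

#' Classify fits by variance explained
#'
#' Bins variance-explained values into the validation categories using
#' half-open intervals: high `[50, Inf)`, medium `[30, 50)`, low `[10, 30)`,
#' excluded `(-Inf, 10)`. Boundary values are assigned upward (an r2 of
#' exactly 50 is "high"). Non-finite values are excluded.
#'
#' @param r2 Numeric vector of variance-explained values in percent (e.g.
#'   the `r2` column of an [fit_dataset()] result).
#' @param bounds Ascending category edges, default `c(10, 30, 50)`.
#' @return Factor with levels `excluded`, `low`, `medium`, `high`.
#' @examples
#' categorize_by_r2(c(55, 50, 35, 12, 5))
#' @export
categorize_by_r2 <- function(r2, bounds = c(10, 30, 50)) {
  labels <- c("excluded", "low", "medium", "high")
  idx <- findInterval(r2, bounds, left.open = FALSE) + 1L
  idx[!is.finite(r2)] <- 1L
  factor(labels[idx], levels = labels)
}

#' Summarize parameter recovery
#'
#' Joins ground-truth metadata to fitted results and reports, per group
#' (default: truth x variance-explained category), the median and 25th/75th
#' percentiles of every recovered parameter and of the derived normalized
#' AUC, together with the ground-truth values and replicate counts. Empty
#' groups are simply absent from the table. Counts per (truth, noise scale)
#' across categories — including the excluded bin — always sum to the
#' replicate count.
#'
#' @param sim An `ncsf_simulation` from [simulate_voxels()].
#' @param fits An `ncsf_fit` table from [fit_dataset()] on `sim$ts`.
#' @param by Grouping columns, any of `"truth"`, `"noise_scale"`,
#'   `"category"` (default `c("truth", "category")`).
#' @param parameters Which recovered quantities to summarize.
#' @return A tibble of class `ncsf_recovery`, long over `parameter`, with
#'   columns `truth_value`, `median`, `q25`, `q75`, `n`.
#' @export
recovery_report <- function(sim, fits, by = c("truth", "category"),
                            parameters = c("sf_p", "cs_p", "width_r",
                                           "slope_crf", "auc_normalized")) {
  if (!inherits(sim, "ncsf_simulation")) abort("`sim` must come from `simulate_voxels()`.")
  by <- match.arg(by, c("truth", "noise_scale", "category"), several.ok = TRUE)
  truth_tbl <- purrr::imap_dfr(sim$config$truths, function(m, nm) {
    tibble::tibble(
      truth = nm,
      parameter = parameters,
      truth_value = vapply(parameters, function(p) {
        switch(p,
          sf_p = m$csf$sf_p, cs_p = m$csf$cs_p, width_r = m$csf$width_r,
          slope_crf = m$slope_crf, amplitude = m$amplitude,
          baseline = m$baseline,
          auc_normalized = auc_normalized(m$csf)$auc_normalized
        )
      }, numeric(1), USE.NAMES = FALSE)
    )
  })
  joined <- dplyr::inner_join(sim$voxels, fits, by = "unit_id") |>
    dplyr::mutate(category = categorize_by_r2(.data$r2))
  long <- joined |>
    tidyr::pivot_longer(dplyr::all_of(parameters), names_to = "parameter",
                        values_to = "estimate")
  out <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "parameter")))) |>
    dplyr::summarise(
      n = sum(is.finite(.data$estimate)),
      median = median(.data$estimate, na.rm = TRUE),
      q25 = quantile(.data$estimate, 0.25, na.rm = TRUE, names = FALSE),
      q75 = quantile(.data$estimate, 0.75, na.rm = TRUE, names = FALSE),
      .groups = "drop"
    )
  if ("truth" %in% by) {
    out <- dplyr::left_join(out, truth_tbl, by = c("truth", "parameter")) |>
      dplyr::relocate("truth_value", .after = "parameter")
  }
  structure(
    out,
    seed = sim$config$seed, n_reps = sim$config$n_reps,
    class = c("ncsf_recovery", class(tibble::tibble()))
  )
}
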