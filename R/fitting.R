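#' Coarse-stage parameter grid
#'
#' Candidate values for the four fitted nCSF parameters, scanned exhaustively
#' in the coarse stage. Defaults: peak spatial frequency log-spaced over the
#' stimulus range 0.25-18 c/deg (12 nodes), peak sensitivity log-spaced
#' 5-500 (10), right-branch width 0.3-3 (8), CRF slope log-spaced 0.5-8 (6) —
#' 5760 nodes. Bounds for the fine stage default to the grid extremes.
#'
#' @param sf_p,cs_p,width_r,slope_crf Numeric vectors of candidate values.
#' @param bounds Optional named list of `c(lower, upper)` per parameter;
#'   defaults to the range of each axis.
#' @return An object of class `ncsf_grid`.
#' @export
fit_grid <- function(sf_p = logspace(0.25, 18, 12),
                     cs_p = logspace(5, 500, 10),
                     width_r = seq(0.3, 3, length.out = 8),
                     slope_crf = logspace(0.5, 8, 6),
                     bounds = NULL) {
  axes <- list(sf_p = sf_p, cs_p = cs_p, width_r = width_r,
               slope_crf = slope_crf)
  for (nm in names(axes)) {
    if (length(axes[[nm]]) == 0 || any(!is.finite(axes[[nm]])) || any(axes[[nm]] <= 0)) {
      abort(sprintf("grid axis `%s` must be nonempty, finite and positive.", nm))
    }
  }
  if (is.null(bounds)) bounds <- lapply(axes, range)
  for (nm in names(axes)) {
    if (any(axes[[nm]] < bounds[[nm]][1] - 1e-12) ||
        any(axes[[nm]] > bounds[[nm]][2] + 1e-12)) {
      abort(sprintf("grid axis `%s` extends outside its bounds.", nm))
    }
  }
  structure(list(axes = axes, bounds = bounds), class = "ncsf_grid")
}

#' @export
print.ncsf_grid <- function(x, ...) {
  n <- prod(vapply(x$axes, length, integer(1)))
  cat(sprintf("<ncsf_grid> %d nodes (%s)\n", n,
              paste(sprintf("%s: %d", names(x$axes),
                            vapply(x$axes, length, integer(1))), collapse = ", ")))
  invisible(x)
}

#' Variance explained by a prediction
#'
#' The coefficient of determination about the data mean, in percent:
#' `100 * (1 - RSS / TSS)`. A perfect prediction scores 100, predicting the
#' mean scores 0, and worse-than-mean predictions are negative. Because TSS
#' depends on the data only, minimizing the residual sum of squares and
#' maximizing variance explained pick the same parameters.
#'
#' @param prediction,data Numeric vectors of equal length (>= 2).
#' @return Variance explained in percent; `NA` with a warning if the data
#'   have zero variance.
#' @examples
#' variance_explained(c(1, 2, 3), c(1, 2, 3)) # 100
#' @export
variance_explained <- function(prediction, data) {
  if (length(prediction) != length(data)) abort("`prediction` and `data` must have equal length.")
  if (length(data) < 2) abort("need at least 2 time points.")
  tss <- sum((data - mean(data))^2)
  if (tss == 0) {
    warn("zero-variance data: variance explained is undefined.")
    return(NA_real_)
  }
  100 * (1 - sum((data - prediction)^2) / tss)
}

# --- shared fitting engine -------------------------------------------------

# Condition table of a design: unique nonzero (sf, contrast) pairs plus a
# per-volume index (0 = blank). Candidate drives need only be evaluated per
# condition, not per volume.
design_conditions <- function(design) {
  on <- design$contrast_pct > 0
  key <- paste(design$sf_cpd, design$contrast_pct)
  conds <- which(on & !duplicated(key))
  idx <- integer(nrow(design))
  idx[on] <- match(key[on], key[conds])
  list(
    sf = design$sf_cpd[conds],
    contrast = design$contrast_pct[conds],
    index = idx
  )
}

# Unit-amplitude, zero-baseline drive of many parameter combinations at the
# design's conditions. Rows = parameter rows, cols = conditions.
condition_drives <- function(sf_p, cs_p, width_r, slope_crf, cond,
                             width_l = 0.68, sens_floor = 1e-6) {
  n_cond <- length(cond$sf)
  out <- matrix(0, length(sf_p), n_cond)
  for (j in seq_len(n_cond)) {
    w <- ifelse(cond$sf[j] < sf_p, width_l, width_r)
    sens <- 10^(log10(cs_p) - (log10(cond$sf[j]) - log10(sf_p))^2 * w^2)
    q50 <- 100 / pmax(sens, sens_floor)
    cq <- cond$contrast[j]^slope_crf
    out[, j] <- cq / (cq + q50^slope_crf)
  }
  out
}

# Everything reusable across voxels for one (design, hrf, grid) triple:
# node table, centered unit predictions and their norms.
fit_engine <- function(design, hrf, grid) {
  tr <- attr(design, "tr")
  if (is.null(tr)) abort("`design` carries no repetition time.")
  kernel <- hrf_kernel(hrf, tr)
  n <- nrow(design)
  cond <- design_conditions(design)
  tmat <- convolution_matrix(kernel, n)

  nodes <- tidyr::expand_grid(
    sf_p = grid$axes$sf_p, cs_p = grid$axes$cs_p,
    width_r = grid$axes$width_r, slope_crf = grid$axes$slope_crf
  )
  drives <- condition_drives(nodes$sf_p, nodes$cs_p, nodes$width_r,
                             nodes$slope_crf, cond)
  dmat <- matrix(0, nrow(nodes), n)
  on <- cond$index > 0
  dmat[, on] <- drives[, cond$index[on], drop = FALSE]
  pred <- dmat %*% t(tmat)
  pmean <- rowMeans(pred)
  pc <- pred - pmean
  pn2 <- rowSums(pc^2)

  list(
    tr = tr, kernel = kernel, tmat = tmat, cond = cond, n = n,
    log_sf = log10(cond$sf),
    nodes = nodes, pred = pred, pmean = pmean, pc = pc, pn2 = pn2,
    bounds = grid$bounds, hrf = hrf
  )
}

# prediction (unit amplitude, zero baseline) for one scalar parameter set;
# vectorized over the design's conditions for speed inside the optimizer
engine_predict_unit <- function(eng, sf_p, cs_p, width_r, slope_crf,
                                width_l = 0.68, sens_floor = 1e-6) {
  w <- ifelse(eng$cond$sf < sf_p, width_l, width_r)
  sens <- 10^(log10(cs_p) - (eng$log_sf - log10(sf_p))^2 * w^2)
  q50 <- 100 / pmax(sens, sens_floor)
  cq <- eng$cond$contrast^slope_crf
  resp <- cq / (cq + q50^slope_crf)
  drive <- numeric(eng$n)
  on <- eng$cond$index > 0
  drive[on] <- resp[eng$cond$index[on]]
  as.numeric(eng$tmat %*% drive)
}

# OLS of data on (intercept, unit prediction): returns amplitude, baseline, rss
solve_linear <- function(p, y) {
  pm <- mean(p)
  pc <- p - pm
  pn2 <- sum(pc^2)
  ym <- mean(y)
  yc <- y - ym
  if (pn2 < 1e-12) {
    return(list(amplitude = 0, baseline = ym, rss = sum(yc^2)))
  }
  a <- sum(pc * yc) / pn2
  list(amplitude = a, baseline = ym - a * pm, rss = sum(yc^2) - a^2 * pn2)
}

# one-row FitResult tibble
fit_row <- function(unit_id, sf_p, cs_p, width_r, slope_crf, amplitude,
                    baseline, rss, r2, r2_grid, stage, converged, flag = "ok") {
  tibble::tibble(
    unit_id = unit_id, sf_p = sf_p, cs_p = cs_p, width_r = width_r,
    slope_crf = slope_crf, amplitude = amplitude, baseline = baseline,
    rss = rss, r2 = r2, r2_grid = r2_grid, stage = stage,
    converged = converged, flag = flag
  )
}

# --- user-facing fits ------------------------------------------------------

#' Coarse grid fit of one voxel
#'
#' Scans every node of the parameter grid; at each node the amplitude and
#' baseline are solved in closed form by ordinary least squares of the
#' unit-amplitude prediction (plus intercept) against the data, and the node
#' with minimal residual sum of squares wins. Ties go to the lowest node
#' index (row order of the expanded grid), making the stage fully
#' deterministic. Negative best-fitting amplitudes are allowed but flagged.
#'
#' @param data Numeric vector: one voxel's time series (same length as the
#'   design).
#' @param design An `ncsf_design`.
#' @param hrf An [hrf_spec()].
#' @param grid An [fit_grid()].
#' @param engine Optional precomputed engine (internal use; built from the
#'   other arguments when `NULL`).
#' @return A one-row tibble (`FitResult`): parameters, `amplitude`,
#'   `baseline`, `rss`, `r2` (percent), `r2_grid`, `stage`, `converged`,
#'   `flag`.
#' @export
grid_fit <- function(data, design, hrf = hrf_spec(), grid = fit_grid(),
                     engine = NULL) {
  eng <- engine %||% fit_engine(design, hrf, grid)
  if (length(data) != eng$n) abort("`data` length must match the design.")
  if (any(!is.finite(data))) {
    return(fit_row("unit", NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
                   NA_real_, NA_real_, NA_real_, NA_real_, "grid", FALSE,
                   flag = "nonfinite_data"))
  }
  ym <- mean(data)
  yc <- data - ym
  tss <- sum(yc^2)
  if (tss == 0) {
    return(fit_row("unit", NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
                   ym, NA_real_, NA_real_, NA_real_, "grid", FALSE,
                   flag = "zero_variance"))
  }
  b <- as.numeric(eng$pc %*% yc)
  ok <- eng$pn2 > 1e-12
  rss <- rep(tss, length(b))
  rss[ok] <- tss - b[ok]^2 / eng$pn2[ok]
  best <- which.min(rss) # first minimum = lowest node index
  amp <- if (ok[best]) b[best] / eng$pn2[best] else 0
  baseline <- ym - amp * eng$pmean[best]
  r2 <- 100 * (1 - rss[best] / tss)
  fit_row("unit",
          eng$nodes$sf_p[best], eng$nodes$cs_p[best],
          eng$nodes$width_r[best], eng$nodes$slope_crf[best],
          amp, baseline, rss[best], r2, r2, "grid", TRUE,
          flag = if (amp < 0) "negative_amplitude" else "ok")
}

#' Fine-stage bounded optimization of one voxel
#'
#' Refines a coarse-stage fit by bounded quasi-Newton minimization
#' ([stats::nlminb()]) of the residual sum of squares over the four
#' nonlinear parameters; the amplitude and baseline are re-solved by least
#' squares inside every objective evaluation. `sf_p`, `cs_p` and `slope_crf`
#' are optimized on a log10 scale (their plausible ranges span decades),
#' `width_r` linearly. The result is never worse than the initialization: if
#' the optimizer fails or terminates uphill, the coarse-stage parameters are
#' returned with `converged = FALSE`.
#'
#' @inheritParams grid_fit
#' @param init A one-row `FitResult`, normally from [grid_fit()].
#' @param bounds Named list of `c(lower, upper)` per parameter; defaults to
#'   the grid bounds.
#' @param control Passed to [stats::nlminb()] (default: RSS tolerance 1e-6,
#'   at most 500 objective evaluations).
#' @return A one-row `FitResult` tibble with `stage = "iterative"`.
#' @export
iterative_fit <- function(data, design, hrf = hrf_spec(), init,
                          grid = fit_grid(), bounds = NULL, engine = NULL,
                          control = list(rel.tol = 1e-6, eval.max = 500,
                                         iter.max = 300)) {
  eng <- engine %||% fit_engine(design, hrf, grid)
  bounds <- bounds %||% eng$bounds
  if (!all(is.finite(c(init$sf_p, init$cs_p, init$width_r, init$slope_crf)))) {
    out <- init
    out$stage <- "iterative"
    out$converged <- FALSE
    return(out)
  }
  ym <- mean(data)
  tss <- sum((data - ym)^2)

  to_theta <- function(sf_p, cs_p, width_r, slope_crf) {
    c(log10(sf_p), log10(cs_p), width_r, log10(slope_crf))
  }
  from_theta <- function(th) {
    list(sf_p = 10^th[1], cs_p = 10^th[2], width_r = th[3],
         slope_crf = 10^th[4])
  }
  lower <- to_theta(bounds$sf_p[1], bounds$cs_p[1], bounds$width_r[1],
                    bounds$slope_crf[1])
  upper <- to_theta(bounds$sf_p[2], bounds$cs_p[2], bounds$width_r[2],
                    bounds$slope_crf[2])
  objective <- function(th) {
    p <- from_theta(th)
    pred <- engine_predict_unit(eng, p$sf_p, p$cs_p, p$width_r, p$slope_crf)
    solve_linear(pred, data)$rss
  }
  start <- pmin(pmax(to_theta(init$sf_p, init$cs_p, init$width_r,
                              init$slope_crf), lower), upper)
  opt <- tryCatch(
    nlminb(start, objective, lower = lower, upper = upper, control = control),
    error = function(e) NULL
  )
  if (is.null(opt) || !is.finite(opt$objective) || opt$objective > init$rss + 1e-12) {
    out <- init
    out$stage <- "iterative"
    out$converged <- FALSE
    return(out)
  }
  p <- from_theta(opt$par)
  pred <- engine_predict_unit(eng, p$sf_p, p$cs_p, p$width_r, p$slope_crf)
  lin <- solve_linear(pred, data)
  r2 <- if (tss > 0) 100 * (1 - lin$rss / tss) else NA_real_
  # terminated at a convergence test (incl. PORT's "false convergence" on a
  # numerically flat objective), as opposed to running out of budget
  converged <- opt$convergence == 0 ||
    grepl("convergence", opt$message %||% "", ignore.case = TRUE)
  fit_row(init$unit_id %||% "unit", p$sf_p, p$cs_p, p$width_r, p$slope_crf,
          lin$amplitude, lin$baseline, lin$rss, r2, init$r2_grid,
          "iterative", converged,
          flag = if (lin$amplitude < 0) "negative_amplitude" else "ok")
}

#' Fit the nCSF model to every voxel of a dataset
#'
#' Independent per-voxel coarse-to-fine fits: an exhaustive grid scan with
#' closed-form amplitude/baseline, followed (by default) by bounded local
#' optimization started at the best node. Per-voxel failures are isolated
#' into flagged rows and never abort the batch. Rows are flagged `included`
#' when variance explained exceeds `r2_threshold` (default 30%). The
#' normalized area under the fitted CSF is appended as a summary metric.
#'
#' @param data Units x time numeric matrix (rows = voxels/vertices), or an
#'   `ncsf_ts` object from [read_timeseries()].
#' @param design An `ncsf_design`.
#' @param hrf An [hrf_spec()].
#' @param grid An [fit_grid()].
#' @param r2_threshold Inclusion threshold on variance explained, percent
#'   (default 30).
#' @param stage `"both"` (default) or `"grid"` to stop after the coarse scan.
#' @param parallel Number of worker processes for the fine stage (default 1,
#'   serial; forked workers give results identical to serial).
#' @param auc_interval Spatial-frequency interval for the AUC summary
#'   (default `c(0.5, 18)`).
#' @return A tibble of class `ncsf_fit`, one row per unit: `unit_id`, the
#'   four fitted parameters, `amplitude`, `baseline`, `rss`, `r2`, `r2_grid`,
#'   `auc_normalized`, `stage`, `converged`, `included`, `flag`.
#' @examples
#' \donttest{
#' d <- build_design()
#' m <- ncsf_model(cs_p = 150, sf_p = 1, width_r = 1.3, slope_crf = 3)
#' y <- predict_timeseries(m, d)$bold
#' fit_dataset(rbind(v1 = y), d, stage = "grid")
#' }
#' @export
fit_dataset <- function(data, design, hrf = hrf_spec(), grid = fit_grid(),
                        r2_threshold = 30, stage = c("both", "grid"),
                        parallel = 1L, auc_interval = c(0.5, 18)) {
  stage <- match.arg(stage)
  if (inherits(data, "ncsf_ts")) data <- data$values
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  if (ncol(data) != nrow(design)) {
    abort(sprintf("data has %d volumes but the design has %d.",
                  ncol(data), nrow(design)))
  }
  ids <- rownames(data) %||% paste0("unit_", seq_len(nrow(data)))
  eng <- fit_engine(design, hrf, grid)

  fit_one <- function(i) {
    y <- data[i, ]
    res <- tryCatch({
      g <- grid_fit(y, design, engine = eng)
      if (stage == "both" && g$flag %in% c("ok", "negative_amplitude")) {
        iterative_fit(y, design, init = g, engine = eng)
      } else {
        g
      }
    }, error = function(e) {
      fit_row(ids[i], NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
              NA_real_, NA_real_, NA_real_, NA_real_, stage, FALSE,
              flag = paste0("error: ", conditionMessage(e)))
    })
    res$unit_id <- ids[i]
    res
  }

  idx <- seq_len(nrow(data))
  rows <- if (parallel > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, fit_one, mc.cores = parallel)
  } else {
    lapply(idx, fit_one)
  }
  out <- dplyr::bind_rows(rows)
  out$auc_normalized <- vapply(seq_len(nrow(out)), function(i) {
    if (!is.finite(out$sf_p[i])) return(NA_real_)
    auc_normalized(
      csf_params(out$cs_p[i], out$sf_p[i], out$width_r[i]),
      sf_lo = auc_interval[1], sf_hi = auc_interval[2]
    )$auc_normalized
  }, numeric(1))
  out$included <- !is.na(out$r2) & out$r2 > r2_threshold
  structure(
    out,
    design_tr = eng$tr, r2_threshold = r2_threshold, grid = grid, hrf = hrf,
    class = c("ncsf_fit", class(tibble::tibble()))
  )
}
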