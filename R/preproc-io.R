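#' Remove low-frequency drift with a DCT basis
#'
#' Per unit (row): the temporal mean is removed, then the projection onto the
#' first `n_remove` non-constant discrete-cosine (DCT-II, orthonormal) basis
#' vectors is subtracted. The output is exactly orthogonal to those
#' regressors, so slow scanner drift is eliminated while task-frequency
#' structure is untouched. The constant component is handled by the demeaning
#' step, not counted among the removed coefficients.
#'
#' @param x Units x volumes numeric matrix (a vector is treated as one unit).
#' @param n_remove Number of low-frequency (non-constant) DCT components to
#'   remove (default 3).
#' @return Matrix of the same shape, demeaned and detrended.
#' @examples
#' detrend_dct(matrix(1:10, nrow = 1)) # a pure trend is (nearly) annihilated
#' @export
detrend_dct <- function(x, n_remove = 3) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (n <= n_remove) abort(sprintf("series of length %d is too short to remove %d DCT components.", n, n_remove))
  b <- dct_basis(n, n_remove)
  xc <- x - rowMeans(x)
  out <- xc - (xc %*% b) %*% t(b)
  if (vec) out <- drop(out)
  out
}

# orthonormal non-constant DCT-II basis vectors, columns k = 1..k_max
dct_basis <- function(n, k_max) {
  t0 <- seq_len(n) - 1
  b <- vapply(seq_len(k_max), function(k) {
    sqrt(2 / n) * cos(pi * k * (2 * t0 + 1) / (2 * n))
  }, numeric(n))
  matrix(b, nrow = n)
}

#' Convert a raw series to BOLD percent signal change
#'
#' `100 * (x - mean) / mean` per unit, with the mean taken over the raw
#' (pre-detrend) series: detrended series have near-zero mean, which would
#' make the division meaningless. The output is invariant to positive
#' rescaling of the input. Units with nonpositive mean cannot be expressed as
#' percent change; their rows are set to `NA` and flagged in the
#' `"excluded_units"` attribute.
#'
#' @param x Units x volumes numeric matrix (or vector = one unit).
#' @param means Optional per-unit raw means to normalize by (e.g. when `x`
#'   was already detrended); defaults to `rowMeans(x)`.
#' @return Matrix of percent-signal-change values; attribute
#'   `excluded_units` lists rows with nonpositive mean, if any.
#' @examples
#' to_percent_signal_change(c(100, 110, 90)) # 0, 10, -10
#' @export
to_percent_signal_change <- function(x, means = NULL) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  m <- means %||% rowMeans(x)
  if (length(m) != nrow(x)) abort("`means` must have one value per unit.")
  bad <- which(!(m > 0))
  out <- 100 * (x - m) / m
  if (length(bad) > 0) {
    out[bad, ] <- NA_real_
    attr(out, "excluded_units") <- bad
    warn(sprintf("%d unit(s) with nonpositive mean excluded from percent signal change.", length(bad)))
  }
  if (vec) out <- drop(out)
  out
}

#' Average time series over runs
#'
#' Element-wise mean of repeated runs of the same units (all matrices must
#' share their dimensions). Averaging before percent-signal-change
#' conversion is the default pipeline order.
#'
#' @param ... Units x volumes matrices, or a single list of them.
#' @return The element-wise mean matrix.
#' @export
average_runs <- function(...) {
  runs <- list(...)
  if (length(runs) == 1 && is.list(runs[[1]]) && !is.matrix(runs[[1]])) runs <- runs[[1]]
  dims <- lapply(runs, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    abort("all runs must have identical dimensions.")
  }
  Reduce(`+`, runs) / length(runs)
}

#' Read voxel or vertex time series
#'
#' Reads BOLD time series into a units x volumes matrix from a 4D NIfTI
#' volume (units = voxels inside `mask`, or all nonzero-variance voxels),
#' a GIFTI functional file (units = vertices), or delimited text (rows =
#' units; an optional first `unit_id` column is used for row names).
#'
#' @param path Input file (`.nii`, `.nii.gz`, `.gii`, or delimited text).
#' @param mask Optional NIfTI mask path or logical/numeric array matching the
#'   volume geometry (NIfTI input only).
#' @param tr Repetition time in seconds; read from the NIfTI header when
#'   available.
#' @return A list of class `ncsf_ts`: `values` (units x volumes), `unit_ids`,
#'   `tr`, `space` (`"volume"`, `"surface"` or `"table"`), and for volumes
#'   the `geometry` (reference image and in-mask voxel indices) needed to
#'   write parameter maps back out.
#' @export
read_timeseries <- function(path, mask = NULL, tr = NULL) {
  ext <- tolower(sub(".*?((\\.[A-Za-z0-9]+){1,2})$", "\\1", basename(path)))
  if (grepl("\\.nii(\\.gz)?$", ext)) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 4) abort(sprintf("expected a 4D NIfTI series, got %d dimensions.", length(d)))
    arr <- matrix(img, prod(d[1:3]), d[4])
    if (!is.null(mask)) {
      m <- if (is.character(mask)) as.array(RNifti::readNifti(mask)) else mask
      if (!all(dim(m)[1:3] == d[1:3])) {
        abort(sprintf("mask geometry (%s) does not match data geometry (%s).",
                      paste(dim(m), collapse = "x"), paste(d[1:3], collapse = "x")))
      }
      keep <- which(as.logical(m != 0))
    } else {
      keep <- which(matrixStats_rowVars(arr) > 0)
    }
    values <- arr[keep, , drop = FALSE]
    rownames(values) <- paste0("vox_", keep)
    structure(
      list(values = values, unit_ids = rownames(values),
           tr = tr %||% RNifti::pixdim(img)[4], space = "volume",
           geometry = list(reference = img, indices = keep, dim = d[1:3])),
      class = "ncsf_ts"
    )
  } else if (grepl("\\.gii$", ext)) {
    values <- read_gifti_data(path)
    rownames(values) <- paste0("vtx_", seq_len(nrow(values)))
    structure(
      list(values = values, unit_ids = rownames(values), tr = tr,
           space = "surface", geometry = list(n_vertices = nrow(values))),
      class = "ncsf_ts"
    )
  } else {
    df <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
    ids <- if (names(df)[1] %in% c("unit_id", "id")) {
      out <- df[[1]]
      df <- df[-1]
      as.character(out)
    } else {
      paste0("unit_", seq_len(nrow(df)))
    }
    values <- as.matrix(df)
    rownames(values) <- ids
    structure(
      list(values = values, unit_ids = ids, tr = tr, space = "table",
           geometry = NULL),
      class = "ncsf_ts"
    )
  }
}

# row variances without a matrixStats dependency
matrixStats_rowVars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1)
}

#' @export
print.ncsf_ts <- function(x, ...) {
  cat(sprintf("<ncsf_ts> %d units x %d volumes (%s space, tr = %s s)\n",
              nrow(x$values), ncol(x$values), x$space,
              format(x$tr %||% NA)))
  invisible(x)
}

#' Write a fit table and parameter maps
#'
#' `write_results()` writes the per-unit fit table as tab-separated text and
#' a JSON provenance sidecar (`<path>.json`: package version, configuration
#' hash, seed if supplied). `write_parameter_maps()` writes one 3D NIfTI map
#' per selected column back into the source volume geometry, preserving the
#' affine and header of the input series.
#'
#' @param fits An `ncsf_fit` tibble.
#' @param path Output TSV path.
#' @param seed Optional seed recorded in the provenance sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(fits, path, seed = NULL) {
  readr::write_tsv(tibble::as_tibble(fits), path)
  prov <- list(
    package = "ncsf",
    version = as.character(packageVersion("ncsf")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_units = nrow(fits),
    r2_threshold = attr(fits, "r2_threshold"),
    config_hash = rlang::hash(list(attr(fits, "grid"), attr(fits, "hrf"),
                                   attr(fits, "design_tr"))),
    seed = seed
  )
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_results
#' @param ts The `ncsf_ts` object the fits came from (volume space).
#' @param prefix Output filename prefix; one `<prefix>_<column>.nii.gz` per
#'   column.
#' @param columns Fit columns to write as maps.
#' @export
write_parameter_maps <- function(fits, ts, prefix,
                                 columns = c("sf_p", "cs_p", "width_r",
                                             "slope_crf", "r2",
                                             "auc_normalized")) {
  if (!inherits(ts, "ncsf_ts") || ts$space != "volume") {
    abort("parameter maps require an `ncsf_ts` read from a NIfTI volume.")
  }
  geom <- ts$geometry
  paths <- character(0)
  for (col in columns) {
    vol <- array(NA_real_, geom$dim)
    vol[geom$indices] <- fits[[col]]
    img <- RNifti::asNifti(vol, reference = geom$reference)
    out <- sprintf("%s_%s.nii.gz", prefix, col)
    RNifti::writeNifti(img, out)
    paths <- c(paths, out)
  }
  invisible(paths)
}

#' Read a fit table written by [write_results()]
#'
#' @param path TSV path.
#' @return An `ncsf_fit` tibble.
#' @export
read_results <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  structure(df, class = c("ncsf_fit", class(tibble::tibble())))
}
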