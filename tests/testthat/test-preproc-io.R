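test_that("DCT detrending removes exactly the low-frequency subspace", {
  n <- 120
  expect_equal(detrend_dct(rep(5, n)), rep(0, n))
  # a pure first-basis-vector input is annihilated
  b1 <- sqrt(2 / n) * cos(pi * 1 * (2 * (0:(n - 1)) + 1) / (2 * n))
  expect_equal(detrend_dct(7 * b1), rep(0, n), tolerance = 1e-12)
  expect_error(detrend_dct(rnorm(3), n_remove = 3), "too short")
})

test_that("detrending matches a least-squares regression oracle and spares task frequencies", {
  n <- 214
  t0 <- 0:(n - 1)
  drift <- 0.05 * t0 # slow linear trend
  sine <- 2 * sin(2 * pi * 12 * t0 / n) # well above the removed band
  set.seed(71)
  x <- 100 + drift + sine + 0.1 * rnorm(n)
  out <- detrend_dct(x)
  # oracle: explicit regression on intercept + the three DCT regressors
  B <- sapply(1:3, function(k) cos(pi * k * (2 * t0 + 1) / (2 * n)))
  oracle <- residuals(lm(x ~ B))
  expect_equal(out, unname(oracle), tolerance = 1e-8)
  # drift power drops by > 99%
  proj <- function(y, r) sum(y * r) / sum(r * r)
  expect_lt(proj(out, drift - mean(drift))^2 / proj(x, drift - mean(drift))^2,
            0.01)
  # a pure task-frequency sinusoid survives detrending within 1% (drift and
  # noise are kept out of this probe: both leak broadband into the bin)
  amp <- function(y) 2 * abs(sum(y * exp(-2i * pi * 12 * t0 / n))) / n
  expect_equal(amp(detrend_dct(100 + sine)), amp(sine), tolerance = 0.01)
})

test_that("percent signal change uses the raw mean and is scale invariant", {
  expect_equal(to_percent_signal_change(c(100, 110, 90)), c(0, 10, -10))
  x <- matrix(rnorm(50, mean = 200, sd = 5), nrow = 2)
  expect_equal(to_percent_signal_change(3 * x), to_percent_signal_change(x))
  expect_warning(out <- to_percent_signal_change(rbind(x[1, ], -x[2, ])),
                 "nonpositive mean")
  expect_true(all(is.na(out[2, ])))
  expect_equal(attr(out, "excluded_units"), 2L)
})

test_that("averaging runs before conversion equals converting the averaged series", {
  set.seed(81)
  run1 <- matrix(100 + rnorm(60), nrow = 3)
  run2 <- matrix(100 + rnorm(60), nrow = 3)
  avg <- average_runs(run1, run2)
  expect_equal(avg, (run1 + run2) / 2)
  expect_equal(to_percent_signal_change(average_runs(list(run1, run2))),
               to_percent_signal_change(avg))
  expect_error(average_runs(run1, run2[, 1:10]), "identical dimensions")
})

test_that("fit tables round-trip through TSV with provenance", {
  d <- default_design()
  fits <- fit_dataset(rbind(a = noiseless_bold(green_model())), d,
                      grid = small_grid(), stage = "grid")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(fits, path, seed = 99)
  back <- read_results(path)
  num <- vapply(tibble::as_tibble(fits), is.numeric, logical(1))
  for (col in names(num)[num]) {
    expect_equal(back[[col]], fits[[col]], tolerance = 1e-9)
  }
  prov <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(prov$package, "ncsf")
  expect_equal(prov$seed, 99)
  expect_true(nzchar(prov$config_hash))
})

test_that("NIfTI series round-trip through masked reading and parameter maps", {
  dims <- c(3, 3, 2, 20)
  set.seed(91)
  arr <- array(100 + rnorm(prod(dims)), dim = dims)
  img_path <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(2, 2, 2, 1.5)
  RNifti::writeNifti(img, img_path)
  mask <- array(FALSE, dims[1:3])
  mask[1:2, 1, 1] <- TRUE
  mask_path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(mask), dims[1:3])), mask_path)

  ts <- read_timeseries(img_path, mask = mask_path)
  expect_s3_class(ts, "ncsf_ts")
  expect_equal(dim(ts$values), c(2, 20))
  expect_equal(ts$values[1, ], arr[1, 1, 1, ], tolerance = 1e-6)
  expect_equal(ts$tr, 1.5, tolerance = 1e-6)
  # geometry mismatch is named in the error
  bad_mask <- array(1, c(4, 4, 4))
  expect_error(read_timeseries(img_path, mask = bad_mask), "4x4x4")

  fake_fits <- tibble::tibble(unit_id = ts$unit_ids, sf_p = c(1.5, 3),
                              r2 = c(60, 20))
  prefix <- withr::local_tempfile()
  paths <- write_parameter_maps(fake_fits, ts, prefix, columns = c("sf_p", "r2"))
  map <- RNifti::readNifti(sprintf("%s_sf_p.nii.gz", prefix))
  expect_equal(dim(map), dims[1:3])
  expect_equal(map[1, 1, 1], 1.5, tolerance = 1e-6)
  expect_true(is.na(map[3, 3, 2]))
})

test_that("delimited-text time series read with unit ids", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- tibble::tibble(unit_id = c("v1", "v2"), t1 = c(1, 4), t2 = c(2, 5),
                       t3 = c(3, 6))
  readr::write_tsv(df, path)
  ts <- read_timeseries(path, tr = 1.5)
  expect_equal(ts$space, "table")
  expect_equal(ts$unit_ids, c("v1", "v2"))
  expect_equal(unname(ts$values[2, ]), c(4, 5, 6))
})

test_that("GIFTI functional arrays round-trip and decode compressed payloads", {
  x <- matrix(rnorm(12), nrow = 4)
  path <- withr::local_tempfile(fileext = ".gii")
  write_gifti_data(x, path)
  back <- read_gifti_data(path)
  expect_equal(back, unname(x), tolerance = 1e-6)
  ts <- read_timeseries(path)
  expect_equal(ts$space, "surface")
  expect_equal(dim(ts$values), c(4, 3))

  # hand-built GZipBase64Binary payload
  vals <- as.numeric(1:5)
  payload <- jsonlite::base64_enc(memCompress(writeBin(vals, raw(), size = 8),
                                              type = "gzip"))
  gz_path <- withr::local_tempfile(fileext = ".gii")
  writeLines(sprintf(
    '<?xml version="1.0"?><GIFTI Version="1.0" NumberOfDataArrays="1"><DataArray DataType="NIFTI_TYPE_FLOAT64" Dimensionality="1" Dim0="5" Encoding="GZipBase64Binary" Endian="LittleEndian"><Data>%s</Data></DataArray></GIFTI>',
    payload), gz_path)
  expect_equal(as.numeric(read_gifti_data(gz_path)), vals)
})

test_that("configuration records round-trip through JSON and YAML", {
  cfg <- ncsf_config(r2_threshold = 25, noise_scales = c(0.3, 0.9))
  expect_equal(cfg$width_l, 0.68)
  expect_equal(cfg$standard_csf$cs_p, 166)
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_ncsf_config(cfg, path)
    back <- read_ncsf_config(path)
    expect_equal(back$r2_threshold, 25)
    expect_equal(back$noise_scales, c(0.3, 0.9))
    expect_equal(back$grid, cfg$grid)
  }
  expect_error(ncsf_config(not_a_field = 1), "unknown configuration")
})

test_that("plot builders return ggplot objects for every result type", {
  d <- default_design()
  expect_s3_class(plot_csf(standard = standard_csf(), green = csf_params(150, 1, 1.3)),
                  "ggplot")
  expect_s3_class(ggplot2::autoplot(d), "ggplot")
  p <- predict_timeseries(green_model(), d)
  expect_s3_class(ggplot2::autoplot(p), "ggplot")
  fits <- fit_dataset(rbind(a = noiseless_bold(green_model())), d,
                      grid = small_grid(), stage = "grid")
  expect_s3_class(ggplot2::autoplot(fits), "ggplot")
  cfg <- simulation_config(n_reps = 2, noise_scales = 0.4, seed = 3,
                           design = d)
  sim <- simulate_voxels(cfg)
  rec <- recovery_report(sim, fit_dataset(sim$ts, d, grid = small_grid(),
                                          stage = "grid"))
  expect_s3_class(ggplot2::autoplot(rec), "ggplot")
})
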