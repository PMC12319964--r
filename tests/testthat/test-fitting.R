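test_that("variance explained is the coefficient of determination in percent", {
  set.seed(21)
  y <- rnorm(60)
  expect_equal(variance_explained(y, y), 100)
  expect_equal(variance_explained(rep(mean(y), 60), y), 0)
  # prediction = data + orthogonal noise of equal variance -> 0%
  d <- y - mean(y)
  e <- rnorm(60)
  e <- e - d * sum(e * d) / sum(d * d) # orthogonalize
  e <- e * sqrt(sum(d^2) / sum(e^2))
  expect_equal(variance_explained(d + e, d), 0, tolerance = 1e-10)
  expect_warning(v <- variance_explained(y[1:3], rep(1, 3)), "zero-variance")
  expect_true(is.na(v))
  expect_error(variance_explained(1:3, 1:4), "equal length")
})

test_that("the grid stage matches an exhaustive brute-force RSS scan", {
  d <- default_design()
  grid <- fit_grid(sf_p = c(0.7, 1.5, 3), cs_p = c(60, 120, 240),
                   width_r = c(0.6, 1.1, 1.9), slope_crf = c(1.2, 2.5, 5))
  set.seed(31)
  truth <- ncsf_model(cs_p = 120, sf_p = 1.5, width_r = 1.1, slope_crf = 2.5,
                      amplitude = 0.8, baseline = 0.1)
  y <- predict_timeseries(truth, d)$bold + 0.5 * rnorm(nrow(d))

  # independent oracle: loop the nodes, predict through the public forward
  # model, fit amplitude/baseline with lm()
  nodes <- expand.grid(slope_crf = grid$axes$slope_crf,
                       width_r = grid$axes$width_r,
                       cs_p = grid$axes$cs_p, sf_p = grid$axes$sf_p)
  oracle <- sapply(seq_len(nrow(nodes)), function(i) {
    m <- ncsf_model(cs_p = nodes$cs_p[i], sf_p = nodes$sf_p[i],
                    width_r = nodes$width_r[i], slope_crf = nodes$slope_crf[i])
    p <- predict_timeseries(m, d)$bold
    sum(residuals(lm(y ~ p))^2)
  })
  best <- which.min(oracle)
  f <- grid_fit(y, d, grid = grid)
  expect_equal(f$sf_p, nodes$sf_p[best])
  expect_equal(f$cs_p, nodes$cs_p[best])
  expect_equal(f$width_r, nodes$width_r[best])
  expect_equal(f$slope_crf, nodes$slope_crf[best])
  expect_equal(f$rss, min(oracle), tolerance = 1e-8)
})

test_that("ties break to the lowest node index", {
  d <- default_design()
  # duplicated axis values create exactly tied nodes; the first must win
  grid <- fit_grid(sf_p = c(1, 1), cs_p = c(150, 150), width_r = c(1.3, 1.3),
                   slope_crf = c(3, 3))
  y <- noiseless_bold(green_model())
  eng <- ncsf:::fit_engine(d, hrf_spec(), grid)
  yc <- y - mean(y)
  rss_all <- sum(yc^2) - (as.numeric(eng$pc %*% yc))^2 / eng$pn2
  expect_true(sum(abs(rss_all - min(rss_all)) < 1e-12) > 1)
  f <- grid_fit(y, d, engine = eng)
  expect_equal(which.min(rss_all), 1L)
})

test_that("pure noise earns little variance explained on a full-length run", {
  d <- default_design()
  set.seed(41)
  y <- rnorm(nrow(d))
  f <- grid_fit(y, d)
  expect_lt(f$r2, 20)
})

test_that("noiseless off-grid truth is recovered to within optimizer tolerance", {
  d <- default_design()
  truth <- ncsf_model(cs_p = 120, sf_p = 1.7, width_r = 0.9, slope_crf = 2.5,
                      amplitude = 1.3, baseline = 0.4)
  y <- predict_timeseries(truth, d)$bold
  f <- fit_dataset(rbind(y), d)
  expect_equal(f$sf_p, 1.7, tolerance = 0.01)
  expect_equal(f$cs_p, 120, tolerance = 0.01)
  expect_equal(f$width_r, 0.9, tolerance = 0.01)
  expect_equal(f$slope_crf, 2.5, tolerance = 0.01)
  expect_equal(f$amplitude, 1.3, tolerance = 0.01)
  expect_equal(f$baseline, 0.4, tolerance = 0.01)
  expect_gt(f$r2, 99.99)
  # on-grid noiseless truth is already optimal: the fine stage keeps it
  g <- grid_fit(noiseless_bold(green_model()), d, grid = small_grid())
  it <- iterative_fit(noiseless_bold(green_model()), d, init = g,
                      grid = small_grid())
  expect_equal(it$sf_p, 1, tolerance = 1e-4)
  expect_equal(it$cs_p, 150, tolerance = 1e-2)
  expect_gte(it$r2, g$r2)
})

test_that("the fine stage never degrades the coarse fit on noisy data", {
  d <- default_design()
  eng <- ncsf:::fit_engine(d, hrf_spec(), fit_grid())
  set.seed(51)
  for (i in 1:6) {
    y <- predict_timeseries(green_model(), d)$bold + 0.9 * rnorm(nrow(d))
    g <- grid_fit(y, d, engine = eng)
    it <- iterative_fit(y, d, init = g, engine = eng)
    expect_gte(it$r2, g$r2)
    expect_lte(it$rss, g$rss + 1e-12)
    expect_equal(it$r2_grid, g$r2)
  }
})

test_that("fits are invariant to data scale and offset in the right way", {
  d <- default_design()
  set.seed(61)
  y <- predict_timeseries(red_model(), d)$bold + 0.4 * rnorm(nrow(d))
  f0 <- fit_dataset(rbind(y), d, grid = small_grid())
  fk <- fit_dataset(rbind(3 * y), d, grid = small_grid())
  fb <- fit_dataset(rbind(y + 5), d, grid = small_grid())
  # scaling the data scales only the amplitude (and baseline), not the shape;
  # agreement is to optimizer precision, since stopping points may differ
  # minutely between the rescaled objectives
  expect_equal(fk$sf_p, f0$sf_p, tolerance = 1e-3)
  expect_equal(fk$cs_p, f0$cs_p, tolerance = 1e-3)
  expect_equal(fk$width_r, f0$width_r, tolerance = 1e-3)
  expect_equal(fk$slope_crf, f0$slope_crf, tolerance = 1e-3)
  expect_equal(fk$amplitude, 3 * f0$amplitude, tolerance = 1e-3)
  expect_equal(fk$r2, f0$r2, tolerance = 1e-6)
  # offsetting the data moves only the baseline
  expect_equal(fb$baseline, f0$baseline + 5, tolerance = 1e-3)
  expect_equal(fb$sf_p, f0$sf_p, tolerance = 1e-3)
  expect_equal(fb$r2, f0$r2, tolerance = 1e-6)
})

test_that("batch fitting isolates failures, flags inclusion, and parallelizes deterministically", {
  d <- default_design()
  y1 <- noiseless_bold(green_model())
  y2 <- noiseless_bold(red_model())
  y3 <- predict_timeseries(
    ncsf_model(cs_p = 50, sf_p = 0.5, width_r = 0.7, slope_crf = 1.5), d
  )$bold
  bad <- y1
  bad[10] <- NaN
  data <- rbind(a = y1, b = y2, c = y3, d = bad)
  fits <- fit_dataset(data, d, grid = small_grid())
  expect_s3_class(fits, "ncsf_fit")
  expect_equal(nrow(fits), 4)
  expect_true(all(fits$r2[1:3] > 99.99))
  expect_true(all(fits$included[1:3]))
  expect_equal(fits$flag[4], "nonfinite_data")
  expect_false(fits$included[4])
  if (.Platform$OS.type == "unix") {
    fits_par <- fit_dataset(data, d, grid = small_grid(), parallel = 2L)
    expect_equal(tibble::as_tibble(fits_par), tibble::as_tibble(fits))
  }
  # tidiers summarize the table
  td <- tidy(fits)
  expect_true(all(c("unit_id", "parameter", "estimate") %in% names(td)))
  gl <- glance(fits)
  expect_equal(gl$n_units, 4)
  expect_equal(gl$n_included, 3)
})
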