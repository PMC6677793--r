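test_that("normalization puts the midpoint of a clean two-state curve at 0.5", {
  g <- gen_melt_curve(tm = 50, width = 2, noise_sd = 0)
  f <- normalize_melt(g$curves[[1]])
  at_tm <- f$signal[which.min(abs(f$temperature - 50))]
  expect_lt(abs(at_tm - 0.5), 0.011)
  expect_true(f$normalized)
  expect_true(all(f$signal >= -0.05 & f$signal <= 1.05))
})

test_that("normalization is idempotent on an already-normalized curve", {
  g <- gen_melt_curve(tm = 42, width = 1.5, noise_sd = 0)
  f1 <- normalize_melt(g$curves[[1]])
  f2 <- normalize_melt(f1)
  expect_equal(f2$signal, f1$signal, tolerance = 1e-6)
})

test_that("sloped baselines are removed before the fraction crosses 0.5 at Tm", {
  g <- gen_melt_curve(tm = 48, width = 2, noise_sd = 0,
                      baseline_intercept = -20, baseline_slope = 0.08)
  f <- normalize_melt(g$curves[[1]])
  cross <- f$temperature[min(which(f$signal >= 0.5))]
  expect_equal(cross, 48, tolerance = 0.5)
})

test_that("degenerate curves refuse to normalize", {
  flat <- melt_curve(seq(20, 65, 0.5), rep(1, 91))
  expect_error(normalize_melt(flat), "normalization error")
  short <- gen_melt_curve(tm = 40, t_range = c(38, 43), step = 0.5)$curves[[1]]
  expect_error(normalize_melt(short, baseline_frac = 0.6),
               "baseline windows overlap")
})

test_that("Savitzky-Golay differentiation reproduces quadratics exactly inside", {
  T <- seq(20, 65, 0.5)
  a <- 0.013; b <- -0.8; c0 <- 4
  curve <- melt_curve(T, a * T^2 + b * T + c0)
  d <- smooth_derivative(curve, window = 5, polyorder = 2)
  interior <- 3:(length(T) - 2)
  expect_equal(d$signal[interior], 2 * a * T[interior] + b, tolerance = 1e-10)
  # constant signal differentiates to zero
  dz <- smooth_derivative(melt_curve(T, rep(3, length(T))))
  expect_equal(dz$signal, rep(0, length(T)), tolerance = 1e-12)
})

test_that("smooth derivative of a sine tracks the cosine closely", {
  x <- seq(0, 2 * pi, length.out = 1200)
  d <- smooth_derivative(melt_curve(x, sin(x)))
  interior <- 5:(length(x) - 4)
  expect_lt(max(abs(d$signal[interior] - cos(x[interior]))), 1e-3)
})

test_that("derivative parameters are validated", {
  c <- gen_melt_curve(tm = 50)$curves[[1]]
  expect_error(smooth_derivative(c, window = 4), "parameter error")
  expect_error(smooth_derivative(c, window = 3, polyorder = 2), "parameter error")
  expect_error(smooth_derivative(c, window = 9999), "parameter error")
})

test_that("a noiseless transition yields a single peak at the true Tm", {
  g <- gen_melt_curve(tm = 52.0, width = 2, noise_sd = 0)
  fit <- melt_pipeline(g$curves[[1]])
  expect_equal(fit$n_components, 1)
  expect_equal(fit$components$center, 52.0, tolerance = 0.1)
  expect_gt(fit$components$amplitude, 0)
})

test_that("Tm recovery is tight across the melting range and transition widths", {
  for (tm in c(40, 50, 60)) {
    for (w in c(2, 6)) {
      g <- gen_melt_curve(tm = tm, width = w, noise_sd = 0,
                          t_range = c(tm - 10 * w, tm + 10 * w))
      fit <- melt_pipeline(g$curves[[1]])
      expect_equal(fit$components$center, tm, tolerance = 0.1)
    }
  }
})

test_that("flat derivatives are a fit error, not a silent zero-peak fit", {
  g <- gen_melt_curve(tm = 50, amplitude = 0, baseline_intercept = 1)
  d <- smooth_derivative(g$curves[[1]])
  expect_error(fit_peaks(d), "fit error")
})

test_that("two transitions ten degrees apart resolve into two centers", {
  g <- gen_melt_curve(seed = 2, tm = c(40, 50), width = c(2, 2),
                      amplitude = c(1, 1), noise_sd = 0)
  der <- smooth_derivative(normalize_melt(g$curves[[1]], method = "minmax"))
  fit <- fit_peaks(der, n_components = 2)
  expect_equal(fit$components$center, c(40, 50), tolerance = 0.3)
})

test_that("close centers trigger the degeneracy warning", {
  g <- gen_melt_curve(seed = 3, tm = c(46, 46.2), amplitude = c(1, 1),
                      noise_sd = 0)
  der <- smooth_derivative(normalize_melt(g$curves[[1]], method = "minmax"))
  expect_warning(
    fit_peaks(der, n_components = 2,
              init = list(centers = c(46, 46.2), amplitudes = c(0.1, 0.1),
                          widths = c(2, 2))),
    "degeneracy")
})

test_that("noisy replicate-averaged melts still localize Tm within half a degree", {
  g <- gen_melt_curve(seed = 7, tm = 44.4, width = 2, noise_sd = 0.02,
                      replicates = 3)
  fit <- melt_pipeline(g$curves)
  expect_equal(fit$components$center, 44.4, tolerance = 0.5)
})

test_that("delta Tm is simple center arithmetic with propagated uncertainty", {
  ctrl <- melt_pipeline(gen_melt_curve(seed = 1, tm = 44.4, noise_sd = 0)$curves[[1]])
  trt <- melt_pipeline(gen_melt_curve(seed = 1, tm = 46.5, noise_sd = 0)$curves[[1]])
  d <- delta_tm(ctrl, trt)
  expect_equal(d$delta_tm, 2.1, tolerance = 0.1)
  # antisymmetry
  expect_equal(delta_tm(trt, ctrl)$delta_tm, -d$delta_tm)
  # identical fits
  expect_equal(delta_tm(ctrl, ctrl)$delta_tm, 0)
  expect_error(delta_tm(ctrl, trt, component = 3), "index error")
})

test_that("the pipeline is a pure function of curve and configuration", {
  g1 <- gen_melt_curve(seed = 9, tm = 47, noise_sd = 0.02, replicates = 2)
  g2 <- gen_melt_curve(seed = 9, tm = 47, noise_sd = 0.02, replicates = 2)
  f1 <- melt_pipeline(g1$curves)
  f2 <- melt_pipeline(g2$curves)
  expect_identical(f1$components, f2$components)
})

test_that("melt tables round-trip through CSV", {
  dir <- withr::local_tempdir()
  g <- gen_melt_curve(seed = 5, tm = 51, noise_sd = 0.01, replicates = 2,
                      dir = dir)
  curves <- read_melt_table(g$paths[["data"]])
  expect_length(curves, 2)
  expect_equal(curves[[1]]$signal, g$curves[[1]]$signal, tolerance = 1e-9)
})
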