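test_that("counts convert to concentration by the specific-activity arithmetic", {
  sa <- specific_activity(125)  # 125 mCi/mmol = 2.775e11 dpm/mmol
  expect_equal(cpm_to_concentration(277500, sa, volume_uL = 1), 1000)
  expect_equal(cpm_to_concentration(0, sa, volume_uL = 1), 0)
  # linear in counts, inverse-linear in specific activity
  expect_equal(cpm_to_concentration(2 * 277500, sa, 1), 2000)
  expect_equal(cpm_to_concentration(277500, specific_activity(250), 1), 500)
  # counting efficiency scales counts back up to disintegrations
  expect_equal(cpm_to_concentration(277500 / 2, specific_activity(125, 0.5), 1),
               1000)
})

test_that("conversion rejects unphysical parameters", {
  expect_error(specific_activity(-1), "positive")
  expect_error(specific_activity(125, 0), "efficiency")
  expect_error(cpm_to_concentration(100, specific_activity(125), 0), "volume")
  expect_error(cpm_to_concentration(-5, specific_activity(125), 1), ">= 0")
})

test_that("isotopic dilution follows SA_mix = SA_hot / (1 + cold:hot)", {
  # 25 Ci/mmol stock diluted to 125 mCi/mmol needs cold:hot of 199
  expect_equal(dilute_specific_activity(25000, target = 125), 199)
  expect_equal(dilute_specific_activity(25000, cold_to_hot = 0), 25000)
  expect_equal(dilute_specific_activity(25000, cold_to_hot = 1), 12500)
  expect_error(dilute_specific_activity(100, target = 100), "dilution error")
})

test_that("a noiseless hyperbola is recovered to machine precision", {
  L <- 0.25 * 2^(0:8)
  iso <- isotherm(L, 5 * L / (2 + L))
  fit <- fit_one_site(iso)
  expect_equal(fit$kd, 2, tolerance = 1e-6)
  expect_equal(fit$bmax, 5, tolerance = 1e-6)
  expect_false(fit$ill_conditioned)
})

test_that("degenerate isotherms are rejected or flagged", {
  L <- c(1, 2, 4, 8)
  expect_error(fit_one_site(isotherm(L, rep(0, 4))), "zero")
  expect_error(isotherm(c(1, 1, 1, 1), 1:4), "distinct")
  # barely-curved data: apparent Kd far beyond the sampled range is flagged
  shallow <- isotherm(L, 5 * L / (100 + L))
  fit <- fit_one_site(shallow)
  expect_true(fit$ill_conditioned)
})

test_that("Poisson-noise isotherms recover Kd within a quarter of truth", {
  for (s in 1:10) {
    g <- gen_isotherm(seed = s, kd = 2, bmax_uM = 5, replicates = 4)
    iso <- isotherm_from_counts(g$table, specific_activity(125), 25,
                                background_cpm = 30)
    fit <- fit_one_site(iso)
    expect_lt(abs(fit$kd - 2) / 2, 0.25)
  }
})

test_that("fixed-Bmax mode constrains the fit", {
  L <- 0.25 * 2^(0:8)
  iso <- isotherm(L, 5 * L / (2 + L))
  fit <- fit_one_site(iso, fix_bmax = 5)
  expect_equal(fit$kd, 2, tolerance = 1e-6)
  expect_equal(fit$bmax, 5)
})

test_that("per-junction stoichiometry is plain ratio arithmetic", {
  expect_equal(molar_ratio_per_junction(5, 5), 1)
  expect_equal(molar_ratio_per_junction(0, 5), 0)
  # invariant to joint unit rescaling
  expect_equal(molar_ratio_per_junction(5e3, 5e3), 1)
  # finite-filament correction
  expect_equal(molar_ratio_per_junction(4.5, 5, junctions_per_dimer = 0.9), 1)
  expect_error(molar_ratio_per_junction(1, 0), "division")
})

test_that("saturating generator stoichiometry of one is read back as one", {
  g <- gen_isotherm(seed = 21, kd = 2, bmax_uM = 5, tpm_dimer_uM = 5,
                    replicates = 4)
  iso <- isotherm_from_counts(g$table, specific_activity(125), 25,
                              background_cpm = 30)
  fit <- fit_one_site(iso)
  expect_equal(molar_ratio_per_junction(fit$bmax, 5), 1, tolerance = 0.1)
})

test_that("condition comparison flags background-level post-incubation binding", {
  g <- gen_isotherm(seed = 8, post_fraction = 0.05)
  sa <- specific_activity(125)
  pre <- isotherm_from_counts(g$table, sa, 25, 30, "pre_incubation")
  post <- isotherm_from_counts(g$table, sa, 25, 30, "post_incubation")
  cmp <- compare_conditions(pre, post)
  expect_true(cmp$background_level)
  expect_true(all(cmp$table$difference >= 0))
  # identical isotherms: no flag, zero difference
  same <- compare_conditions(pre, pre)
  expect_false(same$background_level)
  expect_equal(same$table$difference, rep(0, nrow(same$table)))
  # post above pre: sign reported, no flag
  up <- isotherm(pre$conc_uM, pre$bound * 1.5, condition = "post_incubation")
  cmp_up <- compare_conditions(pre, up)
  expect_false(cmp_up$background_level)
  expect_equal(cmp_up$sign, -1)
})

test_that("disjoint concentration ranges cannot be compared", {
  a <- isotherm(c(0.25, 0.5, 1, 2), c(1, 2, 3, 4))
  b <- isotherm(c(8, 16, 32, 64), c(1, 2, 3, 4), condition = "post_incubation")
  expect_error(compare_conditions(a, b), "disjoint")
})

test_that("binding tables round-trip through CSV with count conversion", {
  dir <- withr::local_tempdir()
  g <- gen_isotherm(seed = 4, dir = dir)
  tab <- read_binding_table(g$paths[["data"]], sa = specific_activity(125),
                            volume_uL = 25)
  expect_true(all(c("conc_uM", "bound_uM") %in% names(tab)))
  expect_equal(nrow(tab), nrow(g$table))
})
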