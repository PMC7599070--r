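test_that("dilution series produces the documented in-well concentrations", {
  expect_equal(final_concentrations(dilution_series(n_steps = 1)), 800)
  expect_equal(final_concentrations(dilution_series(n_steps = 3)),
               c(800, 533.33, 355.56), tolerance = 1e-4)
  expect_equal(final_concentrations(dilution_series(mix_factor = 1,
                                                    n_steps = 2)),
               c(1000, 666.67), tolerance = 1e-4)
})

test_that("standard-curve inversion converts and clamps absorbances", {
  curve <- standard_curve(slope = 0.01, intercept = 0.05)
  expect_equal(as.numeric(absorbance_to_phosphate(0.05, curve)), 0)
  expect_equal(as.numeric(absorbance_to_phosphate(0.15, curve)), 10)
  expect_warning(p <- absorbance_to_phosphate(0.01, curve), "clamped")
  expect_equal(as.numeric(p), 0)
  expect_equal(attr(p, "n_clamped"), 1L)
  expect_error(standard_curve(slope = -1), "positive")
})

test_that("single-timepoint MM fit recovers noise-free parameters", {
  conc <- final_concentrations(dilution_series())
  prod <- predict_mm_product(conc, kcat_over_km = 0.5, km = 30,
                             t = 15, enzyme = 1)
  fit <- fit_single_timepoint_mm(conc, prod, t = 15, enzyme = 1)
  expect_equal(fit$kcat_over_km, 0.5, tolerance = 1e-4)
  expect_equal(fit$km, 30, tolerance = 1e-4)
  expect_true(fit$km_reliable)

  # at C = KM the model predicts P = t*E*kcat/2
  expect_equal(predict_mm_product(30, 0.5, 30, t = 15, enzyme = 1),
               15 * 1 * (0.5 * 30) / 2)

  expect_error(fit_single_timepoint_mm(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
  expect_error(fit_single_timepoint_mm(conc, rep(0, length(conc))), "zero")
})

test_that("K_M far above the assay range is flagged unreliable", {
  conc <- final_concentrations(dilution_series())
  prod <- predict_mm_product(conc, 0.5, 5000, t = 15, enzyme = 1)
  fit <- fit_single_timepoint_mm(conc, prod, t = 15, enzyme = 1)
  expect_false(fit$km_reliable)
  expect_equal(fit$kcat_over_km, 0.5, tolerance = 0.02)
})

test_that("predicted product is strictly increasing in substrate", {
  conc <- sort(final_concentrations(dilution_series()))
  p <- predict_mm_product(conc, 0.3, 50)
  expect_true(all(diff(p) > 0))
})

test_that("efficiency estimate stays nearly unbiased under 2% noise", {
  conc <- final_concentrations(dilution_series())
  truth <- predict_mm_product(conc, 0.5, 30, t = 15, enzyme = 1)
  set.seed(202)
  rel_err <- replicate(200, {
    y <- truth * (1 + rnorm(length(truth), 0, 0.02))
    f <- fit_single_timepoint_mm(conc, y, t = 15, enzyme = 1)
    (f$kcat_over_km - 0.5) / 0.5
  })
  expect_lt(abs(median(rel_err)), 0.05)
})

test_that("unit calibration is the stated linear rule", {
  expect_equal(calibrate_activity(15), 1)
  expect_equal(calibrate_activity(30), 2)
  expect_equal(calibrate_activity(0), 0)
  expect_error(calibrate_activity(-1), "negative")
  set.seed(4)
  for (a in runif(5, 0.1, 5)) {
    p <- runif(1, 1, 50)
    expect_equal(calibrate_activity(a * p), a * calibrate_activity(p))
  }
})

test_that("pNPP hyperbola is recovered and duplicates averaged", {
  conc <- 100 / 2^(0:7) # 2-fold dilution from 100 mM
  a405 <- 1.8 * conc / (conc + 12)
  fit <- fit_pnpp(conc, a405)
  expect_equal(fit$vmax, 1.8, tolerance = 1e-4)
  expect_equal(fit$km, 12, tolerance = 1e-4)

  # duplicates: mean of each pair fitted
  fit2 <- fit_pnpp(rep(conc, 2), c(a405 + 0.01, a405 - 0.01))
  expect_equal(fit2$vmax, 1.8, tolerance = 1e-3)

  expect_error(fit_pnpp(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
})

test_that("efficiency folds divide specificity constants", {
  conc <- final_concentrations(dilution_series())
  fa <- fit_single_timepoint_mm(conc, predict_mm_product(conc, 0.5, 30),
                                t = 15, enzyme = 1)
  fb <- fit_single_timepoint_mm(conc, predict_mm_product(conc, 0.005, 30),
                                t = 15, enzyme = 1)
  expect_equal(efficiency_fold(fa, fa), 1)
  expect_equal(efficiency_fold(fa, fb), 100, tolerance = 0.02)
  fb$kcat_over_km <- 0
  expect_error(efficiency_fold(fa, fb), "positive")
})

test_that("reparameterised fits give identical curves on noise-free data", {
  conc <- final_concentrations(dilution_series())
  prod <- predict_mm_product(conc, 0.5, 30)
  fit <- fit_single_timepoint_mm(conc, prod, t = 15, enzyme = 1)
  # (kcat/KM, KM) and (Vmax = kcat*E, KM) parameterisations of the same curve
  pred1 <- predict_mm_product(conc, fit$kcat_over_km, fit$km)
  pred2 <- 15 * fit$kcat * conc / (conc + fit$km)
  expect_lt(sum((pred1 - pred2)^2), 1e-10)
})

test_that("plate CSVs read with explicit or step-resolved concentrations", {
  series <- dilution_series(n_steps = 4)
  plate <- gen_assay_plate(0.5, 30, series = series)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(plate[, c("well", "dilution_step", "a620")], csv,
                   row.names = FALSE)
  got <- read_plate_csv(csv, series = series)
  expect_equal(got$substrate_conc_uM, final_concentrations(series))
  expect_error(read_plate_csv(csv), "series")
})
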