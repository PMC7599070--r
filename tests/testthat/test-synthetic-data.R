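test_that("generators are pure functions of parameters and seed", {
  p1 <- gen_proteome(n_proteins = 30, n_substrates = 5, seed = 9)
  p2 <- gen_proteome(n_proteins = 30, n_substrates = 5, seed = 9)
  expect_identical(p1, p2)
  p3 <- gen_proteome(n_proteins = 30, n_substrates = 5, seed = 10)
  expect_false(identical(p1$fasta, p3$fasta))

  t1 <- gen_silac(p1, n_sites = 60, seed = 3)
  t2 <- gen_silac(p1, n_sites = 60, seed = 3)
  expect_identical(t1, t2)

  g1 <- gen_tmt(n_sites = 100, n_planted = 5, seed = 3)
  expect_identical(g1, gen_tmt(n_sites = 100, n_planted = 5, seed = 3))

  pl1 <- gen_assay_plate(0.5, 30, noise_sd_abs = 0.01, seed = 12)
  expect_identical(pl1, gen_assay_plate(0.5, 30, noise_sd_abs = 0.01,
                                        seed = 12))

  sg1 <- gen_sensorgrams("WT", noise_sd = 0.005, seed = 2)
  sg2 <- gen_sensorgrams("WT", noise_sd = 0.005, seed = 2)
  expect_identical(sg1, sg2)

  # global RNG state is untouched by seeded generation
  set.seed(777); before <- .Random.seed
  invisible(gen_proteome(n_proteins = 5, n_substrates = 1, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("every planted proteome site matches the default motif pattern", {
  pt <- gen_proteome(n_proteins = 50, length = 60, n_substrates = 20,
                     seed = 21)
  for (i in seq_len(nrow(pt$truth))) {
    m <- scan_motif(pt$fasta[[pt$truth$protein_id[i]]])
    expect_true(pt$truth$position[i] %in% m$target_position)
  }
  none <- gen_proteome(n_proteins = 5, n_substrates = 0, seed = 1)
  expect_equal(nrow(none$truth), 0)
  expect_error(gen_proteome(length = 10), ">= 20")
})

test_that("noise-free generator outputs sit exactly on the model curves", {
  # SILAC: score equals the planted effect exactly
  pt <- gen_proteome(n_proteins = 30, n_substrates = 5, seed = 2)
  tab <- gen_silac(pt, n_sites = 50, noise_sd_log2 = 0, seed = 2)
  sc <- score_table(tab, default_design())
  expect_equal(sc$log2_score[match(pt$truth$site_id, sc$site_id)],
               rep(3, 5), tolerance = 1e-12)

  # TMT: diff_z of planted sites equals the effect exactly (before z-scoring)
  g <- gen_tmt(n_sites = 100, n_planted = 5, noise_sd = 0, seed = 2)
  deltas <- treatment_deltas(g$matrix, tmt_design())
  tab2 <- differential_table(deltas)
  expect_equal(tab2$diff_z[match(g$truth, tab2$site_id)], rep(1.5, 5),
               tolerance = 1e-12)

  # plate: absorbances strictly increasing with concentration, and the fit
  # round-trips the generator parameters
  plate <- gen_assay_plate(0.5, 30, curve = standard_curve(0.01, 0.05))
  ord <- order(plate$substrate_conc_uM)
  expect_true(all(diff(plate$a620[ord]) > 0))
  p <- absorbance_to_phosphate(plate$a620, standard_curve(0.01, 0.05))
  fit <- fit_single_timepoint_mm(plate$substrate_conc_uM, as.numeric(p),
                                 t = 15, enzyme = 1)
  expect_equal(fit$kcat_over_km, 0.5, tolerance = 1e-4)
  expect_equal(fit$km, 30, tolerance = 1e-4)

  # sensorgram: noise-free trace equals the closed-form model
  params <- binding_params(1e5, 1.04e-3, 1)
  sg <- simulate_sensorgram(params, 1e-8, t_assoc = 100, t_dissoc = 100)
  a <- sg[sg$phase == "association", ]
  req <- 1 * 1e-8 / (1e-8 + params$kd)
  expect_equal(a$response,
               req * (1 - exp(-(1e5 * 1e-8 + 1.04e-3) * a$time_s)),
               tolerance = 1e-12)
})

test_that("fixture table is internally consistent and errors on unknowns", {
  fx <- binding_fixtures()
  wt <- fx$kd_M[fx$name == "WT"]
  expect_equal(fx$kd_M, fx$fold_vs_wt * wt, tolerance = 1e-12)
  expect_equal(wt * 1e9, 10.4)
  expect_true(all(fx$bound_flag[fx$name %in% c("R536P", "Y534A", "HHH-A")]))
  expect_error(gen_sensorgrams("XYZ"), "unknown fixture")
  expect_error(gen_equilibrium_responses("XYZ"), "unknown fixture")
})

test_that("unit-calibrated efficiency satisfies the unit definition", {
  for (km in c(10, 30, 125, 1000)) {
    eff <- unit_calibrated_efficiency(km)
    p15 <- predict_mm_product(125, eff, km, t = 15, enzyme = 1)
    expect_equal(p15, 15, tolerance = 1e-12)
    expect_equal(calibrate_activity(p15), 1, tolerance = 1e-12)
  }
})

test_that("child seeds are stable, in range, and name-sensitive", {
  s1 <- child_seed(42, "silac")
  expect_identical(s1, child_seed(42, "silac"))
  expect_false(s1 == child_seed(42, "tmt"))
  expect_false(s1 == child_seed(43, "silac"))
  for (seed in c(1, 1000, 2^30)) {
    cs <- child_seed(seed, "x")
    expect_true(cs >= 1 && cs < 2^31)
  }
})
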