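test_that("noise-free emitted isotopes hit the exact forward-model point", {
  # pure bD without reduction emits exactly the bD endmember
  tr <- truth_config(f_bd = 1, f_fd = 0, f_nd = 0, f_ni = 0, r_n2o = 1)
  pt <- simulate_emitted_isotopes(tr, n_samples = 1, noise = FALSE)
  expect_equal(pt$sp, tr$endmembers$endmembers$bD$sp_mean)
  expect_equal(pt$d18o, tr$endmembers$endmembers$bD$d18o_mean)
  # noise-free truth is recovered by the matching solver to 1e-6
  for (case in c("red_mix", "mix_red")) {
    tr2 <- truth_config(f_bd = 0.87, f_fd = 0.13, f_nd = 0, f_ni = 0,
                        r_n2o = 0.10, mixing_case = case)
    pt2 <- simulate_emitted_isotopes(tr2, n_samples = 1, noise = FALSE)
    solver <- if (case == "red_mix") solve_red_mix else solve_mix_red
    res <- solver(pt2$sp, pt2$d18o, tr2$endmembers, minor = "fD")
    expect_equal(res$f_bd, 0.87, tolerance = 1e-6)
    expect_equal(res$r_n2o, 0.10, tolerance = 1e-6)
  }
})

test_that("simulated chamber series reproduce the configured flux", {
  tr <- truth_config()
  s <- simulate_chamber_series(tr, noise = FALSE)
  f <- fit_flux(s, method = "ols")
  expect_equal(f$flux_ug_n_m2_h, tr$n2o_flux_ug_n_m2_h, tolerance = 1e-9)
  # ambient-only series yields zero flux
  s0 <- simulate_chamber_series(tr, flux_ug_n_m2_h = 0, noise = FALSE)
  expect_equal(fit_flux(s0, method = "ols")$flux_umol_m2_h, 0,
               tolerance = 1e-12)
  # with ppb noise the OLS flux standard error matches theory on average
  set.seed(5)
  tr_n <- truth_config(sigma_conc_ppb = 5)
  ests <- replicate(400, fit_flux(simulate_chamber_series(tr_n),
                                  method = "ols")$flux_ug_n_m2_h)
  expect_equal(mean(ests), tr$n2o_flux_ug_n_m2_h, tolerance = 0.05)
  # empirical SD vs OLS theory: sigma_slope = sigma / sqrt(sum((t - tbar)^2))
  molar_density <- iso_constants$standard_pressure /
    (iso_constants$gas_constant * 293.15)
  sig_conc <- 5 * 1e-3 * molar_density          # ppb noise in umol m-3
  t_h <- c(0, 20, 40, 60) / 60
  sd_theory <- sig_conc / sqrt(sum((t_h - mean(t_h))^2)) *
    0.016 * 2 * iso_constants$molar_mass_n
  expect_equal(sd(ests), sd_theory, tolerance = 0.15)
})

test_that("label dynamics conserve 15N and expose known ground truth", {
  tr <- truth_config()
  dyn <- simulate_label_dynamics(tr, noise = FALSE)
  with(dyn$truth, {
    total_n <- nh4_n + no3_n + plant_n + gas_n + lost_n
    start_n <- 2 * 73 * 15 + (1.6 + 166) * 15
    expect_equal(total_n, start_n, tolerance = 1e-9)
    total_15 <- nh4_15 + no3_15 + plant_15 + gas_15 + lost_15
    start_15 <- 73 * 15 * 0.105 + 73 * 15 * a_nat + (1.6 + 166) * 15 * a_nat
    expect_equal(total_15, start_15, tolerance = 1e-9)
    expect_equal(lost_n, 0)
  })
  # hidden volume is the labeled plus residual volume
  expect_equal(dyn$truth$volume_L, 30)
  # zero nitrification keeps the NO3 pool at natural abundance under NH4 label
  tr0 <- truth_config(nitrification_frac_per_day = 0)
  dyn0 <- simulate_label_dynamics(tr0, noise = FALSE)
  expect_equal(max(abs(dyn0$pools$ape_no3)), 0, tolerance = 1e-9)
  # with nitrification on, NO3 excess grows monotonically
  expect_true(all(diff(dyn$pools$ape_no3[dyn$pools$time_h > 0]) > 0))
})

test_that("datasets regenerate bit-exactly from the same seed", {
  d1 <- simulate_experiment(seed = 99)
  d2 <- simulate_experiment(seed = 99)
  expect_identical(d1$isotopes, d2$isotopes)
  expect_identical(d1$chamber$n2o_ppb, d2$chamber$n2o_ppb)
  expect_identical(d1$label_dynamics, d2$label_dynamics)
  dir1 <- file.path(tempdir(), "synth_a"); dir2 <- file.path(tempdir(), "synth_b")
  f1 <- write_synthetic_dataset(d1, dir1)
  f2 <- write_synthetic_dataset(d2, dir2)
  for (k in names(f1)) {
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
  }
  # a different seed changes the noisy outputs
  d3 <- simulate_experiment(seed = 100)
  expect_false(identical(d1$isotopes, d3$isotopes))
})

test_that("the full pipeline recovers the principal truth parameters", {
  ds <- simulate_experiment(truth_config(f_bd = 0.87, f_fd = 0.08, f_nd = 0,
                                         f_ni = 0.05, r_n2o = 0.10),
                            seed = 42, n_iso_samples = 8)
  rep <- run_experiment_pipeline(ds)
  # the below-threshold headspace samples were excluded and logged
  expect_true(any(!rep$threshold_log$retained))
  expect_true(all(nzchar(rep$threshold_log$reason[!rep$threshold_log$retained])))
  # flux within noise of the configured truth
  expect_equal(rep$flux$flux_ug_n_m2_h, 1.7, tolerance = 0.15)
  # mapping summary near the truth for all four cells
  expect_true(all(abs(rep$mapping_summary$f_bd_mean - 0.87) < 0.05))
  expect_true(all(abs(rep$mapping_summary$r_n2o_mean - 0.10) < 0.05))
  # tracer partitioning recovers the configured source split
  expect_true(all(abs(rep$tracing$f_pn2o - ds$truth$f_pn2o) < 0.05))
  # volume estimate close to the hidden 30 L
  expect_equal(rep$solution_volume$volume_L, 30, tolerance = 0.1)
  # partitioned fluxes sum to the fitted total
  expect_equal(rep$tracing$no3_derived + rep$tracing$nh4_derived,
               rep(rep$flux$flux_ug_n_m2_h, nrow(rep$tracing)))
})

test_that("NO3-labeled experiments run through the isotopologue route", {
  ds <- simulate_experiment(truth_config(label = labeling_config("NO3_15"),
                                         residual_nh4_mg_L = 1.0),
                            seed = 7)
  rep <- run_experiment_pipeline(ds)
  expect_true(all(abs(rep$tracing$f_pn2o - ds$truth$f_pn2o) < 0.05))
  expect_true(all(rep$tracing$f_pn2o >= 0 & rep$tracing$f_pn2o <= 1))
})
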