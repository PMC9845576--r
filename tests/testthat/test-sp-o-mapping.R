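test_that("water adjustment shifts denitrification endmembers exactly once", {
  raw <- load_endmembers()
  em0 <- adjust_endmembers(raw, 0)
  for (p in names(raw$endmembers)) {
    expect_equal(em0$endmembers[[p]]$d18o_mean, raw$endmembers[[p]]$d18o_mean)
  }
  em <- adjust_endmembers(raw, -8.5)
  for (p in c("bD", "fD", "nD")) {
    expect_equal(em$endmembers[[p]]$d18o_mean,
                 raw$endmembers[[p]]$d18o_mean - 8.5)
  }
  # Ni oxygen derives from O2, not water: untouched
  expect_equal(em$endmembers$Ni$d18o_mean, raw$endmembers$Ni$d18o_mean)
  expect_error(adjust_endmembers(em, -8.5), "twice")
})

test_that("Rayleigh residual follows delta0 + eps*ln(r)", {
  eps <- reduction_line(-5, -15)
  expect_equal(rayleigh_residual(3, 20, eps, 1), c(sp = 3, o = 20))
  expect_equal(rayleigh_residual(3, 20, eps, exp(-1))[["sp"]], 8)
  # path slope is eps_sp/eps_o for any r
  rr <- c(0.9, 0.5, 0.2, 0.05)
  pts <- t(vapply(rr, function(r) rayleigh_residual(0, 0, eps, r), numeric(2)))
  expect_equal(pts[, "sp"] / pts[, "o"], rep(eps$slope, 4))
  expect_error(rayleigh_residual(0, 0, eps, 0), "positive")
  expect_error(reduction_line(5, -15), "negative")
})

test_that("red-mix solver recovers forward-generated (f, r) grids exactly", {
  em <- water_adjusted_endmembers()
  for (minor in c("fD", "Ni")) {
    for (f in c(0.5, 0.75, 0.85, 0.95)) {
      for (r in c(0.05, 0.09, 0.3, 0.8)) {
        s <- forward_red_mix(f, r, em, minor)
        res <- solve_red_mix(s["sp"], s["o"], em, minor)
        expect_equal(res$f_bd, f, tolerance = 1e-6)
        expect_equal(res$r_n2o, r, tolerance = 1e-6)
        expect_false(res$out_of_domain)
        expect_equal(res$f_minor, 1 - res$f_bd)
      }
    }
  }
  # pure-bD limit
  s <- forward_red_mix(1, 0.1, em)
  res <- solve_red_mix(s["sp"], s["o"], em)
  expect_equal(res$f_bd, 1, tolerance = 1e-6)
  expect_equal(res$r_n2o, 0.1, tolerance = 1e-6)
  # sample at the minor endmember: f = 0, r unidentifiable
  mm <- em$endmembers$fD
  deg <- solve_red_mix(mm$sp_mean, mm$d18o_mean, em, "fD")
  expect_equal(deg$f_bd, 0)
  expect_equal(deg$r_n2o, 1)
  expect_true(deg$out_of_domain)
})

test_that("mix-red solver recovers forward-generated (f, r) grids exactly", {
  em <- water_adjusted_endmembers()
  for (minor in c("fD", "Ni")) {
    for (f in c(0.5, 0.75, 0.88, 0.95)) {
      for (r in c(0.05, 0.11, 0.3, 0.8)) {
        s <- forward_mix_red(f, r, em, minor)
        res <- solve_mix_red(s["sp"], s["o"], em, minor)
        expect_equal(res$f_bd, f, tolerance = 1e-6)
        expect_equal(res$r_n2o, r, tolerance = 1e-6)
      }
    }
  }
  # sample on the endmember segment: r = 1, f from position
  s <- forward_mix_red(0.6, 1, em)
  res <- solve_mix_red(s["sp"], s["o"], em)
  expect_equal(res$f_bd, 0.6, tolerance = 1e-9)
  expect_equal(res$r_n2o, 1, tolerance = 1e-9)
  # coincident endmembers make the geometry singular
  em_bad <- em
  em_bad$endmembers$fD <- em_bad$endmembers$bD
  expect_error(solve_mix_red(10, 30, em_bad, "fD"), "singular")
})

test_that("mapping requires water-adjusted endmembers", {
  raw <- load_endmembers()
  expect_error(solve_red_mix(10, 30, raw), "water-adjusted")
  expect_error(solve_mix_red(10, 30, raw), "water-adjusted")
})

test_that("N2 back-calculation follows the case-specific convention", {
  red <- list(case = "red_mix", f_bd = 0.85, r_n2o = 0.09, scenario = "bD_fD")
  mix <- list(case = "mix_red", f_bd = 0.85, r_n2o = 0.13, scenario = "bD_fD")
  expect_equal(estimate_n2_flux(list(case = "red_mix", f_bd = 0.9,
                                     r_n2o = 1), 5)$n2_flux, 0)
  expect_equal(estimate_n2_flux(red, 1.7)$n2_flux,
               0.85 * 1.7 * (1 - 0.09) / 0.09)
  expect_equal(estimate_n2_flux(mix, 1.7)$n2_flux, 1.7 * (1 - 0.13) / 0.13)
  expect_error(estimate_n2_flux(list(case = "red_mix", f_bd = 1, r_n2o = 0), 1),
               "positive")
  # monotone: decreasing in r, increasing (red-mix) in f_bD
  rs <- seq(0.05, 1, by = 0.05)
  n2 <- vapply(rs, function(r)
    estimate_n2_flux(list(case = "mix_red", r_n2o = r), 1)$n2_flux, 0)
  expect_true(all(diff(n2) < 0))
  fs <- seq(0.1, 1, by = 0.1)
  n2f <- vapply(fs, function(f)
    estimate_n2_flux(list(case = "red_mix", f_bd = f, r_n2o = 0.1), 1)$n2_flux, 0)
  expect_true(all(diff(n2f) > 0))
})

test_that("map_sample yields all four cells with consistent geometry ordering", {
  em <- water_adjusted_endmembers()
  s <- forward_red_mix(0.87, 0.10, em, "fD")
  cells <- map_sample(s["sp"], s["o"], em, n2o_flux = 1.7)
  expect_equal(nrow(cells), 4)
  expect_setequal(paste(cells$scenario, cells$case),
                  c("bD_fD red_mix", "bD_fD mix_red",
                    "bD_Ni red_mix", "bD_Ni mix_red"))
  expect_equal(cells$f_minor, 1 - cells$f_bd)
  # both cases place the mixture on the same segment point, so f agrees and
  # r(mix_red) = r(red_mix)^f >= r(red_mix)
  for (sc in unique(cells$scenario)) {
    cc <- cells[cells$scenario == sc, ]
    expect_equal(cc$f_bd[cc$case == "red_mix"], cc$f_bd[cc$case == "mix_red"],
                 tolerance = 1e-6)
    expect_gte(cc$r_n2o[cc$case == "mix_red"], cc$r_n2o[cc$case == "red_mix"])
  }
  expect_true(all(nchar(cells$endmember_hash) > 0))
})

test_that("campaign mapping recovers truth within 0.05 under measurement noise", {
  # truth uses only the fD and Ni minors (close to each other), so both
  # scenarios are near-correctly specified
  set.seed(31)
  truth <- truth_config(f_bd = 0.87, f_fd = 0.08, f_nd = 0, f_ni = 0.05,
                        r_n2o = 0.10, mixing_case = "red_mix")
  iso <- simulate_emitted_isotopes(truth, n_samples = 30)
  maps <- do.call(rbind, lapply(seq_len(nrow(iso)), function(i)
    map_sample(iso$sp[i], iso$d18o[i], truth$endmembers)))
  smry <- summarise_campaign(maps)
  expect_true(all(abs(smry$f_bd_mean - 0.87) < 0.05))
  expect_true(all(abs(smry$r_n2o_mean - 0.10) < 0.05))
})
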