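test_that("two-endmember unmixing matches hand arithmetic and limits", {
  amb <- tropospheric_ambient(300)
  amb$d15n_alpha <- 0; amb$d15n_beta <- 0; amb$d18o <- 0
  s <- isotopocule_sample(600, 10, 10, 10, ambient = amb)
  e <- correct_delta_mixing(s)
  # (600*10 - 300*0)/(600-300) = 20 for every delta
  expect_equal(e$d15n_alpha, 20)
  expect_equal(e$d18o, 20)
  expect_equal(e$sp, 0)
  # mixture of identical endmembers returns the shared value
  s2 <- isotopocule_sample(600, 5, -3, 40,
                           ambient = list(conc_ppb = 300, d15n_alpha = 5,
                                          d15n_beta = -3, d18o = 40))
  e2 <- correct_delta_mixing(s2)
  expect_equal(c(e2$d15n_alpha, e2$d15n_beta, e2$d18o), c(5, -3, 40))
  # vanishing background recovers the sample deltas
  s3 <- isotopocule_sample(600, 12, -4, 38,
                           ambient = list(conc_ppb = 1e-9, d15n_alpha = 99,
                                          d15n_beta = 99, d18o = 99))
  e3 <- correct_delta_mixing(s3)
  expect_equal(e3$d15n_alpha, 12, tolerance = 1e-9)
  # sample at or below ambient concentration is excluded, never NaN
  s4 <- isotopocule_sample(300, 10, 10, 10, ambient = amb)
  e4 <- correct_delta_mixing(s4)
  expect_true(e4$excluded)
  expect_match(e4$exclusion_reason, "ambient")
})

test_that("unmixing exactly inverts forward two-pool mixing", {
  amb <- tropospheric_ambient()
  set.seed(11)
  for (i in 1:25) {
    emitted <- list(d15n_alpha = runif(1, -40, 30),
                    d15n_beta = runif(1, -40, 30),
                    d18o = runif(1, 10, 60))
    s <- mixed_headspace_sample(emitted, excess_ppb = runif(1, 5, 500),
                                ambient = amb)
    e <- correct_delta_mixing(s)
    expect_equal(e$d15n_alpha, emitted$d15n_alpha, tolerance = 1e-10)
    expect_equal(e$d15n_beta, emitted$d15n_beta, tolerance = 1e-10)
    expect_equal(e$d18o, emitted$d18o, tolerance = 1e-10)
    expect_equal(e$sp, emitted$d15n_alpha - emitted$d15n_beta,
                 tolerance = 1e-10)
  }
})

test_that("delta-method uncertainty matches Monte Carlo and is monotone", {
  amb <- tropospheric_ambient(272)
  s <- isotopocule_sample(450, 8, -6, 40, ambient = amb)
  # all-zero measurement error propagates to zero
  z <- propagate_mixing_uncertainty(s, sigma_delta = 0, sigma_conc = 0)
  expect_equal(c(z$sigma_sp, z$sigma_d18o, z$sigma_d15n_bulk), c(0, 0, 0))
  # propagated sigma grows monotonically as the sample approaches ambient
  concs <- c(600, 500, 420, 360, 320)
  sig <- vapply(concs, function(cc) {
    propagate_mixing_uncertainty(
      isotopocule_sample(cc, 8, -6, 40, ambient = amb))$sigma_sp
  }, 0)
  expect_true(all(diff(sig) > 0))
  # Monte-Carlo oracle at a smooth point, 1e5 draws
  set.seed(23)
  n <- 1e5
  sd_d <- 0.5; sd_c <- 2
  cs <- rnorm(n, 450, sd_c); ca <- rnorm(n, 272, sd_c)
  da <- rnorm(n, 8, sd_d); db <- rnorm(n, -6, sd_d); do_ <- rnorm(n, 40, sd_d)
  aa <- rnorm(n, amb$d15n_alpha, sd_d); ab <- rnorm(n, amb$d15n_beta, sd_d)
  ao <- rnorm(n, amb$d18o, sd_d)
  g <- function(ds, dam) (cs * ds - ca * dam) / (cs - ca)
  mc_sp <- sd(g(da, aa) - g(db, ab))
  mc_o <- sd(g(do_, ao))
  p <- propagate_mixing_uncertainty(s, sigma_delta = sd_d, sigma_conc = sd_c)
  expect_lt(abs(p$sigma_sp - mc_sp) / mc_sp, 0.05)
  expect_lt(abs(p$sigma_d18o - mc_o) / mc_o, 0.05)
})

test_that("concentration threshold retains the inclusive boundary and logs reasons", {
  amb1 <- tropospheric_ambient(272)
  mk <- function(conc) isotopocule_sample(conc, 8, -6, 40, ambient = amb1)
  # boundary: ambient + margin retained, ambient excluded
  res <- apply_concentration_threshold(list(mk(272 + 65), mk(272.0001)),
                                       margin_ppb = 65)
  expect_equal(res$log$retained, c(TRUE, FALSE))
  expect_match(res$log$reason[2], "below threshold")
  # campaign ambients of 272 and 294 ppb give thresholds 337 and 359 ppb
  expect_equal(res$log$threshold_ppb[1], 337)
  amb2 <- tropospheric_ambient(294)
  res2 <- apply_concentration_threshold(
    list(isotopocule_sample(400, 8, -6, 40, ambient = amb2)))
  expect_equal(res2$log$threshold_ppb, 359)
  # nine-sample fixture with five below threshold keeps four
  concs <- c(280, 300, 320, 330, 336, 340, 380, 500, 700)
  res9 <- apply_concentration_threshold(lapply(concs, mk), margin_ppb = 65)
  expect_length(res9$retained, 4)
  expect_length(res9$excluded, 5)
  expect_equal(sum(res9$log$retained), 4)
  expect_error(apply_concentration_threshold(list(mk(400)), margin_ppb = 0),
               "positive")
})
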