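# shared fixtures built in code

# default endmember table shifted onto the measured-water scale
water_adjusted_endmembers <- function(d18o_h2o = -8.5) {
  adjust_endmembers(load_endmembers(), d18o_h2o)
}

# forward two-endmember generator matching the red-mix solver's model
forward_red_mix <- function(f, r, em, minor = "fD") {
  eb <- c(sp = em$endmembers$bD$sp_mean, o = em$endmembers$bD$d18o_mean)
  mm <- c(sp = em$endmembers[[minor]]$sp_mean,
          o = em$endmembers[[minor]]$d18o_mean)
  b <- rayleigh_residual(eb["sp"], eb["o"], em$reduction, r)
  f * b + (1 - f) * mm
}

# forward generator matching the mix-red solver's model
forward_mix_red <- function(f, r, em, minor = "fD") {
  eb <- c(sp = em$endmembers$bD$sp_mean, o = em$endmembers$bD$d18o_mean)
  mm <- c(sp = em$endmembers[[minor]]$sp_mean,
          o = em$endmembers[[minor]]$d18o_mean)
  m <- f * eb + (1 - f) * mm
  rayleigh_residual(m["sp"], m["o"], em$reduction, r)
}

# chamber ppb series whose umol m-3 concentration is exactly linear in time
linear_ppb_series <- function(slope_umol_m3_h, intercept_umol_m3 = 15,
                              times_h = c(0, 1, 2, 3) / 3,
                              temperature_K = 293.15) {
  conc <- intercept_umol_m3 + slope_umol_m3_h * times_h
  molar_density <- iso_constants$standard_pressure /
    (iso_constants$gas_constant * temperature_K)
  ppb <- conc / (1e-3 * molar_density)
  chamber_series(times_h, ppb, temperature_K = temperature_K)
}

# headspace sample from known emitted deltas by exact forward mixing
mixed_headspace_sample <- function(emitted, excess_ppb, ambient) {
  c_s <- ambient$conc_ppb + excess_ppb
  mixv <- function(de, da) (excess_ppb * de + ambient$conc_ppb * da) / c_s
  isotopocule_sample(c_s,
                     mixv(emitted$d15n_alpha, ambient$d15n_alpha),
                     mixv(emitted$d15n_beta, ambient$d15n_beta),
                     mixv(emitted$d18o, ambient$d18o),
                     ambient = ambient)
}

tropospheric_ambient <- function(conc_ppb = 272) {
  list(conc_ppb = conc_ppb, d15n_alpha = 15.65, d15n_beta = -3.05,
       d18o = 44.4)
}
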