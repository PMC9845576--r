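natural_abundance_15n <- function() {
  iso_constants$r_std_n / (1 + iso_constants$r_std_n)
}

#' Ground-truth configuration of a synthetic labeling experiment
#'
#' Defines every quantity the forward simulator needs, mirroring the design
#' of a hydroponic 15N-labeling campaign: two planted and one unplanted rock
#' wool slab per unit, 15 L of labeled solution mixed into a hidden residual
#' volume, chamber samplings at 0/4/24 h, and emitted N2O generated from a
#' known source-process mixture with known reduction extent.
#'
#' @param f_bd,f_fd,f_nd,f_ni Source fractions of emitted N2O (must sum
#'   to 1). Defaults reflect a bacterial-denitrification-dominated system.
#' @param r_n2o True N2O/(N2O+N2) ratio of denitrification, (0, 1].
#' @param mixing_case `"red_mix"` or `"mix_red"`.
#' @param f_pn2o True fraction of emitted N2O drawn from the NO3- pool.
#' @param endmembers A water-adjusted [load_endmembers()] result; default is
#'   the packaged table adjusted with d18O_H2O = -8.5 permil.
#' @param label A [labeling_config()].
#' @param residual_volume_L Hidden residual solution volume (truth for the
#'   volume estimator).
#' @param residual_nh4_mg_L,residual_no3_mg_L Residual-solution N
#'   concentrations (unlabeled, natural abundance).
#' @param nitrification_frac_per_day Fraction of the NH4+ pool oxidised to
#'   NO3- per day.
#' @param uptake_nh4_mg_h,uptake_no3_mg_h Plant N uptake, mg N h-1 per unit.
#' @param emission_mg_n_h N2O-N emission per unit, mg N h-1.
#' @param n2o_flux_ug_n_m2_h Emitted N2O flux at the chamber scale.
#' @param ambient_ppb,ambient_sp,ambient_d18o,ambient_d15n_bulk Ambient-air
#'   N2O mixing ratio and isotopic composition (tropospheric values).
#' @param sigma_delta,sigma_conc_ppb Measurement noise (permil / ppb).
#' @param loss_frac Fraction of emitted N2O-N lost unmeasured (0 = closed).
#' @param sink_nh4_mg_h,sink_no3_mg_h Unmeasured N sinks (e.g. microbial
#'   immobilisation on the substrate), mg N h-1 drawn from each solution
#'   pool at its current enrichment; the lost 15N is recorded in the truth
#'   sidecar so recovery shortfalls can be checked against it.
#' @return List of class `truth_config`.
#' @export
truth_config <- function(f_bd = 0.87, f_fd = 0.06, f_nd = 0.04, f_ni = 0.03,
                         r_n2o = 0.10, mixing_case = c("red_mix", "mix_red"),
                         f_pn2o = 0.68,
                         endmembers = adjust_endmembers(load_endmembers(), -8.5),
                         label = labeling_config("NH4_15"),
                         residual_volume_L = 15,
                         residual_nh4_mg_L = 1.6, residual_no3_mg_L = 166,
                         nitrification_frac_per_day = 0.02,
                         uptake_nh4_mg_h = 4, uptake_no3_mg_h = 10,
                         emission_mg_n_h = 0.04,
                         n2o_flux_ug_n_m2_h = 1.7,
                         ambient_ppb = 272, ambient_sp = 18.7,
                         ambient_d18o = 44.4, ambient_d15n_bulk = 6.3,
                         sigma_delta = 0.5, sigma_conc_ppb = 2,
                         loss_frac = 0,
                         sink_nh4_mg_h = 0, sink_no3_mg_h = 0) {
  mixing_case <- match.arg(mixing_case)
  fr <- c(f_bd, f_fd, f_nd, f_ni)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("source fractions must be non-negative and sum to 1")
  }
  if (r_n2o <= 0 || r_n2o > 1) stop("r_n2o must lie in (0, 1]")
  if (f_pn2o < 0 || f_pn2o > 1) stop("f_pn2o must lie in [0, 1]")
  if (loss_frac < 0 || loss_frac >= 1) stop("loss_frac must lie in [0, 1)")
  structure(as.list(environment()), class = "truth_config")
}

#' Forward-simulate emitted-N2O isotope signatures
#'
#' Generates (SP, d18O) of substrate-emitted N2O under the configured
#' mixing/reduction order. red-mix: bD-derived N2O is Rayleigh-reduced to
#' remaining fraction r, then mixed with the minor-process N2O (weighted
#' mean of the non-bD endmembers by their truth fractions). mix-red: all
#' sources mix first and the mixture is reduced. Gaussian measurement noise
#' `sigma_delta` is added to each replicate.
#'
#' @param truth A [truth_config()].
#' @param n_samples Number of replicate samples.
#' @param noise Add measurement noise? (`FALSE` returns the exact truth
#'   point replicated.)
#' @return data.frame with `sp`, `d18o`; attribute `truth_point` holds the
#'   noise-free values.
#' @export
simulate_emitted_isotopes <- function(truth, n_samples = 1, noise = TRUE) {
  stopifnot(inherits(truth, "truth_config"))
  em <- truth$endmembers
  eps <- em$reduction
  eb <- em_point(em, "bD")
  w <- c(fD = truth$f_fd, nD = truth$f_nd, Ni = truth$f_ni)
  minor <- if (sum(w) > 0) {
    pts <- vapply(names(w), function(p) em_point(em, p), numeric(2))
    as.numeric(pts %*% (w / sum(w)))
  } else eb  # pure bD: minor point unused
  names(minor) <- c("sp", "o")
  f <- truth$f_bd
  if (truth$mixing_case == "red_mix") {
    b <- rayleigh_residual(eb["sp"], eb["o"], eps, truth$r_n2o)
    pt <- f * b + (1 - f) * minor
  } else {
    m <- f * eb + (1 - f) * minor
    pt <- rayleigh_residual(m["sp"], m["o"], eps, truth$r_n2o)
  }
  names(pt) <- c("sp", "o")
  sp <- rep(pt["sp"], n_samples)
  o <- rep(pt["o"], n_samples)
  if (noise) {
    # SP noise comes from two position deltas
    sp <- sp + stats::rnorm(n_samples, 0, truth$sigma_delta * sqrt(2))
    o <- o + stats::rnorm(n_samples, 0, truth$sigma_delta)
  }
  out <- data.frame(sp = as.numeric(sp), d18o = as.numeric(o))
  attr(out, "truth_point") <- c(sp = unname(pt["sp"]), d18o = unname(pt["o"]))
  out
}

#' Forward-simulate a closed-chamber concentration time series
#'
#' Linear accumulation above the ambient baseline at the rate implied by the
#' flux and the chamber geometry, sampled at 0/20/40/60 min, with iid
#' Gaussian ppb noise.
#'
#' @param truth A [truth_config()].
#' @param flux_ug_n_m2_h Emitted N2O flux (default from the truth).
#' @param temperature_K Chamber temperature.
#' @param volume_m3,area_m2 Chamber geometry.
#' @param noise Add ppb noise?
#' @return A [chamber_series()].
#' @export
simulate_chamber_series <- function(truth,
                                    flux_ug_n_m2_h = truth$n2o_flux_ug_n_m2_h,
                                    temperature_K = 293.15,
                                    volume_m3 = 0.016, area_m2 = 1,
                                    noise = TRUE) {
  stopifnot(inherits(truth, "truth_config"), flux_ug_n_m2_h >= 0)
  t_h <- c(0, 20, 40, 60) / 60
  flux_umol <- flux_ug_n_m2_h / (2 * iso_constants$molar_mass_n)
  rate_umol_m3_h <- flux_umol * area_m2 / volume_m3
  molar_density <- iso_constants$standard_pressure /
    (iso_constants$gas_constant * temperature_K)  # mol m-3
  rate_ppb_h <- rate_umol_m3_h / (1e-3 * molar_density)
  ppb <- truth$ambient_ppb + rate_ppb_h * t_h
  if (noise) ppb <- ppb + stats::rnorm(length(t_h), 0, truth$sigma_conc_ppb)
  chamber_series(t_h, ppb, temperature_K = temperature_K,
                 volume_m3 = volume_m3, area_m2 = area_m2)
}

#' Forward-simulate 15N pool dynamics and labeled-gas measurements
#'
#' Hourly bookkeeping over 24 h for one experimental unit: the 15 L labeled
#' solution mixes instantly into the hidden residual volume; nitrification
#' transfers NH4+-N (at the current NH4+ enrichment) to the NO3- pool; plant
#' uptake removes N from each pool at its current enrichment; N2O emission
#' draws `f_pn2o` of its N from the NO3- pool and the rest from NH4+. All N
#' and 15N amounts are conserved (up to the configured `loss_frac` applied
#' to the emitted N2O).
#'
#' @param truth A [truth_config()].
#' @param times_h Output times (default `c(0, 4, 24)`; 0 is pre-labeling).
#' @param noise Add measurement noise to concentrations/enrichments?
#' @return List with `pools` (per time: NH4/NO3 concentration, atom
#'   fraction, APE), `plant` (cumulative plant N and 15N), `gas` (per
#'   interval: emitted N2O-N, its 15N atom fraction, and chamber-mixed
#'   R45/R46 with concentrations), and `truth` (total volume, pool
#'   trajectories, cumulative emission) for recovery tests.
#' @export
simulate_label_dynamics <- function(truth, times_h = c(0, 4, 24), noise = TRUE) {
  stopifnot(inherits(truth, "truth_config"))
  a_nat <- natural_abundance_15n()
  lab <- truth$label
  v_res <- truth$residual_volume_L
  v_tot <- v_res + lab$solution_volume_L

  # labeled solution: equal NH4-N and NO3-N, one moiety enriched
  n_lab <- lab$nh4_conc_mg_L * lab$solution_volume_L  # mg N per moiety
  a_label <- lab$label_atom_pct / 100
  nh4_n <- n_lab + truth$residual_nh4_mg_L * v_res
  no3_n <- n_lab + truth$residual_no3_mg_L * v_res
  nh4_15 <- n_lab * (if (lab$label_form == "NH4_15") a_label else a_nat) +
    truth$residual_nh4_mg_L * v_res * a_nat
  no3_15 <- n_lab * (if (lab$label_form == "NO3_15") a_label else a_nat) +
    truth$residual_no3_mg_L * v_res * a_nat

  plant_n <- 0; plant_15 <- 0
  gas_n <- 0; gas_15 <- 0
  lost_n <- 0; lost_15 <- 0
  pools <- list(); gas_rows <- list()
  snap <- function(t) {
    data.frame(time_h = t,
               nh4_mg_L = nh4_n / v_tot, no3_mg_L = no3_n / v_tot,
               a_nh4 = nh4_15 / nh4_n, a_no3 = no3_15 / no3_n,
               ape_nh4 = 100 * (nh4_15 / nh4_n - a_nat),
               ape_no3 = 100 * (no3_15 / no3_n - a_nat))
  }
  # pre-labeling snapshot: residual solution only, natural abundance
  pools[[1]] <- data.frame(time_h = 0,
                           nh4_mg_L = truth$residual_nh4_mg_L,
                           no3_mg_L = truth$residual_no3_mg_L,
                           a_nh4 = a_nat, a_no3 = a_nat,
                           ape_nh4 = 0, ape_no3 = 0)

  nitr_h <- truth$nitrification_frac_per_day / 24
  gas_mark_n <- 0; gas_mark_15 <- 0
  int_no3_n <- 0; int_no3_15 <- 0; int_nh4_n <- 0; int_nh4_15 <- 0
  for (h in seq_len(max(times_h))) {
    a_nh4 <- nh4_15 / nh4_n
    a_no3 <- no3_15 / no3_n
    # nitrification NH4 -> NO3 at current NH4 enrichment
    dn <- nitr_h * nh4_n
    nh4_n <- nh4_n - dn; nh4_15 <- nh4_15 - dn * a_nh4
    no3_n <- no3_n + dn; no3_15 <- no3_15 + dn * a_nh4
    # plant uptake
    u_nh4 <- min(truth$uptake_nh4_mg_h, nh4_n)
    u_no3 <- min(truth$uptake_no3_mg_h, no3_n)
    nh4_n <- nh4_n - u_nh4; nh4_15 <- nh4_15 - u_nh4 * a_nh4
    no3_n <- no3_n - u_no3; no3_15 <- no3_15 - u_no3 * a_no3
    plant_n <- plant_n + u_nh4 + u_no3
    plant_15 <- plant_15 + u_nh4 * a_nh4 + u_no3 * a_no3
    # unmeasured sink (lost from the balance; truth sidecar keeps the tally)
    s_nh4 <- min(truth$sink_nh4_mg_h, nh4_n)
    s_no3 <- min(truth$sink_no3_mg_h, no3_n)
    nh4_n <- nh4_n - s_nh4; nh4_15 <- nh4_15 - s_nh4 * a_nh4
    no3_n <- no3_n - s_no3; no3_15 <- no3_15 - s_no3 * a_no3
    lost_n <- lost_n + s_nh4 + s_no3
    lost_15 <- lost_15 + s_nh4 * a_nh4 + s_no3 * a_no3
    # N2O emission drawing from both pools with the truth source split
    e <- truth$emission_mg_n_h
    e_no3 <- e * truth$f_pn2o; e_nh4 <- e - e_no3
    no3_n <- no3_n - e_no3; no3_15 <- no3_15 - e_no3 * a_no3
    nh4_n <- nh4_n - e_nh4; nh4_15 <- nh4_15 - e_nh4 * a_nh4
    kept <- 1 - truth$loss_frac
    gas_n <- gas_n + e * kept
    gas_15 <- gas_15 + (e_no3 * a_no3 + e_nh4 * a_nh4) * kept
    lost_n <- lost_n + e * (1 - kept)
    lost_15 <- lost_15 + (e_no3 * a_no3 + e_nh4 * a_nh4) * (1 - kept)
    int_no3_n <- int_no3_n + e_no3; int_no3_15 <- int_no3_15 + e_no3 * a_no3
    int_nh4_n <- int_nh4_n + e_nh4; int_nh4_15 <- int_nh4_15 + e_nh4 * a_nh4
    if (h %in% times_h) {
      pools[[length(pools) + 1L]] <- snap(h)
      # gas sampled over the interval since the previous output time:
      # chamber headspace = emitted N2O (NO3- and NH4-derived components,
      # each binomially labeled at its pool enrichment) accumulated above
      # the atmospheric baseline, which carries natural-abundance 15N
      int_n <- int_no3_n + int_nh4_n
      a_gas <- if (int_n > 0) (int_no3_15 + int_nh4_15) / int_n else a_nat
      excess_ppb <- 130
      conc_ppb <- truth$ambient_ppb + excess_ppb
      iso <- mixture_isotopologue_ratios(
        weights = c(excess_ppb * int_no3_n / int_n,
                    excess_ppb * int_nh4_n / int_n,
                    truth$ambient_ppb),
        a = c(if (int_no3_n > 0) int_no3_15 / int_no3_n else a_nat,
              if (int_nh4_n > 0) int_nh4_15 / int_nh4_n else a_nat,
              a_nat))
      gas_rows[[length(gas_rows) + 1L]] <- data.frame(
        time_h = h, interval_n2o_mg = gas_n - gas_mark_n,
        a15_emitted = a_gas,
        f_pn2o_emitted = int_no3_n / int_n,
        conc_ppb = conc_ppb, ambient_ppb = truth$ambient_ppb,
        a15_chamber = iso$a_m, R45 = iso$R45, R46 = iso$R46)
      gas_mark_n <- gas_n; gas_mark_15 <- gas_15
      int_no3_n <- 0; int_no3_15 <- 0; int_nh4_n <- 0; int_nh4_15 <- 0
    }
  }
  pools_df <- do.call(rbind, pools)
  gas_df <- do.call(rbind, gas_rows)

  if (noise) {
    k <- nrow(pools_df)
    pools_df$nh4_mg_L <- pmax(pools_df$nh4_mg_L *
                                (1 + stats::rnorm(k, 0, 0.02)), 1e-6)
    pools_df$no3_mg_L <- pmax(pools_df$no3_mg_L *
                                (1 + stats::rnorm(k, 0, 0.02)), 1e-6)
  }
  list(pools = pools_df, gas = gas_df,
       plant = data.frame(n_mg = plant_n, n15_mg = plant_15),
       truth = list(volume_L = v_tot,
                    nh4_n = nh4_n, no3_n = no3_n,
                    nh4_15 = nh4_15, no3_15 = no3_15,
                    plant_n = plant_n, plant_15 = plant_15,
                    gas_n = gas_n, gas_15 = gas_15,
                    lost_n = lost_n, lost_15 = lost_15,
                    a_nat = a_nat))
}

#' Mix emitted-N2O isotope values into chamber headspace samples
#'
#' Forward two-pool mixing of substrate-emitted N2O with the atmospheric
#' baseline, producing the [isotopocule_sample()] objects the inverse
#' pipeline (threshold filter + mixing correction) starts from.
#'
#' @param truth A [truth_config()].
#' @param emitted data.frame with `sp` and `d18o` of emitted N2O.
#' @param excess_ppb Emitted-N2O concentration excess above ambient per
#'   sample (recycled); values below the exclusion margin are deliberately
#'   allowed so the threshold filter has work to do.
#' @param emitted_d15n_bulk Bulk delta-15N of the emitted N2O (permil).
#' @return List of [isotopocule_sample()] objects.
#' @export
simulate_chamber_isotopocules <- function(truth, emitted,
                                          excess_ppb = c(20, 80, 130, 200, 260, 300),
                                          emitted_d15n_bulk = -25) {
  stopifnot(inherits(truth, "truth_config"))
  amb <- list(conc_ppb = truth$ambient_ppb,
              d15n_alpha = truth$ambient_d15n_bulk + truth$ambient_sp / 2,
              d15n_beta = truth$ambient_d15n_bulk - truth$ambient_sp / 2,
              d18o = truth$ambient_d18o)
  ex <- rep_len(excess_ppb, nrow(emitted))
  out <- vector("list", nrow(emitted))
  for (i in seq_len(nrow(emitted))) {
    c_s <- truth$ambient_ppb + ex[i]
    e_alpha <- emitted_d15n_bulk + emitted$sp[i] / 2
    e_beta <- emitted_d15n_bulk - emitted$sp[i] / 2
    mixv <- function(de, da) (ex[i] * de + truth$ambient_ppb * da) / c_s
    out[[i]] <- isotopocule_sample(
      conc_ppb = c_s,
      d15n_alpha = mixv(e_alpha, amb$d15n_alpha),
      d15n_beta = mixv(e_beta, amb$d15n_beta),
      d18o = mixv(emitted$d18o[i], amb$d18o),
      ambient = amb)
  }
  out
}

#' Run the full synthetic experiment for one unit
#'
#' Bundles the forward simulators and a truth sidecar; with `seed` set the
#' dataset is bit-exactly regenerable.
#'
#' @param truth A [truth_config()].
#' @param seed Optional integer seed.
#' @param n_iso_samples Replicate isotopocule samples per campaign.
#' @return List of class `synthetic_dataset` with `isotopes` (emitted
#'   values), `headspace` (chamber-mixed [isotopocule_sample()]s),
#'   `chamber` (concentration time series), `label_dynamics` and `truth`.
#' @export
simulate_experiment <- function(truth = truth_config(), seed = NULL,
                                n_iso_samples = 6) {
  if (!is.null(seed)) set.seed(seed)
  iso <- simulate_emitted_isotopes(truth, n_samples = n_iso_samples)
  head <- simulate_chamber_isotopocules(truth, iso)
  ch <- simulate_chamber_series(truth)
  lab <- simulate_label_dynamics(truth)
  structure(list(isotopes = iso, headspace = head, chamber = ch,
                 label_dynamics = lab, truth = truth, seed = seed),
            class = "synthetic_dataset")
}
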