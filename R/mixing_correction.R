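#' Default measurement uncertainties for headspace isotopocule samples
#'
#' Typical IRMS / GC performance: 0.5 permil per delta value and 2 ppb per
#' concentration. Used by [propagate_mixing_uncertainty()] when no
#' measurement sigmas are supplied.
#' @export
default_measurement_sigmas <- function() {
  list(sigma_delta = 0.5, sigma_conc = 2)
}

#' A chamber-headspace isotopocule sample with its ambient-air reference
#'
#' The N2O collected from a closed chamber is a mixture of atmospheric N2O
#' and substrate-emitted N2O; each sample therefore carries the ambient-air
#' concentration and delta values needed to unmix it.
#'
#' @param conc_ppb Total headspace N2O, ppb (> 0).
#' @param d15n_alpha,d15n_beta delta-15N of the central/peripheral N, permil
#'   vs air N2.
#' @param d18o delta-18O, permil vs VSMOW.
#' @param ambient A list with the same four fields for ambient air.
#' @param campaign_id Optional campaign label (ambient values are
#'   campaign-specific).
#' @return Object of class `isotopocule_sample`.
#' @export
isotopocule_sample <- function(conc_ppb, d15n_alpha, d15n_beta, d18o,
                               ambient, campaign_id = NA_character_) {
  stopifnot(conc_ppb > 0, ambient$conc_ppb > 0)
  for (f in c("conc_ppb", "d15n_alpha", "d15n_beta", "d18o")) {
    if (is.null(ambient[[f]])) stop("ambient reference is missing field ", f)
  }
  structure(list(conc_ppb = conc_ppb, d15n_alpha = d15n_alpha,
                 d15n_beta = d15n_beta, d18o = d18o,
                 ambient = ambient, campaign_id = campaign_id),
            class = "isotopocule_sample")
}

two_pool_delta <- function(c_s, c_atm, d_s, d_atm) {
  (c_s * d_s - c_atm * d_atm) / (c_s - c_atm)
}

#' Remove the atmospheric N2O contribution from measured delta values
#'
#' Two-endmember unmixing: with total concentration C_s and ambient
#' concentration C_atm, the substrate-emitted delta is
#' `(C_s d_s - C_atm d_atm) / (C_s - C_atm)`. The correction is applied to
#' delta-15N-alpha, delta-15N-beta and delta-18O separately; site preference
#' is formed afterwards (correcting alpha and beta is exact because mixing is
#' linear in each, whereas SP of a mixture is not the mixture of SPs).
#'
#' @param sample An [isotopocule_sample()].
#' @return List of class `emitted_delta` with `sp`, `d18o`, `d15n_bulk`,
#'   `d15n_alpha`, `d15n_beta`, `excluded` and `exclusion_reason`. When the
#'   sample concentration does not exceed ambient the sample is marked
#'   excluded (no NaN propagation).
#' @export
correct_delta_mixing <- function(sample) {
  stopifnot(inherits(sample, "isotopocule_sample"))
  amb <- sample$ambient
  if (sample$conc_ppb <= amb$conc_ppb) {
    return(structure(list(sp = NA_real_, d18o = NA_real_, d15n_bulk = NA_real_,
                          d15n_alpha = NA_real_, d15n_beta = NA_real_,
                          excluded = TRUE,
                          exclusion_reason = "sample N2O concentration does not exceed ambient"),
                     class = "emitted_delta"))
  }
  a <- two_pool_delta(sample$conc_ppb, amb$conc_ppb, sample$d15n_alpha, amb$d15n_alpha)
  b <- two_pool_delta(sample$conc_ppb, amb$conc_ppb, sample$d15n_beta, amb$d15n_beta)
  o <- two_pool_delta(sample$conc_ppb, amb$conc_ppb, sample$d18o, amb$d18o)
  structure(list(sp = a - b, d18o = o, d15n_bulk = (a + b) / 2,
                 d15n_alpha = a, d15n_beta = b,
                 excluded = FALSE, exclusion_reason = NA_character_),
            class = "emitted_delta")
}

#' Gaussian (delta-method) error propagation through the mixing correction
#'
#' First-order propagation of measurement uncertainties through the
#' two-endmember unmixing formula. The concentration terms are shared
#' between the alpha and beta corrections, so the site-preference variance is
#' computed jointly (the shared-concentration covariance does not cancel).
#'
#' @param sample An [isotopocule_sample()].
#' @param sigma_delta 1-sigma uncertainty of each measured delta (sample and
#'   ambient), permil.
#' @param sigma_conc 1-sigma uncertainty of each concentration (sample and
#'   ambient), ppb.
#' @return List with `sigma_sp`, `sigma_d18o`, `sigma_d15n_bulk` (permil).
#' @export
propagate_mixing_uncertainty <- function(sample,
                                         sigma_delta = default_measurement_sigmas()$sigma_delta,
                                         sigma_conc = default_measurement_sigmas()$sigma_conc) {
  stopifnot(inherits(sample, "isotopocule_sample"))
  if (any(c(sigma_delta, sigma_conc) < 0)) stop("sigmas must be >= 0")
  amb <- sample$ambient
  cs <- sample$conc_ppb; ca <- amb$conc_ppb
  D <- cs - ca
  if (D <= 0) stop("sample concentration must exceed ambient for propagation")

  # single-delta unmixing g = (cs*ds - ca*da)/D:
  #   dg/dds = cs/D, dg/dda = -ca/D,
  #   dg/dcs = ca*(da - ds)/D^2, dg/dca = cs*(ds - da)/D^2
  var_single <- function(ds, da) {
    (cs / D)^2 * sigma_delta^2 + (ca / D)^2 * sigma_delta^2 +
      (ca * (da - ds) / D^2)^2 * sigma_conc^2 +
      (cs * (ds - da) / D^2)^2 * sigma_conc^2
  }
  # SP = g_alpha - g_beta shares cs, ca: the concentration partials combine
  # before squaring, with (da - ds) replaced by (SP_atm - SP_sample).
  sp_s <- sample$d15n_alpha - sample$d15n_beta
  sp_a <- amb$d15n_alpha - amb$d15n_beta
  var_sp <- 2 * (cs / D)^2 * sigma_delta^2 + 2 * (ca / D)^2 * sigma_delta^2 +
    (ca * (sp_a - sp_s) / D^2)^2 * sigma_conc^2 +
    (cs * (sp_s - sp_a) / D^2)^2 * sigma_conc^2
  # bulk = (g_alpha + g_beta)/2, same joint treatment
  bk_s <- (sample$d15n_alpha + sample$d15n_beta) / 2
  bk_a <- (amb$d15n_alpha + amb$d15n_beta) / 2
  var_bulk <- (cs / D)^2 * sigma_delta^2 / 2 + (ca / D)^2 * sigma_delta^2 / 2 +
    (ca * (bk_a - bk_s) / D^2)^2 * sigma_conc^2 +
    (cs * (bk_s - bk_a) / D^2)^2 * sigma_conc^2
  list(sigma_sp = sqrt(var_sp),
       sigma_d18o = sqrt(var_single(sample$d18o, amb$d18o)),
       sigma_d15n_bulk = sqrt(var_bulk))
}

#' Exclude samples too close to the ambient N2O concentration
#'
#' The uncertainty of the unmixed deltas grows without bound as the sample
#' and ambient concentrations converge, so samples below a minimum margin
#' above ambient are excluded before mapping. The boundary is inclusive: a
#' sample exactly at ambient + margin is retained. With the default 65 ppb
#' margin, campaign ambients of 272 and 294 ppb give absolute thresholds of
#' 337 and 359 ppb.
#'
#' @param samples A list of [isotopocule_sample()] objects.
#' @param margin_ppb Minimum concentration difference, ppb (> 0, default 65).
#' @param ambient_ppb Optional ambient override; by default each sample's own
#'   ambient reference is used (per campaign).
#' @return List with `retained`, `excluded` (both lists of samples) and a
#'   data.frame `log` of every sample with its decision and reason.
#' @export
apply_concentration_threshold <- function(samples, margin_ppb = 65,
                                          ambient_ppb = NULL) {
  if (margin_ppb <= 0) stop("margin_ppb must be positive")
  keep <- logical(length(samples))
  reason <- character(length(samples))
  thr <- numeric(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    amb <- if (is.null(ambient_ppb)) s$ambient$conc_ppb else ambient_ppb
    thr[i] <- amb + margin_ppb
    keep[i] <- s$conc_ppb >= thr[i]
    reason[i] <- if (keep[i]) NA_character_ else
      sprintf("concentration %.1f ppb below threshold %.1f ppb (ambient %.1f + margin %.1f)",
              s$conc_ppb, thr[i], amb, margin_ppb)
  }
  list(retained = samples[keep],
       excluded = samples[!keep],
       log = data.frame(index = seq_along(samples),
                        conc_ppb = vapply(samples, function(s) s$conc_ppb, 0),
                        threshold_ppb = thr, retained = keep,
                        reason = reason, stringsAsFactors = FALSE))
}
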