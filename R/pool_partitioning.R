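#' Oxygen atom fractions for the isotopologue correction
#'
#' 17O is tied to 18O by the mass-dependent relation
#' `17R = 17R_VSMOW * (18R / 18R_VSMOW)^beta` with beta = 0.516.
#'
#' @param d18o d18O of the N2O oxygen, permil vs VSMOW (default 0: natural
#'   abundance; labeled-gas samples are evaluated for bulk 15N only, so the
#'   oxygen composition is assumed natural unless measured).
#' @return List with atom fractions `x16`, `x17`, `x18`.
#' @export
oxygen_atom_fractions <- function(d18o = 0) {
  r18 <- (d18o / 1000 + 1) * iso_constants$r18_vsmow
  r17 <- iso_constants$r17_vsmow *
    (r18 / iso_constants$r18_vsmow)^iso_constants$beta_o17
  x16 <- 1 / (1 + r17 + r18)
  list(x16 = x16, x17 = r17 * x16, x18 = r18 * x16)
}

#' Forward two-pool N2O isotopologue model
#'
#' Generates the molecular isotopologue composition of N2O formed from two N
#' pools, a labeled pool (15N atom fraction `ap`, contributing fraction `x`
#' of the N2O) and a background pool (atom fraction `a_bgd`). Within each
#' pool the two N positions are assumed independently (binomially) labeled.
#' Oxygen isotopes are independent of nitrogen.
#'
#' @param x Fraction of N2O from the labeled pool, 0-1.
#' @param ap 15N atom fraction of the labeled pool.
#' @param a_bgd 15N atom fraction of the background pool.
#' @param d18o d18O of the N2O oxygen (permil vs VSMOW) for the O terms.
#' @return List with ion-current ratios `R45`, `R46` (45/44 and 46/44),
#'   the bulk 15N atom fraction `a_m` and the 15N15N species fraction `m2`.
#' @export
forward_isotopologues <- function(x, ap, a_bgd, d18o = 0) {
  stopifnot(x >= 0, x <= 1, ap >= 0, ap <= 1, a_bgd >= 0, a_bgd <= 1)
  p0 <- x * (1 - ap)^2 + (1 - x) * (1 - a_bgd)^2      # 14N14N
  p1 <- 2 * (x * ap * (1 - ap) + (1 - x) * a_bgd * (1 - a_bgd))  # one 15N
  p2 <- x * ap^2 + (1 - x) * a_bgd^2                  # 15N15N
  ox <- oxygen_atom_fractions(d18o)
  n44 <- p0 * ox$x16
  n45 <- p1 * ox$x16 + p0 * ox$x17
  n46 <- p2 * ox$x16 + p1 * ox$x17 + p0 * ox$x18
  list(R45 = n45 / n44, R46 = n46 / n44,
       a_m = p2 + p1 / 2, m2 = p2)
}

#' Isotopologue ratios of N2O mixed from several binomially labeled pools
#'
#' Generalisation of [forward_isotopologues()] to any number of source
#' pools: each contributes `weights[i]` of the N2O with 15N atom fraction
#' `a[i]`, binomially distributed over the two N positions.
#'
#' @param weights Non-negative mixing weights (normalised internally).
#' @param a 15N atom fractions of the pools.
#' @param d18o d18O of the N2O oxygen, permil vs VSMOW.
#' @return List with `R45`, `R46`, `a_m`, `m2` as in
#'   [forward_isotopologues()].
#' @export
mixture_isotopologue_ratios <- function(weights, a, d18o = 0) {
  stopifnot(length(weights) == length(a), all(weights >= 0), sum(weights) > 0,
            all(a >= 0), all(a <= 1))
  w <- weights / sum(weights)
  p0 <- sum(w * (1 - a)^2)
  p1 <- sum(w * 2 * a * (1 - a))
  p2 <- sum(w * a^2)
  ox <- oxygen_atom_fractions(d18o)
  n44 <- p0 * ox$x16
  n45 <- p1 * ox$x16 + p0 * ox$x17
  n46 <- p2 * ox$x16 + p1 * ox$x17 + p0 * ox$x18
  list(R45 = n45 / n44, R46 = n46 / n44, a_m = p2 + p1 / 2, m2 = p2)
}

#' Extract bulk 15N and the 15N15N species fraction from ion-current ratios
#'
#' Inverts the oxygen contributions of [forward_isotopologues()]: with known
#' (mass-dependently linked) 17O/18O abundances, `R45` and `R46` yield the
#' nitrogen isotopologue proportions and hence the bulk 15N atom fraction
#' `a_m` and the doubly-labeled species fraction `m2`.
#'
#' @param R45,R46 Ion-current ratios 45/44 and 46/44 (> 0).
#' @param d18o Assumed d18O of the N2O oxygen, permil vs VSMOW.
#' @return List with `a_m` and `m2`.
#' @export
ratios_to_nitrogen_fractions <- function(R45, R46, d18o = 0) {
  if (any(c(R45, R46) <= 0)) stop("ion-current ratios must be positive")
  ox <- oxygen_atom_fractions(d18o)
  q17 <- ox$x17 / ox$x16
  q18 <- ox$x18 / ox$x16
  g1 <- R45 - q17               # = p1/p0
  g2 <- R46 - g1 * q17 - q18    # = p2/p0
  if (g1 < 0 || g2 < 0) stop("ratios below the oxygen-only baseline; check d18o assumption")
  p0 <- 1 / (1 + g1 + g2)
  p1 <- g1 * p0
  p2 <- g2 * p0
  list(a_m = p2 + p1 / 2, m2 = p2)
}

#' Two-pool non-equilibrium partitioning of labeled N2O
#'
#' When N2O derives from two pools of different 15N enrichment, its
#' isotopologue distribution is non-random: the doubly-labeled (mass 46 N
#' part) excess over the binomial expectation identifies both the enrichment
#' of the labeled pool actually producing N2O (`ap`) and the fraction of
#' N2O from that pool (`x`). With `u = a_m - a_bgd` and `v = m2 - a_bgd^2`:
#' `ap = v/u - a_bgd` and `x = u / (ap - a_bgd)` (exact under binomial
#' within-pool labeling).
#'
#' @param a_m Bulk 15N atom fraction of the measured N2O.
#' @param m2 15N15N species fraction of the measured N2O.
#' @param a_bgd 15N atom fraction of the background (unlabeled) pool.
#' @return List with `ap`, `x`, and `below_detection` (TRUE when
#'   `a_m <= a_bgd`, in which case `ap`/`x` are NA); `ap > 1` is flagged via
#'   `out_of_domain`.
#' @export
two_pool_nonequilibrium <- function(a_m, m2, a_bgd) {
  u <- a_m - a_bgd
  if (u <= 0) {
    return(list(ap = NA_real_, x = NA_real_,
                below_detection = TRUE, out_of_domain = FALSE))
  }
  v <- m2 - a_bgd^2
  ap <- v / u - a_bgd
  x <- u / (ap - a_bgd)
  list(ap = ap, x = x, below_detection = FALSE,
       out_of_domain = ap > 1 || x > 1 + 1e-9 || x < 0)
}

#' Rescale a labeled fraction from the measured to the emitted N2O basis
#'
#' Chamber samples contain atmospheric N2O carrying no label; the fraction
#' of MEASURED N2O from the labeled pool therefore understates the fraction
#' of EMITTED N2O. Rescales by total/(total - ambient) concentration.
#'
#' @param x_total Fraction of measured N2O from the labeled pool.
#' @param conc_ppb Total sample N2O concentration, ppb.
#' @param ambient_ppb Ambient N2O concentration, ppb (< conc_ppb).
#' @return List with `f_emitted` (clipped to `[0, 1]`), `raw` and `clipped`.
#' @export
atmospheric_correction_fraction <- function(x_total, conc_ppb, ambient_ppb) {
  if (conc_ppb <= ambient_ppb) stop("sample concentration must exceed ambient")
  raw <- x_total * conc_ppb / (conc_ppb - ambient_ppb)
  list(f_emitted = clip01(raw), raw = raw, clipped = raw < 0 || raw > 1)
}

#' Fraction of NO3-derived N2O from a two-source mixing equation
#'
#' For units labeled with 15NH4+, labeled N2O can originate from either pool
#' (nitrification moves label into NO3-), so the labeled-pool fraction is
#' ambiguous; instead the bulk 15N atom fraction of emitted N2O is placed on
#' the mixing line between the two measured pool enrichments:
#' `f_PN2O = (a_N2O - a_NH4) / (a_NO3 - a_NH4)`.
#' Pool enrichments should be the measured values at the matching time point
#' (label dilution in the pools matters), not nominal label strengths.
#'
#' @param a_n2o 15N atom fraction of emitted N2O.
#' @param a_no3,a_nh4 15N atom fractions of the NO3- and NH4+ pools.
#' @return List with `f_pn2o` (clipped), `raw` and `clipped`.
#' @export
f_from_mixing <- function(a_n2o, a_no3, a_nh4) {
  if (a_no3 == a_nh4) stop("pool enrichments are equal; mixing fraction undefined")
  raw <- (a_n2o - a_nh4) / (a_no3 - a_nh4)
  list(f_pn2o = clip01(raw), raw = raw, clipped = raw < 0 || raw > 1)
}

#' Split a total N2O flux into NO3-derived and NH4-derived components
#'
#' `no3_derived = f_PN2O * total`; the NH4-derived flux is the remainder.
#' Assumes the labeled-pool emission grew linearly over the chamber closure,
#' like the total.
#'
#' @param f_pn2o Fraction of emitted N2O derived from the NO3- pool, 0-1.
#' @param total_flux Total N2O flux (any unit).
#' @return List with `no3_derived`, `nh4_derived` (same unit); they sum to
#'   `total_flux` exactly.
#' @export
partition_flux <- function(f_pn2o, total_flux) {
  stopifnot(f_pn2o >= 0, f_pn2o <= 1)
  no3 <- f_pn2o * total_flux
  list(no3_derived = no3, nh4_derived = total_flux - no3)
}

#' Combined nitrifier-denitrification / coupled fraction
#'
#' The isotopocule map attributes `f_bD` of emitted N2O to bacterial (plus,
#' unresolvably, nitrifier) denitrification, while 15N tracing attributes
#' `f_PN2O` to the NO3- pool; their difference estimates the share of
#' NH4-derived N2O passing through denitrification-type chemistry
#' (nitrifier denitrification and coupled nitrification-denitrification).
#' A negative difference is retained and flagged: it signals violation of
#' the equal-active-pool assumption rather than a physical fraction.
#'
#' @param f_bd Fraction of emitted N2O from (bacterial) denitrification.
#' @param f_pn2o Fraction of emitted N2O from the NO3- pool.
#' @return List with `f_nd_cnd` and `assumption_violated` flag.
#' @export
nd_cnd_fraction <- function(f_bd, f_pn2o) {
  stopifnot(f_bd >= 0, f_bd <= 1, f_pn2o >= 0, f_pn2o <= 1)
  d <- f_bd - f_pn2o
  list(f_nd_cnd = d, assumption_violated = d < 0)
}
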