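#' Physical constants used throughout the package
#'
#' A single source of truth for the isotope-ratio and gas constants every
#' other function relies on. `r_std_n` is the 15N/14N ratio of atmospheric
#' N2, the reference for all delta-15N values handled here; `r17_vsmow` and
#' `r18_vsmow` anchor the mass-dependent 17O correction of isotopologue
#' ratios.
#'
#' @format A list with elements:
#' \describe{
#'   \item{r_std_n}{15N/14N of atmospheric N2 (0.0036765).}
#'   \item{r17_vsmow, r18_vsmow}{17O/16O and 18O/16O of VSMOW.}
#'   \item{beta_o17}{Exponent of the mass-dependent 17O/18O relation.}
#'   \item{molar_mass_n}{Molar mass of N, g mol-1.}
#'   \item{gas_constant}{Ideal gas constant, J mol-1 K-1.}
#'   \item{standard_pressure}{Default chamber pressure, Pa.}
#' }
#' @export
iso_constants <- list(
  r_std_n           = 0.0036765,
  r17_vsmow         = 0.0003799,
  r18_vsmow         = 0.0020052,
  beta_o17          = 0.516,
  molar_mass_n      = 14.007,
  gas_constant      = 8.31446,
  standard_pressure = 101325
)

#' Construct a delta value with reference scale and uncertainty
#'
#' Light-weight container for a per-mil (permil) isotope delta value. Values
#' at or below -1000 permil are rejected because they imply a non-positive
#' heavy-isotope abundance.
#'
#' @param value Delta value in permil.
#' @param reference Reference scale, `"AIR_N2"` (15N) or `"VSMOW"` (18O).
#' @param sigma Optional 1-sigma uncertainty in permil (>= 0).
#' @return An object of class `iso_value`.
#' @export
iso_value <- function(value, reference = c("AIR_N2", "VSMOW"), sigma = NA_real_) {
  reference <- match.arg(reference)
  stopifnot(is.numeric(value), length(value) == 1L)
  if (!is.finite(value) || value <= -1000) {
    stop("delta value must be finite and > -1000 permil (atom fraction must stay positive)")
  }
  if (!is.na(sigma) && sigma < 0) stop("sigma must be >= 0")
  structure(list(value = value, reference = reference, sigma = sigma),
            class = "iso_value")
}

#' @export
print.iso_value <- function(x, ...) {
  cat(sprintf("%.4g permil vs %s", x$value, x$reference))
  if (!is.na(x$sigma)) cat(sprintf(" (1s = %.3g)", x$sigma))
  cat("\n")
  invisible(x)
}

as_delta_value <- function(d) {
  if (inherits(d, "iso_value")) d$value else as.numeric(d)
}

#' Convert delta-15N (vs air N2) to 15N atom fraction
#'
#' Uses the isotope-ratio identity x = R/(1+R) with R = (d/1000 + 1) * R_std,
#' R_std being the 15N/14N ratio of atmospheric N2. Strictly increasing in d.
#'
#' @param d Delta-15N in permil (numeric or [iso_value()] on the AIR_N2 scale).
#' @return A list with `x` (atom fraction, 0-1) and `as_percent` (atom-%).
#' @examples
#' delta_to_atom_fraction(0)$as_percent      # 0.36630, natural abundance
#' delta_to_atom_fraction(1000)$as_percent   # ~0.73
#' @export
delta_to_atom_fraction <- function(d) {
  if (inherits(d, "iso_value") && d$reference != "AIR_N2") {
    stop("delta_to_atom_fraction expects a value on the AIR_N2 scale")
  }
  d <- as_delta_value(d)
  if (any(!is.finite(d)) || any(d <= -1000)) {
    stop("delta value must be > -1000 permil")
  }
  r <- (d / 1000 + 1) * iso_constants$r_std_n
  x <- r / (1 + r)
  list(x = x, as_percent = 100 * x)
}

#' Convert a 15N atom fraction back to delta-15N (vs air N2)
#'
#' Exact algebraic inverse of [delta_to_atom_fraction()].
#'
#' @param x Atom fraction in (0, 1).
#' @return Delta-15N in permil.
#' @export
atom_fraction_to_delta <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    stop("atom fraction must lie strictly within (0, 1)")
  }
  r <- x / (1 - x)
  1000 * (r / iso_constants$r_std_n - 1)
}

#' Atom-percent 15N excess (APE) of a labeled pool
#'
#' APE = atom-% of the labeled sample minus atom-% of the natural-abundance
#' sample of the same pool. May be slightly negative for unlabeled pools
#' within measurement noise; such values are flagged, not clipped.
#'
#' @param labeled,natural Atom fractions in `[0, 1]` (not percent).
#' @return List with `ape_pct` (atom-% excess) and `below_detection` flag
#'   (`TRUE` when APE <= 0).
#' @export
atom_percent_excess <- function(labeled, natural = iso_constants$r_std_n /
                                  (1 + iso_constants$r_std_n)) {
  stopifnot(labeled >= 0, labeled <= 1, natural >= 0, natural <= 1)
  ape <- 100 * (labeled - natural)
  list(ape_pct = ape, below_detection = ape <= 0)
}

#' Express d18O of N2O relative to the water that fed the process
#'
#' Subtracts the d18O of the nutrient-solution water from the d18O of N2O
#' (both on the VSMOW scale), the conventional precursor correction for
#' denitrification-derived N2O whose oxygen derives largely from H2O.
#' Uncertainties, when present on both operands, propagate as root sum of
#' squares.
#'
#' @param d18o_n2o,d18o_h2o d18O values in permil vs VSMOW; numeric or
#'   [iso_value()] objects (mixed scales are an error).
#' @return An [iso_value()] on the VSMOW scale.
#' @export
correct_o18_for_water <- function(d18o_n2o, d18o_h2o) {
  for (v in list(d18o_n2o, d18o_h2o)) {
    if (inherits(v, "iso_value") && v$reference != "VSMOW") {
      stop("both d18O values must be on the VSMOW scale")
    }
  }
  s1 <- if (inherits(d18o_n2o, "iso_value")) d18o_n2o$sigma else NA_real_
  s2 <- if (inherits(d18o_h2o, "iso_value")) d18o_h2o$sigma else NA_real_
  sig <- if (!is.na(s1) && !is.na(s2)) sqrt(s1^2 + s2^2) else NA_real_
  iso_value(as_delta_value(d18o_n2o) - as_delta_value(d18o_h2o),
            reference = "VSMOW", sigma = sig)
}

#' 15N site preference of N2O
#'
#' Site preference (SP) is the difference between delta-15N of the central
#' (alpha) and peripheral (beta) nitrogen of the N2O molecule; the bulk
#' delta-15N is their arithmetic mean. SP is diagnostic of the producing
#' process and independent of the substrate delta-15N.
#'
#' @param alpha,beta delta-15N-alpha and delta-15N-beta in permil vs air N2;
#'   numeric or [iso_value()].
#' @param bulk Optional independently measured bulk delta-15N; when supplied
#'   it is checked for consistency with the alpha/beta mean.
#' @param tol Consistency tolerance (permil) for a supplied bulk value.
#' @return A list of class `sp_pair` with `sp`, `d15n_alpha`, `d15n_beta`,
#'   `d15n_bulk` and propagated `sigma_sp`/`sigma_bulk` when input sigmas are
#'   available.
#' @export
site_preference <- function(alpha, beta, bulk = NULL, tol = 0.5) {
  for (v in list(alpha, beta)) {
    if (inherits(v, "iso_value") && v$reference != "AIR_N2") {
      stop("alpha and beta must be on the AIR_N2 scale")
    }
  }
  a <- as_delta_value(alpha); b <- as_delta_value(beta)
  sa <- if (inherits(alpha, "iso_value")) alpha$sigma else NA_real_
  sb <- if (inherits(beta, "iso_value")) beta$sigma else NA_real_
  have_s <- !is.na(sa) && !is.na(sb)
  mean_ab <- (a + b) / 2
  if (!is.null(bulk)) {
    bv <- as_delta_value(bulk)
    if (abs(bv - mean_ab) > tol) {
      warning(sprintf(
        "measured bulk d15N (%.3f) differs from mean of alpha/beta (%.3f) by more than %.2f permil",
        bv, mean_ab, tol))
    }
    mean_ab <- bv
  }
  structure(list(
    d15n_alpha = a, d15n_beta = b,
    sp = a - b, d15n_bulk = mean_ab,
    sigma_sp = if (have_s) sqrt(sa^2 + sb^2) else NA_real_,
    sigma_bulk = if (have_s) sqrt(sa^2 + sb^2) / 2 else NA_real_
  ), class = "sp_pair")
}
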