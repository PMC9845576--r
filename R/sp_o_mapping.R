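#' Load an endmember / reduction-effect configuration
#'
#' Reads the YAML table of (SP, d18O) endmember signatures for bacterial
#' denitrification (bD), fungal denitrification (fD), nitrifier
#' denitrification (nD) and nitrification (Ni), together with the net
#' isotope effects of N2O reduction. The packaged default table holds
#' literature-compilation values and is meant to be copied and edited; a
#' content hash of the loaded table travels with every mapping result.
#'
#' @param path Path to a YAML file; default is the table shipped with the
#'   package.
#' @return Object of class `endmember_set`: per-process means/SDs, the
#'   `reduction` epsilons, `water_adjusted` state and `table_hash`.
#' @export
load_endmembers <- function(path = system.file("extdata", "endmembers.yaml",
                                               package = "n2osource")) {
  cfg <- yaml::read_yaml(path)
  need <- c("bD", "fD", "nD", "Ni")
  if (!all(need %in% names(cfg$endmembers))) {
    stop("endmember table must define bD, fD, nD and Ni")
  }
  em <- lapply(cfg$endmembers[need], function(e) {
    stopifnot(all(c("sp_mean", "sp_sd", "d18o_mean", "d18o_sd") %in% names(e)))
    lapply(e, as.numeric)
  })
  red <- reduction_line(cfg$reduction$eps_sp, cfg$reduction$eps_o)
  structure(list(endmembers = em, reduction = red,
                 water_adjusted = FALSE, d18o_h2o = NA_real_,
                 table_hash = sprintf("%08x", sum(utf8ToInt(paste(
                   unlist(em), red$eps_sp, red$eps_o, collapse = ","))))),
            class = "endmember_set")
}

#' Net isotope effects of N2O reduction to N2
#'
#' Both effects are negative: residual N2O becomes enriched in the heavy
#' isotopes as the remaining fraction r shrinks (delta = delta0 + eps ln r).
#'
#' @param eps_sp,eps_o Net isotope effects (permil) on SP and d18O; both < 0.
#' @return List of class `reduction_line` with `eps_sp`, `eps_o`, `slope`.
#' @export
reduction_line <- function(eps_sp, eps_o) {
  if (eps_sp >= 0 || eps_o >= 0) {
    stop("reduction isotope effects must be negative (residual N2O is enriched)")
  }
  structure(list(eps_sp = eps_sp, eps_o = eps_o, slope = eps_sp / eps_o),
            class = "reduction_line")
}

#' Shift water-referenced endmembers onto the measured-water scale
#'
#' The d18O endmember values of bD, fD and nD are expressed relative to the
#' process water; to compare them with measured d18O of N2O they are shifted
#' by the measured d18O of the local water. Ni is untouched because its N2O
#' oxygen derives from atmospheric O2. The adjustment may be applied exactly
#' once.
#'
#' @param em An unadjusted [load_endmembers()] result.
#' @param d18o_h2o d18O of the water, permil vs VSMOW (numeric or
#'   [iso_value()]).
#' @return The adjusted `endmember_set`.
#' @export
adjust_endmembers <- function(em, d18o_h2o) {
  stopifnot(inherits(em, "endmember_set"))
  if (isTRUE(em$water_adjusted)) {
    stop("endmember set is already water-adjusted; refusing to adjust twice")
  }
  shift <- as_delta_value(d18o_h2o)
  for (p in c("bD", "fD", "nD")) {
    em$endmembers[[p]]$d18o_mean <- em$endmembers[[p]]$d18o_mean + shift
  }
  em$water_adjusted <- TRUE
  em$d18o_h2o <- shift
  em
}

#' Residual N2O composition after partial reduction (closed-system Rayleigh)
#'
#' Applies the closed-system residual-substrate approximation
#' delta = delta0 + eps * ln(r) componentwise to (SP, d18O), where r is the
#' remaining N2O fraction N2O/(N2O + N2).
#'
#' @param sp0,o0 Initial SP and d18O (permil).
#' @param eps A [reduction_line()].
#' @param r Remaining fraction, 0 < r <= 1.
#' @return Named vector `c(sp =, o =)`.
#' @export
rayleigh_residual <- function(sp0, o0, eps, r) {
  stopifnot(inherits(eps, "reduction_line"))
  if (any(r <= 0)) stop("remaining fraction r must be positive")
  if (any(r > 1)) stop("remaining fraction r cannot exceed 1")
  c(sp = unname(sp0 + eps$eps_sp * log(r)), o = unname(o0 + eps$eps_o * log(r)))
}

em_point <- function(em, process) {
  e <- em$endmembers[[process]]
  c(sp = e$sp_mean, o = e$d18o_mean)
}

map_result <- function(scenario, case, f_bd, r_n2o, flag = NA_character_) {
  structure(list(scenario = scenario, case = case,
                 f_bd = f_bd, r_n2o = r_n2o, f_minor = 1 - f_bd,
                 out_of_domain = !is.na(flag), flag = flag),
            class = "map_result")
}

clip01 <- function(x) min(max(x, 0), 1)

#' Solve the reduction-then-mixing case of the isotopocule map
#'
#' Case (i): N2O produced by bD is first partially reduced to N2 (remaining
#' fraction r), and the enriched residual then mixes with unreduced N2O from
#' the minor process. The sample satisfies
#' `sample = f * Rayleigh(E_bD, r) + (1 - f) * E_minor` in both SP and d18O.
#' f is eliminated from the d18O component and r found by 1-D root finding
#' on the SP component over r in `[1e-4, 1]`.
#'
#' @param sp,o Emitted-N2O SP and d18O (permil).
#' @param em A water-adjusted [load_endmembers()] result.
#' @param minor `"fD"` or `"Ni"` (the non-bD endmember of the scenario).
#' @return A `map_result` with `f_bd` (bD share of EMITTED N2O), `r_n2o`,
#'   `f_minor = 1 - f_bd` and out-of-domain flags. When no root lies in the
#'   bracket the clipped boundary solution is returned with a warning.
#' @export
solve_red_mix <- function(sp, o, em, minor = c("fD", "Ni")) {
  minor <- match.arg(minor)
  stopifnot(inherits(em, "endmember_set"))
  if (!isTRUE(em$water_adjusted)) stop("endmembers must be water-adjusted before mapping")
  scenario <- if (minor == "fD") "bD_fD" else "bD_Ni"
  eb <- em_point(em, "bD"); mm <- em_point(em, minor)
  eps <- em$reduction
  f_of_r <- function(r) {
    denom <- eb["o"] + eps$eps_o * log(r) - mm["o"]
    if (abs(denom) < 1e-12) return(NA_real_)
    unname((o - mm["o"]) / denom)
  }
  g <- function(r) {
    f <- f_of_r(r)
    b <- rayleigh_residual(eb["sp"], eb["o"], eps, r)
    unname(f * b["sp"] + (1 - f) * mm["sp"] - sp)
  }
  # degenerate: sample at the minor endmember -> f = 0, r unidentifiable
  if (abs(sp - mm["sp"]) < 1e-9 && abs(o - mm["o"]) < 1e-9) {
    return(map_result(scenario, "red_mix", 0, 1,
                      flag = "sample equals minor endmember; r unidentifiable, reported as 1"))
  }
  lo <- 1e-4; hi <- 1
  # The d18O denominator eb_o + eps_o*ln(r) - mm_o vanishes at one r inside
  # the bracket whenever mm_o > eb_o (the usual geometry): g has a pole
  # there. Root-find on each side of the pole and keep the physical branch.
  brackets <- list(c(lo, hi))
  if (mm["o"] != eb["o"]) {
    r_pole <- exp((mm["o"] - eb["o"]) / eps$eps_o)
    if (r_pole > lo && r_pole < hi) {
      brackets <- list(c(lo, r_pole * (1 - 1e-9)),
                       c(r_pole * (1 + 1e-9), hi))
    }
  }
  roots <- list()
  for (br in brackets) {
    g1 <- g(br[1]); g2 <- g(br[2])
    if (is.finite(g1) && is.finite(g2) && g1 * g2 <= 0) {
      r_hat <- stats::uniroot(g, br, tol = 1e-10)$root
      roots[[length(roots) + 1L]] <- c(r = r_hat, f = f_of_r(r_hat))
    }
  }
  if (length(roots) > 0L) {
    valid <- Filter(function(z) z["f"] >= -1e-9 && z["f"] <= 1 + 1e-9, roots)
    if (length(valid) > 0L) {
      # multiple exact solutions would mean genuine non-identifiability;
      # prefer the least-reduced one
      pick <- valid[[which.max(vapply(valid, function(z) z["r"], 0))]]
      return(map_result(scenario, "red_mix",
                        clip01(unname(pick["f"])), unname(pick["r"])))
    }
    pick <- roots[[1L]]
    return(map_result(scenario, "red_mix",
                      clip01(unname(pick["f"])), unname(pick["r"]),
                      flag = sprintf("f_bD = %.4f outside [0, 1]; clipped", pick["f"])))
  }
  # no sign change anywhere: clip to whichever bracket end comes closer
  ends <- c(lo, hi)
  gv <- abs(vapply(ends, g, 0))
  r_hat <- ends[which.min(ifelse(is.finite(gv), gv, Inf))]
  f_hat <- clip01(f_of_r(r_hat))
  warning("red-mix solver: no root in r bracket; reporting clipped boundary solution")
  map_result(scenario, "red_mix", f_hat, r_hat,
             flag = "no root in r bracket; boundary solution")
}

#' Solve the mixing-then-reduction case of the isotopocule map
#'
#' Case (ii): N2O from bD and the minor process mixes first, and the whole
#' mixture is then partially reduced. Geometrically: the mixture point M lies
#' on the segment between the two endmembers, and the sample sits on the
#' reduction line through M with direction (eps_o, eps_sp); solving the
#' 2 x 2 linear system gives f (position of M on the segment) and
#' L = ln r, so `r = exp(L)`.
#'
#' @inheritParams solve_red_mix
#' @return A `map_result`; M outside the segment or r > 1 is clipped and
#'   flagged, coincident endmembers raise a singular-geometry error.
#' @export
solve_mix_red <- function(sp, o, em, minor = c("fD", "Ni")) {
  minor <- match.arg(minor)
  stopifnot(inherits(em, "endmember_set"))
  if (!isTRUE(em$water_adjusted)) stop("endmembers must be water-adjusted before mapping")
  scenario <- if (minor == "fD") "bD_fD" else "bD_Ni"
  eb <- em_point(em, "bD"); mm <- em_point(em, minor)
  eps <- em$reduction
  # f*(eb - mm) + mm + L*(eps) = sample, unknowns (f, L)
  A <- matrix(c(eb["o"] - mm["o"], eps$eps_o,
                eb["sp"] - mm["sp"], eps$eps_sp),
              nrow = 2, byrow = TRUE)
  if (abs(det(A)) < 1e-10) {
    stop("singular mixing geometry: endmember segment is parallel to the reduction line (or endmembers coincide)")
  }
  sol <- solve(A, c(o - mm["o"], sp - mm["sp"]))
  f_hat <- sol[1]; L <- sol[2]
  r_hat <- exp(L)
  flag <- NA_character_
  if (f_hat < -1e-9 || f_hat > 1 + 1e-9) {
    flag <- sprintf("mixture point outside endmember segment (f = %.4f); clipped", f_hat)
  }
  if (r_hat > 1 + 1e-9) {
    flag <- paste(stats::na.omit(c(flag,
      sprintf("r = %.4f > 1 (sample below the mixing segment); clipped", r_hat))),
      collapse = "; ")
  }
  f_hat <- clip01(f_hat)
  r_hat <- min(r_hat, 1)
  res <- map_result(scenario, "mix_red", f_hat, r_hat, flag = flag)
  # consistency: forward model must reproduce the sample (exact when unflagged)
  if (!res$out_of_domain) {
    m <- f_hat * eb + (1 - f_hat) * mm
    back <- rayleigh_residual(m["sp"], m["o"], eps, r_hat)
    if (max(abs(back - c(sp, o))) > 1e-8) {
      stop("mix-red internal consistency check failed")
    }
  }
  res
}

#' Back-calculate the N2 flux implied by a mapping result
#'
#' In the reduction-then-mixing case only the bD stream passed reduction, so
#' `N2 = f_bD * F_N2O * (1 - r)/r`; in the mixing-then-reduction case the
#' whole mixture was reduced, so `N2 = F_N2O * (1 - r)/r`. F_N2O is the
#' measured (emitted) N2O flux.
#'
#' @param res A `map_result` from [solve_red_mix()] or [solve_mix_red()],
#'   or a list with `case`, `f_bd`, `r_n2o`.
#' @param n2o_flux Emitted N2O flux (any unit; the N2 flux inherits it).
#' @return List of class `n2_flux_estimate` with `n2_flux`, `n2o_flux` and
#'   `ratio_n2_n2o`.
#' @export
estimate_n2_flux <- function(res, n2o_flux) {
  r <- res$r_n2o
  if (r <= 0) stop("r_n2o must be positive")
  if (r > 1) stop("r_n2o cannot exceed 1")
  n2 <- switch(res$case,
               red_mix = res$f_bd * n2o_flux * (1 - r) / r,
               mix_red = n2o_flux * (1 - r) / r,
               stop("unknown case: ", res$case))
  structure(list(n2_flux = n2, n2o_flux = n2o_flux,
                 ratio_n2_n2o = n2 / n2o_flux,
                 scenario = res$scenario, case = res$case),
            class = "n2_flux_estimate")
}

#' Map one emitted-N2O sample under all scenario/case combinations
#'
#' Runs both endmember scenarios (bD-fD and bD-Ni) under both process-order
#' cases (red-mix and mix-red) and back-calculates the implied N2 flux for
#' each cell.
#'
#' @param sp,o Emitted-N2O SP and d18O (permil), e.g. from
#'   [correct_delta_mixing()].
#' @param em A water-adjusted endmember set.
#' @param n2o_flux Optional emitted N2O flux for the N2 back-calculation.
#' @return A data.frame with one row per scenario x case: `scenario`, `case`,
#'   `f_bd`, `r_n2o`, `f_minor`, `out_of_domain`, `flag`, `n2_flux`,
#'   `endmember_hash`.
#' @export
map_sample <- function(sp, o, em, n2o_flux = NA_real_) {
  cells <- list()
  for (minor in c("fD", "Ni")) {
    for (solver in list(solve_red_mix, solve_mix_red)) {
      res <- solver(sp, o, em, minor = minor)
      n2 <- if (is.na(n2o_flux)) NA_real_ else estimate_n2_flux(res, n2o_flux)$n2_flux
      cells[[length(cells) + 1L]] <- data.frame(
        scenario = res$scenario, case = res$case,
        f_bd = res$f_bd, r_n2o = res$r_n2o, f_minor = res$f_minor,
        out_of_domain = res$out_of_domain,
        flag = ifelse(is.na(res$flag), "", res$flag),
        n2_flux = n2, endmember_hash = em$table_hash,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, cells)
}

#' Summarise per-sample mapping results for a campaign
#'
#' @param maps A data.frame of stacked [map_sample()] outputs.
#' @return Mean and SD of `f_bd` and `r_n2o` per scenario x case.
#' @export
summarise_campaign <- function(maps) {
  agg <- stats::aggregate(cbind(f_bd, r_n2o) ~ scenario + case, data = maps,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  data.frame(scenario = agg$scenario, case = agg$case,
             f_bd_mean = agg$f_bd[, "mean"], f_bd_sd = agg$f_bd[, "sd"],
             r_n2o_mean = agg$r_n2o[, "mean"], r_n2o_sd = agg$r_n2o[, "sd"],
             stringsAsFactors = FALSE)
}
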