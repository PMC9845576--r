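#' Labeling configuration of one experimental unit
#'
#' Describes the 15N label applied to a hydroponic unit: ammonium nitrate
#' with either the NH4+ (10.5 atom-%) or the NO3- (11 atom-%) moiety
#' enriched, delivered as 15 L of labeled nutrient solution with
#' 73 mg NH4+-N L-1 (and equal NO3--N), adding 115 or 120 mg 15N per unit.
#'
#' @param label_form `"NH4_15"` or `"NO3_15"`.
#' @param label_atom_pct Atom-% 15N of the labeled moiety (defaults by form).
#' @param n15_added_mg mg of 15N tracer added per unit (defaults by form).
#' @param solution_volume_L Volume of labeled solution added (15 L).
#' @param nh4_conc_mg_L NH4+-N concentration of the labeled solution.
#' @return List of class `labeling_config`.
#' @export
labeling_config <- function(label_form = c("NH4_15", "NO3_15"),
                            label_atom_pct = NULL, n15_added_mg = NULL,
                            solution_volume_L = 15, nh4_conc_mg_L = 73) {
  label_form <- match.arg(label_form)
  if (is.null(label_atom_pct)) {
    label_atom_pct <- if (label_form == "NH4_15") 10.5 else 11.0
  }
  if (is.null(n15_added_mg)) {
    n15_added_mg <- if (label_form == "NH4_15") 115 else 120
  }
  natural_pct <- 100 * iso_constants$r_std_n / (1 + iso_constants$r_std_n)
  if (label_atom_pct <= natural_pct || label_atom_pct > 100) {
    stop("label_atom_pct must exceed natural abundance and not exceed 100")
  }
  structure(list(label_form = label_form, label_atom_pct = label_atom_pct,
                 n15_added_mg = n15_added_mg,
                 solution_volume_L = solution_volume_L,
                 nh4_conc_mg_L = nh4_conc_mg_L),
            class = "labeling_config")
}

#' Estimate the total nutrient-solution volume from NH4+ dilution
#'
#' The labeled solution (concentration `c_label`, volume `v_label`) mixes
#' with residual unlabeled solution held in the substrate. Assuming the
#' unlabeled solution carries negligible NH4+, the measured NH4+-N
#' concentration at the 4 h sampling gives the total volume by dilution:
#' `V = c_label * v_label / c_measured`.
#'
#' @param c_measured_t4 Measured NH4+-N at 4 h, mg N L-1 (0 < c <= c_label).
#' @param c_label NH4+-N of the labeled solution, mg N L-1 (default 73).
#' @param v_label Volume of labeled solution, L (default 15).
#' @param c_residual_t0 Optional NH4+-N of the residual solution (mg N L-1);
#'   when supplied the dilution equation accounts for it instead of assuming
#'   zero (off by default, matching the negligible-NH4 assumption).
#' @return List of class `solution_volume` with `volume_L` and the inputs.
#' @export
estimate_solution_volume <- function(c_measured_t4, c_label = 73, v_label = 15,
                                     c_residual_t0 = NULL) {
  if (c_measured_t4 <= 0) stop("measured concentration must be positive")
  if (c_measured_t4 > c_label) {
    stop("measured concentration exceeds the labeled solution: impossible dilution")
  }
  if (is.null(c_residual_t0)) {
    v <- c_label * v_label / c_measured_t4
  } else {
    # c_meas * V = c_label * v_label + c_res * (V - v_label)
    if (c_residual_t0 >= c_measured_t4) {
      stop("residual concentration must be below the measured mixture")
    }
    v <- v_label * (c_label - c_residual_t0) / (c_measured_t4 - c_residual_t0)
  }
  structure(list(volume_L = v, c_label = c_label, v_label = v_label,
                 c_measured_t4 = c_measured_t4,
                 c_residual_t0 = c_residual_t0),
            class = "solution_volume")
}

#' Per-pool nitrogen amounts of one experimental unit
#'
#' Solution pools: concentration x total solution volume. Plant pools: dry
#' weight x total-N content. The N2O pool is the cumulative per-unit
#' emission from [cumulative_emission()].
#'
#' @param nh4_mg_L,no3_mg_L Solution N concentrations, mg N L-1.
#' @param volume_L Total solution volume (see [estimate_solution_volume()]).
#' @param shoots_g,roots_g,fruits_g Dry weights per unit, g.
#' @param nt_shoots,nt_roots,nt_fruits N contents, g N per g dry weight.
#' @param n2o_mg Cumulative per-unit N2O-N, mg.
#' @return data.frame with columns `pool` and `n_mg`.
#' @export
pool_nitrogen <- function(nh4_mg_L, no3_mg_L, volume_L,
                          shoots_g = 0, roots_g = 0, fruits_g = 0,
                          nt_shoots = 0, nt_roots = 0, nt_fruits = 0,
                          n2o_mg = 0) {
  if (any(c(nh4_mg_L, no3_mg_L, volume_L, shoots_g, roots_g, fruits_g) < 0)) {
    stop("pool inputs must be non-negative")
  }
  data.frame(
    pool = c("NH4_solution", "NO3_solution", "N2O_gas",
             "shoots", "roots", "fruits"),
    n_mg = c(nh4_mg_L * volume_L, no3_mg_L * volume_L, n2o_mg,
             shoots_g * nt_shoots * 1000, roots_g * nt_roots * 1000,
             fruits_g * nt_fruits * 1000),
    stringsAsFactors = FALSE)
}

#' Excess 15N held in one pool
#'
#' `excess = APE/100 * N_pool`, with APE the atom-% 15N excess of the pool
#' against its own natural-abundance sample.
#'
#' @param ape_pct Atom-% 15N excess of the pool.
#' @param n_pool_mg N amount in the pool, mg N per unit.
#' @return mg 15N per unit.
#' @export
excess_15n <- function(ape_pct, n_pool_mg) {
  ape_pct / 100 * n_pool_mg
}

#' 15N mass-balance ledger and tracer recovery
#'
#' Sums the excess 15N over all measured pools and expresses it as a
#' percentage of the tracer added. Pools below detection enter as zero.
#'
#' @param excess_by_pool Named numeric vector of excess 15N, mg per unit
#'   (e.g. NH4_solution, NO3_solution, N2O_gas, shoots, roots, fruits).
#' @param label_added_mg 15N added during labeling, mg per unit (> 0).
#' @return List of class `mass_balance_ledger` with `pools`,
#'   `total_plant_mg` (shoots + roots + fruits, when present),
#'   `total_recovered_mg`, `label_added_mg`, `recovery_pct`.
#' @export
recovery <- function(excess_by_pool, label_added_mg) {
  if (label_added_mg <= 0) stop("label_added_mg must be positive")
  pools <- vapply(excess_by_pool, function(v) ifelse(is.na(v), 0, v), 0)
  plant_pools <- intersect(names(pools), c("shoots", "roots", "fruits"))
  total <- sum(pools)
  structure(list(pools = pools,
                 total_plant_mg = if (length(plant_pools))
                   sum(pools[plant_pools]) else NA_real_,
                 total_recovered_mg = total,
                 label_added_mg = label_added_mg,
                 recovery_pct = 100 * total / label_added_mg),
            class = "mass_balance_ledger")
}

#' @export
print.mass_balance_ledger <- function(x, ...) {
  cat("15N mass balance (mg 15N per unit)\n")
  for (p in names(x$pools)) cat(sprintf("  %-14s %8.3f\n", p, x$pools[p]))
  cat(sprintf("  total recovered %8.2f of %.0f added (recovery %.1f%%)\n",
              x$total_recovered_mg, x$label_added_mg, x$recovery_pct))
  invisible(x)
}
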