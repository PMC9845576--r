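---
title: "Attributing N2O emissions to microbial sources: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing N2O emissions to microbial sources: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2osource)
```

# The inference problem

Nitrous oxide escaping from a closed cultivation system carries two
independent isotopic fingerprints of its microbial origin. First, at
natural abundance, the intramolecular distribution of ^15^N (the *site
preference*, SP = delta^15^N^alpha^ − delta^15^N^beta^) and the
delta^18^O of N2O differ characteristically between bacterial
denitrification (bD), fungal denitrification (fD), nitrifier
denitrification (nD) and NH2OH-route nitrification (Ni), and shift
predictably when part of the N2O is further reduced to N2. Second, after
adding a ^15^N label to one inorganic N pool (NH4^+^ or NO3^−^), the
enrichment of the emitted N2O identifies the pool it was made from.
`n2osource` implements the complete chain from raw chamber measurements to
these two attributions and the closing ^15^N mass balance, together with a
forward simulator that generates whole experiments with known ground truth.

# Chamber fluxes

Mole fractions (ppb) are converted to concentrations with the ideal gas
law, `C [umol m^-3] = x * 1e-3 * P/(R*T)`, each sample at its own
temperature; the default pressure is 101325 Pa and configurable, since
chamber pressure is rarely logged. The flux is the slope of concentration
against time, scaled by headspace volume over covered area (defaults
0.016 m^3^ and 1 m^2^, a 16 L chamber over two plants at a typical
greenhouse planting density of 2 plants m^-2^). With four or more time
points the slope comes from a Huber M-estimator (tuning constant 1.345,
iterated to 1e-8), the standard robust-regression default, which protects
against single leaky-vial outliers; with two or three points the robust
weights are not identified and ordinary least squares is used. A
zero-residual series makes the IRLS scale estimate degenerate, so exact
fits short-circuit to the OLS solution, which the Huber estimate equals
there. Negative fitted fluxes are retained: truncation would bias
cumulative sums. Unit conversions use two N atoms per N2O
(1 umol N2O m^-2^ h^-1^ = 28.014 ug N m^-2^ h^-1 = 6.723 g N ha^-1^ d^-1^).

Cumulative emissions over a 24 h labeling window integrate the rates
measured at 0, 4 and 24 h by exact trapezoid (identical to summing hourly
linear-interpolated rates, but free of step-size ambiguity); unplanted
substrate is assumed to emit at a constant rate. A per-unit total counts
two planted slabs and one unplanted slab.

# Removing the atmospheric background

Headspace N2O is a mixture of substrate-emitted and atmospheric N2O.
Each delta is unmixed as
`d_emitted = (C_s*d_s − C_atm*d_atm) / (C_s − C_atm)`.
The correction is applied to delta^15^N^alpha^ and delta^15^N^beta^
separately and SP formed afterwards: mixing is linear in each positional
delta, so this is exact, whereas the SP of a mixture is not the mixture of
SPs. Because the denominator vanishes as the sample approaches ambient,
uncertainty explodes near the baseline; samples are therefore excluded
unless they exceed ambient by a margin (default 65 ppb, boundary
inclusive, since the criterion is a minimum difference rather than a
strict inequality). Every exclusion is logged with its reason.
First-order (delta-method) Gaussian propagation through the unmixing
formula supports the choice of margin; the concentration terms are shared
between the alpha and beta corrections, so the SP variance is computed
jointly — ignoring that covariance would overstate it. Default
measurement sigmas are 0.5 permil per delta and 2 ppb per concentration,
typical IRMS/GC performance; both are arguments. Under these defaults,
retained samples keep propagated errors below 6 permil (SP) and 5 permil
(delta^18^O), which the test suite asserts on simulated campaigns.

# The dual-isotope map

Endmember signatures (mean ± SD of SP and delta^18^O per process) and the
net isotope effects of N2O reduction are literature-compilation values
that are *not* measured by any one experiment; they ship as an editable
YAML table (`inst/extdata/endmembers.yaml`) and every mapping result
records a hash of the table in use, so results are traceable to their
calibration. The d18O values of bD, fD and nD are stored relative to the
process water (their oxygen derives predominantly from H2O) and must be
shifted once by the measured water delta^18^O before mapping
(`adjust_endmembers()`, which refuses to run twice); Ni keeps its
VSMOW-scale value because its oxygen comes from atmospheric O2.

Reduction follows the closed-system Rayleigh residual approximation
`delta = delta0 + eps*ln(r)`, with `r = N2O/(N2O+N2)` the remaining
fraction and both eps negative (defaults −5.9 permil for SP, −15.9 permil
for delta^18^O).

Two process orders bracket reality:

* **red-mix** — bD-derived N2O is partially reduced, then the residual
  mixes with unreduced N2O from the minor process (fD or Ni):
  `sample = f*Rayleigh(E_bD, r) + (1−f)*E_minor`. Eliminating `f` from the
  delta^18^O component leaves a 1-D root-finding problem in `r` over
  [1e-4, 1] (tolerance 1e-10). The d18O denominator vanishes at one `r`
  inside that bracket whenever the minor endmember is heavier in ^18^O
  than bD — a pole, not a root — so the solver brackets each side of the
  pole separately and keeps the root on the physical branch
  (f in [0, 1]); if several exact roots exist the least-reduced one is
  reported, and a no-root sample returns the clipped boundary solution
  with a flag rather than disappearing from campaign summaries.
* **mix-red** — all sources mix first, then the mixture is reduced. The
  mixture point must lie on the endmember segment *and* on the line
  through the sample with direction (eps_O, eps_SP); this is a 2x2 linear
  solve giving `f` and `ln r` at machine precision, with a
  singular-geometry error when the segment is parallel to the reduction
  line, and clipped, flagged results when the intersection leaves the
  segment or `r > 1`.

The two cases share a useful geometry: both place the mixture on the same
segment point, so `f` agrees between them and
`r_mix-red = r_red-mix^f >= r_red-mix`. The package asserts this ordering
on simulated campaigns; it also explains why reduction-then-mixing always
yields the larger back-calculated N2 flux.

`f_bD` is interpreted as the bD share of *emitted* N2O. The implied N2
flux is `f_bD * F_N2O * (1−r)/r` for red-mix (only the bD stream passed
reduction) and `F_N2O * (1−r)/r` for mix-red (the whole mixture did);
this emitted-basis convention is the one that makes the four published
per-campaign N2 values internally consistent, which the acceptance tests
verify. Campaign summaries average per-sample solutions by default;
because the solvers are non-linear, solving at the campaign-mean deltas
gives slightly different numbers (a Jensen effect), and both modes are
available — pass per-sample deltas or their means to `map_sample()`.

# ^15^N tracer partitioning

Labeled-gas samples are evaluated for bulk ^15^N only. Conversion between
delta and atom fraction uses the ratio identity with
R_std = 0.0036765 (^15^N/^14^N of atmospheric N2); the two conversions
are exact inverses, property-tested to 1e-9 across the full physical
range.

For ^15^NO3^−^-labeled units the isotopologue route applies: N2O built
from two pools of different enrichment has a *non-random* molecular mass
distribution. With each pool binomially labeled across the two N
positions, the bulk atom fraction `a_m` and the ^15^N^15^N species
fraction `m2` of the mixture satisfy `u = a_m − a_bgd`,
`v = m2 − a_bgd^2`, `ap = v/u − a_bgd`, `x = u/(ap − a_bgd)` — an exact
algebraic inversion returning both the enrichment of the active labeled
pool (`ap_N2O`) and its share `x` of the measured N2O. Ion-current ratios
45/44 and 46/44 are first stripped of their oxygen contributions using a
mass-dependent ^17^O relation (`a17 = K * a18^0.516`, VSMOW-anchored)
with the oxygen composition assumed natural unless measured. The
atmospheric share of the chamber N2O carries no label, so `x` is rescaled
to the emitted basis by `conc/(conc − ambient)`. The returned `ap_N2O`
is also a diagnostic: if it falls below the measured bulk NO3^−^
enrichment, the pool actually feeding denitrification is not the bulk
pool, and the package reports the ratio without interpreting it.

For ^15^NH4^+^-labeled units that route is ambiguous, because
nitrification can move label into the NO3^−^ pool and labeled N2O then
originates from two pools. There the mixing equation on the emitted bulk
enrichment is mandatory:
`f_PN2O = (a_N2O − a_NH4)/(a_NO3 − a_NH4)`, with the *measured* pool
enrichments at the matching time point (label dilution in the pools is
substantial and must not be replaced by nominal label strengths). Flux
partitioning is then linear: `NO3-derived = f_PN2O * total`, remainder
NH4-derived; the two always sum to the total exactly. Fractions outside
[0, 1] are clipped only at reporting, with the raw value retained and
flagged. The difference `f_nD/cND = f_bD − f_PN2O` estimates the share of
NH4-derived N2O passing through denitrification-type chemistry; a
negative value is reported with a flag, as it signals a violated
equal-active-pool assumption rather than a physical fraction.

# ^15^N mass balance

The hidden total solution volume is estimated from dilution of the
labeled solution's NH4^+^ (73 mg N L^-1 in 15 L):
`V = 73*15/c_measured(4 h)`, under the assumption that residual unlabeled
solution carries negligible NH4^+^; an optional correction term for a
measured residual concentration exists but is off by default to keep the
primary assumption visible. Pool N amounts are concentration x volume
(solutions), dry weight x N content (plants), and the per-unit cumulative
emission (gas). Excess ^15^N per pool is `APE/100 * N_pool`, with APE
taken against the pool's own natural-abundance sample where one exists
(falling back to the R_std-derived 0.36630 atom-% otherwise); the gas
pool uses interval-wise APE (0–4 h, 4–24 h) by default, with a single
24 h mean as the alternative. Totals are exactly additive, recovery is
total/label x 100, and fruits below detection contribute zero. Unit
exclusions (e.g. solution spillover between neighbouring units) are a
data filter flag, never hardcoded.

One bookkeeping subtlety: the nominal label mass (115/120 mg ^15^N per
unit) is *total* ^15^N including its natural-abundance share, while pool
excesses count only the enrichment above natural. For synthetic
closed-system checks the package therefore divides by the excess ^15^N
actually introduced, making loss-free recovery exactly 100%; with the
nominal denominator the same experiment reads ~96.5%, a ~3.5% systematic
any study using nominal label masses inherits.

# What the simulator emulates — and what it does not

`truth_config()` fixes the study conditions: source fractions
(f_bD = 0.87, f_fD = 0.06, f_nD = 0.04, f_Ni = 0.03), r_N2O = 0.10 under
red-mix, f_PN2O = 0.68, a 16 L chamber sampled at 0/20/40/60 min, an N2O
flux of 1.7 ug N m^-2^ h^-1 above a 272 ppb ambient baseline
(tropospheric isotopic composition SP 18.7, delta^18^O 44.4,
bulk delta^15^N 6.3 permil), 15 L of labeled solution (10.5/11 atom-%
^15^N for the NH4/NO3 forms) mixed into a hidden 15 L residual
(1.6 mg NH4-N, 166 mg NO3-N per L), nitrification moving 2% of the
NH4^+^ pool per day, plant uptake of 4 and 10 mg N h^-1 from the two
pools, and measurement noise of 0.5 permil per delta and 2 ppb per
concentration. Label dynamics run in hourly steps with outputs at the
0/4/24 h sampling nodes; all randomness flows from one seed and datasets
regenerate byte-identically.

The generator reproduces the *statistical structure the inference
assumes* — linear chamber accumulation, two-endmember mixing with
Rayleigh reduction, binomial within-pool labeling, conservative pool
transfers — plus controlled violations (an unmeasured N sink, emission
losses, below-threshold samples). It contains no microbial kinetics, no
pH or O2 response, no spatial heterogeneity and no drift in ambient air.
Passing recovery tests therefore demonstrate that the inverse machinery
is correct and well-conditioned at realistic noise, not that the
structural assumptions hold in any particular greenhouse. One deliberate
mismatch is built in: the default truth emits N2O from four processes
while each mapping scenario models two, biasing recovered f_bD upward by
a few hundredths — the same specification error a real two-endmember
analysis commits, and visible in the analysis scripts' output.

# Numerical choices and problem sizes

Root finding uses `stats::uniroot` at tolerance 1e-10 on a bracketed,
pole-split function; the linear mix-red solve checks its own forward
reconstruction to 1e-8. Degenerate inputs are handled explicitly: a
sample at the minor endmember reports f = 0 with r = 1 and a
non-identifiability flag; coincident endmembers raise an error rather
than returning noise. Monte-Carlo error checks in the test suite use
1e5 draws; solver noise studies use 100 seeded replicates; campaign
simulations use 6–8 isotopocule samples per unit and 8 units — sizes
chosen so the whole suite runs in seconds while keeping Monte-Carlo
standard errors well below the asserted tolerances.

# Known limitations

* Two-endmember scenarios cannot separate bD from nD, nor fD from Ni;
  only the complements (1 − f_bD) and differences (f_bD − f_PN2O) are
  identified, and endmember-box overlap makes even those sensitive to the
  configured table.
* The Rayleigh residual form assumes a closed system during reduction;
  open-system dynamics would flatten the effective eps.
* The delta-method error propagation is first-order and degrades very
  close to the concentration threshold (which is why the threshold
  exists).
* The volume estimator inherits its two stated assumptions; spillover
  between units silently breaks it, which is precisely why such units
  must be excluded rather than corrected.
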