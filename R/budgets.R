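#' Daily nitrogen demand from tissue or skeletal N content
#'
#' Demand is modeled as a fixed fraction of the standing N stock turned over
#' per day: `demand = growth_fraction * N_content`, with the content supplied
#' in mg N cm-2 and the demand returned in ug N cm-2 d-1. The default growth
#' fraction, 0.2% of dry weight per day, is the literature value for coral
#' tissue growth in low-light environments and is applied to both tissue and
#' skeletal (endolithic) compartments.
#'
#' @param N_content N content in mg N cm-2; nonnegative.
#' @param growth_fraction Daily growth fraction (d-1), default 0.002.
#' @return Daily N demand in ug N cm-2 d-1 (vectorized).
#' @examples
#' daily_n_demand(0.26)  # 0.52 ug N cm-2 d-1
#' @export
daily_n_demand <- function(N_content, growth_fraction = 0.002) {
  check_nonneg(N_content, "N_content")
  check_nonneg(growth_fraction, "growth_fraction")
  growth_fraction * N_content * 1000       # mg -> ug
}

#' Holobiont nitrogen budget
#'
#' Relates daily diazotroph-derived nitrogen assimilation to the holobiont's
#' daily nitrogen demand, split into a tissue compartment (host + symbionts +
#' mucus) and a skeletal (endolithic) compartment. Demands follow
#' [daily_n_demand()]; the budget reports four percentages: total fixation
#' over total demand, fixation over demand within each compartment, and total
#' fixation over tissue demand alone (the upper bound if all skeletal DDN
#' were translocated to the tissue).
#'
#' The total/total percentage is algebraically the demand-weighted mean of
#' the two compartment percentages — an exact identity used as an internal
#' consistency check.
#'
#' @param tissue_N,skeletal_N N contents in mg N cm-2.
#' @param tissue_fix,skeletal_fix Daily DDN assimilation in ug N cm-2 d-1.
#' @param growth_fraction Daily growth fraction, default 0.002 d-1; either a
#'   single value or `c(tissue, skeletal)`.
#' @return An object of class `"holobiont_budget"`: demands (ug N cm-2 d-1)
#'   and the four percentages `total_over_total_pct`, `tissue_over_tissue_pct`,
#'   `skeletal_over_skeletal_pct`, `total_over_tissue_pct`.
#' @examples
#' b <- holobiont_budget(0.26, 1.06, tissue_fix = 0.0115, skeletal_fix = 0.159)
#' b$total_over_total_pct
#' @export
holobiont_budget <- function(tissue_N, skeletal_N, tissue_fix, skeletal_fix,
                             growth_fraction = 0.002) {
  check_nonneg(c(tissue_N, skeletal_N), "N contents")
  check_nonneg(c(tissue_fix, skeletal_fix), "fixation rates")
  gf <- rep_len(growth_fraction, 2)
  tissue_demand <- daily_n_demand(tissue_N, gf[1])
  skeletal_demand <- daily_n_demand(skeletal_N, gf[2])
  total_demand <- tissue_demand + skeletal_demand
  total_fix <- tissue_fix + skeletal_fix
  if ((tissue_demand == 0 && tissue_fix > 0) ||
      (skeletal_demand == 0 && skeletal_fix > 0))
    stop_domain("nonzero fixation against zero demand: ratio undefined")
  pct <- function(num, den) if (den == 0) 0 else 100 * num / den
  structure(list(
    tissue_N = tissue_N, skeletal_N = skeletal_N,
    growth_fraction = gf,
    tissue_demand = tissue_demand, skeletal_demand = skeletal_demand,
    total_demand = total_demand,
    tissue_fix = tissue_fix, skeletal_fix = skeletal_fix,
    total_fix = total_fix,
    total_over_total_pct = pct(total_fix, total_demand),
    tissue_over_tissue_pct = pct(tissue_fix, tissue_demand),
    skeletal_over_skeletal_pct = pct(skeletal_fix, skeletal_demand),
    total_over_tissue_pct = pct(total_fix, tissue_demand)
  ), class = "holobiont_budget")
}

#' @export
print.holobiont_budget <- function(x, digits = 3, ...) {
  cat("Holobiont N budget (daily)\n")
  cat(sprintf("  demand  (ug N cm-2 d-1): tissue %.3g, skeletal %.3g, total %.3g\n",
              x$tissue_demand, x$skeletal_demand, x$total_demand))
  cat(sprintf("  DDN fix (ug N cm-2 d-1): tissue %.3g, skeletal %.3g, total %.3g\n",
              x$tissue_fix, x$skeletal_fix, x$total_fix))
  cat(sprintf("  fixation/demand: total %.*f%%, tissue %.*f%%, skeletal %.*f%%, total/tissue %.*f%%\n",
              digits, x$total_over_total_pct, digits, x$tissue_over_tissue_pct,
              digits, x$skeletal_over_skeletal_pct, digits, x$total_over_tissue_pct))
  invisible(x)
}

#' Mucus-derived DDN addition to the reef water column
#'
#' Scales a per-coral-area mucus N2 fixation rate to a daily per-litre
#' addition to the overlying water column:
#' `rate * 24 * cover * surface_area_factor` gives ng N per cm2 of seabed per
#' day, divided by the water volume above each cm2 of seabed
#' (`depth_cm * 1e-3` litres) and by the molar mass of N to express nmol N
#' l-1 d-1.
#'
#' @param mucus_rate Mucus fixation rate, ng N per cm2 of coral surface per h.
#' @param coral_cover_fraction Areal live coral cover, in \[0, 1\].
#' @param surface_area_factor 3D coral surface area per unit planar cover
#'   (unitless), default 1.
#' @param water_depth Water column depth in m; must be > 0. Default 5 m, the
#'   approximate reef depth of the study sites.
#' @return Contribution in nmol N l-1 d-1.
#' @examples
#' mucus_watercolumn_contribution(0.005, 0.5)  # ~0.0086 nmol N l-1 d-1
#' @export
mucus_watercolumn_contribution <- function(mucus_rate, coral_cover_fraction,
                                           surface_area_factor = 1,
                                           water_depth = 5) {
  check_nonneg(mucus_rate, "mucus_rate")
  check_nonneg(surface_area_factor, "surface_area_factor")
  if (!is.finite(coral_cover_fraction) || coral_cover_fraction < 0 ||
      coral_cover_fraction > 1)
    stop_domain("coral_cover_fraction must lie in [0, 1]")
  if (!is.finite(water_depth) || water_depth <= 0)
    stop_domain("water_depth must be positive")
  ng_per_cm2_seabed_day <- mucus_rate * 24 * coral_cover_fraction * surface_area_factor
  litres_per_cm2 <- water_depth * 100 * 1e-3
  ng_per_cm2_seabed_day / litres_per_cm2 / isotope_constants()$molar_mass_N
}

#' Daily water-column N2 fixation in molar units
#'
#' Converts an hourly mass-based water column fixation rate (ng N l-1 h-1)
#' to a daily molar rate (nmol N l-1 d-1): multiply by 24, divide by the
#' molar mass of N.
#'
#' @param rate Water column fixation rate, ng N l-1 h-1; nonnegative.
#' @return Rate in nmol N l-1 d-1 (vectorized).
#' @examples
#' watercolumn_daily_fixation(0.1)  # ~0.171
#' @export
watercolumn_daily_fixation <- function(rate) {
  check_nonneg(rate, "rate")
  rate * 24 / isotope_constants()$molar_mass_N
}

#' Mucus contribution as a percentage of water-column fixation
#'
#' @param mucus_contrib,wc_contrib Daily contributions in nmol N l-1 d-1;
#'   `wc_contrib` must be > 0.
#' @return Percentage (100 x mucus / water column).
#' @export
mucus_fraction_of_watercolumn <- function(mucus_contrib, wc_contrib) {
  check_nonneg(mucus_contrib, "mucus_contrib")
  if (any(!is.finite(wc_contrib)) || any(wc_contrib <= 0))
    stop_domain("water-column contribution must be positive")
  100 * mucus_contrib / wc_contrib
}

#' Molar N:P ratio of site water
#'
#' Dissolved inorganic nitrogen (NOx + NH4+) over dissolved inorganic
#' phosphorus (phosphate), both in uM; compared against the Redfield ratio
#' (16) as a nutrient-limitation benchmark.
#'
#' @param DIN Dissolved inorganic nitrogen, uM; nonnegative.
#' @param DIP Dissolved inorganic phosphorus, uM; must be > 0.
#' @return The unitless N:P ratio (vectorized).
#' @examples
#' np_ratio(3.2, 0.2)  # 16
#' @export
np_ratio <- function(DIN, DIP) {
  check_nonneg(DIN, "DIN")
  if (any(!is.finite(DIP)) || any(DIP <= 0))
    stop_domain("DIP must be positive")
  DIN / DIP
}
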