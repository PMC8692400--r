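#' Isotope reference constants
#'
#' Reference isotope ratios and the molar mass of nitrogen used throughout the
#' package: `R_air` = 0.003676, the 15N/14N ratio of atmospheric N2 (the delta
#' reference for nitrogen); `R_PDB` = 0.011180, the 13C/12C ratio of the
#' Pee Dee Belemnite carbonate standard; `molar_mass_N` = 14.0067 g/mol.
#'
#' @return A named list with elements `R_air`, `R_PDB` and `molar_mass_N`.
#' @examples
#' isotope_constants()$R_air
#' @export
isotope_constants <- function() {
  list(R_air = 0.003676, R_PDB = 0.011180, molar_mass_N = 14.0067)
}

#' Delta notation from a raw isotope ratio
#'
#' Converts a measured heavy/light isotope ratio to per-mil delta notation,
#' `delta = (R_sample / R_ref - 1) * 1000`, against air N2 for nitrogen or
#' PDB for carbon.
#'
#' @param R_sample Measured isotope ratio (15N/14N or 13C/12C); must be > 0.
#' @param element `"N"` or `"C"`, selecting the reference ratio.
#' @return Delta value in per mil (vectorized over `R_sample`).
#' @examples
#' delta_from_ratio(0.003676, "N")   # 0 by definition
#' delta_from_ratio(0.011180, "C")   # 0 by definition
#' @export
delta_from_ratio <- function(R_sample, element = c("N", "C")) {
  element <- match.arg(element)
  if (any(!is.finite(R_sample)) || any(R_sample <= 0))
    stop_domain("isotope ratio must be positive and finite")
  R_ref <- if (element == "N") isotope_constants()$R_air else isotope_constants()$R_PDB
  (R_sample / R_ref - 1) * 1000
}

#' Atom percent 15N from delta-15N
#'
#' Converts delta-15N (per mil vs. air) to atom percent 15N:
#' `A = 100 * R_air * (delta * 0.001 + 1) / (1 + R_air * (delta * 0.001 + 1))`.
#' The map is strictly increasing in delta. Natural-abundance seawater
#' (delta = 0) evaluates to about 0.3663 atom%.
#'
#' @param delta15N Delta-15N in per mil; must exceed -1000 (positive ratio).
#' @return Atom percent 15N (vectorized).
#' @examples
#' atom_percent_from_delta(0)
#' @export
atom_percent_from_delta <- function(delta15N) {
  if (any(!is.finite(delta15N)) || any(delta15N <= -1000))
    stop_domain("delta15N must be finite and > -1000 per mil")
  r <- isotope_constants()$R_air * (delta15N * 0.001 + 1)
  100 * r / (1 + r)
}

#' Delta-15N from atom percent 15N
#'
#' Exact algebraic inverse of [atom_percent_from_delta()]: recovers the
#' per-mil delta value from an atom-percent measurement. Round trips are exact
#' to well below 1e-10 per mil.
#'
#' @param A Atom percent 15N, strictly between 0 and 100.
#' @return Delta-15N in per mil (vectorized).
#' @examples
#' delta_from_atom_percent(atom_percent_from_delta(10))  # 10
#' @export
delta_from_atom_percent <- function(A) {
  if (any(!is.finite(A)) || any(A <= 0) || any(A >= 100))
    stop_domain("atom percent must lie strictly between 0 and 100")
  r <- (A / 100) / (1 - A / 100)            # back to the 15N/14N ratio
  (r / isotope_constants()$R_air - 1) * 1000
}

#' Natural-abundance atom percent 15N
#'
#' Atom percent 15N of unlabeled material (delta-15N = 0), the default A0 of
#' the rate equation when no measured unlabeled-seawater value is supplied.
#'
#' @return Atom percent 15N at delta = 0 (about 0.366254).
#' @export
natural_abundance_atom_pct <- function() atom_percent_from_delta(0)

#' Particulate nitrogen mass of a sample
#'
#' `PN = percentN / 100 * dry_weight`, returned in micrograms of N. The %N is
#' taken from the enriched sample of a pair.
#'
#' @param percentN Nitrogen content as percent of dry mass, in \[0, 100\].
#' @param dry_weight Sample dry weight in grams.
#' @return Particulate nitrogen in ug N (vectorized).
#' @examples
#' pn_mass(1.0, 0.01)   # 100 ug N
#' @export
pn_mass <- function(percentN, dry_weight) {
  check_nonneg(percentN, "percentN")
  check_nonneg(dry_weight, "dry_weight")
  if (any(percentN > 100)) stop_domain("percentN cannot exceed 100")
  percentN / 100 * dry_weight * 1e6
}
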