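#' Detection threshold for isotope enrichment
#'
#' Enrichment of a sample pair counts as detectable when the atom-percent
#' excess (Ae - Ac) exceeds three times the standard deviation of repeated
#' control (Ac) measurements. This computes that threshold: 3 x sample SD
#' (n - 1 denominator) of the supplied control atom-percent values.
#'
#' @param control_atom_pcts Numeric vector of control atom% 15N values;
#'   at least two are required.
#' @return The detection threshold in atom%.
#' @examples
#' detection_threshold(c(0.3660, 0.3665, 0.3670))  # 0.0015
#' @export
detection_threshold <- function(control_atom_pcts) {
  control_atom_pcts <- control_atom_pcts[is.finite(control_atom_pcts)]
  if (length(control_atom_pcts) < 2)
    stop_validation("need at least 2 control atom%% values to estimate a detection threshold")
  3 * stats::sd(control_atom_pcts)
}

#' Diazotroph-derived nitrogen assimilation rate
#'
#' The tracer rate equation:
#' `rate = (1 / duration_h) * (Ae - Ac) / (A15N2 - A0) * PN`,
#' in ug N per fragment per hour. `Ae` and `Ac` are the atom% 15N of the
#' enriched and paired control sample, `A15N2` the measured atom% of the
#' labeled incubation water, `A0` the atom% of unlabeled seawater and `PN`
#' the particulate nitrogen of the fragment in ug. The result may be
#' negative; detection logic is applied downstream, not here.
#'
#' @param Ae,Ac Enriched / control atom% 15N.
#' @param A15N2 Atom% 15N of the labeled incubation water; must exceed `A0`.
#' @param A0 Atom% 15N of unlabeled seawater.
#' @param PN Particulate nitrogen, ug N; nonnegative.
#' @param duration_h Incubation duration in hours; must be > 0.
#' @return Rate in ug N per fragment per hour (vectorized).
#' @examples
#' ddn_rate(0.3763, 0.3663, 10.0, 0.3663, 100, 24)  # ~0.0043 ug N/h
#' @export
ddn_rate <- function(Ae, Ac, A15N2, A0, PN, duration_h) {
  if (any(!is.finite(A15N2)) || any(A15N2 <= A0))
    stop_domain("label enrichment A15N2 must exceed the unlabeled atom%% A0")
  if (any(!is.finite(duration_h)) || any(duration_h <= 0))
    stop_domain("duration_h must be positive")
  check_nonneg(PN, "PN")
  (1 / duration_h) * (Ae - Ac) / (A15N2 - A0) * PN
}

#' Standardize a per-fragment rate
#'
#' Rescales a per-fragment mass rate (ug N/h) to the study's reporting units:
#' per surface area (ng N cm-2 h-1), per dry weight (ng N g-1 DW h-1), or per
#' volume (ng N l-1 h-1, for seawater incubations).
#'
#' @param rate_mass Rate in ug N per fragment per hour.
#' @param value The denominator: surface area in cm2, dry weight in g, or
#'   volume in litres; must be > 0.
#' @param by One of `"surface_area"`, `"dry_weight"`, `"volume"`.
#' @return Standardized rate in ng N per unit per hour.
#' @examples
#' standardize_rate(0.1038, 30, "surface_area")  # 3.46 ng N cm-2 h-1
#' @export
standardize_rate <- function(rate_mass, value,
                             by = c("surface_area", "dry_weight", "volume")) {
  by <- match.arg(by)
  if (any(!is.finite(value)) || any(value <= 0))
    stop_domain("standardization denominator (%s) must be positive", by)
  rate_mass * 1000 / value          # ug -> ng
}

#' Acetylene-reduction ethylene to nitrogen equivalents
#'
#' Converts moles of ethylene from an acetylene reduction assay (ARA) to
#' moles of fixed N by the theoretical 3:2 stoichiometry (multiply by 2/3),
#' used when comparing ARA-based gross fixation with 15N2 net assimilation.
#'
#' @param ethylene Moles of C2H4; nonnegative.
#' @return Moles of N equivalents.
#' @examples
#' ara_to_n_equivalents(3)  # 2
#' @export
ara_to_n_equivalents <- function(ethylene) {
  check_nonneg(ethylene, "ethylene")
  ethylene * 2 / 3
}

#' Hourly to daily rate
#'
#' Multiplies an hourly rate by 24, for reporting daily rates in the units of
#' the cross-study comparison (e.g. ng N cm-2 h-1 -> ng N cm-2 d-1).
#'
#' @param rate_hourly Any hourly rate; nonnegative.
#' @return The corresponding daily rate.
#' @export
hourly_to_daily <- function(rate_hourly) {
  check_nonneg(rate_hourly, "rate_hourly")
  rate_hourly * 24
}

#' Estimate DDN assimilation rates from an incubation sample table
#'
#' The package's central estimator. Takes a table of incubation samples (one
#' row per fragment/compartment measurement, as returned by
#' [read_sample_table()] or [simulate_incubation_dataset()]), converts
#' delta-15N to atom%, pairs each enriched fragment with the control fragment
#' of the same colony, computes the detection threshold from repeated control
#' measurements within a pooling group, and evaluates the tracer rate
#' equation with all standardizations.
#'
#' Pairing is by `colony` within species x site x compartment; an enriched
#' sample with no same-colony control falls back to the pooling-group mean
#' control atom% with a warning. The detection threshold is 3 x SD of control
#' atom% values pooled within `pool_by` (default species x site x
#' compartment). `A0` defaults to natural abundance (delta = 0) unless a
#' measured unlabeled-seawater atom% is supplied.
#'
#' @param samples Data frame with the columns of the incubation sample table
#'   (see [read_sample_table()]).
#' @param a0 Atom% 15N of unlabeled seawater; default
#'   [natural_abundance_atom_pct()].
#' @param pool_by Character vector of grouping columns used to pool control
#'   replicates for the detection SD.
#' @return An object of class `"ddn_rates"`: a list with `pairs` (one row per
#'   enriched/control pair: atom% excess, detection threshold and flag, rate
#'   in ug N/h and its per-area / per-DW / per-volume standardizations),
#'   `a0`, and `pool_by`. Has `print` and `summary` methods; `summary`
#'   applies the below-detection zeroing rule and averages by group.
#' @examples
#' sim <- simulate_incubation_dataset(sim_config(seed = 1))
#' fit <- ddn_rates(sim$samples)
#' summary(fit)
#' @export
ddn_rates <- function(samples, a0 = natural_abundance_atom_pct(),
                      pool_by = c("species", "site", "compartment")) {
  samples <- validate_sample_table(samples)
  samples$atom_pct <- atom_percent_from_delta(samples$delta15N)

  enr <- samples[samples$treatment == "enriched", , drop = FALSE]
  ctl <- samples[samples$treatment == "control", , drop = FALSE]
  if (nrow(enr) == 0 || nrow(ctl) == 0)
    stop_validation("need both enriched and control samples to estimate rates")

  pool_key <- function(df) do.call(paste, c(df[pool_by], sep = "\r"))
  ctl_key <- pool_key(ctl)
  thr <- tapply(ctl$atom_pct, ctl_key, function(x) {
    if (length(x) < 2) NA_real_ else detection_threshold(x)
  })
  ctl_mean <- tapply(ctl$atom_pct, ctl_key, mean)

  # pair by colony within species x site x compartment
  pair_key <- function(df)
    do.call(paste, c(df[c("species", "site", "compartment", "colony")], sep = "\r"))
  ctl_by_pair <- split(ctl, pair_key(ctl))
  ekey <- pair_key(enr)

  n <- nrow(enr)
  Ac <- numeric(n); ctl_id <- character(n); fallback <- logical(n)
  for (i in seq_len(n)) {
    mate <- ctl_by_pair[[ekey[i]]]
    if (!is.null(mate) && nrow(mate) >= 1) {
      Ac[i] <- mean(mate$atom_pct)
      ctl_id[i] <- paste(mate$sample_id, collapse = ";")
    } else {
      gk <- pool_key(enr[i, , drop = FALSE])
      if (is.na(ctl_mean[gk]))
        stop_validation("no control samples available for group %s",
                        gsub("\r", "/", gk))
      Ac[i] <- ctl_mean[[gk]]
      ctl_id[i] <- NA_character_
      fallback[i] <- TRUE
    }
  }
  if (any(fallback))
    warning(sum(fallback), " enriched sample(s) had no same-colony control; ",
            "group-mean control atom% used instead")

  PN <- pn_mass(enr$percentN, enr$dry_weight_g)
  rate <- ddn_rate(enr$atom_pct, Ac, enr$label_atom_pct, a0, PN, enr$duration_h)
  excess <- enr$atom_pct - Ac
  thr_i <- as.numeric(thr[pool_key(enr)])
  detected <- !is.na(thr_i) & excess > thr_i

  std <- function(value) ifelse(is.finite(value) & value > 0,
                                rate * 1000 / value, NA_real_)
  pairs <- data.frame(
    sample_id = enr$sample_id, control_id = ctl_id,
    site = enr$site, species = enr$species, colony = enr$colony,
    compartment = enr$compartment,
    atom_pct_excess = excess, detection_threshold = thr_i,
    detected = detected,
    pn_ug = PN,
    rate_ugN_h = rate,
    rate_per_area_ngN_cm2_h = std(enr$surface_area_cm2),
    rate_per_dw_ngN_g_h = std(enr$dry_weight_g),
    rate_per_volume_ngN_l_h = std(enr$volume_l),
    stringsAsFactors = FALSE
  )
  structure(list(pairs = pairs, a0 = a0, pool_by = pool_by,
                 call = match.call()),
            class = "ddn_rates")
}

#' @export
print.ddn_rates <- function(x, ...) {
  cat("DDN assimilation rate estimates\n")
  cat(sprintf("  pairs: %d   detected: %d   A0 = %.6f atom%%\n",
              nrow(x$pairs), sum(x$pairs$detected), x$a0))
  cat("  detection pooling:", paste(x$pool_by, collapse = " x "), "\n")
  invisible(x)
}

#' @export
summary.ddn_rates <- function(object,
                              by = c("species", "site", "compartment"),
                              measure = "rate_per_area_ngN_cm2_h", ...) {
  out <- summarize_group_rates(object$pairs, by = by, measure = measure)
  structure(list(groups = out, measure = measure), class = "summary.ddn_rates")
}

#' @export
print.summary.ddn_rates <- function(x, ...) {
  cat("Group mean DDN rates (below-detection rates zeroed), measure:",
      x$measure, "\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Group averages of DDN rates under the detection rule
#'
#' Averages per-pair rates within groups, after replacing every
#' below-detection rate (including negative excesses) by zero — the
#' conservative averaging convention for tracer incubations. Reports the mean,
#' SD, group size and number of detected pairs.
#'
#' @param pairs Data frame of pair-level rates with a logical `detected`
#'   column (the `pairs` element of a [ddn_rates()] fit).
#' @param by Grouping columns.
#' @param measure Name of the rate column to average.
#' @return Data frame with one row per group: `mean`, `sd`, `n`, `n_detected`.
#' @export
summarize_group_rates <- function(pairs,
                                  by = c("species", "site", "compartment"),
                                  measure = "rate_per_area_ngN_cm2_h") {
  if (!is.data.frame(pairs) || !"detected" %in% names(pairs))
    stop_validation("`pairs` must be a data frame carrying a `detected` flag")
  if (!measure %in% names(pairs))
    stop_validation("unknown rate measure `%s`", measure)
  r <- ifelse(pairs$detected, pairs[[measure]], 0)
  keep <- !is.na(r)
  if (!all(keep)) {
    warning(sum(!keep), " pair(s) lacking `", measure, "` skipped")
    pairs <- pairs[keep, , drop = FALSE]; r <- r[keep]
  }
  key <- do.call(paste, c(pairs[by], sep = "\r"))
  agg <- function(f) as.numeric(tapply(r, key, f))
  det <- as.numeric(tapply(pairs$detected, key, sum))
  lab <- do.call(rbind, strsplit(names(tapply(r, key, length)), "\r", fixed = TRUE))
  out <- data.frame(lab, stringsAsFactors = FALSE)
  names(out) <- by
  out$mean <- agg(mean)
  out$sd <- agg(function(x) if (length(x) > 1) stats::sd(x) else 0)
  out$n <- agg(length)
  out$n_detected <- det
  out[order(out[[1]], out[[2]]), , drop = FALSE]
}
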