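# Independent brute-force oracles used by unit and acceptance tests.

# Group-by aggregation oracle: plain loop over unique taxa, independent of
# aggregate_by_rank()'s split/vapply path.
brute_force_aggregate <- function(ratios, taxonomy, rank = "order") {
  taxon <- as.character(taxonomy[[rank]][match(names(ratios), taxonomy$asv_id)])
  taxon[is.na(taxon) | taxon == ""] <- "unassigned"
  out <- NULL
  for (tx in sort(unique(taxon))) {
    x <- unname(ratios[taxon == tx])
    out <- rbind(out, data.frame(
      taxon = tx, mean = sum(x) / length(x),
      sd = if (length(x) > 1) sqrt(sum((x - mean(x))^2) / (length(x) - 1)) else 0,
      n = length(x), sd_defined = length(x) > 1,
      stringsAsFactors = FALSE))
  }
  out
}

# A small random ratios + taxonomy pair for property tests.
random_ratio_case <- function(n_asvs = 20, n_orders = 4) {
  asv <- sprintf("A%03d", seq_len(n_asvs))
  tax <- data.frame(
    asv_id = asv, domain = "Bacteria", phylum = "P", class = "C",
    order = sample(paste0("Order", seq_len(n_orders)), n_asvs, replace = TRUE),
    family = "F", genus = "G",
    nifh_cluster = sample(c("I", "II", "III", "IV", "V", "none"), n_asvs,
                          replace = TRUE),
    stringsAsFactors = FALSE)
  ratios <- stats::setNames(stats::rlnorm(n_asvs, 0, 1), asv)
  list(ratios = ratios, taxonomy = tax)
}

table1_inputs <- function() {
  # printed N contents (mg N cm-2) and compartment-level fixation/demand
  # percentages of the four holobiont budget columns
  data.frame(
    label = c("Goniopora-Hantu", "Platygyra-Hantu", "Platygyra-Kusu",
              "Pocillopora-Kusu"),
    tissue_N = c(1.85, 0.62, 0.49, 0.26),
    skeletal_N = c(1.76, 1.54, 2.17, 1.06),
    tissue_pct = c(0.29, 0.83, 1.25, 2.22),
    skeletal_pct = c(5.62, 4.89, 4.01, 7.49),
    total_pct = c(2.89, 3.72, 3.51, 6.45),
    total_over_tissue_pct = c(5.56, 12.96, 19.15, 32.54),
    stringsAsFactors = FALSE)
}

# Rebuild a holobiont budget from printed contents and compartment ratios.
budget_from_printed_row <- function(row) {
  td <- daily_n_demand(row$tissue_N)
  sd_ <- daily_n_demand(row$skeletal_N)
  holobiont_budget(row$tissue_N, row$skeletal_N,
                   tissue_fix = row$tissue_pct / 100 * td,
                   skeletal_fix = row$skeletal_pct / 100 * sd_)
}
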