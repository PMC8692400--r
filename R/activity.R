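#' Normalize an ASV count matrix to per-sample proportions
#'
#' Total-sum scaling: each sample (column) is divided by its library size so
#' proportions sum to 1. Rarefaction is deliberately not offered — it is
#' nondeterministic and discards counts — and no other transformation is
#' applied before replicate merging.
#'
#' @param counts Numeric matrix, ASVs in rows, samples in columns; counts
#'   nonnegative, every column total > 0.
#' @return Matrix of proportions with the same dimnames.
#' @examples
#' normalize_to_proportions(cbind(s1 = c(a = 90, b = 10)))
#' @export
normalize_to_proportions <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_validation("counts must be nonnegative")
  tot <- colSums(counts)
  if (any(tot <= 0)) {
    bad <- colnames(counts)[tot <= 0]
    if (is.null(bad)) bad <- which(tot <= 0)
    stop_validation("sample(s) with zero library size: %s",
                    paste(bad, collapse = ", "))
  }
  sweep(counts, 2, tot, "/")
}

#' Merge replicate samples by averaging proportions
#'
#' Each replicate is normalized first, then replicate proportion vectors are
#' averaged arithmetically within a group, so unequal library sizes do not
#' weight replicates unequally (averaging proportions, not pooling counts).
#' The merged vector again sums to 1.
#'
#' @param proportions Matrix of per-sample proportions (ASVs x samples).
#' @param groups Character/factor vector, one group label per sample column.
#' @return Matrix of merged proportions, one column per group.
#' @export
merge_replicates <- function(proportions, groups) {
  proportions <- as.matrix(proportions)
  if (length(groups) != ncol(proportions))
    stop_validation("`groups` must have one label per sample column")
  groups <- as.character(groups)
  out <- vapply(split(seq_along(groups), groups),
                function(j) rowMeans(proportions[, j, drop = FALSE]),
                numeric(nrow(proportions)))
  out <- matrix(out, nrow = nrow(proportions),
                dimnames = list(rownames(proportions), sort(unique(groups))))
  out
}

#' Per-ASV RNA:DNA activity ratios
#'
#' Ratio of an ASV's relative abundance in the merged RNA library to its
#' relative abundance in the paired merged DNA library, a relative-activity
#' indicator. Only ASVs with nonzero proportion on both sides are ratioed;
#' ASVs absent from either side are excluded, never imputed.
#'
#' @param rna,dna Named numeric vectors of merged proportions for the same
#'   species x compartment group.
#' @return Named numeric vector of ratios for the shared ASVs. Empty (with a
#'   warning) when no ASV is shared.
#' @examples
#' rna_dna_ratios(rna = c(a = 0.25, b = 0.75), dna = c(a = 0.5, b = 0.5))
#' @export
rna_dna_ratios <- function(rna, dna) {
  if (is.null(names(rna)) || is.null(names(dna)))
    stop_validation("rna and dna proportion vectors must be named by ASV")
  shared <- intersect(names(rna)[rna > 0], names(dna)[dna > 0])
  if (length(shared) == 0) {
    warning("no ASVs shared between RNA and DNA libraries; empty result")
    return(stats::setNames(numeric(0), character(0)))
  }
  rna[shared] / dna[shared]
}

#' Aggregate RNA:DNA ratios by taxonomic rank
#'
#' Arithmetic mean and sample SD of per-ASV ratios within each taxon at a
#' chosen rank (default order), the reporting convention for relative
#' microbial activity ("mean +/- SD, n"). Since rRNA copy number and growth
#' physiology confound per-ASV ratios, `n` and `sd` are always reported
#' alongside the mean; a single-ASV taxon gets `sd = 0` and `sd_defined =
#' FALSE`. ASVs missing the rank in the taxonomy are pooled into an
#' `"unassigned"` bucket rather than dropped.
#'
#' @param ratios Named numeric vector of per-ASV ratios (names are ASV ids).
#' @param taxonomy Taxonomy data frame from [read_taxonomy()] (must contain
#'   `asv_id` and the rank column).
#' @param rank Rank column name, default `"order"`.
#' @return Data frame with `taxon`, `mean`, `sd`, `n`, `sd_defined`.
#' @export
aggregate_by_rank <- function(ratios, taxonomy, rank = "order") {
  if (!rank %in% names(taxonomy))
    stop_validation("taxonomy has no `%s` rank column", rank)
  idx <- match(names(ratios), taxonomy$asv_id)
  if (anyNA(idx))
    stop_validation("ASV(s) absent from taxonomy: %s",
                    paste(names(ratios)[is.na(idx)], collapse = ", "))
  taxon <- as.character(taxonomy[[rank]][idx])
  taxon[is.na(taxon) | taxon == ""] <- "unassigned"
  sp <- split(unname(ratios), taxon)
  out <- data.frame(
    taxon = names(sp),
    mean = vapply(sp, mean, 0),
    sd = vapply(sp, function(x) if (length(x) > 1) stats::sd(x) else 0, 0),
    n = vapply(sp, length, 0L),
    sd_defined = vapply(sp, function(x) length(x) > 1, TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(out$taxon), , drop = FALSE]
}

#' Relative abundance of nitrogen-fixing nifH clusters
#'
#' nifH-like sequences fall into canonical phylogenetic clusters I-V, of
#' which only Clusters I-III contain genuine nitrogen fixers (IV/V hold
#' homologs such as chlorophyll-synthesis genes). For each sample group this
#' reports (a) the share of the nifH community carried by the clusters of
#' interest and (b) the composition within those clusters, both as
#' percentages of per-sample relative abundance averaged over the group
#' (so library size never weights the composition).
#'
#' @param counts ASV x sample count matrix (nifH table).
#' @param taxonomy Taxonomy data frame with `asv_id` and `nifh_cluster`.
#' @param clusters Clusters of interest, default `c("I", "II", "III")`.
#' @param groups Group label per sample column; default one pooled group.
#' @return List with `share` (data frame: group, pct of total nifH counts in
#'   the clusters of interest) and `within` (data frame: group, cluster, pct
#'   within the clusters of interest; sums to 100 per group).
#' @export
cluster_relative_abundance <- function(counts, taxonomy,
                                       clusters = c("I", "II", "III"),
                                       groups = NULL) {
  counts <- as.matrix(counts)
  if (is.null(groups)) groups <- rep("all", ncol(counts))
  idx <- match(rownames(counts), taxonomy$asv_id)
  if (anyNA(idx))
    stop_validation("ASV(s) absent from taxonomy: %s",
                    paste(rownames(counts)[is.na(idx)], collapse = ", "))
  cl <- as.character(taxonomy$nifh_cluster[idx])
  is_nifh <- cl != "none"
  share <- list(); within <- list()
  for (g in unique(as.character(groups))) {
    # per-sample proportions averaged within the group, so an individual
    # library's sequencing depth cannot weight the composition
    tot <- rowMeans(normalize_to_proportions(counts[, groups == g, drop = FALSE]))
    nifh_total <- sum(tot[is_nifh])
    if (nifh_total == 0) {
      warning("group ", g, " has no nifH counts; skipped")
      next
    }
    coi <- is_nifh & cl %in% clusters
    share[[g]] <- data.frame(group = g,
                             pct_of_nifh = 100 * sum(tot[coi]) / nifh_total,
                             stringsAsFactors = FALSE)
    coi_total <- sum(tot[coi])
    wi <- vapply(clusters, function(k) sum(tot[coi & cl == k]), 0)
    within[[g]] <- data.frame(
      group = g, cluster = clusters,
      pct_within = if (coi_total > 0) 100 * wi / coi_total else rep(NA_real_, length(clusters)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  list(share = do.call(rbind, share), within = do.call(rbind, within))
}

#' Minimum raw-abundance filter for ASVs
#'
#' Retains ASVs whose raw count strictly exceeds a threshold, the rule used
#' to screen spurious low-abundance sequences (e.g. seawater nifH ASVs kept
#' only when raw abundance > 10). No renormalization happens here: the result
#' is an exact sub-matrix of the input.
#'
#' @param counts ASV x sample count matrix.
#' @param threshold Nonnegative count threshold; strict `>`. Default 10.
#' @param scope `"total"` (default): an ASV's counts are summed over the
#'   aggregation scope before comparison; `"per_sample"`: the ASV is kept if
#'   it exceeds the threshold in at least one sample.
#' @return The filtered count matrix (possibly with zero rows).
#' @export
min_abundance_filter <- function(counts, threshold = 10,
                                 scope = c("total", "per_sample")) {
  scope <- match.arg(scope)
  counts <- as.matrix(counts)
  if (!is.finite(threshold) || threshold < 0)
    stop_validation("threshold must be nonnegative")
  keep <- if (scope == "total") rowSums(counts) > threshold
          else apply(counts, 1, function(x) any(x > threshold))
  counts[keep, , drop = FALSE]
}

#' Paired DNA/RNA relative-activity analysis
#'
#' End-to-end wrapper for the activity workflow: normalizes every sample to
#' proportions, merges replicates within species x site x compartment for
#' each nucleic-acid type, computes per-ASV RNA:DNA ratios for every group
#' present in both libraries, and aggregates them by taxonomic order.
#'
#' @param table An abundance table as returned by [read_count_matrix()] or
#'   [simulate_paired_amplicon_tables()]: list with `counts` (ASV x sample
#'   matrix) and `metadata` (per-sample `nucleic_acid`, `species`, `site`,
#'   `compartment`, `replicate`).
#' @param taxonomy Taxonomy data frame ([read_taxonomy()]).
#' @param rank Rank for aggregation, default `"order"`.
#' @return Object of class `"activity_summary"`: `ratios` (list of named
#'   per-ASV ratio vectors, one per group), `by_rank` (data frame of
#'   per-taxon mean/sd/n per group), and `groups`.
#' @export
rna_dna_activity <- function(table, taxonomy, rank = "order") {
  counts <- table$counts; meta <- table$metadata
  props <- normalize_to_proportions(counts)
  gkey <- paste(meta$species, meta$site, meta$compartment, sep = "/")
  ratios <- list(); by_rank <- list()
  for (g in unique(gkey)) {
    jd <- which(gkey == g & meta$nucleic_acid == "DNA")
    jr <- which(gkey == g & meta$nucleic_acid == "RNA")
    if (length(jd) == 0 || length(jr) == 0) next
    dna <- rowMeans(props[, jd, drop = FALSE])
    rna <- rowMeans(props[, jr, drop = FALSE])
    rat <- rna_dna_ratios(rna, dna)
    if (length(rat) == 0) next
    ratios[[g]] <- rat
    agg <- aggregate_by_rank(rat, taxonomy, rank = rank)
    agg <- cbind(group = g, agg, stringsAsFactors = FALSE)
    by_rank[[g]] <- agg
  }
  structure(list(ratios = ratios,
                 by_rank = do.call(rbind, c(by_rank, list(make.row.names = FALSE))),
                 groups = names(ratios), rank = rank),
            class = "activity_summary")
}

#' @export
print.activity_summary <- function(x, ...) {
  cat("RNA:DNA relative-activity summary\n")
  cat("  groups:", paste(x$groups, collapse = ", "), "\n")
  cat("  shared-ASV ratios per group:",
      paste(vapply(x$ratios, length, 0L), collapse = ", "), "\n")
  if (!is.null(x$by_rank)) {
    cat("  per-", x$rank, " aggregates:\n", sep = "")
    print(utils::head(x$by_rank, 10), row.names = FALSE)
  }
  invisible(x)
}
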