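# Tabular io. TSV is the canonical dialect (tab-separated, UTF-8, '.' decimal,
# mandatory header); CSV is accepted on input by extension. Writers prepend
# '#'-comment header lines (version, seed, config hash) which all readers skip.

.compartments <- c("host", "symbiont", "mucus", "skeleton", "seawater")
.treatments <- c("enriched", "control", "baseline")
.clusters <- c("I", "II", "III", "IV", "V", "none")

.sample_cols <- c("sample_id", "site", "species", "colony", "compartment",
                  "treatment", "delta15N", "delta13C", "percentN",
                  "dry_weight_g", "surface_area_cm2", "volume_l",
                  "label_atom_pct", "duration_h")

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "", quote = "\"")
}

#' @noRd
write_tsv <- function(df, path, seed = NULL, extra = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("reefnfix"))
  writeLines(sprintf("# reefnfix %s", ver), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  if (!is.null(extra)) writeLines(paste0("# ", extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Validate an incubation sample table
#'
#' Checks the column set, numeric ranges and controlled vocabularies of a
#' sample table; errors name the offending row. Enforced: compartment and
#' treatment vocabularies; `percentN` in \[0, 100\]; nonnegative weights,
#' areas, volumes and durations; `label_atom_pct` present exactly on
#' enriched rows and above natural abundance.
#'
#' @param samples Data frame to validate.
#' @return The validated data frame, invisibly coerced to canonical column
#'   order.
#' @export
validate_sample_table <- function(samples) {
  miss <- setdiff(.sample_cols, names(samples))
  if (length(miss))
    stop_validation("sample table lacks column(s): %s", paste(miss, collapse = ", "))
  num_cols <- c("delta15N", "delta13C", "percentN", "dry_weight_g",
                "surface_area_cm2", "volume_l", "label_atom_pct", "duration_h")
  for (cl in num_cols) {
    v <- samples[[cl]]
    if (is.logical(v) && all(is.na(v))) {   # all-empty column read as logical
      samples[[cl]] <- as.numeric(v)
      next
    }
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad))
        stop_validation("non-numeric value in column %s at row %d: '%s'",
                        cl, bad[1], v[bad[1]])
      samples[[cl]] <- conv
    }
  }
  bad <- which(!samples$compartment %in% .compartments)
  if (length(bad))
    stop_validation("unknown compartment '%s' at row %d (allowed: %s)",
                    samples$compartment[bad[1]], bad[1],
                    paste(.compartments, collapse = ", "))
  bad <- which(!samples$treatment %in% .treatments)
  if (length(bad))
    stop_validation("unknown treatment '%s' at row %d", samples$treatment[bad[1]], bad[1])
  bad <- which(samples$percentN < 0 | samples$percentN > 100)
  if (length(bad))
    stop_validation("percentN outside [0, 100] at row %d", bad[1])
  for (cl in c("dry_weight_g", "surface_area_cm2", "volume_l", "duration_h")) {
    bad <- which(!is.na(samples[[cl]]) & samples[[cl]] < 0)
    if (length(bad)) stop_validation("negative %s at row %d", cl, bad[1])
  }
  enr <- samples$treatment == "enriched"
  bad <- which(enr & is.na(samples$label_atom_pct))
  if (length(bad))
    stop_validation("enriched sample lacking label_atom_pct at row %d", bad[1])
  bad <- which(enr & (samples$label_atom_pct <= natural_abundance_atom_pct() |
                        samples$label_atom_pct >= 100))
  if (length(bad))
    stop_validation("label_atom_pct at row %d must lie in (natural abundance, 100)", bad[1])
  bad <- which(!enr & !is.na(samples$label_atom_pct))
  if (length(bad))
    stop_validation("label_atom_pct present on non-enriched row %d", bad[1])
  samples[, .sample_cols]
}

#' Read an incubation sample table
#'
#' Reads a TSV (or, by extension, CSV) of per-fragment incubation
#' measurements and validates it with [validate_sample_table()]. Required
#' columns: `sample_id, site, species, colony, compartment, treatment,
#' delta15N, delta13C, percentN, dry_weight_g, surface_area_cm2, volume_l,
#' label_atom_pct, duration_h`. Empty cells are missing values.
#'
#' @param path File path.
#' @return Validated sample data frame.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  validate_sample_table(read_delim_auto(path))
}

#' Write an incubation sample table
#' @param samples Validated sample data frame.
#' @param path Output TSV path.
#' @param seed Optional seed recorded in the file header.
#' @return The path, invisibly.
#' @export
write_sample_table <- function(samples, path, seed = NULL) {
  write_tsv(validate_sample_table(samples), path, seed = seed)
}

#' Read an ASV count matrix
#'
#' Reads an ASV x sample count matrix from TSV (first column `asv_id`,
#' remaining columns one per sample) or from a BIOM file (`.biom`, requires
#' the `biomformat` package). Counts must be nonnegative; if `metadata` is
#' supplied, every sample column must resolve in it by `sample_id`.
#'
#' @param path Matrix file path (.tsv/.csv or .biom).
#' @param metadata Optional path to (or data frame of) per-sample metadata
#'   with columns `sample_id, nucleic_acid, species, site, compartment,
#'   replicate`.
#' @return A list of class `"abundance_table"` with `counts` (numeric
#'   matrix) and `metadata` (data frame or NULL).
#' @export
read_count_matrix <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop_validation("reading BIOM requires the biomformat package")
    b <- biomformat::read_biom(path)
    counts <- as.matrix(biomformat::biom_data(b))
  } else {
    df <- read_delim_auto(path)
    if (names(df)[1] != "asv_id")
      stop_validation("count matrix must have `asv_id` as its first column")
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- df$asv_id
  }
  storage.mode(counts) <- "double"
  if (anyNA(counts)) stop_validation("count matrix contains missing values")
  if (any(counts < 0)) stop_validation("count matrix contains negative counts")
  meta <- NULL
  if (!is.null(metadata)) {
    meta <- if (is.data.frame(metadata)) metadata else read_delim_auto(metadata)
    if (!"sample_id" %in% names(meta))
      stop_validation("metadata lacks a sample_id column")
    missing <- setdiff(colnames(counts), meta$sample_id)
    if (length(missing))
      stop_validation("sample(s) in matrix but absent from metadata: %s",
                      paste(missing, collapse = ", "))
    meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(list(counts = counts, metadata = meta), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("ASV abundance table: %d ASVs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$metadata))
    cat("  nucleic acid:", paste(unique(x$metadata$nucleic_acid), collapse = "/"),
        "  groups:", length(unique(paste(x$metadata$species, x$metadata$compartment))), "\n")
  invisible(x)
}

#' Write an ASV count matrix as TSV
#' @param counts ASV x sample matrix.
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @return The path, invisibly.
#' @export
write_count_matrix <- function(counts, path, seed = NULL) {
  df <- data.frame(asv_id = rownames(counts), as.data.frame(counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, seed = seed)
}

#' Read a taxonomy table
#'
#' TSV with columns `asv_id`, ranked lineage (`domain, phylum, class, order,
#' family, genus`) and `nifh_cluster` in I-V or `none`. Duplicate ASV ids
#' and unknown cluster tokens are errors; an empty/missing order rank is
#' allowed and flags the ASV as unassigned at that rank.
#'
#' @param path File path.
#' @return Taxonomy data frame.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  tax <- read_delim_auto(path)
  need <- c("asv_id", "domain", "phylum", "class", "order", "family", "genus",
            "nifh_cluster")
  miss <- setdiff(need, names(tax))
  if (length(miss))
    stop_validation("taxonomy lacks column(s): %s", paste(miss, collapse = ", "))
  dup <- tax$asv_id[duplicated(tax$asv_id)]
  if (length(dup))
    stop_validation("duplicate asv_id in taxonomy: %s",
                    paste(unique(dup), collapse = ", "))
  bad <- which(!tax$nifh_cluster %in% .clusters)
  if (length(bad))
    stop_validation("unknown nifh_cluster token '%s' at row %d (allowed: %s)",
                    tax$nifh_cluster[bad[1]], bad[1], paste(.clusters, collapse = ", "))
  tax
}
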