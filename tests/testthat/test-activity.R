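test_that("total-sum scaling yields proportions summing to one", {
  m <- cbind(s1 = c(a = 50, b = 50), s2 = c(a = 90, b = 10))
  p <- normalize_to_proportions(m)
  expect_equal(p[, "s1"], c(a = 0.5, b = 0.5))
  expect_equal(p[, "s2"], c(a = 0.9, b = 0.1))
  expect_equal(unname(colSums(p)), c(1, 1), tolerance = 1e-12)
  expect_equal(normalize_to_proportions(m * 7), p)
  m0 <- cbind(s1 = c(1, 2), empty = c(0, 0))
  expect_error(normalize_to_proportions(m0), "empty",
               class = "reefnfix_validation_error")
})

test_that("replicate merging averages proportions, not pooled counts", {
  p <- cbind(r1 = c(0.4, 0.6), r2 = c(0.6, 0.4))
  expect_equal(unname(merge_replicates(p, c("g", "g"))[, 1]), c(0.5, 0.5))
  expect_equal(unname(merge_replicates(p[, 1, drop = FALSE], "g")[, 1]),
               c(0.4, 0.6))
  p3 <- cbind(c(0.2, 0.8), c(0.4, 0.6), c(0.6, 0.4))
  expect_equal(unname(merge_replicates(p3, rep("g", 3))[, 1]), c(0.4, 0.6))
  expect_equal(sum(merge_replicates(p3, rep("g", 3))), 1, tolerance = 1e-12)
  expect_error(merge_replicates(p, "g"), class = "reefnfix_validation_error")
})

test_that("RNA:DNA ratios cover shared ASVs only", {
  expect_equal(rna_dna_ratios(rna = c(a = 0.25, b = 0.75),
                              dna = c(a = 0.5, b = 0.5)),
               c(a = 0.5, b = 1.5))
  r <- rna_dna_ratios(rna = c(x = 1.0), dna = c(x = 0.9, z = 0.1))
  expect_named(r, "x")
  expect_equal(unname(r), 1 / 0.9, tolerance = 1e-9)
  same <- c(a = 0.3, b = 0.7)
  expect_equal(unname(rna_dna_ratios(same, same)), c(1, 1))
  expect_warning(out <- rna_dna_ratios(c(a = 1), c(b = 1)), "no ASVs shared")
  expect_length(out, 0)
})

test_that("rank aggregation reports mean, SD and n per taxon", {
  tax <- data.frame(asv_id = c("a1", "a2", "a3"), domain = "B", phylum = "P",
                    class = "C", order = c("O1", "O1", "O2"), family = "F",
                    genus = "G", nifh_cluster = "none",
                    stringsAsFactors = FALSE)
  agg <- aggregate_by_rank(c(a1 = 2, a2 = 4, a3 = 5), tax)
  o1 <- agg[agg$taxon == "O1", ]
  expect_equal(o1$mean, 3)
  expect_equal(o1$sd, sqrt(2), tolerance = 1e-9)
  expect_equal(o1$n, 2L)
  o2 <- agg[agg$taxon == "O2", ]
  expect_equal(o2$sd, 0)
  expect_false(o2$sd_defined)
  tax$order[3] <- NA
  agg2 <- aggregate_by_rank(c(a3 = 5), tax)
  expect_equal(agg2$taxon, "unassigned")
})

test_that("rank aggregation equals the brute-force group-by oracle", {
  set.seed(33)
  for (i in 1:100) {
    case <- random_ratio_case(n_asvs = sample(5:30, 1))
    shuffled <- sample(case$ratios)
    got <- aggregate_by_rank(shuffled, case$taxonomy)
    want <- brute_force_aggregate(case$ratios, case$taxonomy)
    expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("nifH cluster shares and within-cluster composition are consistent", {
  tax <- data.frame(asv_id = paste0("a", 1:4), domain = "B", phylum = "P",
                    class = "C", order = "O", family = "F", genus = "G",
                    nifh_cluster = c("I", "III", "V", "none"),
                    stringsAsFactors = FALSE)
  counts <- matrix(c(80, 20, 100, 999), ncol = 1,
                   dimnames = list(paste0("a", 1:4), "s1"))
  res <- cluster_relative_abundance(counts, tax)
  # 'none' ASVs are outside the nifH table; share of I-III within nifH counts
  expect_equal(res$share$pct_of_nifh, 100 * 100 / 200)
  wi <- res$within
  expect_equal(wi$pct_within[wi$cluster == "I"], 80)
  expect_equal(wi$pct_within[wi$cluster == "III"], 20)
  expect_equal(sum(wi$pct_within), 100, tolerance = 1e-9)
  # sample permutation invariance
  counts2 <- cbind(counts, s2 = c(10, 5, 2, 7))
  r1 <- cluster_relative_abundance(counts2, tax)
  r2 <- cluster_relative_abundance(counts2[, c(2, 1)], tax)
  expect_equal(r1$share$pct_of_nifh, r2$share$pct_of_nifh)
})

test_that("minimum-abundance filter keeps strictly exceeding ASVs unchanged", {
  counts <- matrix(c(11, 10, 3), ncol = 1,
                   dimnames = list(c("a", "b", "c"), "s1"))
  f <- min_abundance_filter(counts, 10)
  expect_equal(rownames(f), "a")
  expect_identical(f["a", ], counts["a", ])
  expect_equal(nrow(min_abundance_filter(counts, 0)), 3)
  multi <- cbind(counts, s2 = c(0, 8, 15))
  expect_setequal(rownames(min_abundance_filter(multi, 10, scope = "per_sample")),
                  c("a", "c"))
  expect_setequal(rownames(min_abundance_filter(multi, 10, scope = "total")),
                  c("a", "b", "c"))
})

test_that("activity results are invariant to library size", {
  set.seed(5)
  amp <- simulate_paired_amplicon_tables(sim_config(seed = 5, n_asvs = 12,
                                                    dispersion = 0.4))
  counts <- cbind(amp$dna$counts, amp$rna$counts)
  meta <- rbind(amp$dna$metadata, amp$rna$metadata)
  tab1 <- list(counts = counts, metadata = meta)
  counts2 <- counts
  counts2[, 2] <- counts2[, 2] * 13   # rescale one library
  counts2[, 5] <- counts2[, 5] * 0.25
  tab2 <- list(counts = counts2, metadata = meta)
  a1 <- rna_dna_activity(tab1, amp$taxonomy)
  a2 <- rna_dna_activity(tab2, amp$taxonomy)
  expect_equal(a1$ratios, a2$ratios, tolerance = 1e-12)
  expect_equal(a1$by_rank, a2$by_rank, tolerance = 1e-12)
  s1 <- cluster_relative_abundance(counts, amp$taxonomy)
  s2 <- cluster_relative_abundance(counts2, amp$taxonomy)
  expect_equal(s1$share, s2$share, tolerance = 1e-12)
})
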