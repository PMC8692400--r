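test_that("incubation simulator emits one enriched and one control per colony x compartment", {
  cfg <- sim_config(n_colonies = 4, seed = 2)
  sim <- simulate_incubation_dataset(cfg)
  expect_equal(nrow(sim$samples), 4 * 4 * 2)
  tab <- table(sim$samples$colony, sim$samples$compartment, sim$samples$treatment)
  expect_true(all(tab == 1))
  expect_equal(nrow(sim$truth), 16)
  expect_silent(validate_sample_table(sim$samples))
})

test_that("simulator is deterministic given the seed", {
  cfg <- sim_config(seed = 99)
  expect_identical(simulate_incubation_dataset(cfg),
                   simulate_incubation_dataset(cfg))
  amp1 <- simulate_paired_amplicon_tables(cfg)
  amp2 <- simulate_paired_amplicon_tables(cfg)
  expect_identical(amp1, amp2)
  cfg2 <- sim_config(seed = 100)
  expect_false(identical(simulate_incubation_dataset(cfg)$samples$delta15N,
                         simulate_incubation_dataset(cfg2)$samples$delta15N))
})

test_that("zero noise inverts the rate equation exactly downstream", {
  cfg <- sim_config(seed = 4, noise_sd_atom_pct = 0)
  sim <- simulate_incubation_dataset(cfg)
  fit <- ddn_rates(sim$samples)
  m <- merge(fit$pairs, sim$truth[, c("sample_id", "true_rate_ugN_h")])
  expect_equal(m$rate_ugN_h, m$true_rate_ugN_h, tolerance = 1e-10)
  # zero rate, zero noise: excess identically zero
  cfg0 <- sim_config(seed = 4, noise_sd_atom_pct = 0,
                     true_rate_per_compartment = c(host = 0, symbiont = 0,
                                                   mucus = 0, skeleton = 0))
  fit0 <- ddn_rates(simulate_incubation_dataset(cfg0)$samples)
  expect_equal(fit0$pairs$atom_pct_excess, rep(0, 16), tolerance = 1e-13)
})

test_that("noisy rate estimates are unbiased", {
  truth <- 0.01
  cfg <- sim_config(n_colonies = 1000, compartments = "host",
                    true_rate_per_compartment = c(host = truth),
                    noise_sd_atom_pct = 5e-4, seed = 12)
  fit <- ddn_rates(simulate_incubation_dataset(cfg)$samples)
  r <- fit$pairs$rate_ugN_h
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - truth), 3 * se)
})

test_that("simulated amplicon tables respect library size and the activity model", {
  mult <- c(2, 1, 0.5, 1.5)
  cfg <- sim_config(seed = 6, n_asvs = 4, n_samples = 2, dispersion = 0,
                    activity_multipliers = mult, library_size = 1e4)
  amp <- simulate_paired_amplicon_tables(cfg)
  expect_equal(unname(colSums(amp$dna$counts)), rep(1e4, 2), tolerance = 1e-9)
  expect_equal(unname(colSums(amp$rna$counts)), rep(1e4, 2), tolerance = 1e-9)
  p_dna <- normalize_to_proportions(amp$dna$counts)
  p_rna <- normalize_to_proportions(amp$rna$counts)
  expect_equal(unname(colSums(p_dna)), rep(1, 2), tolerance = 1e-12)
  # zero dispersion: RNA proportions equal DNA x multiplier, renormalized
  expected <- p_dna[, 1] * mult / sum(p_dna[, 1] * mult)
  expect_equal(unname(p_rna[, 1]), unname(expected), tolerance = 1e-12)
  # all multipliers one: every RNA:DNA ratio is 1
  cfg1 <- sim_config(seed = 6, n_asvs = 4, n_samples = 1, dispersion = 0,
                     activity_multipliers = rep(1, 4))
  amp1 <- simulate_paired_amplicon_tables(cfg1)
  r <- rna_dna_ratios(normalize_to_proportions(amp1$rna$counts)[, 1],
                      normalize_to_proportions(amp1$dna$counts)[, 1])
  expect_equal(unname(r), rep(1, 4), tolerance = 1e-12)
  # noisy draws still integers summing to the library size
  cfgn <- sim_config(seed = 6, n_asvs = 10, dispersion = 0.5)
  ampn <- simulate_paired_amplicon_tables(cfgn)
  expect_true(all(ampn$dna$counts == round(ampn$dna$counts)))
  expect_equal(unname(colSums(ampn$rna$counts)), rep(1e4, 3))
  expect_error(simulate_paired_amplicon_tables(sim_config(seed = 1, n_asvs = 0)),
               class = "reefnfix_validation_error")
})

test_that("fixture bundles round-trip and are reproducible", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- sim_config(seed = 21, n_asvs = 8, n_colonies = 2)
  f1 <- write_fixture_bundle(dir1, cfg)
  expect_gte(length(f1), 5)
  expect_true(all(file.exists(f1)))
  samples <- read_sample_table(f1[["samples"]])
  sim <- simulate_incubation_dataset(cfg)
  expect_equal(samples, sim$samples, tolerance = 1e-12)
  tab <- read_count_matrix(f1[["dna"]], f1[["metadata"]])
  amp <- simulate_paired_amplicon_tables(cfg)
  expect_equal(tab$counts, amp$dna$counts, tolerance = 1e-12)
  tax <- read_taxonomy(f1[["taxonomy"]])
  expect_equal(tax, amp$taxonomy)
  truth <- utils::read.delim(f1[["truth"]], comment.char = "#")
  expect_equal(sort(unique(truth$true_value[truth$kind == "rate_ugN_h"])),
               sort(unique(cfg$true_rate_per_compartment)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # regeneration with the same seed is byte-identical
  f2 <- write_fixture_bundle(dir2, cfg)
  for (k in names(f1))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
})
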