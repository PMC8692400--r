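test_that("detection threshold is three sample SDs of the controls", {
  expect_equal(detection_threshold(c(0.3660, 0.3665, 0.3670)), 0.0015)
  expect_equal(detection_threshold(rep(0.3663, 5)), 0)
  ctl <- c(0.366, 0.367, 0.3655)
  expect_equal(detection_threshold(ctl + 0.01), detection_threshold(ctl))
  expect_error(detection_threshold(0.3663), class = "reefnfix_validation_error")
})

test_that("tracer rate equation evaluates, is linear, and is scale-invariant", {
  expect_equal(ddn_rate(0.3763, 0.3663, 10.0, 0.3663, 100, 24),
               0.0043251, tolerance = 1e-4)
  expect_equal(ddn_rate(0.3663, 0.3663, 10, 0.3663, 100, 24), 0)
  r1 <- ddn_rate(0.38, 0.3663, 10, 0.3663, 100, 24)
  expect_equal(ddn_rate(0.38, 0.3663, 10, 0.3663, 200, 24), 2 * r1)
  # doubling the excess doubles the rate; rescaling excess and label
  # difference together leaves it unchanged
  expect_equal(ddn_rate(0.3663 + 2 * (0.38 - 0.3663), 0.3663, 10, 0.3663, 100, 24),
               2 * r1)
  a0 <- 0.3663
  expect_equal(ddn_rate(a0 + 3 * (0.38 - a0), a0, a0 + 3 * (10 - a0), a0, 100, 24),
               r1)
  expect_error(ddn_rate(0.38, 0.3663, 0.3, 0.3663, 100, 24),
               class = "reefnfix_validation_error")
  expect_error(ddn_rate(0.38, 0.3663, 10, 0.3663, 100, 0),
               class = "reefnfix_validation_error")
})

test_that("standardized rates are consistent rescalings of the mass rate", {
  expect_equal(standardize_rate(0.1038, 30, "surface_area"), 3.46)
  expect_equal(standardize_rate(0, 12, "dry_weight"), 0)
  rate <- 0.0721; area <- 28.5; dw <- 0.41; vol <- 1
  pa <- standardize_rate(rate, area, "surface_area")
  pd <- standardize_rate(rate, dw, "dry_weight")
  pv <- standardize_rate(rate, vol, "volume")
  expect_equal(pa * area / 1000, rate, tolerance = 1e-9)
  expect_equal(pd * dw / 1000, rate, tolerance = 1e-9)
  expect_equal(pv * vol / 1000, rate, tolerance = 1e-9)
  expect_error(standardize_rate(1, 0, "volume"), class = "reefnfix_validation_error")
})

test_that("group averaging zeroes below-detection rates", {
  pairs <- data.frame(
    species = "Sp", site = "A", compartment = "host",
    detected = c(FALSE, TRUE, TRUE),
    rate_per_area_ngN_cm2_h = c(1.7, 2, 4))
  s <- summarize_group_rates(pairs)
  expect_equal(s$mean, 2)
  expect_equal(s$n, 3)
  expect_equal(s$n_detected, 2)
  pairs$detected <- FALSE
  s0 <- summarize_group_rates(pairs)
  expect_equal(s0$mean, 0)
  expect_equal(s0$n_detected, 0)
})

test_that("zeroed group mean never exceeds the raw mean for positive rates", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    r <- rlnorm(n, -1, 1)
    det <- runif(n) < 0.6
    pairs <- data.frame(species = "S", site = "A", compartment = "host",
                        detected = det, rate_per_area_ngN_cm2_h = r)
    expect_lte(summarize_group_rates(pairs)$mean, mean(r))
  }
})

test_that("ARA ethylene converts to N equivalents by 2/3 and scales to days", {
  expect_equal(ara_to_n_equivalents(3), 2)
  expect_equal(ara_to_n_equivalents(0), 0)
  expect_equal(ara_to_n_equivalents(1.5), 1)
  expect_equal(hourly_to_daily(8.3), 199.2)
  expect_error(ara_to_n_equivalents(-1), class = "reefnfix_validation_error")
})

test_that("estimator pairs by colony and falls back to group-mean controls", {
  sim <- simulate_incubation_dataset(sim_config(seed = 11, noise_sd_atom_pct = 0))
  fit <- ddn_rates(sim$samples)
  expect_setequal(fit$pairs$sample_id, sim$truth$sample_id)
  # same-colony pairing: control id shares the colony stem
  expect_true(all(mapply(grepl,
                         paste0("-", fit$pairs$colony, "-"),
                         fit$pairs$control_id, fixed = TRUE)))
  # drop one control: that pair falls back to the group mean, with a warning
  drop_id <- sim$samples$sample_id[sim$samples$treatment == "control"][1]
  samples2 <- sim$samples[sim$samples$sample_id != drop_id, ]
  expect_warning(fit2 <- ddn_rates(samples2), "no same-colony control")
  expect_equal(nrow(fit2$pairs), nrow(fit$pairs))
  expect_true(any(is.na(fit2$pairs$control_id)))
})
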