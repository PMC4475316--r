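test_that("cardiac sources are zero-mean, unit-RMS and decorrelated", {
  cfg <- synthetic_config(seed = 31)
  s <- make_sources(cfg)
  expect_equal(dim(s), c(3L, 5000L))
  expect_lt(max(abs(rowMeans(s))), 1e-10)
  expect_equal(apply(s, 1, function(r) sqrt(mean(r^2))), rep(1, 3))
  r <- cor(t(s))
  expect_lt(max(abs(r[upper.tri(r)])), 0.2)
  # one source: a periodic beat train with the configured beat count
  s1 <- make_sources(synthetic_config(n_sources = 1, seed = 31))
  expect_equal(dim(s1), c(1L, 5000L))
  # more sources than templates still decorrelated
  s5 <- make_sources(synthetic_config(n_sources = 5, seed = 31))
  r5 <- cor(t(s5))
  expect_lt(max(abs(r5[upper.tri(r5)])), 0.2)
  expect_error(synthetic_config(n_sources = 0), "1..8")
  expect_error(synthetic_config(duration = 0), "at least 2 samples")
})

test_that("the clean mixing model produces an exactly rank-N spectrum", {
  out <- mix_and_contaminate(synthetic_config(seed = 41))
  lam <- as.numeric(extract_features(out$record))
  expect_equal(sum(lam > 1e-6 * lam[1]), 3)
  expect_lt(lam[4], 1e-6 * lam[1])
  expect_identical(out$record$lead_names, c("I", "II", paste0("V", 1:6)))
  expect_length(out$report, 0)
  # longer records stay rank N: lambda4/lambda1 negligible at 10 s and 60 s
  lam60 <- as.numeric(extract_features(
    mix_and_contaminate(synthetic_config(seed = 41, duration = 60))$record))
  expect_lt(lam[4] / lam[1], 1e-9)
  expect_lt(lam60[4] / lam60[1], 1e-9)
})

test_that("flat leads collapse the spectrum; high-power artifacts inflate it", {
  # disconnected V4 on top of the noise floor: rank deficiency
  cfg <- synthetic_config(seed = 42,
                          noise = list(noise_event("white", 1:8, power = 9),
                                       noise_event("flat_lead", leads = 6)))
  lam <- as.numeric(extract_features(mix_and_contaminate(cfg)$record))
  expect_lt(lam[8], 1e-9 * lam[1])
  # burst artifact at >= 100x the cardiac power inflates the leading eigenvalues
  clean <- as.numeric(extract_features(
    mix_and_contaminate(ac_config(seed = 42))$record))
  burst_var <- 100 * sum(clean) / 0.2          # 2 s of 10 s active
  cfg2 <- ac_config(seed = 42)
  cfg2$noise <- c(cfg2$noise, list(noise_event("transient_artifact", leads = c(2, 5),
                                               power = burst_var, onset = 3,
                                               duration = 2)))
  lam2 <- as.numeric(extract_features(mix_and_contaminate(cfg2)$record))
  expect_gt(log10(lam2[1]), 5.09)
  expect_gt(log10(lam2[2]), 3.75)
})

test_that("white noise raises every eigenvalue by about its variance", {
  sigma2 <- 1e4
  for (s in 1:5) {
    clean <- as.numeric(extract_features(
      mix_and_contaminate(synthetic_config(seed = s))$record))
    noisy <- as.numeric(extract_features(mix_and_contaminate(
      synthetic_config(seed = s,
                       noise = list(noise_event("white", 1:8, power = sigma2))))$record))
    expect_lt(max(abs((noisy - clean) - sigma2)) / sigma2, 0.1)
  }
})

test_that("injected noise power adds to the spectrum's total power", {
  cfg0 <- synthetic_config(seed = 3)
  tr0 <- sum(as.numeric(extract_features(mix_and_contaminate(cfg0)$record)))
  p <- 400
  cfgn <- synthetic_config(seed = 3,
                           noise = list(noise_event("white", 1:8, power = p)))
  trn <- sum(as.numeric(extract_features(mix_and_contaminate(cfgn)$record)))
  expect_equal(trn, tr0 + 8 * p, tolerance = 0.05)
  # coherent powerline: one extra eigenvalue of n_leads * a^2 / 2
  a <- 500
  cfgp <- synthetic_config(seed = 3,
                           noise = list(noise_event("powerline", 1:4, amplitude = a)))
  trp <- sum(as.numeric(extract_features(mix_and_contaminate(cfgp)$record)))
  expect_equal(trp, tr0 + 4 * a^2 / 2, tolerance = 0.05)
})

test_that("clipping saturates at the configured ceiling", {
  cfg <- synthetic_config(seed = 13, amplitude_scale = 5000,
                          noise = list(noise_event("clipping", 1:8, amplitude = 800)))
  rec <- mix_and_contaminate(cfg)$record
  expect_lte(max(abs(rec$samples)), 800)
})

test_that("generation is a pure function of the seed", {
  c1 <- mix_and_contaminate(ac_config(seed = 77))
  c2 <- mix_and_contaminate(ac_config(seed = 77))
  expect_identical(c1$record$samples, c2$record$samples)
  coh1 <- generate_cohort(6, 0.5, template = synthetic_config(duration = 2), seed = 5)
  coh2 <- generate_cohort(6, 0.5, template = synthetic_config(duration = 2), seed = 5)
  expect_identical(serialize(coh1, NULL), serialize(coh2, NULL))
  coh3 <- generate_cohort(6, 0.5, template = synthetic_config(duration = 2), seed = 6)
  expect_false(identical(coh1$records[[1]]$samples, coh3$records[[1]]$samples))
})

test_that("cohorts honor size, label balance and contamination reporting", {
  coh <- generate_cohort(20, 0.5, template = synthetic_config(duration = 2), seed = 9)
  expect_length(coh$records, 20)
  expect_equal(sum(coh$labels == "AC"), 10)
  # AC draws carry only the equipment noise floor; UN draws >= 1 extra event
  n_events <- vapply(coh$reports, length, 0L)
  expect_true(all(n_events[coh$labels == "AC"] == 1))
  expect_true(all(n_events[coh$labels == "UN"] >= 2))
  all_ac <- generate_cohort(5, 1, template = synthetic_config(duration = 2), seed = 9)
  expect_true(all(all_ac$labels == "AC"))
  expect_error(generate_cohort(0), ">= 1")
  expect_error(generate_cohort(5, 1.2), "ac_fraction")
})
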