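test_that("an empty design yields an empty observation table", {
  sim <- simulate_apms_experiment(sim_config(n_true = 0, n_background = 0,
                                             n_contaminants = 0, seed = 1))
  expect_equal(nrow(sim$observations), 0)
  expect_equal(nrow(sim$truth), 0)
})

test_that("identical seeds reproduce identical tables", {
  cfg <- sim_config(n_true = 8, n_background = 12, n_contaminants = 3,
                    seed = 321)
  a <- simulate_apms_experiment(cfg)
  b <- simulate_apms_experiment(cfg)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
  c <- simulate_apms_experiment(sim_config(n_true = 8, n_background = 12,
                                           n_contaminants = 3, seed = 322))
  expect_false(identical(a$observations, c$observations))
})

test_that("planted bait counts match their Poisson means", {
  cfg <- sim_config(n_true = 50, n_background = 0, n_contaminants = 0,
                    lambda_bg = 2, enrichment_factor = 10,
                    true_detection_prob = 1, single_peptide_fraction = 0,
                    seed = 99)
  sim <- simulate_apms_experiment(cfg)
  bait <- sim$observations[sim$observations$channel == "BAIT", ]
  # mean of Poisson(20) across 50 preys x 18 bait purifications
  n <- nrow(bait)
  se <- sqrt(20 / n)
  expect_lt(abs(mean(bait$spectral_count) - 20), 3 * se + 20 * 0.01)
})

test_that("forced single-peptide truths carry exactly one unique peptide", {
  cfg <- sim_config(n_true = 10, n_background = 0, n_contaminants = 0,
                    single_peptide_fraction = 0.3, seed = 17)
  sim <- simulate_apms_experiment(cfg)
  singles <- sim$truth$prey_id[sim$truth$single_peptide]
  expect_length(singles, 3)
  obs <- sim$observations
  expect_true(all(obs$unique_peptides[obs$prey_id %in% singles &
                                        obs$spectral_count > 0] == 1))
  expect_true(all(obs$spectral_count >= obs$unique_peptides))
})

test_that("observation tables from the generator satisfy the reader contract", {
  sim <- simulate_apms_experiment(sim_config(n_true = 5, n_background = 10,
                                             n_contaminants = 2, seed = 3))
  expect_silent(baitprey:::validate_observations(sim$observations))
})

test_that("impossible configurations are rejected", {
  expect_error(sim_config(true_detection_prob = 0, n_true = 5),
               class = "baitprey_validation_error")
  expect_error(sim_config(lambda_bg = 0), class = "baitprey_validation_error")
  expect_error(sim_config(n_true = -1), class = "baitprey_validation_error")
})

test_that("noiseless IV curves invert exactly and noisy ones on average", {
  pts <- simulate_iv_curve(-55, 3.5, seq(-90, -30, 10), noise_sd = 0)
  expect_equal(pts$peak_amplitude, 3.5 * (pts$holding_potential + 55))
  fit <- fit_iv_reversal(pts)
  expect_equal(fit$e_rev, -55, tolerance = 1e-12)
  expect_equal(fit$conductance, 3.5, tolerance = 1e-12)

  # Monte-Carlo recovery: mean fitted reversal within 0.5 mV of truth
  fits <- vapply(1:200, function(i) {
    fit_iv_reversal(simulate_iv_curve(-40, 2, seq(-80, -40, 10),
                                      noise_sd = 1, seed = i))$e_rev
  }, numeric(1))
  expect_lt(abs(mean(fits) - (-40)), 0.5)
})

test_that("default-condition recovery: sensitive to truths, tight on background", {
  seeds <- 1:5
  stats <- vapply(seeds, function(s) {
    sim <- simulate_apms_experiment(sim_config(seed = s))
    res <- build_interactome(sim$observations,
                             contaminants = simulated_contaminant_list(sim))
    truth <- sim$truth
    truths <- truth$prey_id[truth$class == "TRUE_INTERACTOR"]
    detected <- truths[truths %in% res$members$prey_id]
    multi <- res$members[res$members$prey_id %in% detected &
                           res$members$replicate_presence >= 2, ]
    c(sens = mean(truths %in% res$members$prey_id),
      platinum = mean(multi$tier == "PLATINUM"),
      contam = sum(truth$prey_id[truth$class == "CONTAMINANT"] %in%
                     res$members$prey_id))
  }, numeric(3))
  expect_gte(mean(stats["sens", ]), 0.9)
  expect_gte(mean(stats["platinum", ]), 0.8)
  # planted frequent contaminants are always removed at threshold 0.5
  expect_equal(sum(stats["contam", ]), 0)
})
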