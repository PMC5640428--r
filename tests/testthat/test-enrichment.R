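test_that("fold enrichment matches direct arithmetic and handles zeros", {
  expect_equal(fold_enrichment(5, 5, 0), 1.0)
  expect_equal(fold_enrichment(16, 4, 1), 3.4)
  expect_equal(fold_enrichment(0, 0, 1), 1.0)
  expect_error(fold_enrichment(0, 0, 0), class = "baitprey_validation_error")
  expect_error(fold_enrichment(-1, 2), class = "baitprey_validation_error")
})

test_that("fold enrichment is monotone in each argument", {
  set.seed(101)
  for (i in 1:50) {
    b <- sample(0:100, 1)
    ct <- sample(0:100, 1)
    expect_gt(fold_enrichment(b + 1, ct), fold_enrichment(b, ct))
    expect_lt(fold_enrichment(b, ct + 1), fold_enrichment(b, ct))
  }
})

test_that("NSAF matches closed forms, sums to one and is scale-invariant", {
  expect_equal(nsaf(c(p = 7), c(p = 432)), c(p = 1))
  two <- nsaf(c(a = 10, b = 10), c(a = 100, b = 200))
  expect_equal(unname(two), c(2 / 3, 1 / 3))

  set.seed(7)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    cts <- setNames(rpois(n, 20) + 1, paste0("p", 1:n))
    lens <- setNames(sample(100:2000, n), names(cts))
    v <- nsaf(cts, lens)
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_equal(nsaf(cts * 5, lens), v, tolerance = 1e-12)
  }

  expect_error(nsaf(c(a = 1), c(b = 100)), "a",
               class = "baitprey_validation_error")
  expect_error(nsaf(c(a = 0, b = 0), c(a = 100, b = 100)),
               class = "baitprey_validation_error")
})

test_that("replicate presence counts bait-channel replicates only", {
  obs <- rbind(
    toy_observation("P1", 5, 2, replicate = 1),
    toy_observation("P1", 3, 2, replicate = 3),
    toy_observation("P1", 9, 3, replicate = 3, antibody = "PS940"),
    toy_observation("P2", 8, 2, channel = "CONTROL", replicate = 1)
  )
  expect_equal(replicate_presence(obs, "P1"), 2)
  expect_equal(replicate_presence(obs, "P2"), 0)
  expect_equal(replicate_presence(obs, "ABSENT"), 0)

  # brute-force scan over a synthetic 3-replicate design
  sim <- simulate_apms_experiment(sim_config(n_true = 6, n_background = 6,
                                             n_contaminants = 2, seed = 5))
  o <- sim$observations
  for (prey in sim$truth$prey_id) {
    seen <- unique(o$replicate[o$prey_id == prey & o$channel == "BAIT" &
                                 o$spectral_count > 0])
    expect_equal(replicate_presence(o, prey), length(seen))
  }
})

test_that("the posterior score equals its direct-mixture oracle", {
  for (x in c(0, 1, 2, 5, 10, 20, 50)) {
    expect_equal(score_maxp(x, lambda_bg = 2, enrichment_factor = 10),
                 oracle_posterior(x, 2, 10), tolerance = 1e-12)
  }
  # at the background mean the score is low; at the enriched mean, high
  expect_lt(score_maxp(2, lambda_bg = 2, enrichment_factor = 10), 0.5)
  expect_gt(score_maxp(20, lambda_bg = 2, enrichment_factor = 10), 0.99)
  # MaxP of several replicates is the max of the single-replicate scores
  for (pair in list(c(1, 7), c(0, 22), c(3, 3))) {
    expect_equal(score_maxp(pair, 2, 10),
                 max(score_maxp(pair[[1]], 2, 10),
                     score_maxp(pair[[2]], 2, 10)))
  }
  expect_error(score_maxp(5, lambda_bg = 0),
               class = "baitprey_validation_error")
})

test_that("the score is monotone in counts and never drops with replicates", {
  for (x in 0:30) {
    expect_lte(score_maxp(x, 2, 10), score_maxp(x + 1, 2, 10))
  }
  set.seed(33)
  for (i in 1:20) {
    cts <- rpois(sample(1:4, 1), 6)
    expect_gte(score_maxp(c(cts, rpois(1, 6)), 2, 10), score_maxp(cts, 2, 10))
  }
})

test_that("planted interactors outscore background preys on average", {
  sim <- simulate_apms_experiment(sim_config(n_true = 30, n_background = 100,
                                             n_contaminants = 0,
                                             enrichment_factor = 5,
                                             seed = 19))
  prof <- enrichment_profiles(sim$observations, enrichment_factor = 5)
  truth <- sim$truth
  mean_true <- mean(prof$maxp[prof$prey_id %in%
                                truth$prey_id[truth$class == "TRUE_INTERACTOR"]])
  mean_bg <- mean(prof$maxp[prof$prey_id %in%
                              truth$prey_id[truth$class == "BACKGROUND"]])
  expect_gt(mean_true, mean_bg)
})

test_that("enrichment profiles aggregate a small table as hand-computed", {
  obs <- rbind(
    toy_observation("P1", 16, 4, replicate = 1),
    toy_observation("P1", 10, 3, replicate = 2),
    toy_observation("P1", 4, 2, channel = "CONTROL", replicate = 1),
    toy_observation("P2", 3, 1, age = "P5", replicate = 1),
    toy_observation("P2", 2, 1, age = "P50", replicate = 1)
  )
  prof <- enrichment_profiles(obs)
  p1 <- prof[prof$prey_id == "P1", ]
  expect_equal(p1$psm_bait, 26)
  expect_equal(p1$psm_control, 4)
  expect_equal(p1$fold_ratio, 27 / 5)
  expect_equal(p1$unique_peptides_max, 4)
  expect_equal(p1$replicate_presence, 2)
  p2 <- prof[prof$prey_id == "P2", ]
  expect_equal(p2$n_conditions, 2)
  expect_equal(p2$fold_ratio, 6 / 1)
  expect_equal(p2$unique_peptides_max, 1)
})
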