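test_that("first pass keeps exactly the preys passing both thresholds", {
  profs <- rbind(
    toy_profile("A", fold_ratio = 3.4, unique_peptides_max = 2),
    toy_profile("B", fold_ratio = 100, unique_peptides_max = 1),
    toy_profile("C", fold_ratio = 1.4, unique_peptides_max = 5)
  )
  ids <- first_pass_filter(profs)
  expect_setequal(ids, "A")

  # oracle: independent predicate scan over a random 20-profile table
  set.seed(55)
  many <- do.call(rbind, lapply(1:20, function(i) {
    toy_profile(sprintf("X%02d", i),
                fold_ratio = runif(1, 0.5, 8),
                unique_peptides_max = sample(0:5, 1))
  }))
  cfg <- filter_config()
  expected <- many$prey_id[
    many$unique_peptides_max >= 2 & many$fold_ratio >= 1.5]
  expect_setequal(first_pass_filter(many, cfg), expected)

  # raising the fold threshold never grows the survivor set
  prev <- first_pass_filter(many, filter_config(first_pass_fold = 0.5))
  for (fold in c(1, 1.5, 2, 3, 5, 10)) {
    cur <- first_pass_filter(many, filter_config(first_pass_fold = fold))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("rescue applies criteria in order a > b > c with single-peptide gating", {
  lit <- protein_list(c("LITGENE"), name = "lit")
  first <- toy_profile("FP1", gene_symbol = "ATP1A1", fold_ratio = 6,
                       unique_peptides_max = 3)
  fam_map <- c(ATP1A1 = "ATP1A", ATP1A2 = "ATP1A")

  # (a) literature beats everything, even when (b)/(c) would also match
  cand_a <- toy_profile("L1", gene_symbol = "LITGENE",
                        unique_peptides_max = 1, n_conditions = 3)
  r <- second_pass_rescue(cand_a, "FP1", lit, fam_map, first)
  expect_true(r$rescued)
  expect_equal(r$rescue_reason, "LITERATURE_VALIDATED")

  # (b) family already in first pass, via explicit map
  cand_b <- toy_profile("F1", gene_symbol = "ATP1A2",
                        unique_peptides_max = 1, n_conditions = 1)
  r <- second_pass_rescue(cand_b, "FP1", protein_list(character(0)),
                          fam_map, first)
  expect_equal(r$rescue_reason, "FAMILY_IN_FIRST_PASS")

  # (b) via the opt-in trailing-digit heuristic
  cand_b2 <- toy_profile("F2", gene_symbol = "ATP1A3",
                         unique_peptides_max = 1, n_conditions = 1)
  expect_message(
    r <- second_pass_rescue(cand_b2, "FP1", protein_list(character(0)),
                            "symbol_prefix", first),
    "heuristic")
  expect_equal(r$rescue_reason, "FAMILY_IN_FIRST_PASS")

  # without a family map, family rescue is off
  r <- second_pass_rescue(cand_b2, "FP1", protein_list(character(0)),
                          NULL, first)
  expect_false(r$rescued)

  # (c) single-peptide prey recurring across conditions or replicates
  cand_c <- toy_profile("S1", unique_peptides_max = 1, n_conditions = 2)
  r <- second_pass_rescue(cand_c, "FP1", protein_list(character(0)),
                          NULL, first)
  expect_equal(r$rescue_reason, "MULTI_EXPERIMENT")
  cand_c2 <- toy_profile("S2", unique_peptides_max = 1, n_conditions = 1,
                         replicate_presence = 2)
  r <- second_pass_rescue(cand_c2, "FP1", protein_list(character(0)),
                          NULL, first)
  expect_equal(r$rescue_reason, "MULTI_EXPERIMENT")

  # (c) does not fire for multi-peptide preys that merely recur
  cand_no <- toy_profile("M1", unique_peptides_max = 3, fold_ratio = 1.2,
                         n_conditions = 3, replicate_presence = 3)
  r <- second_pass_rescue(cand_no, "FP1", protein_list(character(0)),
                          NULL, first)
  expect_false(r$rescued)
  expect_equal(r$rescue_reason, "NONE")

  # a one-shot single-peptide prey with no other support stays out
  cand_none <- toy_profile("S3", unique_peptides_max = 1, n_conditions = 1,
                           replicate_presence = 1)
  r <- second_pass_rescue(cand_none, "FP1", protein_list(character(0)),
                          NULL, first)
  expect_false(r$rescued)
})

test_that("contaminant removal follows the frequency threshold", {
  ids <- c("A", "B", "C")
  cont <- protein_list(c("B", "C"), frequency = c(B = 0.6, C = 0.3))
  expect_equal(remove_contaminants(ids, cont, 0.5), c("A", "C"))
  expect_equal(remove_contaminants(ids, protein_list(character(0))), ids)
  expect_equal(remove_contaminants(ids, cont, 0), "A")
  # members without a stated frequency are treated as frequency 1
  cont2 <- protein_list("B")
  expect_equal(remove_contaminants(ids, cont2, 0.9), c("A", "C"))
})

test_that("tier assignment matches the published rules and is exhaustive", {
  expect_equal(assign_tier(136, 1, 3), "PLATINUM")
  expect_equal(assign_tier(6, 0.92, 1), "GOLD")
  expect_equal(assign_tier(4, 0.8, 1), "SILVER")
  expect_equal(assign_tier(3, 0.69, 2), "BRONZE")  # below Silver MaxP bound
  expect_equal(assign_tier(1.5, 0.04, 3), "BRONZE")
  # fold >= 5 with low MaxP matches no named rule and falls to Bronze
  expect_equal(assign_tier(8, 0.5, 3), "BRONZE")

  set.seed(77)
  tiers <- assign_tier(runif(500, 0.5, 10), runif(500), sample(0:3, 500, TRUE))
  expect_true(all(tiers %in% c("PLATINUM", "GOLD", "SILVER", "BRONZE")))
  expect_length(tiers, 500)
})

test_that("literature merge deduplicates by identity and adds the rest", {
  screen <- do.call(rbind, lapply(1:150, function(i) {
    toy_profile(sprintf("SCR%03d", i))
  }))
  screen$provenance <- "SCREEN"
  screen$tier <- "BRONZE"
  lit31 <- protein_list(sprintf("LIT%02d", 1:31))
  merged <- merge_literature_partners(screen, lit31)
  expect_equal(nrow(merged), 181)
  expect_equal(sum(merged$provenance == "LITERATURE"), 31)
  expect_true(all(merged$tier[merged$provenance == "LITERATURE"] ==
                    "NA_LITERATURE"))

  # an overlapping literature member is not duplicated and stays SCREEN
  lit_overlap <- protein_list(c("SCR001", sprintf("LIT%02d", 1:5)))
  merged2 <- merge_literature_partners(screen, lit_overlap)
  expect_equal(nrow(merged2), 155)
  expect_equal(merged2$provenance[merged2$prey_id == "SCR001"], "SCREEN")

  expect_equal(nrow(merge_literature_partners(screen,
                                              protein_list(character(0)))),
               150)
})

test_that("the full filter is invariant to input row order", {
  sim <- simulate_apms_experiment(sim_config(n_true = 10, n_background = 30,
                                             n_contaminants = 5, seed = 9))
  cont <- simulated_contaminant_list(sim)
  res1 <- build_interactome(sim$observations, contaminants = cont)
  set.seed(1)
  shuffled <- sim$observations[sample(nrow(sim$observations)), ]
  res2 <- build_interactome(shuffled, contaminants = cont)
  expect_equal(res1$members, res2$members)
})

test_that("tiers partition the screen members", {
  sim <- simulate_apms_experiment(sim_config(n_true = 10, n_background = 30,
                                             n_contaminants = 5, seed = 13))
  res <- build_interactome(sim$observations,
                           contaminants = simulated_contaminant_list(sim))
  screen <- res$members[res$members$provenance == "SCREEN", ]
  expect_true(all(screen$tier %in% c("PLATINUM", "GOLD", "SILVER", "BRONZE")))
  counts <- table(factor(screen$tier,
                         c("PLATINUM", "GOLD", "SILVER", "BRONZE")))
  expect_equal(sum(counts), nrow(screen))
})
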