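#' Fold enrichment of bait over control spectral counts
#'
#' The normalised bait/control spectral ratio
#' `(bait + pseudocount) / (control + pseudocount)`.  The pseudocount keeps
#' the ratio defined when the control purification recovered no spectra, the
#' common case for genuine interactors pulled down against an IgG/IgY mock.
#'
#' @param bait_total Total bait-channel PSM count (vectorised).
#' @param control_total Total control-channel PSM count.
#' @param pseudocount Non-negative stabiliser added to both counts; default 1.
#' @return Positive numeric fold ratio(s).
#' @export
#' @examples
#' fold_enrichment(16, 4)      # (16 + 1) / (4 + 1) = 3.4
#' fold_enrichment(5, 5, 0)    # 1
fold_enrichment <- function(bait_total, control_total, pseudocount = 1) {
  assert_scalar_number(pseudocount, "pseudocount", lower = 0)
  if (any(bait_total < 0) || any(control_total < 0)) {
    abort("counts must be non-negative", class = "baitprey_validation_error")
  }
  if (pseudocount == 0 && any(bait_total + control_total == 0)) {
    abort("fold ratio undefined: both totals zero with pseudocount 0",
          class = "baitprey_validation_error")
  }
  (bait_total + pseudocount) / (control_total + pseudocount)
}

#' Normalized Spectral Abundance Factor (NSAF)
#'
#' Length-normalised spectral counts rescaled to sum to one within a sample:
#' `NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j)`.
#'
#' @param spectral_counts Named non-negative counts (names are prey ids).
#' @param lengths Named protein lengths in residues covering every counted
#'   prey.
#' @return Named numeric vector of NSAF values summing to one.
#' @export
nsaf <- function(spectral_counts, lengths) {
  ids <- names(spectral_counts)
  if (is.null(ids)) {
    abort("spectral_counts must be named by prey",
          class = "baitprey_validation_error")
  }
  missing <- ids[!ids %in% names(lengths) | is.na(lengths[ids])]
  if (length(missing) > 0) {
    abort(sprintf("missing protein length for: %s",
                  paste(missing, collapse = ", ")),
          class = "baitprey_validation_error")
  }
  len <- lengths[ids]
  if (any(len <= 0)) {
    abort("protein lengths must be positive",
          class = "baitprey_validation_error")
  }
  saf <- spectral_counts / len
  total <- sum(saf)
  if (total == 0) {
    abort("all spectral counts are zero: no abundance mass to normalise",
          class = "baitprey_validation_error")
  }
  saf / total
}

#' Count replicates with bait-channel evidence for one prey
#'
#' The number of distinct replicates in which a prey was seen with at least
#' one bait-channel PSM; control-channel observations do not count.  Absent
#' preys return 0.
#'
#' @param observations Tibble of prey observations (see [read_count_table()]).
#' @param prey A `prey_id` value.
#' @return Integer replicate count.
#' @export
replicate_presence <- function(observations, prey) {
  hit <- observations$prey_id == prey &
    observations$channel == "BAIT" & observations$spectral_count > 0
  length(unique(observations$replicate[hit]))
}

#' Simplified SAINT-style posterior score (MaxP)
#'
#' Scores one prey from its per-replicate bait-channel counts under a
#' two-component Poisson mixture: counts from a true interaction follow
#' `Poisson(enrichment_factor * lambda_bg)` and background binding follows
#' `Poisson(lambda_bg)`.  The per-replicate posterior probability of a true
#' interaction is
#' `p_r = pi * f_true(x_r) / (pi * f_true(x_r) + (1 - pi) * f_bg(x_r))`,
#' and the reported score is the maximum of `p_r` across replicates -- the
#' "largest probability of a bait-prey pair across all replicate
#' purifications".  This is a deliberately simple stand-in for the full
#' SAINT empirical-Bayes count model; published MaxP values, when available,
#' take precedence over this scorer.
#'
#' @param counts Non-negative per-replicate bait PSM counts (at least one).
#' @param lambda_bg Background Poisson mean (> 0); typically the mean
#'   control-channel count, floored to avoid degenerate posteriors.
#' @param enrichment_factor Multiplier (> 1) giving the true-interaction mean.
#' @param prior_true Mixture weight `pi` of the true-interaction component.
#' @return Posterior score in `[0, 1]`.
#' @export
#' @examples
#' score_maxp(20, lambda_bg = 2, enrichment_factor = 10)  # ~1
#' score_maxp(2, lambda_bg = 2, enrichment_factor = 10)   # ~0
score_maxp <- function(counts, lambda_bg, enrichment_factor = 10,
                       prior_true = 0.5) {
  if (length(counts) < 1 || any(counts < 0)) {
    abort("counts must be a non-empty vector of non-negative integers",
          class = "baitprey_validation_error")
  }
  if (!is.numeric(lambda_bg) || lambda_bg <= 0) {
    abort("lambda_bg must be positive; estimate it with a floor",
          class = "baitprey_validation_error")
  }
  assert_scalar_number(enrichment_factor, "enrichment_factor", lower = 1)
  assert_scalar_number(prior_true, "prior_true", lower = 0, upper = 1)
  lambda_true <- enrichment_factor * lambda_bg
  # log-space odds for numerical stability at large counts
  log_odds <- log(prior_true) - log1p(-prior_true) +
    dpois(counts, lambda_true, log = TRUE) -
    dpois(counts, lambda_bg, log = TRUE)
  max(stats::plogis(log_odds))
}

#' Per-prey enrichment profiles from an observation table
#'
#' Aggregates a long observation table into one row per prey: bait and
#' control PSM totals, the pseudocounted fold ratio, the maximum unique
#' peptide count across purifications, replicate presence, the number of
#' distinct (antibody, age) conditions with bait evidence, and the
#' Poisson-mixture MaxP score: the maximum per-purification posterior, with
#' `lambda_bg` estimated per prey as its mean control-channel count per
#' control run (floored at `lambda_bg_floor`).
#'
#' @param observations Tibble of prey observations (see [read_count_table()]).
#' @param pseudocount Stabiliser for the fold ratio; default 1.
#' @param enrichment_factor,prior_true Score-model parameters, see
#'   [score_maxp()].
#' @param lambda_bg_floor Minimum background mean used in scoring.
#' @return A tibble with one row per prey: `prey_id`, `gene_symbol`,
#'   `psm_bait`, `psm_control`, `fold_ratio`, `unique_peptides_max`,
#'   `replicate_presence`, `n_conditions`, `maxp`.
#' @export
enrichment_profiles <- function(observations, pseudocount = 1,
                                enrichment_factor = 10, prior_true = 0.5,
                                lambda_bg_floor = 0.1) {
  assert_columns(observations,
                 c("prey_id", "gene_symbol", "antibody", "age", "replicate",
                   "channel", "spectral_count", "unique_peptides"),
                 what = "observation table")
  assert_scalar_number(lambda_bg_floor, "lambda_bg_floor", lower = 0)
  if (nrow(observations) == 0) {
    return(tibble(prey_id = character(0), gene_symbol = character(0),
                  psm_bait = integer(0), psm_control = integer(0),
                  fold_ratio = numeric(0), unique_peptides_max = integer(0),
                  replicate_presence = integer(0), n_conditions = integer(0),
                  maxp = numeric(0)))
  }
  n_control_runs <- max(1L, nrow(dplyr::distinct(
    dplyr::filter(observations, .data$channel == "CONTROL"),
    .data$antibody, .data$age, .data$replicate)))

  per_prey <- observations |>
    dplyr::group_by(.data$prey_id) |>
    dplyr::summarise(
      gene_symbol = .data$gene_symbol[[1]],
      psm_bait = sum(.data$spectral_count[.data$channel == "BAIT"]),
      psm_control = sum(.data$spectral_count[.data$channel == "CONTROL"]),
      unique_peptides_max = max(c(0L,
        .data$unique_peptides[.data$channel == "BAIT"])),
      replicate_presence = dplyr::n_distinct(
        .data$replicate[.data$channel == "BAIT" & .data$spectral_count > 0]),
      n_conditions = nrow(unique(data.frame(
        a = .data$antibody, g = .data$age)[
          .data$channel == "BAIT" & .data$spectral_count > 0, ])),
      rep_bait = list(.data$spectral_count[.data$channel == "BAIT"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fold_ratio = fold_enrichment(.data$psm_bait, .data$psm_control,
                                   pseudocount),
      lambda_bg = pmax(.data$psm_control / n_control_runs, lambda_bg_floor),
      maxp = purrr::map2_dbl(.data$rep_bait, .data$lambda_bg, function(cts, lb) {
        cts <- as.numeric(cts)
        if (length(cts) == 0) cts <- 0
        score_maxp(cts, lb, enrichment_factor, prior_true)
      })
    ) |>
    dplyr::select("prey_id", "gene_symbol", "psm_bait", "psm_control",
                  "fold_ratio", "unique_peptides_max", "replicate_presence",
                  "n_conditions", "maxp") |>
    dplyr::arrange(dplyr::desc(.data$fold_ratio), .data$prey_id)
  per_prey
}
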