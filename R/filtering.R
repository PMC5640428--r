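#' Filtering and tiering configuration
#'
#' Thresholds for the two-pass candidate filter, contaminant removal and
#' confidence tiering.  Defaults follow the published procedure: at least two
#' unique peptides and a fold change of total spectra above 1.5 in the first
#' pass (the lower of the two printed fold thresholds, so that the Bronze
#' tier, spanning 1.5-3 fold, remains reachable); contaminants removed at a
#' control-observation frequency of 50% or more; Platinum requiring presence
#' in at least 2 of 3 replicates with >= 5-fold enrichment and MaxP >= 0.89;
#' Silver spanning 3-5 fold with MaxP in `[0.7, 0.89)`.
#'
#' @param min_unique_peptides First-pass minimum unique peptides; default 2.
#' @param first_pass_fold First-pass minimum fold ratio; default 1.5.
#' @param contaminant_frequency_threshold Removal threshold on contaminant
#'   observation frequency; default 0.5.
#' @param platinum_min_replicates Replicate presence required for Platinum.
#' @param high_fold Fold threshold shared by Platinum and Gold; default 5.
#' @param high_maxp MaxP threshold shared by Platinum and Gold; default 0.89.
#' @param silver_fold_low Lower fold bound of the Silver tier; default 3.
#' @param silver_maxp_low Lower MaxP bound of the Silver tier; default 0.7.
#' @param bronze_fold_low Nominal lower fold bound of the Bronze tier
#'   (documentation of the printed range; Bronze is the catch-all tier).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_unique_peptides = 2,
                          first_pass_fold = 1.5,
                          contaminant_frequency_threshold = 0.5,
                          platinum_min_replicates = 2,
                          high_fold = 5,
                          high_maxp = 0.89,
                          silver_fold_low = 3,
                          silver_maxp_low = 0.7,
                          bronze_fold_low = 1.5) {
  assert_scalar_number(min_unique_peptides, "min_unique_peptides", lower = 0)
  assert_scalar_number(first_pass_fold, "first_pass_fold", lower = 0)
  assert_scalar_number(contaminant_frequency_threshold,
                       "contaminant_frequency_threshold", 0, 1)
  assert_scalar_number(platinum_min_replicates, "platinum_min_replicates", 0)
  assert_scalar_number(high_fold, "high_fold", lower = 0)
  assert_scalar_number(high_maxp, "high_maxp", 0, 1)
  assert_scalar_number(silver_fold_low, "silver_fold_low", lower = 0)
  assert_scalar_number(silver_maxp_low, "silver_maxp_low", 0, 1)
  assert_scalar_number(bronze_fold_low, "bronze_fold_low", lower = 0)
  if (!(bronze_fold_low <= silver_fold_low && silver_fold_low <= high_fold)) {
    abort("tier fold bounds must satisfy bronze <= silver <= high",
          class = "baitprey_validation_error")
  }
  if (silver_maxp_low > high_maxp) {
    abort("silver_maxp_low must not exceed high_maxp",
          class = "baitprey_validation_error")
  }
  structure(list(
    min_unique_peptides = min_unique_peptides,
    first_pass_fold = first_pass_fold,
    contaminant_frequency_threshold = contaminant_frequency_threshold,
    platinum_min_replicates = platinum_min_replicates,
    high_fold = high_fold,
    high_maxp = high_maxp,
    silver_fold_low = silver_fold_low,
    silver_maxp_low = silver_maxp_low,
    bronze_fold_low = bronze_fold_low
  ), class = "filter_config")
}

#' First-pass candidate filter
#'
#' Keeps preys with at least `min_unique_peptides` unique peptides and a fold
#' ratio of at least `first_pass_fold`.
#'
#' @param profiles Tibble of enrichment profiles
#'   (see [enrichment_profiles()]).
#' @param config A [filter_config()].
#' @return Character vector of surviving `prey_id`s.
#' @export
first_pass_filter <- function(profiles, config = filter_config()) {
  assert_columns(profiles, c("prey_id", "unique_peptides_max", "fold_ratio"),
                 what = "profile table")
  keep <- profiles$unique_peptides_max >= config$min_unique_peptides &
    profiles$fold_ratio >= config$first_pass_fold
  profiles$prey_id[keep]
}

#' Second-pass rescue of first-pass failures
#'
#' A prey that failed the first pass (on peptide count or fold change) is
#' rescued if, in order of precedence: (a) it is a previously validated
#' literature partner; (b) its protein family already appears among the
#' first-pass survivors; or (c) it recurs as a single-peptide interactor
#' across multiple experiments (seen in at least two (antibody, age)
#' conditions or at least two replicates, with only one unique peptide).
#' Only the first matching criterion is recorded.
#'
#' @param profiles Tibble of enrichment profiles for the rescue candidates.
#' @param first_pass_ids `prey_id`s that survived the first pass.
#' @param literature A [protein_list()] of validated partners (criterion a).
#' @param family_map Protein-family assignment for criterion (b): a named
#'   character vector mapping `prey_id` or gene symbol to a family
#'   identifier, or the string `"symbol_prefix"` to use the approximate
#'   heuristic of stripping trailing digits from gene symbols
#'   (e.g. ATP1A2 -> ATP1A).  `NULL` (default) disables family rescue:
#'   preys without a family assignment evaluate criterion (b) as false.
#' @param first_pass_profiles Profiles of the first-pass survivors, used to
#'   derive their families for criterion (b); defaults to `profiles` filtered
#'   to `first_pass_ids`.
#' @return A tibble with columns `prey_id`, `rescued`, `rescue_reason`.
#' @export
second_pass_rescue <- function(profiles, first_pass_ids,
                               literature = protein_list(character(0)),
                               family_map = NULL,
                               first_pass_profiles = NULL) {
  assert_columns(profiles,
                 c("prey_id", "gene_symbol", "unique_peptides_max",
                   "replicate_presence", "n_conditions"),
                 what = "profile table")
  first_pass_profiles <- first_pass_profiles %||%
    dplyr::filter(profiles, .data$prey_id %in% first_pass_ids)
  use_heuristic <- identical(family_map, "symbol_prefix")
  if (use_heuristic) {
    inform("family rescue: using approximate trailing-digit symbol heuristic")
    family_map <- NULL
  }
  family_of <- function(prey_id, gene_symbol) {
    fam <- NA_character_
    if (!is.null(family_map)) {
      fam <- unname(family_map[toupper(prey_id)])
      if (is.na(fam)) fam <- unname(family_map[toupper(gene_symbol)])
    } else if (use_heuristic) {
      # approximate family: gene symbol with trailing digits stripped
      fam <- sub("[0-9]+$", "", toupper(gene_symbol))
    }
    fam
  }
  first_pass_families <- unique(purrr::map2_chr(
    first_pass_profiles$prey_id, first_pass_profiles$gene_symbol, family_of))
  res <- purrr::pmap(profiles, function(prey_id, gene_symbol,
                                        unique_peptides_max,
                                        replicate_presence, n_conditions, ...) {
    if (in_protein_list(protein_key(prey_id, gene_symbol), literature) ||
        in_protein_list(gene_symbol, literature) ||
        in_protein_list(prey_id, literature)) {
      return(c(TRUE, "LITERATURE_VALIDATED"))
    }
    fam <- family_of(prey_id, gene_symbol)
    if (!is.na(fam) && nzchar(fam) && fam %in% first_pass_families) {
      return(c(TRUE, "FAMILY_IN_FIRST_PASS"))
    }
    if (unique_peptides_max == 1 &&
        (n_conditions >= 2 || replicate_presence >= 2)) {
      return(c(TRUE, "MULTI_EXPERIMENT"))
    }
    c(FALSE, "NONE")
  })
  tibble(
    prey_id = profiles$prey_id,
    rescued = vapply(res, function(x) as.logical(x[[1]]), logical(1)),
    rescue_reason = vapply(res, `[[`, character(1), 2)
  )
}

#' Remove CRAPome-style contaminants
#'
#' Drops ids whose contaminant observation frequency is at or above the
#' threshold.  Listed contaminants without a stated frequency are treated as
#' frequency 1 (always removed at any threshold <= 1); ids not on the list
#' are always retained.
#'
#' @param ids Character vector of candidate ids.
#' @param contaminants A [protein_list()] with optional frequencies.
#' @param threshold Removal threshold in `[0, 1]`; default 0.5.
#' @return The retained subset of `ids`, in input order.
#' @export
remove_contaminants <- function(ids, contaminants, threshold = 0.5) {
  assert_scalar_number(threshold, "threshold", 0, 1)
  if (length(contaminants$members) == 0) return(ids)
  freq <- setNames(rep(1, length(contaminants$members)),
                   toupper(contaminants$members))
  if (length(contaminants$frequency) > 0) {
    freq[toupper(names(contaminants$frequency))] <- contaminants$frequency
  }
  f <- freq[toupper(ids)]
  drop <- !is.na(f) & f >= threshold
  ids[!drop]
}

#' Assign a confidence tier to one enrichment profile
#'
#' Platinum: present in at least `platinum_min_replicates` replicates with
#' fold ratio >= `high_fold` and MaxP >= `high_maxp`.  Gold: same fold and
#' MaxP thresholds in fewer replicates.  Silver: fold in
#' `[silver_fold_low, high_fold)` with MaxP in `[silver_maxp_low, high_maxp)`.
#' Bronze: all remaining proteins.  The classification is total: profiles
#' matching no named rule (e.g. high fold with low MaxP) fall to Bronze.
#'
#' @param fold_ratio,maxp,replicate_presence Profile fields (vectorised).
#' @param config A [filter_config()].
#' @return Character vector of tiers.
#' @export
#' @examples
#' assign_tier(136, 1, 3)    # PLATINUM
#' assign_tier(6, 0.92, 1)   # GOLD
#' assign_tier(3, 0.69, 2)   # BRONZE (below the Silver MaxP bound)
assign_tier <- function(fold_ratio, maxp, replicate_presence,
                        config = filter_config()) {
  dplyr::case_when(
    replicate_presence >= config$platinum_min_replicates &
      fold_ratio >= config$high_fold & maxp >= config$high_maxp ~ "PLATINUM",
    fold_ratio >= config$high_fold & maxp >= config$high_maxp ~ "GOLD",
    fold_ratio >= config$silver_fold_low & fold_ratio < config$high_fold &
      maxp >= config$silver_maxp_low & maxp < config$high_maxp ~ "SILVER",
    TRUE ~ "BRONZE"
  )
}

#' Merge literature partners into the screen-derived member table
#'
#' Union keyed by case-insensitive protein identity (accession, else symbol).
#' Literature members already present keep their SCREEN provenance and tier;
#' new literature members enter with provenance LITERATURE and tier
#' NA_LITERATURE.  The merged size is `|screen| + |literature \ screen|`.
#'
#' @param screen_members Tibble of screen members with at least `prey_id`
#'   and `gene_symbol`.
#' @param literature A [protein_list()].
#' @return The merged member tibble.
#' @export
merge_literature_partners <- function(screen_members, literature) {
  assert_columns(screen_members, c("prey_id", "gene_symbol"),
                 what = "screen member table")
  keys <- unique(c(toupper(screen_members$prey_id),
                   toupper(screen_members$gene_symbol)))
  new_members <- literature$members[!toupper(literature$members) %in% keys]
  if (length(new_members) == 0) return(screen_members)
  lit_rows <- tibble(prey_id = new_members, gene_symbol = new_members)
  for (col in setdiff(names(screen_members), names(lit_rows))) {
    template <- screen_members[[col]]
    lit_rows[[col]] <- if (col == "provenance") "LITERATURE"
      else if (col == "tier") "NA_LITERATURE"
      else if (col == "rescue_reason") "NONE"
      else template[rep(NA_integer_, length(new_members))]
  }
  dplyr::bind_rows(screen_members, lit_rows[, names(screen_members)])
}

#' Build an interactome from an AP-MS observation table
#'
#' Runs the full published filtering procedure: per-prey enrichment profiling,
#' the two-unique-peptide / fold-change first pass, literature-family-
#' recurrence second-pass rescue, CRAPome-style contaminant removal,
#' Platinum/Gold/Silver/Bronze tiering, and finally the merge of previously
#' established literature partners not seen in the screen.
#'
#' @param observations Tibble of prey observations (see [read_count_table()]).
#' @param literature A [protein_list()] of previously validated partners;
#'   used both for second-pass rescue and the final merge.
#' @param contaminants A [protein_list()] of recurrent spurious interactors
#'   with observation frequencies.
#' @param family_map Optional named map to protein families for rescue
#'   criterion (b); see [second_pass_rescue()].
#' @param config A [filter_config()].
#' @param pseudocount,enrichment_factor,prior_true,lambda_bg_floor Passed to
#'   [enrichment_profiles()].
#' @return An `interactome` object: a list with `members` (tibble sorted by
#'   tier, then descending fold ratio, then id), `profiles`, `stage_counts`
#'   and `config`.
#' @export
build_interactome <- function(observations,
                              literature = protein_list(character(0)),
                              contaminants = protein_list(character(0)),
                              family_map = NULL,
                              config = filter_config(),
                              pseudocount = 1, enrichment_factor = 10,
                              prior_true = 0.5, lambda_bg_floor = 0.1) {
  profiles <- enrichment_profiles(observations, pseudocount,
                                  enrichment_factor, prior_true,
                                  lambda_bg_floor)
  candidates <- profiles$prey_id
  first_ids <- first_pass_filter(profiles, config)
  failed <- dplyr::filter(profiles, !.data$prey_id %in% first_ids)
  rescue <- second_pass_rescue(failed, first_ids, literature, family_map,
                               dplyr::filter(profiles,
                                             .data$prey_id %in% first_ids))
  second_ids <- c(first_ids, rescue$prey_id[rescue$rescued])
  kept_ids <- remove_contaminants(second_ids, contaminants,
                                  config$contaminant_frequency_threshold)
  members <- profiles |>
    dplyr::filter(.data$prey_id %in% kept_ids) |>
    dplyr::left_join(rescue, by = "prey_id") |>
    dplyr::mutate(
      rescued = dplyr::coalesce(.data$rescued, FALSE),
      rescue_reason = dplyr::coalesce(.data$rescue_reason, "NONE"),
      provenance = "SCREEN",
      tier = assign_tier(.data$fold_ratio, .data$maxp,
                         .data$replicate_presence, config)
    )
  merged <- merge_literature_partners(members, literature)
  merged <- merged |>
    dplyr::mutate(tier = factor(.data$tier, levels = TIERS)) |>
    dplyr::arrange(.data$tier, dplyr::desc(.data$fold_ratio),
                   .data$prey_id) |>
    dplyr::mutate(tier = as.character(.data$tier))
  stage_counts <- tibble(
    stage = c("profiles", "first_pass", "second_pass",
              "contaminant_removal", "tiering", "literature_merge"),
    n_in = c(length(candidates), length(candidates), length(first_ids),
             length(second_ids), length(kept_ids), length(kept_ids)),
    n_out = c(length(candidates), length(first_ids), length(second_ids),
              length(kept_ids), length(kept_ids), nrow(merged))
  )
  structure(list(members = as_tibble(merged), profiles = profiles,
                 stage_counts = stage_counts, config = config),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  counts <- table(factor(x$members$tier, levels = TIERS))
  cat(sprintf("<interactome: %d members (%d from screen, %d literature)>\n",
              nrow(x$members),
              sum(x$members$provenance == "SCREEN"),
              sum(x$members$provenance == "LITERATURE")))
  cat("  tiers:", paste(sprintf("%s=%d", names(counts), counts),
                        collapse = " "), "\n")
  invisible(x)
}

#' @rdname build_interactome
#' @param x An `interactome` object.
#' @param ... Unused.
#' @method tidy interactome
#' @export
tidy.interactome <- function(x, ...) {
  x$members
}

#' @rdname build_interactome
#' @method glance interactome
#' @export
glance.interactome <- function(x, ...) {
  m <- x$members
  tibble(
    n_members = nrow(m),
    n_screen = sum(m$provenance == "SCREEN"),
    n_literature = sum(m$provenance == "LITERATURE"),
    n_platinum = sum(m$tier == "PLATINUM"),
    n_gold = sum(m$tier == "GOLD"),
    n_silver = sum(m$tier == "SILVER"),
    n_bronze = sum(m$tier == "BRONZE")
  )
}

#' @rdname build_interactome
#' @param object An `interactome` object.
#' @method autoplot interactome
#' @export
autoplot.interactome <- function(object, ...) {
  df <- dplyr::count(object$members,
                     tier = factor(.data$tier, levels = TIERS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tier, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "confidence tier", y = "members",
                  title = "Interactome members by confidence tier") +
    ggplot2::theme_minimal()
}
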