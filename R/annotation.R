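#' Bundle named synapse-proteome sets
#'
#' Collects published excitatory-synapse-enriched proteomes (e.g. PSD, Nlgn1,
#' Lrrtm1, Lrrtm2) and inhibitory-synapse-enriched proteomes (e.g. iPSD,
#' GABA-A/GABA-B receptor, NLGN2, Slitrk3, GlyR) for membership mapping.
#'
#' @param excitatory,inhibitory Lists of [protein_list()] objects (or bare
#'   character vectors, which are wrapped).  Set names must be unique across
#'   the two groups.
#' @return A `synapse_proteomes` object.
#' @export
synapse_proteomes <- function(excitatory = list(), inhibitory = list()) {
  wrap <- function(sets, side) {
    sets <- purrr::imap(sets, function(s, nm) {
      if (inherits(s, "protein_list")) s
      else protein_list(s, name = as.character(nm))
    })
    if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
      names(sets) <- vapply(sets, `[[`, character(1), "name")
    }
    sets
  }
  excitatory <- wrap(excitatory, "excitatory")
  inhibitory <- wrap(inhibitory, "inhibitory")
  if (anyDuplicated(c(names(excitatory), names(inhibitory)))) {
    abort("synapse proteome set names must be unique across both groups",
          class = "baitprey_validation_error")
  }
  structure(list(excitatory = excitatory, inhibitory = inhibitory),
            class = "synapse_proteomes")
}

#' Classify members by synapse-proteome membership
#'
#' Each member is EXCITATORY_ONLY if it occurs in at least one excitatory set
#' and no inhibitory set, INHIBITORY_ONLY in the symmetric case, BOTH if in
#' at least one of each, and NEITHER otherwise.  Membership is resolved by
#' accession first, then case-insensitive gene symbol.  If the member table
#' already carries precomputed `es`/`is_flag` columns (as the packaged
#' partner table does) and no proteomes are supplied, those flags are used
#' directly.
#'
#' @param members Tibble with `prey_id`/`gene_symbol` columns, or with
#'   logical `es` and `is_flag` columns.
#' @param proteomes Optional [synapse_proteomes()] collection.
#' @return `members` with an added `synapse_category` column.
#' @export
#' @examples
#' partners <- read_me_ap_partners()
#' tab <- map_synapse_category(partners[!partners$is_bait, ])
#' table(tab$synapse_category)
map_synapse_category <- function(members, proteomes = NULL) {
  if (is.null(proteomes)) {
    assert_columns(members, c("es", "is_flag"),
                   what = "member table (flag path)")
    es <- members$es
    is_flag <- members$is_flag
  } else {
    assert_columns(members, c("prey_id", "gene_symbol"),
                   what = "member table (proteome path)")
    in_any <- function(sets) {
      if (length(sets) == 0) return(rep(FALSE, nrow(members)))
      hits <- purrr::map(sets, function(s) {
        in_protein_list(members$prey_id, s) |
          in_protein_list(members$gene_symbol, s)
      })
      Reduce(`|`, hits)
    }
    es <- in_any(proteomes$excitatory)
    is_flag <- in_any(proteomes$inhibitory)
  }
  members$synapse_category <- dplyr::case_when(
    es & is_flag ~ "BOTH",
    es ~ "EXCITATORY_ONLY",
    is_flag ~ "INHIBITORY_ONLY",
    TRUE ~ "NEITHER"
  )
  members
}

#' Partition screen members by developmental condition
#'
#' Splits members detected in at least one age into P5_ONLY (developing brain
#' only), P50_ONLY (mature brain only) and SHARED.  Members lacking both age
#' flags (e.g. literature-only members) are excluded.
#'
#' @param members Tibble with logical `p5` and `p50` columns and an identity
#'   column (`gene_symbol` or `prey_id`).
#' @return A named list of character vectors `P5_ONLY`, `P50_ONLY`, `SHARED`.
#' @export
#' @examples
#' partners <- read_me_ap_partners()
#' parts <- partition_developmental(partners[!partners$is_bait, ])
#' lengths(parts)
partition_developmental <- function(members) {
  assert_columns(members, c("p5", "p50"), what = "member table")
  id_col <- intersect(c("gene_symbol", "prey_id"), names(members))[[1]]
  ids <- members[[id_col]]
  list(
    P5_ONLY = ids[members$p5 & !members$p50],
    P50_ONLY = ids[members$p50 & !members$p5],
    SHARED = ids[members$p5 & members$p50]
  )
}

#' Summarise a partition as counts and percentages
#'
#' @param partition Named list of id vectors (e.g. from
#'   [partition_developmental()]) or a named vector of counts.
#' @param total Denominator for the percentages; must be at least the sum of
#'   the counts.
#' @param digits Decimal places for the percentage column; default 1.
#' @return A tibble with columns `category`, `count`, `percent`.
#' @export
summarize_partitions <- function(partition, total, digits = 1) {
  counts <- if (is.list(partition)) lengths(partition) else partition
  assert_scalar_number(total, "total", lower = 0)
  if (total == 0) {
    abort("total is zero: percentages undefined",
          class = "baitprey_validation_error")
  }
  if (total < sum(counts)) {
    abort("total is smaller than the summed category counts",
          class = "baitprey_validation_error")
  }
  tibble(
    category = names(counts),
    count = as.integer(counts),
    percent = round(100 * as.integer(counts) / total, digits)
  )
}
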