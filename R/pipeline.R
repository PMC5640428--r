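#' Run the full interactome pipeline
#'
#' Orchestrates the published filtering order on a spectral-count table:
#' enrichment profiling, first-pass filter, second-pass rescue, contaminant
#' removal, confidence tiering and literature merge; then partitions the
#' screen members by developmental condition (ages with bait evidence) and,
#' when synapse proteomes are supplied, by synapse-proteome membership.
#' Outputs are sorted deterministically (tier, then descending fold ratio,
#' then id) so that repeated runs and permuted inputs produce identical
#' report bundles.
#'
#' @param counts Observation tibble or path to a count table
#'   (see [read_count_table()]).
#' @param literature Optional [protein_list()] or path (see
#'   [read_protein_list()]).
#' @param contaminants Optional [protein_list()] or path.
#' @param family_map Optional named family map for rescue criterion (b).
#' @param config A [filter_config()].
#' @param proteomes Optional [synapse_proteomes()] collection.
#' @param out_dir Optional directory; when given, the member table, the
#'   partition summary, the stage counts and the run log are written there
#'   as TSV/plain text.
#' @param ... Passed to [build_interactome()] (score-model parameters).
#' @return A `pipeline_report`: list with `interactome`, `members`,
#'   `developmental`, `developmental_summary`, `synapse_summary` (or NULL),
#'   `stage_counts` and `log`.
#' @export
run_pipeline <- function(counts, literature = NULL, contaminants = NULL,
                         family_map = NULL, config = filter_config(),
                         proteomes = NULL, out_dir = NULL, ...) {
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }
  load_list <- function(x, what) {
    if (is.null(x)) return(protein_list(character(0), name = what))
    if (inherits(x, "protein_list")) return(x)
    read_protein_list(x, name = what)
  }
  observations <- if (is.character(counts)) read_count_table(counts) else {
    validate_observations(counts)
    counts
  }
  note("loaded %d observations over %d preys", nrow(observations),
       length(unique(observations$prey_id)))
  literature <- load_list(literature, "literature")
  contaminants <- load_list(contaminants, "contaminants")
  note("literature partners: %d; contaminant list: %d",
       length(literature$members), length(contaminants$members))

  result <- build_interactome(observations, literature, contaminants,
                              family_map, config, ...)
  for (i in seq_len(nrow(result$stage_counts))) {
    note("stage %-19s in=%4d out=%4d", result$stage_counts$stage[[i]],
         result$stage_counts$n_in[[i]], result$stage_counts$n_out[[i]])
  }

  # developmental flags: ages in which each screen member had bait evidence
  age_flags <- observations |>
    dplyr::filter(.data$channel == "BAIT", .data$spectral_count > 0) |>
    dplyr::group_by(.data$prey_id) |>
    dplyr::summarise(p5 = any(.data$age == "P5"),
                     p50 = any(.data$age == "P50"), .groups = "drop")
  screen <- result$members |>
    dplyr::filter(.data$provenance == "SCREEN") |>
    dplyr::left_join(age_flags, by = "prey_id")
  developmental <- partition_developmental(screen)
  dev_summary <- if (nrow(screen) > 0) {
    summarize_partitions(developmental, nrow(screen))
  } else {
    tibble(category = names(developmental), count = 0L, percent = NA_real_)
  }

  synapse_summary <- NULL
  if (!is.null(proteomes)) {
    mapped <- map_synapse_category(result$members, proteomes)
    synapse_summary <- summarize_partitions(
      split(mapped$prey_id,
            factor(mapped$synapse_category, levels = SYNAPSE_CATEGORIES)),
      nrow(mapped))
  }

  report <- structure(list(
    interactome = result,
    members = result$members,
    developmental = developmental,
    developmental_summary = dev_summary,
    synapse_summary = synapse_summary,
    stage_counts = result$stage_counts,
    log = log_lines
  ), class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(result$members, file.path(out_dir, "interactome.tsv"))
    readr::write_tsv(dev_summary,
                     file.path(out_dir, "developmental_summary.tsv"))
    if (!is.null(synapse_summary)) {
      readr::write_tsv(synapse_summary,
                       file.path(out_dir, "synapse_summary.tsv"))
    }
    readr::write_tsv(result$stage_counts, file.path(out_dir,
                                                    "stage_counts.tsv"))
    readr::write_lines(log_lines, file.path(out_dir, "run.log"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  print(x$interactome)
  cat("developmental partition:\n")
  print(x$developmental_summary)
  invisible(x)
}

#' Per-stage candidate bookkeeping of a pipeline run
#'
#' One row per stage with candidates in and out; the output count of each
#' stage equals the input count of the next.
#'
#' @param report A `pipeline_report` or `interactome` object.
#' @return Tibble with columns `stage`, `n_in`, `n_out`.
#' @export
stage_counts <- function(report) {
  report$stage_counts
}
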