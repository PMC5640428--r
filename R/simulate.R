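#' Configuration for the synthetic AP-MS experiment generator
#'
#' Defaults emulate the study conditions of the multi-epitope purification
#' design: three antibody epitopes crossed with two ages (developing P5,
#' mature P50) and three biological replicates, with parallel IgG/IgY
#' control purifications; and a raw candidate list of 440 preys split into
#' 50 planted true interactors, 354 background preys and 36 frequent
#' contaminants (the published screen removed 36 CRAPome proteins from 440
#' raw candidates).  Background binding is Poisson with mean `lambda_bg` in
#' both channels; true interactors are enriched `enrichment_factor`-fold in
#' the bait channel and detected per purification with probability
#' `true_detection_prob`; contaminants appear in both channels at high
#' counts (`contaminant_mean`) with probability `contaminant_frequency`.
#' A `single_peptide_fraction` of the true interactors is forced to a single
#' unique peptide to exercise the second-pass rescue criteria.
#'
#' @param n_true,n_background,n_contaminants Prey counts by class.
#' @param replicates Biological replicates per condition; default 3.
#' @param antibodies,ages Condition factors; defaults are the full design.
#' @param lambda_bg Background Poisson mean per purification; default 2.
#' @param enrichment_factor Bait-channel enrichment of true interactors;
#'   default 10.
#' @param true_detection_prob Per-purification detection probability of a
#'   true interactor; default 0.9.
#' @param contaminant_frequency Per-purification appearance probability of a
#'   contaminant; default 0.8.
#' @param contaminant_mean Poisson mean of contaminant counts in both
#'   channels; default `enrichment_factor * lambda_bg`.
#' @param single_peptide_fraction Fraction of true interactors forced to one
#'   unique peptide; default 0.1.
#' @param overdispersion Optional negative-binomial size parameter; `Inf`
#'   (default) gives Poisson counts.
#' @param seed Integer seed fixing the full output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_true = 50, n_background = 354, n_contaminants = 36,
                       replicates = 3,
                       antibodies = ANTIBODIES, ages = AGES,
                       lambda_bg = 2, enrichment_factor = 10,
                       true_detection_prob = 0.9,
                       contaminant_frequency = 0.8,
                       contaminant_mean = enrichment_factor * lambda_bg,
                       single_peptide_fraction = 0.1,
                       overdispersion = Inf,
                       seed = 1L) {
  for (nm in c("n_true", "n_background", "n_contaminants", "replicates")) {
    assert_scalar_number(get(nm), nm, lower = 0)
  }
  assert_scalar_number(lambda_bg, "lambda_bg", lower = 1e-12)
  assert_scalar_number(enrichment_factor, "enrichment_factor", lower = 1e-12)
  assert_scalar_number(true_detection_prob, "true_detection_prob", 0, 1)
  assert_scalar_number(contaminant_frequency, "contaminant_frequency", 0, 1)
  assert_scalar_number(single_peptide_fraction, "single_peptide_fraction",
                       0, 1)
  if (n_true > 0 && true_detection_prob == 0) {
    abort("true_detection_prob 0 with planted interactors is impossible",
          class = "baitprey_validation_error")
  }
  stopifnot(all(antibodies %in% ANTIBODIES), all(ages %in% AGES))
  structure(list(
    n_true = as.integer(n_true), n_background = as.integer(n_background),
    n_contaminants = as.integer(n_contaminants),
    replicates = as.integer(replicates),
    antibodies = antibodies, ages = ages,
    lambda_bg = lambda_bg, enrichment_factor = enrichment_factor,
    true_detection_prob = true_detection_prob,
    contaminant_frequency = contaminant_frequency,
    contaminant_mean = contaminant_mean,
    single_peptide_fraction = single_peptide_fraction,
    overdispersion = overdispersion,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Poisson draw, or negative binomial when a finite overdispersion size is set.
draw_counts <- function(n, mu, size = Inf) {
  if (is.infinite(size)) rpois(n, mu) else stats::rnbinom(n, size = size,
                                                          mu = mu)
}

# unique peptides: 1 + Binomial(spc - 1, 1/2), capped by the spectral count;
# zero when no spectra; forced to 1 for designated single-peptide preys.
draw_unique_peptides <- function(spc, force_single) {
  u <- ifelse(spc == 0, 0L,
              pmin(spc, 1L + rbinom(length(spc), pmax(spc - 1L, 0L), 0.5)))
  ifelse(force_single & spc > 0, 1L, as.integer(u))
}

#' Simulate a multi-epitope AP-MS experiment
#'
#' Generates a long bait/control spectral-count table over the configured
#' antibodies x ages x replicates design, together with the ground truth of
#' planted prey classes.  Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `observations` (tibble of prey observations, see
#'   [read_count_table()]) and `truth` (tibble: `prey_id`, `class`,
#'   `lambda_bait`, `lambda_control`, `single_peptide`).
#' @export
#' @examples
#' sim <- simulate_apms_experiment(sim_config(n_true = 5, n_background = 10,
#'                                            n_contaminants = 2, seed = 7))
#' dplyr::count(sim$observations, channel)
simulate_apms_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cls <- rep(c("TRUE_INTERACTOR", "BACKGROUND", "CONTAMINANT"),
             c(config$n_true, config$n_background, config$n_contaminants))
  n_prey <- length(cls)
  prey_id <- sprintf("%s%04d",
                     c(TRUE_INTERACTOR = "TRU", BACKGROUND = "BKG",
                       CONTAMINANT = "CON")[cls], seq_len(n_prey))
  single <- cls == "TRUE_INTERACTOR" &
    seq_len(n_prey) <= config$n_true * config$single_peptide_fraction
  lambda_bait <- ifelse(cls == "TRUE_INTERACTOR",
                        config$enrichment_factor * config$lambda_bg,
                        ifelse(cls == "CONTAMINANT", config$contaminant_mean,
                               config$lambda_bg))
  lambda_control <- ifelse(cls == "CONTAMINANT", config$contaminant_mean,
                           config$lambda_bg)
  truth <- tibble(prey_id = prey_id, class = cls,
                  lambda_bait = lambda_bait, lambda_control = lambda_control,
                  single_peptide = single)
  design <- expand.grid(antibody = config$antibodies, age = config$ages,
                        replicate = seq_len(config$replicates),
                        channel = CHANNELS, stringsAsFactors = FALSE)
  if (n_prey == 0 || nrow(design) == 0) {
    empty <- tibble(prey_id = character(0), gene_symbol = character(0),
                    purification_id = character(0), antibody = character(0),
                    age = character(0), replicate = integer(0),
                    channel = character(0), spectral_count = integer(0),
                    unique_peptides = integer(0), protein_length = integer(0))
    return(list(observations = empty, truth = truth))
  }
  protein_length <- as.integer(round(runif(n_prey, 200, 1500)))
  obs <- purrr::pmap(design, function(antibody, age, replicate, channel) {
    mu <- if (channel == "BAIT") lambda_bait else lambda_control
    present <- rep(TRUE, n_prey)
    present[cls == "TRUE_INTERACTOR"] <-
      runif(sum(cls == "TRUE_INTERACTOR")) < config$true_detection_prob
    present[cls == "CONTAMINANT"] <-
      runif(sum(cls == "CONTAMINANT")) < config$contaminant_frequency
    # detection/appearance gates only modulate the specific signal: a gated
    # true interactor still shows background-level bait binding
    mu_eff <- ifelse(present, mu,
                     ifelse(cls == "TRUE_INTERACTOR" & channel == "BAIT",
                            config$lambda_bg,
                            ifelse(cls == "CONTAMINANT", 0, mu)))
    spc <- as.integer(draw_counts(n_prey, mu_eff, config$overdispersion))
    tibble(
      prey_id = prey_id,
      gene_symbol = prey_id,
      purification_id = sprintf("%s_%s_R%d_%s", antibody, age, replicate,
                                channel),
      antibody = antibody, age = age, replicate = as.integer(replicate),
      channel = channel,
      spectral_count = spc,
      unique_peptides = draw_unique_peptides(spc, single),
      protein_length = protein_length
    )
  })
  observations <- dplyr::bind_rows(obs)
  observations <- observations[observations$spectral_count > 0, ]
  list(observations = as_tibble(observations), truth = truth)
}

#' Contaminant list implied by a simulation ground truth
#'
#' @param sim Output of [simulate_apms_experiment()].
#' @param frequency Observation frequency to record for every planted
#'   contaminant; defaults to the generator's appearance probability.
#' @return A [protein_list()] usable with [remove_contaminants()].
#' @export
simulated_contaminant_list <- function(sim, frequency = 0.8) {
  ids <- sim$truth$prey_id[sim$truth$class == "CONTAMINANT"]
  protein_list(ids, name = "simulated_contaminants",
               frequency = setNames(rep(frequency, length(ids)), ids))
}

#' Simulate an IV curve around a known reversal potential
#'
#' `amplitude = conductance * (V - e_rev) + Gaussian(0, noise_sd)` at the
#' given holding potentials.
#'
#' @param e_rev True reversal potential (mV).
#' @param conductance True slope (pA/mV).
#' @param potentials Holding potentials (mV), at least 3.
#' @param noise_sd Gaussian noise standard deviation (pA); 0 for exact data.
#' @param seed Optional integer seed.
#' @return Tibble with columns `holding_potential`, `peak_amplitude`.
#' @export
simulate_iv_curve <- function(e_rev, conductance,
                              potentials = seq(-80, -40, 10),
                              noise_sd = 0, seed = NULL) {
  if (length(potentials) < 3) {
    abort("at least 3 holding potentials are required",
          class = "baitprey_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)
  tibble(
    holding_potential = as.numeric(potentials),
    peak_amplitude = conductance * (potentials - e_rev) +
      rnorm(length(potentials), 0, noise_sd)
  )
}
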