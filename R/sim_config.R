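#' Simulation configuration for the synthetic EHR
#'
#' Parameters of the generative model.  The defaults are the study
#' conditions used throughout the package's analyses; see the methods
#' vignette for the reasoning behind each choice.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; identical `(config, seed)` yields an
#'   identical dataset.
#' @param index_date_range Days (from the simulation epoch, day 0) over
#'   which patients enter the record.
#' @param age_distribution `list(mean, sd, min, max)` for age at first
#'   encounter (truncated normal, years).
#' @param sex_mix,race_mix Named probability vectors (must sum to 1).
#' @param true_model Score driving outcomes: `"charge_af"` or `"pce"`.
#' @param baseline_hazard `NULL` (default) generates event times from the
#'   true score's own published baseline survival, `-log(s0)/horizon`
#'   events per person-year with the hazard centered at the score's
#'   published mean linear predictor, so the score is the literally true
#'   model.  A numeric value instead gives events per person-year with
#'   the hazard centered at the population mean linear predictor.
#' @param ascertainment_strength Real >= 0; how strongly tabular
#'   completeness rises with latent risk.  `P(vital recorded) =
#'   plogis(qlogis(1 - missingness_base) + strength * (z + 2 *
#'   clinical_encounter))` with `z` the standardized latent LP.
#' @param prevalent_fraction Proportion with outcome onset before the
#'   first encounter.
#' @param coding_delay_days Mean of the exponential diagnosis-recording
#'   delay; 0 switches all delays off (recorded = true onset).
#' @param note_styles Named weights over the note dialects
#'   (`bare`, `unit`, `compound`, `failure`, `distractor`).
#' @param missingness_base Named per-vital probability that a tabular
#'   value is absent at `ascertainment_strength = 0`.
#' @param p_primary_care Probability a patient is engaged in longitudinal
#'   primary care (regular PCP visit stream).
#' @param admin_censor_day Administrative censoring date (days).
#' @param death_rate Death hazard, per person-year.
#' @param note_rate Probability an encounter generates a note.
#' @param note_embed_p Probability each measured vital is mentioned in a
#'   note.
#' @param p_missing_race Probability the race field is missing
#'   (demographic-completeness exclusion pathway).
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 20000,
                       seed = 1,
                       index_date_range = c(0, 4000),
                       age_distribution = list(mean = 48, sd = 17, min = 18, max = 89),
                       sex_mix = c(female = 0.6, male = 0.4),
                       race_mix = c(white = 0.75, black = 0.07, hispanic = 0.07,
                                    asian = 0.04, other = 0.07),
                       true_model = c("charge_af", "pce"),
                       baseline_hazard = NULL,
                       ascertainment_strength = 1,
                       prevalent_fraction = 0.10,
                       coding_delay_days = 180,
                       note_styles = c(bare = 0.30, unit = 0.30, compound = 0.15,
                                       failure = 0.10, distractor = 0.15),
                       missingness_base = c(height = 0.45, weight = 0.40,
                                            sbp = 0.35, dbp = 0.35,
                                            tc = 0.60, hdl = 0.60),
                       p_primary_care = 0.55,
                       admin_censor_day = 7305,
                       death_rate = 0.005,
                       note_rate = 0.6,
                       note_embed_p = 0.6,
                       p_missing_race = 0.002) {
  true_model <- match.arg(true_model)
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(p, nm) {
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8)
      stop("configuration error: ", nm,
           " must be probabilities in [0,1] summing to 1")
  }
  if (cfg$n_patients < 1) stop("configuration error: n_patients must be >= 1")
  chk_prob(cfg$sex_mix, "sex_mix")
  chk_prob(cfg$race_mix, "race_mix")
  chk_prob(cfg$note_styles / sum(cfg$note_styles), "note_styles")  # weights
  if (any(cfg$note_styles < 0)) stop("configuration error: negative note_styles weight")
  if (!is.null(cfg$baseline_hazard) && cfg$baseline_hazard <= 0)
    stop("configuration error: baseline_hazard must be > 0")
  if (cfg$ascertainment_strength < 0)
    stop("configuration error: ascertainment_strength must be >= 0")
  if (cfg$prevalent_fraction < 0 || cfg$prevalent_fraction > 1)
    stop("configuration error: prevalent_fraction must be in [0,1]")
  if (cfg$coding_delay_days < 0)
    stop("configuration error: coding_delay_days must be >= 0")
  if (any(cfg$missingness_base < 0) || any(cfg$missingness_base >= 1))
    stop("configuration error: missingness_base must be in [0,1)")
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys mirror the [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (nm in c("sex_mix", "race_mix", "note_styles", "missingness_base"))
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  do.call(sim_config, y)
}
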