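# Brute-force all-pairs concordance (Harrell), the independent oracle for
# the IPCW estimator on uncensored data.  O(n^2) double loop, n <= 200.
brute_cindex <- function(time, event, p, horizon = Inf) {
  n <- length(time)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1 || time[i] >= horizon) next
    for (j in seq_len(n)) {
      if (time[j] <= time[i]) next
      den <- den + 1
      if (p[i] > p[j]) num <- num + 1
      else if (p[i] == p[j]) num <- num + 0.5
    }
  }
  num / den
}

# Survival records generated from a proportional-hazards model whose
# predicted risks are exactly calibrated at `horizon`.
gen_calibrated <- function(n, seed, h0 = 0.02, beta = 1, horizon = 5,
                           censor_rate = 0.10, admin = 7.5) {
  set.seed(seed)
  lp <- rnorm(n)
  t_evt <- rexp(n, h0 * exp(beta * lp))
  cens <- pmin(rexp(n, censor_rate), admin)
  data.frame(time = pmin(t_evt, cens),
             event = as.integer(t_evt <= cens),
             lp = lp,
             p = 1 - exp(-h0 * horizon * exp(beta * lp)))
}

# Minimal hand-built EHR dataset for cohort-rule unit tests.
make_mini_ds <- function(patients, encounters, vitals = NULL, labs = NULL,
                         diagnoses = NULL, config = sim_config(n_patients = 1)) {
  empty_v <- data.frame(patient_id = character(0), date = numeric(0),
                        encounter_id = integer(0), vital = character(0),
                        value = numeric(0), source = character(0),
                        stringsAsFactors = FALSE)
  empty_d <- data.frame(patient_id = character(0), condition = character(0),
                        recorded_date = numeric(0), stringsAsFactors = FALSE)
  if (is.null(encounters$encounter_id))
    encounters$encounter_id <- seq_len(nrow(encounters))
  if (is.null(encounters$kind)) encounters$kind <- "primary-care-eligible"
  structure(list(patients = patients, encounters = encounters,
                 vitals = if (is.null(vitals)) empty_v else vitals,
                 labs = if (is.null(labs)) empty_v else labs,
                 notes = NULL,
                 diagnoses = if (is.null(diagnoses)) empty_d else diagnoses,
                 config = config, registry = pcp_registry()),
            class = "ehr_dataset")
}

mini_patient <- function(id = "P1", birth_day = -40 * 365.25, sex = "female",
                         race = "white", death_day = NA_real_) {
  data.frame(patient_id = id, birth_day = birth_day, sex = sex, race = race,
             death_day = death_day, stringsAsFactors = FALSE)
}
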