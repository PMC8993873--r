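#' Draw proportional-hazards event times
#'
#' Event times (years) from an exponential proportional-hazards model,
#' `hazard_i = baseline_hazard * exp(lp_i - lp_center)`.  With all linear
#' predictors equal the times are exponential with rate `baseline_hazard`.
#' Optionally draws an independent censoring time (exponential dropout
#' truncated at an administrative horizon).
#'
#' @param lp Linear predictors (finite).
#' @param baseline_hazard Events per person-year at `lp = lp_center`.
#' @param lp_center Centering constant; defaults to the population mean
#'   LP.
#' @param censor_rate Dropout hazard per person-year (0 = none).
#' @param admin_years Administrative censoring horizon (Inf = none).
#' @return Data frame with `time` (observed follow-up, years), `event`
#'   (1 = outcome), `event_time` (latent outcome time).
#' @export
assign_outcomes <- function(lp, baseline_hazard, lp_center = mean(lp),
                            censor_rate = 0, admin_years = Inf) {
  stopifnot(all(is.finite(lp)), baseline_hazard > 0)
  n <- length(lp)
  t_evt <- rexp(n, rate = baseline_hazard * exp(lp - lp_center))
  t_cens <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
  t_cens <- pmin(t_cens, admin_years)
  data.frame(time = pmin(t_evt, t_cens),
             event = as.integer(t_evt <= t_cens),
             event_time = t_evt)
}

#' Simulate a synthetic EHR population
#'
#' Generates the full synthetic record: patients with true (latent)
#' covariates and a score-based latent linear predictor, per-patient
#' encounter streams (regular primary-care streams for engaged patients,
#' sparse clinically-driven streams otherwise, plus an event-driven
#' encounter at outcome recording), complete tabular vitals and lipid
#' labs at encounters, free-text notes in the configured dialects, and
#' diagnosis events; then applies the observation process
#' ([inject_observation_process()]) that deletes tabular values with
#' probability decreasing in latent risk and delays diagnosis recording.
#'
#' Hidden simulation truth (latent LP, true onset dates, true covariates,
#' note ground truth) is kept in the `truth` element, separate from the
#' observable tables.
#'
#' @param config A [sim_config()].
#' @param registry PCP visit-code registry used for primary-care
#'   encounter codes, see [pcp_registry()].
#' @return An object of class `ehr_dataset`: list with observable tables
#'   `patients`, `encounters`, `vitals`, `labs`, `notes`, `diagnoses`,
#'   plus `truth` and `config`.
#' @export
simulate_ehr <- function(config = sim_config(), registry = pcp_registry()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_patients

  ## ---- patients & true covariates -------------------------------------
  patient_id <- sprintf("P%06d", seq_len(n))
  sex <- sample(names(config$sex_mix), n, TRUE, prob = config$sex_mix)
  race <- sample(names(config$race_mix), n, TRUE, prob = config$race_mix)
  race[runif(n) < config$p_missing_race] <- NA

  ad <- config$age_distribution
  age <- rnorm(n, ad$mean, ad$sd)
  bad <- which(age < ad$min | age > ad$max)
  while (length(bad)) {
    age[bad] <- rnorm(length(bad), ad$mean, ad$sd)
    bad <- bad[age[bad] < ad$min | age[bad] > ad$max]
  }
  rng <- config$index_date_range
  entry_day <- floor(runif(n, rng[1], rng[2] + 1))
  birth_day <- entry_day - round(age * 365.25)

  male <- sex == "male"
  height <- rnorm(n, ifelse(male, 176, 162), ifelse(male, 7.5, 7))
  weight <- pmax(40, rnorm(n, ifelse(male, 85, 72), 15))
  sbp <- pmin(220, pmax(85, 103 + 0.35 * age + rnorm(n, 0, 13)))
  dbp <- pmin(130, pmax(40, 30 + 0.3 * sbp + rnorm(n, 0, 7)))
  tc <- pmin(400, pmax(90, 170 + 0.4 * age + rnorm(n, 0, 35)))
  hdl <- pmin(120, pmax(20, rnorm(n, 55, 16)))
  smoker <- rbinom(n, 1, 0.08)
  bp_treated <- rbinom(n, 1, plogis(-4.2 + 0.055 * age))
  diabetes <- rbinom(n, 1, plogis(-4.6 + 0.045 * age))
  heart_failure <- rbinom(n, 1, plogis(-7.0 + 0.055 * age))
  prior_mi <- rbinom(n, 1, plogis(-6.5 + 0.05 * age))

  race_imp <- ifelse(is.na(race), "other", race)
  cov <- data.frame(age = age, sex = sex, race = race_imp,
                    height = height, weight = weight, sbp = sbp, dbp = dbp,
                    tc = tc, hdl = hdl, smoker = smoker,
                    bp_treated = bp_treated, diabetes = diabetes,
                    heart_failure = heart_failure, prior_mi = prior_mi,
                    stringsAsFactors = FALSE)
  score <- score_definition(config$true_model)
  sr <- compute_linear_predictor(cov, score)
  center <- vapply(score$strata, `[[`, numeric(1), "mean_lp")[sr$stratum]
  lp_c <- sr$lp - center      # latent LP centered at the published mean

  ## ---- outcome onset, death, record window ----------------------------
  if (is.null(config$baseline_hazard)) {
    s0 <- vapply(score$strata, `[[`, numeric(1), "s0")[sr$stratum]
    rate <- -log(s0) / score$horizon * exp(lp_c)
  } else {
    rate <- config$baseline_hazard * exp(lp_c - mean(lp_c))
  }
  t_evt_years <- rexp(n) / rate
  onset_day <- entry_day + round(t_evt_years * 365.25)
  prevalent <- runif(n) < config$prevalent_fraction
  onset_day[prevalent] <- entry_day[prevalent] - floor(runif(sum(prevalent), 1, 1826))

  death_day <- entry_day + round(rexp(n, config$death_rate) * 365.25)
  engaged <- runif(n) < config$p_primary_care
  record_years <- rexp(n, 1 / ifelse(engaged, 12, 6))
  record_end <- pmin(entry_day + round(record_years * 365.25),
                     death_day, config$admin_censor_day)
  record_end <- pmax(record_end, entry_day)

  ## ---- encounters ------------------------------------------------------
  enc <- list()
  # engaged: regular PCP stream starting at entry
  eng_idx <- which(engaged)
  if (length(eng_idx)) {
    max_v <- 30
    gaps <- matrix(runif(length(eng_idx) * max_v, 330, 760), ncol = max_v)
    cum <- gaps
    for (j in 2:max_v) cum[, j] <- cum[, j - 1] + gaps[, j]
    dates <- cbind(0, cum) + entry_day[eng_idx]
    keep <- dates <= record_end[eng_idx]    # recycles by column
    ii <- rep(eng_idx, times = max_v + 1)[as.vector(keep)]
    dd <- as.vector(dates)[as.vector(keep)]
    enc$pcp <- data.frame(
      patient_id = patient_id[ii], date = round(dd),
      code = sample(registry$cpt_codes, length(ii), TRUE),
      location_id = sample(registry$locations, length(ii), TRUE),
      kind = "primary-care-eligible", stringsAsFactors = FALSE)
  }
  # sporadic specialty/other encounters (everyone); non-engaged start at entry
  window_years <- pmax((record_end - entry_day) / 365.25, 0)
  n_other <- rpois(n, 0.8 * window_years)
  n_other[!engaged] <- n_other[!engaged] + 1L    # at least the entry encounter
  ii <- rep(seq_len(n), n_other)
  dd <- entry_day[ii] + floor(runif(length(ii)) * (record_end[ii] - entry_day[ii] + 1))
  first_other <- !duplicated(ii) & !engaged[ii]
  dd[first_other] <- entry_day[ii][first_other]
  enc$other <- data.frame(
    patient_id = patient_id[ii], date = dd,
    code = sample(c("99243", "93000", "45378", "99213"), length(ii), TRUE),
    location_id = sample(sprintf("SP%03d", 1:30), length(ii), TRUE),
    kind = sample(c("specialty", "other"), length(ii), TRUE),
    stringsAsFactors = FALSE)
  # event-driven encounter at outcome recording (clinical need)
  evt_delay_mean <- if (config$coding_delay_days == 0) 0 else 14
  incident <- !prevalent & onset_day > entry_day &
    onset_day < pmin(death_day, config$admin_censor_day)
  evt_enc_day <- rep(NA_real_, n)
  if (any(incident)) {
    dly <- if (evt_delay_mean == 0) rep(0, sum(incident))
           else round(rexp(sum(incident), 1 / evt_delay_mean))
    cand <- onset_day[incident] + dly
    okc <- cand < pmin(death_day[incident], config$admin_censor_day)
    evt_enc_day[which(incident)[okc]] <- cand[okc]
  }
  has_evt <- which(!is.na(evt_enc_day))
  if (length(has_evt)) {
    enc$event <- data.frame(
      patient_id = patient_id[has_evt], date = evt_enc_day[has_evt],
      code = "99223", location_id = "IP001", kind = "inpatient",
      stringsAsFactors = FALSE)
  }
  encounters <- do.call(rbind, enc)
  encounters <- encounters[order(encounters$patient_id, encounters$date), ]
  encounters$encounter_id <- seq_len(nrow(encounters))
  encounters$clinical <- encounters$kind == "inpatient"
  rownames(encounters) <- NULL

  ## ---- complete tabular vitals & labs at encounters --------------------
  pi <- match(encounters$patient_id, patient_id)
  ne <- nrow(encounters)
  meas <- data.frame(
    patient_id = rep(encounters$patient_id, 4),
    date = rep(encounters$date, 4),
    encounter_id = rep(encounters$encounter_id, 4),
    vital = rep(c("height", "weight", "sbp", "dbp"), each = ne),
    value = c(round(height[pi] + rnorm(ne, 0, 0.7), 1),
              round(pmax(30, weight[pi] + rnorm(ne, 0, 2)), 1),
              round(pmax(60, sbp[pi] + rnorm(ne, 0, 8))),
              round(pmax(30, dbp[pi] + rnorm(ne, 0, 5)))),
    source = "tabular", stringsAsFactors = FALSE)
  lab_enc <- encounters$kind %in% c("primary-care-eligible", "inpatient")
  nl <- sum(lab_enc)
  labs <- data.frame(
    patient_id = rep(encounters$patient_id[lab_enc], 2),
    date = rep(encounters$date[lab_enc], 2),
    encounter_id = rep(encounters$encounter_id[lab_enc], 2),
    vital = rep(c("tc", "hdl"), each = nl),
    value = c(round(pmax(80, tc[match(encounters$patient_id[lab_enc], patient_id)] +
                           rnorm(nl, 0, 15))),
              round(pmax(15, hdl[match(encounters$patient_id[lab_enc], patient_id)] +
                           rnorm(nl, 0, 5)))),
    source = "tabular", stringsAsFactors = FALSE)

  ds <- structure(list(
    patients = data.frame(patient_id = patient_id, birth_day = birth_day,
                          sex = sex, race = race,
                          death_day = ifelse(death_day <= config$admin_censor_day,
                                             death_day, NA_real_),
                          stringsAsFactors = FALSE),
    encounters = encounters,
    vitals = meas, labs = labs,
    notes = NULL, diagnoses = NULL,
    truth = list(
      patients = data.frame(patient_id = patient_id, latent_lp = lp_c,
                            lp_raw = sr$lp, stratum = sr$stratum,
                            onset_day = onset_day, prevalent = prevalent,
                            death_day = death_day, entry_day = entry_day,
                            record_end = record_end, engaged = engaged,
                            stringsAsFactors = FALSE),
      covariates = cbind(patient_id = patient_id, cov),
      complete_vitals = meas),
    config = config, registry = registry), class = "ehr_dataset")

  ds <- inject_observation_process(ds, config)
  ds <- generate_notes(ds, config)
  ds
}

#' Apply the observation process to a complete dataset
#'
#' Two mechanisms: (1) tabular vital/lab records are deleted with
#' probability increasing in latent risk when `ascertainment_strength > 0`
#' (logistic link on the standardized latent LP, with an additional
#' clinical-need boost at event-driven encounters); (2) diagnosis
#' recording dates are delayed relative to true onset.  Comorbidities are
#' coded at the first encounter after an exponential delay (never, if the
#' record ends first).  Incident outcomes are coded at the event-driven
#' encounter.  Prevalent outcomes are coded shortly after the first
#' primary-care visit (engaged patients) or the first encounter at which
#' all score components were measured (non-engaged patients) -- the
#' delayed-recording mechanism that misclassifies prevalent disease as
#' incident under convenience sampling.  With `coding_delay_days = 0`
#' every recorded date equals the true onset date.
#'
#' @param ds An `ehr_dataset` with complete `vitals`/`labs`.
#' @param config The `sim_config`.
#' @return The dataset with thinned vitals/labs and a `diagnoses` table
#'   (`patient_id`, `condition`, `recorded_date`); true onsets stay in
#'   `truth`.
#' @export
inject_observation_process <- function(ds, config) {
  tp <- ds$truth$patients
  z <- as.vector(scale(tp$latent_lp))
  alpha <- qlogis(1 - config$missingness_base)
  s <- config$ascertainment_strength

  thin <- function(tab) {
    pi <- match(tab$patient_id, tp$patient_id)
    clin <- ds$encounters$clinical[match(tab$encounter_id, ds$encounters$encounter_id)]
    p_keep <- plogis(alpha[tab$vital] + s * (z[pi] + 2 * clin))
    tab[runif(nrow(tab)) < p_keep, , drop = FALSE]
  }
  ds$vitals <- thin(ds$vitals)
  ds$labs <- thin(ds$labs)
  rownames(ds$vitals) <- rownames(ds$labs) <- NULL

  ## first score-complete encounter per patient (observable completeness)
  comp <- score_definition(config$true_model)$components
  tabs <- rbind(ds$vitals, ds$labs)
  tabs <- tabs[tabs$vital %in% comp, ]
  key <- paste(tabs$encounter_id, tabs$vital)
  tabs <- tabs[!duplicated(key), ]
  cnt <- table(tabs$encounter_id)
  complete_enc <- as.integer(names(cnt)[cnt == length(comp)])
  enc_c <- ds$encounters[ds$encounters$encounter_id %in% complete_enc, ]
  first_complete <- tapply(enc_c$date, enc_c$patient_id, min)

  ## encounter helpers
  enc <- ds$encounters
  flagged <- identify_pcp_visits(enc, ds$registry)
  pcp_first <- tapply(enc$date[flagged], enc$patient_id[flagged], min)
  enc_by_pat <- split(enc$date, enc$patient_id)

  delay0 <- config$coding_delay_days == 0
  n <- nrow(tp)
  first_enc_after <- function(cand) {
    # first encounter date >= cand, per patient; NA if none
    vapply(seq_len(n), function(i) {
      d <- enc_by_pat[[tp$patient_id[i]]]
      d <- d[d >= cand[i]]
      if (length(d)) min(d) else NA_real_
    }, numeric(1))
  }

  diag <- list()
  ## comorbidities: present from entry, coded at first encounter after delay
  cv <- ds$truth$covariates
  comorb <- c(smoking = "smoker", hypertension_treated = "bp_treated",
              diabetes = "diabetes", heart_failure = "heart_failure",
              mi = "prior_mi")
  for (cond in names(comorb)) {
    has <- cv[[comorb[[cond]]]] == 1
    if (!any(has)) next
    dly <- if (delay0) rep(0, n) else rexp(n, 1 / config$coding_delay_days)
    rec <- rep(NA_real_, n)
    rec[has] <- first_enc_after(tp$entry_day + round(dly))[has]
    ok <- has & !is.na(rec)
    diag[[cond]] <- data.frame(patient_id = tp$patient_id[ok], condition = cond,
                               true_onset = tp$entry_day[ok], recorded_date = rec[ok],
                               stringsAsFactors = FALSE)
  }

  ## outcome condition
  outc <- score_definition(config$true_model)$outcome
  rec <- rep(NA_real_, n)
  if (delay0) {
    rec <- tp$onset_day
    rec[tp$onset_day >= pmin(tp$death_day, config$admin_censor_day)] <- NA
  } else {
    inc <- !tp$prevalent
    # incident: coded at the event-driven inpatient encounter
    evt_enc <- enc[enc$kind == "inpatient", ]
    m <- match(tp$patient_id, evt_enc$patient_id)
    rec[inc] <- evt_enc$date[m][inc]
    # prevalent: coded shortly after first PCP visit / first complete encounter
    prev <- which(tp$prevalent)
    anchor <- rep(NA_real_, n)
    anchor[prev] <- pcp_first[tp$patient_id[prev]]
    noanchor <- prev[is.na(anchor[prev])]
    anchor[noanchor] <- first_complete[tp$patient_id[noanchor]]
    still <- prev[is.na(anchor[prev])]
    if (length(still)) {
      fe <- vapply(enc_by_pat[tp$patient_id[still]], min, numeric(1))
      anchor[still] <- fe + round(rexp(length(still), 1 / config$coding_delay_days))
    }
    rec[prev] <- pmax(anchor[prev], tp$onset_day[prev]) +
      round(rexp(length(prev), 1 / 30))
    rec[rec >= pmin(tp$death_day, config$admin_censor_day)] <- NA
  }
  ok <- !is.na(rec) & tp$onset_day < pmin(tp$death_day, config$admin_censor_day)
  diag$outcome <- data.frame(patient_id = tp$patient_id[ok], condition = outc,
                             true_onset = tp$onset_day[ok], recorded_date = rec[ok],
                             stringsAsFactors = FALSE)

  dd <- do.call(rbind, diag)
  rownames(dd) <- NULL
  stopifnot(all(dd$recorded_date >= dd$true_onset | dd$condition %in% names(comorb)))
  ds$truth$diagnoses <- dd
  ds$diagnoses <- dd[, c("patient_id", "condition", "recorded_date")]
  ds$truth$first_complete <- first_complete
  ds
}

# Generate notes at encounters.  Embedded values are the encounter's own
# measured values (the pre-deletion measurement table), so same-day
# tabular/NLP pairs agree up to unit-conversion rounding; a fraction of
# blood pressures are repeat measurements (a documented source of
# same-day disagreement).
generate_notes <- function(ds, config) {
  enc <- ds$encounters
  cv <- ds$truth$complete_vitals
  pick <- runif(nrow(enc)) < config$note_rate
  e <- enc[pick, ]
  m <- nrow(e)
  if (!m) stop("note generation produced no notes; increase note_rate")
  styles <- sample(names(config$note_styles), m, TRUE,
                   prob = config$note_styles / sum(config$note_styles))
  types <- sample(c("history_and_physical", "discharge_summary",
                    "cardiology", "endoscopy"), m, TRUE,
                  prob = c(0.938, 0.038, 0.023, 0.001))
  embed <- matrix(runif(m * 4) < config$note_embed_p, ncol = 4)
  enc_val <- function(vital) {
    v <- cv[cv$vital == vital, ]
    v$value[match(e$encounter_id, v$encounter_id)]
  }
  repeat_bp <- runif(m) < 0.15
  sbp <- enc_val("sbp"); dbp <- enc_val("dbp")
  sbp[repeat_bp] <- pmax(60, sbp[repeat_bp] + round(rnorm(sum(repeat_bp), 0, 6)))
  dbp[repeat_bp] <- pmax(30, dbp[repeat_bp] + round(rnorm(sum(repeat_bp), 0, 4)))
  vit <- data.frame(
    height = ifelse(embed[, 1], enc_val("height"), NA),
    weight = ifelse(embed[, 2], enc_val("weight"), NA),
    sbp = ifelse(embed[, 3], sbp, NA),
    dbp = ifelse(embed[, 3], dbp, NA),
    style = styles, note_type = types, stringsAsFactors = FALSE)
  out <- render_notes_vec(vit)
  note_id <- sprintf("N%07d", seq_len(m))
  ds$notes <- data.frame(note_id = note_id, patient_id = e$patient_id,
                         date = e$date, note_type = types, text = out$text,
                         stringsAsFactors = FALSE)
  tr <- out$truth
  ds$truth$notes <- data.frame(note_id = note_id[tr$note_row],
                               patient_id = e$patient_id[tr$note_row],
                               date = e$date[tr$note_row],
                               vital = tr$vital, value = tr$value,
                               extractable = tr$extractable,
                               style = styles[tr$note_row],
                               stringsAsFactors = FALSE)
  ds
}

#' Observable tables of a synthetic EHR
#'
#' Returns the dataset without its hidden simulation truth; pipeline
#' stages downstream of the generator consume only these tables.
#'
#' @param ds An `ehr_dataset`.
#' @return The same list minus `truth`.
#' @export
observable_tables <- function(ds) {
  ds$truth <- NULL
  ds
}
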