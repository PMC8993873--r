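#' Primary-care visit registry
#'
#' The rule-based definition of a primary care office visit: a visit
#' procedure code from the registry's CPT-style code set occurring at a
#' registered primary-care location.  Defaults give the synthetic
#' registry used by the simulator.
#'
#' @param cpt_codes Character set of office-visit procedure codes.
#' @param locations Character set of primary-care location ids.
#' @return Object of class `pcp_registry`.
#' @export
pcp_registry <- function(cpt_codes = c("99201", "99202", "99203", "99204",
                                       "99205", "99211", "99212", "99213",
                                       "99214", "99215", "99395", "99396",
                                       "99397"),
                         locations = sprintf("PC%03d", 1:40)) {
  if (!length(cpt_codes) || !length(locations))
    stop("registry code and location sets must be non-empty")
  structure(list(cpt_codes = cpt_codes, locations = locations),
            class = "pcp_registry")
}

#' Flag primary care office visits
#'
#' An encounter is flagged iff its code is in the registry's code set AND
#' its location is registered as primary care.  Unknown codes are simply
#' left unflagged.
#'
#' @param encounters Encounter data frame (`code`, `location_id`).
#' @param registry A [pcp_registry()].
#' @return Logical vector, one element per encounter row.
#' @export
identify_pcp_visits <- function(encounters, registry) {
  encounters$code %in% registry$cpt_codes &
    encounters$location_id %in% registry$locations
}

#' Find the start of follow-up from a patient's primary-care visits
#'
#' Scans flagged visit dates chronologically for the earliest qualifying
#' pair: two primary-care visits 1-3 years apart (closed interval,
#' 365-1095 days).  The start of follow-up is the second visit of the
#' earliest qualifying pair (pairs ordered by second-visit date, ties by
#' first-visit date -- which cannot change the returned date).
#'
#' @param dates Numeric visit dates (days) for one patient.
#' @param min_gap,max_gap Inclusive gap bounds in days.
#' @return The start-of-follow-up date, or `NA` if no pair qualifies.
#' @export
find_qualifying_pair <- function(dates, min_gap = 365, max_gap = 1095) {
  if (length(dates) < 2) return(NA_real_)
  d <- sort(dates)
  n_le_lo <- findInterval(d - min_gap, d)        # visits <= d_j - 365
  n_le_hi <- findInterval(d - max_gap - 1, d)    # visits <= d_j - 1096
  ok <- which(n_le_lo - n_le_hi > 0)
  if (!length(ok)) return(NA_real_)
  d[ok[1]]
}

#' Resolve the end of follow-up
#'
#' Person-time ends at the earliest of: outcome event, death, last
#' encounter of any kind, the date of turning 90, or the administrative
#' censoring date.  All arguments are vectorized; missing termini are
#' ignored (`NA` = not applicable).
#'
#' @param start Start of follow-up (days).
#' @param outcome_day First recorded outcome date (`NA` if none); only
#'   dates strictly after `start` count as events.
#' @param death_day,last_enc_day,age90_day,admin_censor_day Candidate
#'   termini (days).
#' @return Data frame `end`, `time_years`, `event` (0/1), `end_reason`
#'   (`event`, `death`, `last_encounter`, `age_90`, `administrative`).
#' @export
define_followup_interval <- function(start, outcome_day, death_day,
                                     last_enc_day, age90_day,
                                     admin_censor_day) {
  outcome_day[!is.na(outcome_day) & outcome_day <= start] <- NA
  cand <- cbind(event = outcome_day, death = death_day,
                last_encounter = last_enc_day, age_90 = age90_day,
                administrative = admin_censor_day)
  cand[is.na(cand)] <- Inf
  end <- do.call(pmin, as.data.frame(cand))
  reason <- colnames(cand)[max.col(-cand, ties.method = "first")]
  if (any(end < start)) stop("end of follow-up precedes start")
  data.frame(end = end, time_years = (end - start) / 365.25,
             event = as.integer(reason == "event"),
             end_reason = reason, stringsAsFactors = FALSE)
}

first_outcome_day <- function(diagnoses, outcome) {
  d <- diagnoses[diagnoses$condition == outcome, ]
  tapply(d$recorded_date, d$patient_id, min)
}

followup_members <- function(ds, starts, outcome, admin_censor_day) {
  pats <- ds$patients
  m <- match(names(starts), pats$patient_id)
  age_at_start <- (as.numeric(starts) - pats$birth_day[m]) / 365.25
  # age range and demographic completeness must hold before interval
  # resolution (age-90 censoring is undefined past age 90)
  keep <- age_at_start >= 18 & age_at_start < 90 &
    !is.na(pats$sex[m]) & !is.na(pats$race[m])
  starts <- starts[keep]; m <- m[keep]; age_at_start <- age_at_start[keep]
  if (!length(starts)) return(empty_members())
  out_day <- first_outcome_day(ds$diagnoses, outcome)[names(starts)]
  last_enc <- tapply(ds$encounters$date, ds$encounters$patient_id, max)[names(starts)]
  age90 <- pats$birth_day[m] + round(90 * 365.25)
  fi <- define_followup_interval(as.numeric(starts), as.numeric(out_day),
                                 pats$death_day[m], as.numeric(last_enc),
                                 age90, admin_censor_day)
  data.frame(patient_id = names(starts), start = as.numeric(starts),
             end = fi$end, time_years = fi$time_years, event = fi$event,
             end_reason = fi$end_reason, age_at_start = age_at_start,
             sex = pats$sex[m], race = pats$race[m],
             outcome_day = as.numeric(out_day),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the longitudinal primary-care cohort
#'
#' Cohort entry requires at least one pair of flagged primary-care visits
#' 1-3 years apart; follow-up starts at the second visit of the earliest
#' qualifying pair.  Individuals aged <18 or >=90 at start, or with
#' missing demographics, are removed; zero-length follow-up drops the
#' member.  Cohort entry uses encounters only (notes play no role).
#'
#' @param ds An `ehr_dataset` (observable tables are sufficient).
#' @param registry A [pcp_registry()].
#' @param admin_censor_day Administrative censoring date (days).
#' @param outcome Outcome condition for event/censoring resolution
#'   (defaults to the generator's true model outcome).
#' @return Data frame of cohort members with follow-up interval, event
#'   indicator, end reason, age and demographics at start.
#' @export
build_longitudinal_cohort <- function(ds, registry = ds$registry,
                                      admin_censor_day = ds$config$admin_censor_day,
                                      outcome = score_definition(ds$config$true_model)$outcome) {
  enc <- ds$encounters
  flagged <- identify_pcp_visits(enc, registry)
  pcp <- enc[flagged, ]
  starts <- tapply(pcp$date, pcp$patient_id, find_qualifying_pair)
  starts <- starts[!is.na(starts)]
  if (!length(starts)) return(empty_members())
  mem <- followup_members(ds, starts, outcome, admin_censor_day)
  mem <- mem[mem$time_years > 0, ]
  rownames(mem) <- NULL
  mem
}

empty_members <- function() {
  data.frame(patient_id = character(0), start = numeric(0), end = numeric(0),
             time_years = numeric(0), event = integer(0),
             end_reason = character(0), age_at_start = numeric(0),
             sex = character(0), race = character(0),
             outcome_day = numeric(0), stringsAsFactors = FALSE)
}

#' Build a complete-data convenience sample
#'
#' Follow-up starts at the earliest date at which every measured score
#' component has a tabular value dated within the preceding 3 years
#' (height, when a component, is exempt from the window: any earlier
#' value qualifies).  Candidate start dates are evaluated only at
#' measurement dates.  Individuals with no follow-up of any kind (last
#' encounter on the start date), with the outcome recorded on or before
#' the start, aged outside 18-90, or with missing demographics are
#' excluded.
#'
#' @param ds An `ehr_dataset`.
#' @param score A `score_definition` (defines the component list).
#' @param admin_censor_day Administrative censoring date (days).
#' @return Data frame of members, same shape as
#'   [build_longitudinal_cohort()].
#' @export
build_convenience_sample <- function(ds, score,
                                     admin_censor_day = ds$config$admin_censor_day) {
  tab <- rbind(ds$vitals[, c("patient_id", "date", "vital")],
               ds$labs[, c("patient_id", "date", "vital")])
  comp <- score$components
  tab <- tab[tab$vital %in% comp, ]
  windowed <- setdiff(comp, "height")
  by_pat <- split(tab[, c("date", "vital")], tab$patient_id)
  starts <- vapply(by_pat, function(g) {
    if (length(unique(g$vital)) < length(comp)) return(NA_real_)
    dl <- lapply(comp, function(v) sort(g$date[g$vital == v]))
    names(dl) <- comp
    D <- sort(unique(g$date))
    ok <- rep(TRUE, length(D))
    for (v in windowed) {
      ok <- ok & (findInterval(D, dl[[v]]) - findInterval(D - 1096, dl[[v]]) > 0)
    }
    if ("height" %in% comp) ok <- ok & findInterval(D, dl[["height"]]) > 0
    if (!any(ok)) return(NA_real_)
    D[which(ok)[1]]
  }, numeric(1))
  starts <- starts[!is.na(starts)]
  if (!length(starts)) return(empty_members())
  mem <- followup_members(ds, starts, score$outcome, admin_censor_day)
  prevalent <- !is.na(mem$outcome_day) & mem$outcome_day <= mem$start
  mem <- mem[!prevalent, ]
  mem <- mem[mem$time_years > 0, ]
  rownames(mem) <- NULL
  mem
}
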