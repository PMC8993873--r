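#' Configuration of the end-to-end bias experiment
#'
#' @param sim A [sim_config()].
#' @param registry A [pcp_registry()].
#' @param score_name Risk score to deploy (defaults to the generator's
#'   true model).
#' @param mode PCE deployment mode.
#' @param n_groups Calibration groups for the GND test.
#' @param n_boot Bootstrap iterations for sample comparisons.
#' @param n_boot_ici Bootstrap iterations for ICI confidence intervals
#'   (0 = point estimates only).
#' @param use_nlp Whether the longitudinal cohort uses NLP-recovered
#'   vitals (convenience samples never do).
#' @param thresholds Risk-stratification thresholds; defaults to the
#'   guideline thresholds (2.5%/5% for AF, 7.5% for MI/stroke).
#' @param seed Seed for all evaluation-stage randomness (bootstraps).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(),
                              registry = pcp_registry(),
                              score_name = sim$true_model,
                              mode = "primary",
                              n_groups = 10,
                              n_boot = 200,
                              n_boot_ici = 0,
                              use_nlp = TRUE,
                              thresholds = NULL,
                              seed = sim$seed) {
  if (is.null(thresholds))
    thresholds <- if (score_name == "charge_af") c(0.025, 0.05) else 0.075
  structure(as.list(environment()), class = "experiment_config")
}

# Score + evaluate one member table; returns records and per-stratum
# evaluation reports.
score_and_evaluate <- function(members, score, cfg) {
  elig <- check_eligibility(members, score)
  records <- members[elig$eligible, , drop = FALSE]
  excl <- table(elig$reasons[!elig$eligible])
  h <- score$horizon
  strata <- intersect(names(score$strata), unique(records$stratum))
  evals <- list()
  for (s in strata) {
    r <- records[records$stratum == s, ]
    if (sum(r$event == 1 & r$time_years <= h) < 10) next
    th <- at_horizon(r$time_years, r$event, h)
    km <- km_cumulative_risk(th$time, th$event, h)
    inc <- incidence_rate(th$time, th$event)
    hr <- cox_hr_per_sd(th$time, th$event, r$lp)
    cidx <- ipcw_cindex(th$time, th$event, r$risk, h)
    gnd <- gnd_test(th$time, th$event, r$risk, h, cfg$n_groups)
    ic <- suppressWarnings(ici(th$time, th$event, r$risk, h,
                               n_boot = cfg$n_boot_ici, seed = cfg$seed))
    sl <- calibration_slope(th$time, th$event, r$risk)
    rec <- recalibrate_baseline(score, data.frame(stratum = r$stratum, lp = r$lp,
                                                  time_years = th$time,
                                                  event = th$event))
    p2 <- predicted_risk(r$lp, rec$strata[[s]]$s0, rec$strata[[s]]$mean_lp)
    gnd2 <- gnd_test(th$time, th$event, p2, h, cfg$n_groups)
    ic2 <- suppressWarnings(ici(th$time, th$event, p2, h,
                                n_boot = cfg$n_boot_ici, seed = cfg$seed))
    early <- sum(th$event == 1 & th$time <= 90 / 365.25) /
      max(1, sum(th$event == 1))
    strat_km <- suppressWarnings(
      risk_stratified_km(th$time, th$event, r$risk, cfg$thresholds, h))
    evals[[s]] <- list(
      n = nrow(r), events = inc$events,
      km_risk = km, incidence = inc,
      discrimination = list(hr_per_sd = hr, c_index = cidx),
      calibration = list(gnd = gnd[c("chi2", "p_value", "df", "n_groups")],
                         ici = ic, slope = sl),
      recalibrated = list(gnd = gnd2[c("chi2", "p_value", "df", "n_groups")],
                          ici = ic2,
                          s0 = rec$strata[[s]]$s0,
                          mean_lp = rec$strata[[s]]$mean_lp),
      early_event_fraction = early,
      risk_strata = strat_km$table)
  }
  list(records = records, evals = evals, excluded = excl,
       n_members = nrow(members), n_eligible = nrow(records))
}

#' Run the end-to-end sampling-bias experiment
#'
#' Simulates one EHR, builds the longitudinal primary-care cohort and the
#' complete-data convenience sample from its observable tables, recovers
#' vitals from notes (cohort only), computes the deployed risk score,
#' evaluates discrimination and calibration in each sample (original and
#' recalibrated-in-the-large), and compares calibration between samples
#' by bootstrap.
#'
#' @param cfg An [experiment_config()].
#' @return Object of class `bias_report`: list with elements `score`,
#'   `samples` (per-sample per-stratum evaluations and accounting),
#'   `comparison` (per-stratum ICI/slope differences with bootstrap
#'   p-values), `agreement` (tabular-vs-NLP Bland-Altman per vital),
#'   `nlp_yield` (complete-score counts with and without NLP), and
#'   `measured_comorbidity` (per-sample prevalence of recorded
#'   comorbidities).
#' @export
run_bias_experiment <- function(cfg = experiment_config()) {
  score <- score_definition(cfg$score_name, cfg$mode)
  ds <- simulate_ehr(cfg$sim, cfg$registry)
  obs <- observable_tables(ds)
  nlp <- extract_vitals(obs$notes)

  coh <- build_longitudinal_cohort(obs, cfg$registry,
                                   cfg$sim$admin_censor_day, score$outcome)
  cnv <- build_convenience_sample(obs, score, cfg$sim$admin_censor_day)

  resolve_score <- function(members, nlp_values) {
    members <- resolve_baseline(obs, members, nlp_values, score$outcome)
    sc <- compute_linear_predictor(members, score)
    members$stratum <- sc$stratum; members$lp <- sc$lp; members$risk <- sc$risk
    members
  }
  coh_nlp <- resolve_score(coh, if (cfg$use_nlp) nlp else NULL)
  coh_tab <- resolve_score(coh, NULL)
  cnv_tab <- resolve_score(cnv, NULL)

  ev_coh <- score_and_evaluate(coh_nlp, score, cfg)
  ev_coh_tab <- score_and_evaluate(coh_tab, score, cfg)
  ev_cnv <- score_and_evaluate(cnv_tab, score, cfg)

  h <- score$horizon
  comparison <- list()
  for (s in intersect(names(ev_coh$evals), names(ev_cnv$evals))) {
    ra <- ev_coh$records[ev_coh$records$stratum == s, ]
    rb <- ev_cnv$records[ev_cnv$records$stratum == s, ]
    ta <- at_horizon(ra$time_years, ra$event, h)
    tb <- at_horizon(rb$time_years, rb$event, h)
    comparison[[s]] <- compare_samples(
      data.frame(time = ta$time, event = ta$event, p = ra$risk),
      data.frame(time = tb$time, event = tb$event, p = rb$risk),
      h, n_boot = cfg$n_boot, seed = cfg$seed)
    comparison[[s]]$draws <- NULL
  }

  agreement <- compute_agreement(
    obs$vitals[, c("patient_id", "date", "vital", "value")],
    nlp[, c("patient_id", "date", "vital", "value")],
    data.frame(patient_id = coh$patient_id, start = coh$start))

  complete_for <- function(members) {
    comps <- score$components
    sum(Reduce(`&`, lapply(comps, function(v) !is.na(members[[v]]))))
  }
  nlp_yield <- data.frame(
    sample = "cohort",
    n_complete_tabular = complete_for(coh_tab),
    n_complete_with_nlp = complete_for(coh_nlp),
    n_members = nrow(coh), stringsAsFactors = FALSE)

  comorb_prev <- function(m) {
    vapply(c("smoker", "bp_treated", "diabetes", "heart_failure", "prior_mi"),
           function(v) mean(m[[v]]), numeric(1))
  }
  measured_comorbidity <- rbind(
    cohort = comorb_prev(ev_coh$records),
    convenience = comorb_prev(ev_cnv$records))

  structure(list(
    score = cfg$score_name, mode = cfg$mode, horizon = h,
    n_population = nrow(obs$patients),
    samples = list(cohort = ev_coh, cohort_no_nlp = ev_coh_tab,
                   convenience = ev_cnv),
    comparison = comparison,
    agreement = agreement,
    nlp_yield = nlp_yield,
    measured_comorbidity = measured_comorbidity,
    config = cfg), class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat("Sampling-bias experiment:", x$score, "(horizon", x$horizon, "y)\n")
  cat("Population:", x$n_population, "patients\n")
  for (nm in names(x$samples)) {
    s <- x$samples[[nm]]
    cat(sprintf("\n== %s: %d members, %d eligible ==\n",
                nm, s$n_members, s$n_eligible))
    for (st in names(s$evals)) {
      e <- s$evals[[st]]
      cat(sprintf(
        paste0("  [%s] n=%d ev=%d | inc %.1f/1000py | risk %.3f | ",
               "HR/SD %.2f | c %.3f | GND %.0f | ICI %.4f | slope %.2f | ",
               "recal ICI %.4f | early-ev %.3f\n"),
        st, e$n, e$events, e$incidence$rate, e$km_risk$risk,
        e$discrimination$hr_per_sd$hr, e$discrimination$c_index$c_index,
        e$calibration$gnd$chi2, e$calibration$ici$ici,
        e$calibration$slope$slope, e$recalibrated$ici$ici,
        e$early_event_fraction))
    }
  }
  for (st in names(x$comparison)) {
    cm <- x$comparison[[st]]
    cat(sprintf(
      "\ncomparison [%s]: ICI diff %.4f (p=%.3f), slope diff %.3f (p=%.3f)\n",
      st, cm$ici_diff, cm$ici_p, cm$slope_diff, cm$slope_p))
  }
  invisible(x)
}
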