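#' Load a clinical risk score definition
#'
#' Builds a `score_definition` for the CHARGE-AF score (5-year incident
#' atrial fibrillation) or the Pooled Cohort Equations (PCE; 10-year
#' MI/stroke).  Coefficients, centering constants (mean linear predictor),
#' and baseline survival at the horizon are read from versioned CSV files
#' shipped with the package, sourced from the scores' original publications.
#'
#' The PCE comprise four sex- and race-stratified submodels.  In the
#' `"primary"` deployment mode the Black equations are used for Black
#' individuals and the White equations for individuals of all other races;
#' in the `"white_only"` mode the White equations are restricted to White
#' individuals and everyone else is marked ineligible.  CHARGE-AF is a
#' single model whose White-race indicator is 1 only for White individuals.
#'
#' @param name `"charge_af"` or `"pce"`.
#' @param mode PCE deployment mode, `"primary"` or `"white_only"`.
#' @param charge_af_age_range Published age range applied at eligibility.
#'   The primary analysis uses `c(46, 90)`; `c(45, 94)` is also in
#'   circulation and is accepted here as an option.
#' @return An object of class `score_definition`: a list with elements
#'   `name`, `mode`, `horizon` (years), `age_range`, `outcome`
#'   (`"af"` or `"mi_stroke"`), `components` (measured covariates the
#'   sample-construction rules require), and `strata`, a named list with
#'   per-stratum `beta` (named coefficient vector), `mean_lp`, and `s0`.
#' @export
score_definition <- function(name = c("charge_af", "pce"),
                             mode = c("primary", "white_only"),
                             charge_af_age_range = c(46, 90)) {
  name <- match.arg(name)
  mode <- match.arg(mode)
  coef_file <- if (name == "charge_af") "charge_af_coefficients.csv" else "pce_coefficients.csv"
  coefs <- read.csv(system.file("extdata", coef_file, package = "ehrbias"),
                    stringsAsFactors = FALSE)
  meta <- read.csv(system.file("extdata", "score_meta.csv", package = "ehrbias"),
                   stringsAsFactors = FALSE)
  meta <- meta[meta$score == name, , drop = FALSE]
  strata <- lapply(seq_len(nrow(meta)), function(i) {
    s <- meta$stratum[i]
    b <- coefs[coefs$stratum == s, ]
    list(beta = setNames(b$beta, b$term),
         mean_lp = meta$mean_lp[i],
         s0 = meta$s0[i])
  })
  names(strata) <- meta$stratum
  age_range <- if (name == "charge_af") charge_af_age_range else c(40, 79)
  components <- if (name == "charge_af") {
    c("height", "weight", "sbp", "dbp")
  } else {
    c("sbp", "tc", "hdl")
  }
  structure(list(name = name, mode = mode,
                 horizon = meta$horizon_years[1],
                 age_range = age_range,
                 outcome = if (name == "charge_af") "af" else "mi_stroke",
                 components = components,
                 strata = strata),
            class = "score_definition")
}

#' Assign each subject to a score stratum
#'
#' @param sex Character vector, `"female"`/`"male"`.
#' @param race Character vector of self-identified race groups
#'   (`"white"`, `"black"`, `"hispanic"`, `"asian"`, `"other"`, ...).
#' @param score A `score_definition`.
#' @return Character vector of stratum names; `NA` where the deployment
#'   mode leaves the subject without an applicable submodel
#'   (only possible in PCE `"white_only"` mode).
#' @export
assign_stratum <- function(sex, race, score) {
  if (score$name == "charge_af") return(rep("all", length(sex)))
  bad <- is.na(sex) | !(sex %in% c("female", "male"))
  if (any(bad)) stop("unknown sex category; PCE strata are sex-specific")
  race_grp <- ifelse(race == "black", "black", "white")
  out <- paste0(race_grp, "_", sex)
  if (score$mode == "white_only") {
    out[race != "black" & race != "white"] <- NA_character_
  }
  out
}

# Per-score covariate transforms.  Each returns a matrix with one column per
# coefficient term; rows with missing covariates propagate NA.
charge_af_design <- function(d) {
  cbind(age_per5 = d$age / 5,
        race_white = as.numeric(d$race == "white"),
        height_per10 = d$height / 10,
        weight_per15 = d$weight / 15,
        sbp_per20 = d$sbp / 20,
        dbp_per10 = d$dbp / 10,
        smoker = as.numeric(d$smoker),
        bp_treated = as.numeric(d$bp_treated),
        diabetes = as.numeric(d$diabetes),
        heart_failure = as.numeric(d$heart_failure),
        prior_mi = as.numeric(d$prior_mi))
}

pce_design <- function(d) {
  la <- log(d$age); lt <- log(d$tc); lh <- log(d$hdl); ls <- log(d$sbp)
  trt <- as.numeric(d$bp_treated)
  smk <- as.numeric(d$smoker)
  cbind(ln_age = la, ln_age_sq = la^2,
        ln_tc = lt, ln_age_ln_tc = la * lt,
        ln_hdl = lh, ln_age_ln_hdl = la * lh,
        ln_sbp_treated = ls * trt,
        ln_age_ln_sbp_treated = la * ls * trt,
        ln_sbp_untreated = ls * (1 - trt),
        ln_age_ln_sbp_untreated = la * ls * (1 - trt),
        smoker = smk, ln_age_smoker = la * smk,
        diabetes = as.numeric(d$diabetes))
}

#' Compute score linear predictors
#'
#' Evaluates the published linear predictor for each subject in `data`
#' within the stratum given by [assign_stratum()].  Transforms (per-5-year
#' age, log terms, treatment interactions) are applied here; coefficients
#' come from the `score_definition`.
#'
#' @param data Data frame of baseline covariates: `age`, `sex`, `race`,
#'   and, as required by the score, `height` (cm), `weight` (kg), `sbp`,
#'   `dbp` (mmHg), `tc`, `hdl` (mg/dL), and the 0/1 indicators `smoker`,
#'   `bp_treated`, `diabetes`, `heart_failure`, `prior_mi`.
#' @param score A `score_definition`.
#' @return Data frame with `stratum`, `lp`, and `risk` (predicted event
#'   probability at the score horizon, `1 - s0^exp(lp - mean_lp)`).
#'   `lp` is `NA` where a required covariate is missing or no stratum
#'   applies.
#' @export
compute_linear_predictor <- function(data, score) {
  stratum <- assign_stratum(data$sex, data$race, score)
  X <- if (score$name == "charge_af") charge_af_design(data) else pce_design(data)
  if (any(is.nan(X) | is.infinite(X))) {
    bad <- colnames(X)[apply(X, 2, function(v) any(is.nan(v) | is.infinite(v)))]
    stop("non-finite covariate transform: ", paste(bad, collapse = ", "))
  }
  lp <- rep(NA_real_, nrow(data))
  risk <- rep(NA_real_, nrow(data))
  for (s in names(score$strata)) {
    idx <- which(stratum == s)
    if (!length(idx)) next
    st <- score$strata[[s]]
    Xs <- X[idx, names(st$beta), drop = FALSE]
    lp[idx] <- as.vector(Xs %*% st$beta)
    risk[idx] <- predicted_risk(lp[idx], st$s0, st$mean_lp)
  }
  data.frame(stratum = stratum, lp = lp, risk = risk,
             stringsAsFactors = FALSE)
}

#' Convert a linear predictor to a predicted event probability
#'
#' `p = 1 - s0 ^ exp(lp - mean_lp)`, the standard survival-score risk
#' equation with baseline survival `s0` at the horizon and centering
#' constant `mean_lp`.
#'
#' @param lp Linear predictor(s).
#' @param s0 Baseline survival at the horizon, in (0, 1).
#' @param mean_lp Centering constant (derivation-cohort mean LP).
#' @return Predicted risk in (0, 1).
#' @export
predicted_risk <- function(lp, s0, mean_lp) {
  stopifnot(s0 > 0, s0 < 1)
  1 - s0^exp(lp - mean_lp)
}

#' Check score eligibility
#'
#' Applies the deployment restrictions: age within the published range at
#' the start of follow-up, no prevalent outcome, all required covariates
#' resolved, positive follow-up, and an applicable stratum.
#'
#' @param members Data frame with `age_at_start`, `prevalent_outcome`,
#'   `time_years`, baseline covariates, and (from scoring) `lp`.
#' @param score A `score_definition`.
#' @return Data frame with logical `eligible` and a character `reasons`
#'   column (`;`-separated reason codes, empty when eligible).
#' @export
check_eligibility <- function(members, score) {
  n <- nrow(members)
  reasons <- vector("list", n)
  add <- function(flag, code) {
    for (i in which(flag)) reasons[[i]] <<- c(reasons[[i]], code)
  }
  add(members$age_at_start < score$age_range[1] |
        members$age_at_start >= score$age_range[2], "age_out_of_range")
  add(!is.na(members$prevalent_outcome) & members$prevalent_outcome, "prevalent_outcome")
  add(is.na(members$lp), "missing_covariate_or_stratum")
  add(is.na(members$time_years) | members$time_years <= 0, "zero_followup")
  data.frame(eligible = vapply(reasons, function(r) length(r) == 0, logical(1)),
             reasons = vapply(reasons, paste, character(1), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Recalibrate a score to a sample's baseline hazard
#'
#' Recalibration-in-the-large: within each stratum the baseline survival
#' `s0` is replaced by the sample's own baseline survival at the score
#' horizon -- estimated by the Breslow cumulative hazard of a Cox model
#' with the (sample-mean-centered) linear predictor as a fixed offset --
#' and the centering constant by the sample mean linear predictor.
#' Relative risks (and hence rank-based discrimination) are unchanged;
#' on a sample generated from the score's own baseline this recovers
#' `s0` up to sampling error.  The original definition is not modified.
#'
#' @param score A `score_definition`.
#' @param records Data frame with `stratum`, `lp`, `time_years`, `event`
#'   for the analysis sample.
#' @return A new `score_definition` with updated `s0`/`mean_lp` per
#'   stratum present in `records`.
#' @export
recalibrate_baseline <- function(score, records) {
  out <- score
  for (s in unique(records$stratum)) {
    if (is.na(s)) next
    r <- records[!is.na(records$stratum) & records$stratum == s, ]
    if (sum(r$event) < 1) stop("recalibration requires at least one event in stratum ", s)
    off <- r$lp - mean(r$lp)
    fit <- survival::coxph(survival::Surv(time_years, event) ~ offset(off),
                           data = r)
    bh <- survival::basehaz(fit, centered = FALSE)
    idx <- findInterval(score$horizon, bh$time)
    H0 <- if (idx == 0) 0 else bh$hazard[idx]
    s0_new <- exp(-H0)
    if (s0_new <= 0 || s0_new >= 1) stop("degenerate baseline survival in stratum ", s)
    out$strata[[s]]$s0 <- s0_new
    out$strata[[s]]$mean_lp <- mean(r$lp)
  }
  out
}
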