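#' Truncate survival records at a score horizon
#'
#' @param time Follow-up times (years).
#' @param event 0/1 event indicators.
#' @param horizon Horizon (years).
#' @return Data frame `time`, `event` with follow-up capped at the
#'   horizon (events after the horizon become censorings at the horizon).
#' @export
at_horizon <- function(time, event, horizon) {
  data.frame(time = pmin(time, horizon),
             event = as.integer(event == 1 & time <= horizon))
}

#' Kaplan-Meier cumulative risk at a time point
#'
#' `1 - S(t)` from the Kaplan-Meier estimator, with a Greenwood-variance
#' confidence interval on the complementary log-log scale (boundary
#' respecting).
#'
#' @param time,event Survival records.
#' @param t Evaluation time (years), > 0.
#' @param conf_level Confidence level.
#' @return List `risk`, `lower`, `upper`, `n_events` (events by `t`).
#' @export
km_cumulative_risk <- function(time, event, t, conf_level = 0.95) {
  if (!length(time)) stop("empty input")
  stopifnot(t > 0)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          conf.type = "log-log", conf.int = conf_level)
  sm <- summary(sf, times = t, extend = TRUE)
  risk <- 1 - sm$surv
  # cloglog CI for S reverses order under 1 - S
  lower <- 1 - sm$upper
  upper <- 1 - sm$lower
  if (sum(event) == 0) lower <- upper <- risk
  list(risk = risk, lower = lower, upper = upper,
       n_events = sum(event[time <= t]))
}

#' Incidence rate per 1000 person-years with Wald CI
#'
#' `rate = 1000 * events / person-years`; the Wald interval uses the
#' normal approximation `rate +/- 1.96 * 1000 * sqrt(events) /
#' person-years`.
#'
#' @param time,event Survival records.
#' @return List `rate`, `lower`, `upper`, `events`, `person_years`.
#' @export
incidence_rate <- function(time, event) {
  py <- sum(time)
  if (py <= 0) stop("zero person-time")
  ev <- sum(event)
  rate <- 1000 * ev / py
  if (ev == 0) {
    warning("zero events; degenerate Wald interval")
    return(list(rate = 0, lower = 0, upper = 0, events = 0, person_years = py))
  }
  half <- qnorm(0.975) * 1000 * sqrt(ev) / py
  list(rate = rate, lower = rate - half, upper = rate + half,
       events = ev, person_years = py)
}

#' Hazard ratio per 1-SD of a risk score
#'
#' Cox proportional-hazards fit (Efron ties) with the standardized linear
#' predictor as the only covariate.
#'
#' @param time,event Survival records.
#' @param lp Linear predictor (positive variance required).
#' @return List `hr`, `lower`, `upper`, `beta`, `se`.
#' @export
cox_hr_per_sd <- function(time, event, lp) {
  if (sd(lp) == 0) stop("linear predictor has zero variance")
  if (sum(event) == 0) stop("no events")
  z <- (lp - mean(lp)) / sd(lp)
  fit <- survival::coxph(survival::Surv(time, event) ~ z, ties = "efron")
  b <- unname(coef(fit)); se <- sqrt(unname(vcov(fit)[1, 1]))
  list(hr = exp(b), lower = exp(b - qnorm(0.975) * se),
       upper = exp(b + qnorm(0.975) * se), beta = b, se = se)
}

# Left-continuous KM estimate of the censoring survival G(t-).
censoring_km <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  function(t) {
    # G evaluated just before t
    idx <- findInterval(t - 1e-9, sf$time)
    c(1, sf$surv)[idx + 1]
  }
}

#' IPCW (Uno) concordance index
#'
#' Truncated inverse-probability-of-censoring-weighted concordance:
#' comparable pairs `(i, j)` have an observed event at `t_i < horizon`
#' with `t_j > t_i`; each pair is weighted by `G(t_i-)^-2` where `G` is
#' the Kaplan-Meier estimate of the censoring distribution.  Ties in the
#' predictions count 1/2.  The optional confidence interval is a
#' patient-resampling bootstrap (percentile).
#'
#' @param time,event Survival records.
#' @param p Risk predictions (higher = higher risk).
#' @param horizon Truncation time (years).
#' @param n_boot Bootstrap iterations for the CI (0 = point estimate
#'   only).
#' @param seed Bootstrap seed.
#' @return List `c_index`, and with `n_boot > 0` also `lower`, `upper`.
#' @export
ipcw_cindex <- function(time, event, p, horizon = Inf, n_boot = 0, seed = 1) {
  est <- function(time, event, p) {
    ev <- which(event == 1 & time < horizon)
    if (!length(ev)) stop("no comparable pairs")
    G <- censoring_km(time, event)
    w <- 1 / G(time[ev])^2
    num <- 0; den <- 0
    chunk <- 128L   # bounds the outer() working set at ~20 MB for n = 20k
    for (k in seq(1, length(ev), by = chunk)) {
      ii <- ev[k:min(k + chunk - 1L, length(ev))]
      cmp <- outer(time[ii], time, "<")                    # comparable pairs
      conc <- outer(p[ii], p, ">") + 0.5 * outer(p[ii], p, "==")
      wk <- w[match(ii, ev)]
      num <- num + sum(wk * rowSums(cmp * conc))
      den <- den + sum(wk * rowSums(cmp))
    }
    if (den == 0) stop("no comparable pairs")
    num / den
  }
  out <- list(c_index = est(time, event, p))
  if (n_boot > 0) {
    set.seed(seed)
    n <- length(time)
    bs <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      tryCatch(est(time[i], event[i], p[i]), error = function(e) NA_real_)
    }, numeric(1))
    qs <- quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    out$lower <- qs[1]; out$upper <- qs[2]
  }
  out
}

#' Kaplan-Meier cumulative risk stratified by predicted risk
#'
#' Splits subjects at the supplied ascending risk thresholds and returns
#' per-stratum cumulative-risk curves with at-risk counts, plus a summary
#' table at the horizon.  Empty strata are omitted with a warning.
#'
#' @param time,event Survival records.
#' @param p Predicted risks.
#' @param thresholds Ascending thresholds in (0, 1).
#' @param horizon Summary horizon (years).
#' @return List `curves` (data frame `stratum`, `time`, `risk`,
#'   `n_risk`), `table` (per-stratum n, events, KM risk at horizon).
#' @export
risk_stratified_km <- function(time, event, p, thresholds, horizon) {
  stopifnot(all(diff(thresholds) > 0), all(thresholds > 0 & thresholds < 1))
  brk <- c(-Inf, thresholds, Inf)
  lab <- c(paste0("<", thresholds[1] * 100, "%"),
           if (length(thresholds) > 1)
             paste0(">=", thresholds[-length(thresholds)] * 100, "-",
                    thresholds[-1] * 100, "%"),
           paste0(">=", thresholds[length(thresholds)] * 100, "%"))
  g <- cut(p, brk, labels = lab, right = FALSE)
  empty <- setdiff(lab, unique(as.character(g)))
  if (length(empty)) warning("empty risk strata omitted: ",
                             paste(empty, collapse = ", "))
  curves <- list(); tab <- list()
  for (s in intersect(lab, unique(as.character(g)))) {
    i <- which(g == s)
    sf <- survival::survfit(survival::Surv(time[i], event[i]) ~ 1)
    curves[[s]] <- data.frame(stratum = s, time = sf$time,
                              risk = 1 - sf$surv, n_risk = sf$n.risk,
                              stringsAsFactors = FALSE)
    km <- km_cumulative_risk(time[i], event[i], horizon)
    tab[[s]] <- data.frame(stratum = s, n = length(i),
                           events = sum(event[i] & time[i] <= horizon),
                           risk_at_horizon = km$risk, stringsAsFactors = FALSE)
  }
  list(curves = do.call(rbind, c(curves, make.row.names = FALSE)),
       table = do.call(rbind, c(tab, make.row.names = FALSE)))
}
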