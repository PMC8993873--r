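cloglog <- function(p) log(-log(1 - pmin(pmax(p, 1e-10), 1 - 1e-10)))

#' Greenwood-Nam-D'Agostino calibration test
#'
#' Groups subjects by quantiles of predicted risk (deciles by default),
#' estimates the observed risk in each group by Kaplan-Meier at the
#' horizon with its Greenwood variance, and forms
#' `chi^2 = sum_g (observed_g - mean predicted_g)^2 / var_g` with
#' `df = groups - 1`.  Groups with fewer than 5 events are merged into
#' the adjacent (lower, else upper) group before the statistic is
#' computed.  Larger chi-squared / smaller p indicates miscalibration.
#'
#' @param time,event Survival records.
#' @param p Predicted risks at the horizon.
#' @param horizon Horizon (years).
#' @param n_groups Initial number of quantile groups (>= 2).
#' @return List `chi2`, `p_value`, `df`, `n_groups` (after merging), and
#'   `groups`: per-group n, events, mean predicted, KM observed,
#'   Greenwood variance.
#' @export
gnd_test <- function(time, event, p, horizon, n_groups = 10) {
  stopifnot(n_groups >= 2)
  brk <- unique(quantile(p, probs = seq(0, 1, length.out = n_groups + 1)))
  g <- as.integer(cut(p, brk, include.lowest = TRUE))
  # merge groups with <5 events into the adjacent group
  repeat {
    ev <- tapply(as.integer(event == 1 & time <= horizon), g, sum)
    ids <- as.integer(names(ev))
    small <- ids[ev < 5]
    if (!length(small) || length(ids) <= 2) break
    s <- small[1]
    nb <- if (any(ids < s)) max(ids[ids < s]) else min(ids[ids > s])
    g[g == s] <- nb
  }
  ids <- sort(unique(g))
  if (length(ids) < 2) stop("fewer than 2 groups remain after merging")
  rows <- lapply(ids, function(k) {
    i <- which(g == k)
    sf <- survival::survfit(survival::Surv(time[i], event[i]) ~ 1)
    sm <- summary(sf, times = horizon, extend = TRUE)
    obs <- 1 - sm$surv
    v <- sm$std.err^2          # Greenwood variance of S (= var of 1 - S)
    data.frame(group = k, n = length(i),
               events = sum(event[i] == 1 & time[i] <= horizon),
               predicted = mean(p[i]), observed = obs, var = v)
  })
  tab <- do.call(rbind, rows)
  if (any(tab$var <= 0)) stop("degenerate Greenwood variance in a group")
  chi2 <- sum((tab$observed - tab$predicted)^2 / tab$var)
  df <- nrow(tab) - 1
  list(chi2 = chi2, p_value = pchisq(chi2, df, lower.tail = FALSE),
       df = df, n_groups = nrow(tab), groups = tab)
}

# Smooth observed-risk curve: proportional-hazards regression of the
# outcome on a natural cubic spline of cloglog(p), evaluated at the
# horizon.  Returns per-subject smoothed observed risk.
smooth_observed <- function(time, event, p, horizon, knots = c(0.05, 0.35, 0.65, 0.95)) {
  x <- cloglog(p)
  q <- quantile(x, knots, names = FALSE)
  if (length(unique(q)) < length(q) || sd(x) < 1e-8) stop("degenerate predictions")
  B <- splines::ns(x, knots = q[2:3], Boundary.knots = q[c(1, 4)])
  fit <- survival::coxph(survival::Surv(time, event) ~ B, ties = "efron")
  bh <- survival::basehaz(fit, centered = FALSE)
  idx <- findInterval(horizon, bh$time)
  H0 <- if (idx == 0) 0 else bh$hazard[idx]
  eta <- as.vector(B %*% coef(fit))
  1 - exp(-H0 * exp(eta))
}

#' Integrated calibration index
#'
#' Mean absolute difference between predicted risk and a smoothed
#' observed-risk curve (flexible proportional-hazards regression on a
#' natural cubic spline of `cloglog(p)`, evaluated at the horizon),
#' averaged over the empirical distribution of predicted risk.  If the
#' curve cannot be fitted (e.g. near-constant predictions) the index
#' falls back to `|mean comparison|` against the overall Kaplan-Meier
#' risk, with a warning.  The CI is a percentile bootstrap over patients
#' with a fixed seed.
#'
#' @param time,event Survival records.
#' @param p Predicted risks at the horizon.
#' @param horizon Horizon (years).
#' @param n_boot Bootstrap iterations (0 = point estimate only).
#' @param seed Bootstrap seed.
#' @return List `ici`, `fallback`, and with `n_boot > 0` also `lower`,
#'   `upper`.
#' @export
ici <- function(time, event, p, horizon, n_boot = 0, seed = 1) {
  point <- function(time, event, p) {
    tryCatch(mean(abs(p - smooth_observed(time, event, p, horizon))),
             error = function(e) {
               km <- km_cumulative_risk(time, event, horizon)
               structure(mean(abs(p - km$risk)), fallback = TRUE)
             })
  }
  est <- point(time, event, p)
  out <- list(ici = as.numeric(est),
              fallback = isTRUE(attr(est, "fallback")))
  if (out$fallback)
    warning("calibration curve fit failed; ICI computed against overall KM risk")
  if (n_boot > 0) {
    set.seed(seed)
    n <- length(time)
    bs <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      as.numeric(point(time[i], event[i], p[i]))
    }, numeric(1))
    qs <- quantile(bs, c(0.025, 0.975), names = FALSE)
    out$lower <- qs[1]; out$upper <- qs[2]
  }
  out
}

#' Calibration slope
#'
#' Coefficient of `cloglog(p)` in a proportional-hazards model with the
#' transformed prediction as sole covariate.  A slope of 1 is optimally
#' calibrated; the Wald test against 1 is reported.  Because the
#' covariate is `cloglog(p)`, the slope is invariant to
#' recalibration-in-the-large.
#'
#' @param time,event Survival records.
#' @param p Predicted risks.
#' @return List `slope`, `lower`, `upper`, `se`, `p_vs_1`.
#' @export
calibration_slope <- function(time, event, p) {
  x <- cloglog(p)
  if (sd(x) < 1e-8) stop("degenerate predictions")
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  b <- unname(coef(fit)); se <- sqrt(unname(vcov(fit)[1, 1]))
  list(slope = b, lower = b - qnorm(0.975) * se,
       upper = b + qnorm(0.975) * se, se = se,
       p_vs_1 = 2 * pnorm(-abs((b - 1) / se)))
}

#' Compare calibration between two independent samples
#'
#' Bootstraps the difference in ICI and in calibration slope between two
#' samples (resampling patients within each, fixed seed) and reports
#' two-sided p-values from the percentile position of zero.
#'
#' @param a,b Data frames `time`, `event`, `p` for the two samples.
#' @param horizon Horizon (years).
#' @param n_boot Bootstrap iterations.
#' @param seed Seed.
#' @param ids_a,ids_b Optional patient ids; overlap triggers a warning
#'   (independence assumption).
#' @return List `ici_diff`, `ici_p`, `slope_diff`, `slope_p`, and the
#'   bootstrap draws.
#' @export
compare_samples <- function(a, b, horizon, n_boot = 500, seed = 1,
                            ids_a = NULL, ids_b = NULL) {
  if (!is.null(ids_a) && !is.null(ids_b) && length(intersect(ids_a, ids_b)))
    warning("samples share patient ids; independence assumption violated")
  stat <- function(d) {
    c(ici = as.numeric(ici(d$time, d$event, d$p, horizon)$ici),
      slope = calibration_slope(d$time, d$event, d$p)$slope)
  }
  pt_a <- suppressWarnings(stat(a)); pt_b <- suppressWarnings(stat(b))
  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, 2,
                  dimnames = list(NULL, c("ici_diff", "slope_diff")))
  for (k in seq_len(n_boot)) {
    ia <- sample.int(nrow(a), replace = TRUE)
    ib <- sample.int(nrow(b), replace = TRUE)
    sa <- suppressWarnings(stat(a[ia, ])); sb <- suppressWarnings(stat(b[ib, ]))
    draws[k, ] <- sa - sb
  }
  pval <- function(d) min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
  list(ici_a = pt_a[["ici"]], ici_b = pt_b[["ici"]],
       ici_diff = pt_a[["ici"]] - pt_b[["ici"]],
       ici_p = pval(draws[, "ici_diff"]),
       slope_a = pt_a[["slope"]], slope_b = pt_b[["slope"]],
       slope_diff = pt_a[["slope"]] - pt_b[["slope"]],
       slope_p = pval(draws[, "slope_diff"]),
       draws = draws)
}
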