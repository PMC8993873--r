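#' Select the baseline value of a vital for one patient
#'
#' The value most closely preceding the start of follow-up, within 3
#' years (1095 days); height is exempt from the window (any earlier value
#' is accepted).  Ties on the same date are broken tabular-first, then by
#' the latest note order.
#'
#' @param values Data frame with `date`, `value`, `source`
#'   (`"tabular"`/`"nlp"`) for one patient and one vital, in note order.
#' @param start Start of follow-up (days).
#' @param vital Vital name; `"height"` disables the window.
#' @param window Window in days.
#' @return The selected value, or `NA` if none qualifies.
#' @export
select_baseline_vital <- function(values, start, vital = "other",
                                  window = 1095) {
  keep <- values$date <= start
  if (vital != "height") keep <- keep & (start - values$date) <= window
  v <- values[keep, , drop = FALSE]
  if (!nrow(v)) return(NA_real_)
  ord <- order(-v$date, v$source != "tabular", -seq_len(nrow(v)))
  v$value[ord[1]]
}

# Vectorized baseline selection across patients and vitals.
# `stream`: patient_id, date, vital, value, source (row order = note order);
# `members`: patient_id, start.  Returns long data frame of selected
# baselines with provenance.
baseline_table <- function(stream, members, window = 1095) {
  m <- match(stream$patient_id, members$patient_id)
  start <- members$start[m]
  keep <- !is.na(start) & stream$date <= start &
    (stream$vital == "height" | (start - stream$date) <= window)
  s <- stream[keep, , drop = FALSE]
  if (!nrow(s)) {
    return(data.frame(patient_id = character(0), vital = character(0),
                      value = numeric(0), source = character(0),
                      stringsAsFactors = FALSE))
  }
  ord <- order(s$patient_id, s$vital, -s$date,
               s$source != "tabular", -seq_len(nrow(s)))
  s <- s[ord, ]
  first <- !duplicated(paste(s$patient_id, s$vital))
  out <- s[first, c("patient_id", "vital", "value", "source")]
  rownames(out) <- NULL
  out
}

#' Merge tabular and NLP baseline values
#'
#' The tabular value wins whenever present; NLP values only fill gaps
#' (the merge is idempotent on complete tabular data).  Provenance is
#' retained per patient-vital.
#'
#' @param tabular,nlp Long data frames `patient_id`, `vital`, `value`
#'   (one row per patient-vital; `source` added if absent).
#' @return Long data frame `patient_id`, `vital`, `value`, `source`, plus
#'   attribute `fill_counts`: per-vital patients with a value before and
#'   after NLP fill.
#' @export
merge_tabular_nlp <- function(tabular, nlp) {
  tabular$source <- "tabular"
  nlp$source <- "nlp"
  key_t <- paste(tabular$patient_id, tabular$vital)
  key_n <- paste(nlp$patient_id, nlp$vital)
  fill <- nlp[!(key_n %in% key_t), , drop = FALSE]
  out <- rbind(tabular, fill)
  rownames(out) <- NULL
  before <- table(tabular$vital)
  after <- table(out$vital)
  attr(out, "fill_counts") <- data.frame(
    vital = names(after),
    n_tabular = as.integer(before[names(after)]),
    n_after_fill = as.integer(after), stringsAsFactors = FALSE)
  out
}

#' Resolve baseline covariates for a member table
#'
#' Combines demographics, baseline vitals (tabular, optionally gap-filled
#' with NLP extractions), lipid labs, and code-based comorbidity
#' indicators (any diagnosis code recorded on or before the start of
#' follow-up) into the covariate set the risk scores consume; also flags
#' the prevalent outcome.
#'
#' @param ds An `ehr_dataset`.
#' @param members Member table from a cohort builder.
#' @param nlp_values Optional harmonized NLP vitals from
#'   [extract_vitals()]; `NULL` disables NLP recovery.
#' @param outcome Outcome condition used for the prevalence flag.
#' @return `members` with covariate columns (`age`, `height`, `weight`,
#'   `sbp`, `dbp`, `tc`, `hdl`, `smoker`, `bp_treated`, `diabetes`,
#'   `heart_failure`, `prior_mi`), per-vital provenance columns
#'   (`src_<vital>`), and `prevalent_outcome`.
#' @export
resolve_baseline <- function(ds, members, nlp_values = NULL,
                             outcome = score_definition(ds$config$true_model)$outcome) {
  stream <- rbind(ds$vitals[, c("patient_id", "date", "vital", "value", "source")],
                  ds$labs[, c("patient_id", "date", "vital", "value", "source")])
  tab_base <- baseline_table(stream, members)
  if (!is.null(nlp_values) && nrow(nlp_values)) {
    nlp_base <- baseline_table(
      nlp_values[, c("patient_id", "date", "vital", "value", "source")], members)
    base <- merge_tabular_nlp(tab_base, nlp_base)
  } else {
    base <- tab_base
  }
  members$age <- members$age_at_start
  for (v in c("height", "weight", "sbp", "dbp", "tc", "hdl")) {
    b <- base[base$vital == v, ]
    m <- match(members$patient_id, b$patient_id)
    members[[v]] <- b$value[m]
    members[[paste0("src_", v)]] <- b$source[m]
  }
  dg <- ds$diagnoses
  dm <- match(dg$patient_id, members$patient_id)
  at_base <- !is.na(dm) & dg$recorded_date <= members$start[dm]
  comorb <- c(smoker = "smoking", bp_treated = "hypertension_treated",
              diabetes = "diabetes", heart_failure = "heart_failure",
              prior_mi = "mi")
  for (cvn in names(comorb)) {
    hit <- unique(dg$patient_id[at_base & dg$condition == comorb[[cvn]]])
    members[[cvn]] <- as.integer(members$patient_id %in% hit)
  }
  members$prevalent_outcome <- !is.na(members$outcome_day) &
    members$outcome_day <= members$start
  members
}

#' Tabular vs NLP agreement (Bland-Altman)
#'
#' Pairs values from the two sources obtained on the same day within 3
#' years before the start of follow-up; for patients with multiple
#' eligible pairs only the pair most closely preceding the start is used.
#' Reports Pearson r, mean difference (tabular - NLP), 95% limits of
#' agreement (mean +/- 1.96 SD of the differences), and the percentage of
#' pairs inside the limits.
#'
#' @param tabular,nlp Streams `patient_id`, `date`, `vital`, `value` (row
#'   order = note order for `nlp`).
#' @param starts Data frame `patient_id`, `start`.
#' @param window Days before start considered.
#' @return Data frame with one row per vital: `vital`, `n_pairs`,
#'   `pearson_r`, `mean_diff`, `loa_low`, `loa_high`, `pct_within_loa`,
#'   `underpowered`.
#' @export
compute_agreement <- function(tabular, nlp, starts, window = 1095) {
  dedup <- function(s) {
    # same-day repeats: keep the last value in record/note order
    ord <- order(s$patient_id, s$vital, s$date, seq_len(nrow(s)))
    s <- s[ord, ]
    last <- !duplicated(paste(s$patient_id, s$vital, s$date), fromLast = TRUE)
    s[last, ]
  }
  t1 <- dedup(tabular); n1 <- dedup(nlp)
  pr <- merge(t1, n1, by = c("patient_id", "vital", "date"),
              suffixes = c("_tab", "_nlp"))
  st <- starts$start[match(pr$patient_id, starts$patient_id)]
  pr <- pr[!is.na(st) & pr$date <= st & (st - pr$date) <= window, ]
  # one pair per patient-vital: most closely preceding start
  pr <- pr[order(pr$patient_id, pr$vital, -pr$date), ]
  pr <- pr[!duplicated(paste(pr$patient_id, pr$vital)), ]
  if (!nrow(pr)) {
    return(data.frame(vital = character(0), n_pairs = integer(0),
                      pearson_r = numeric(0), mean_diff = numeric(0),
                      loa_low = numeric(0), loa_high = numeric(0),
                      pct_within_loa = numeric(0), underpowered = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(split(pr, pr$vital), function(g) {
    d <- g$value_tab - g$value_nlp
    n <- nrow(g)
    if (n < 3) {
      return(data.frame(vital = g$vital[1], n_pairs = n, pearson_r = NA_real_,
                        mean_diff = mean(d), loa_low = NA_real_,
                        loa_high = NA_real_, pct_within_loa = NA_real_,
                        underpowered = TRUE, stringsAsFactors = FALSE))
    }
    md <- mean(d); s <- sd(d)
    lo <- md - 1.96 * s; hi <- md + 1.96 * s
    data.frame(vital = g$vital[1], n_pairs = n,
               pearson_r = if (sd(g$value_tab) > 0 && sd(g$value_nlp) > 0)
                 cor(g$value_tab, g$value_nlp) else NA_real_,
               mean_diff = md, loa_low = lo, loa_high = hi,
               pct_within_loa = 100 * mean(d >= lo & d <= hi),
               underpowered = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
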