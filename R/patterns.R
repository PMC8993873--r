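#' Vital-sign text pattern registry
#'
#' The single registry of context words, unit tokens, and token shapes used
#' both by the note generator ([render_note()]) and the rule-based labeler
#' ([label_vitals_rule_based()]), so that what the generator writes is by
#' construction what the labeler is specified to read.
#'
#' Shapes are matched longest-first at the first number following a context
#' word: `NUM UNIT NUM UNIT` (compound, e.g. feet + inches), `NUM UNIT`,
#' bare `NUM`; blood pressure admits only `NUM/NUM` and has no unit tokens.
#' Unit factors convert to canonical units (cm, kg, mmHg).
#'
#' @return Named list with entries `height`, `weight`, `bp`.
#' @export
vital_patterns <- function() {
  list(
    height = list(
      context = c("height", "ht"),
      units = c(inches = 2.54, "in" = 2.54, feet = 30.48, ft = 30.48,
                meters = 100, m = 100, centimeters = 1, cm = 1),
      shapes = c("num_unit_num_unit", "num_unit", "num"),
      plaus = c(91, 305)),
    weight = list(
      context = c("weight", "wt"),
      units = c(pounds = 0.45359237, lbs = 0.45359237, lb = 0.45359237,
                ounces = 0.028349523, oz = 0.028349523,
                kilograms = 1, kg = 1, grams = 0.001, g = 0.001),
      shapes = c("num_unit_num_unit", "num_unit", "num"),
      plaus = c(20, 450)),
    bp = list(
      context = c("pressure", "bp"),
      units = NULL,
      shapes = "num_slash_num",
      plaus_sbp = c(50, 300),
      plaus_dbp = c(20, 200))
  )
}

NUM_RE <- "[0-9]+(?:\\.[0-9]+)?"

unit_alt <- function(units) {
  # longest token first so "inches" wins over "in"
  toks <- names(units)[order(-nchar(names(units)))]
  paste0("(?:", paste(toks, collapse = "|"), ")")
}

# Normalize 5'11'' (and 5' 11") quote notation to "5 ft 11 in" so shape
# matching sees ordinary unit tokens.
normalize_quotes <- function(text) {
  gsub("([0-9])\\s*'\\s*([0-9]+(?:\\.[0-9]+)?)\\s*(?:''|\")",
       "\\1 ft \\2 in", text, perl = TRUE)
}

#' Label vital signs in note text with the rule-based approach
#'
#' For every occurrence of a context word (case-insensitive, optionally
#' followed by a colon), the labeler finds the first number beginning
#' within `window` characters and matches the longest applicable shape
#' anchored there.  Blood pressure requires `NUM/NUM`.  Accepted
#' extractions never overlap (earliest span wins).
#'
#' @param text Character vector of note texts.
#' @param note_id Optional ids, recycled against `text` (defaults to the
#'   element index).
#' @param patterns Pattern registry, see [vital_patterns()].
#' @param window Maximum number of characters between the end of the
#'   context word and the start of the matched shape.
#' @return Data frame of raw extractions: `note_id`, `vital`, `context`,
#'   `start`, `end` (character span in the quote-normalized text),
#'   `num1`, `unit1`, `num2`, `unit2` (`NA` where absent; for blood
#'   pressure `num1`/`num2` are the systolic/diastolic tokens).
#' @export
label_vitals_rule_based <- function(text, note_id = seq_along(text),
                                    patterns = vital_patterns(), window = 40) {
  text <- normalize_quotes(text)
  low <- tolower(text)
  out <- list()
  for (v in names(patterns)) {
    p <- patterns[[v]]
    ctx_re <- paste0("\\b(?:", paste(p$context, collapse = "|"), ")\\b:?")
    hits <- gregexpr(ctx_re, low, perl = TRUE)
    n_hits <- vapply(hits, function(h) if (h[1] == -1L) 0L else length(h), integer(1))
    if (sum(n_hits) == 0) next
    idx <- rep(seq_along(low), n_hits)
    ctx_start <- unlist(lapply(hits, function(h) if (h[1] == -1L) integer(0) else as.integer(h)))
    ctx_len <- unlist(lapply(hits, function(h) {
      if (h[1] == -1L) integer(0) else attr(h, "match.length")
    }))
    ctx_end <- ctx_start + ctx_len - 1L
    seg <- substr(low[idx], ctx_end + 1L, ctx_end + window + 40L)
    # first number in the window
    m0 <- regexpr(paste0("(?<![0-9a-z.])", NUM_RE), seg, perl = TRUE)
    ok <- m0 != -1L & m0 <= window
    if (!any(ok)) next
    anchored <- substring(seg[ok], m0[ok])
    res <- match_shapes(anchored, p)
    keep <- !is.na(res$num1)
    if (!any(keep)) next
    abs_start <- ctx_end[ok] + m0[ok]
    out[[v]] <- data.frame(
      note_id = note_id[idx[ok]][keep],
      vital = v,
      context = substr(low[idx[ok]], ctx_start[ok], ctx_end[ok])[keep],
      start = abs_start[keep],
      end = (abs_start + res$len - 1L)[keep],
      num1 = res$num1[keep], unit1 = res$unit1[keep],
      num2 = res$num2[keep], unit2 = res$unit2[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(note_id = note_id[0], vital = character(0),
                      context = character(0), start = integer(0), end = integer(0),
                      num1 = numeric(0), unit1 = character(0),
                      num2 = numeric(0), unit2 = character(0),
                      stringsAsFactors = FALSE))
  }
  raw <- do.call(rbind, out)
  resolve_overlaps(raw)
}

# Anchored shape matching at the first number; longest shape first.
match_shapes <- function(anchored, p) {
  n <- length(anchored)
  res <- list(num1 = rep(NA_real_, n), unit1 = rep(NA_character_, n),
              num2 = rep(NA_real_, n), unit2 = rep(NA_character_, n),
              len = rep(NA_integer_, n))
  grab <- function(re) regmatches(anchored, regexec(re, anchored, perl = TRUE))
  if ("num_slash_num" %in% p$shapes) {
    re <- paste0("^(", NUM_RE, ")\\s*/\\s*(", NUM_RE, ")")
    mm <- grab(re)
    hit <- lengths(mm) > 0
    if (any(hit)) {
      res$num1[hit] <- as.numeric(vapply(mm[hit], `[`, "", 2))
      res$num2[hit] <- as.numeric(vapply(mm[hit], `[`, "", 3))
      res$len[hit] <- nchar(vapply(mm[hit], `[`, "", 1))
    }
    return(res)
  }
  u <- unit_alt(p$units)
  shapes <- list(
    num_unit_num_unit = paste0("^(", NUM_RE, ")\\s*(", u, ")\\b\\s*(",
                               NUM_RE, ")\\s*(", u, ")\\b"),
    num_unit = paste0("^(", NUM_RE, ")\\s*(", u, ")\\b"),
    num = paste0("^(", NUM_RE, ")"))
  done <- rep(FALSE, n)
  for (s in p$shapes) {
    mm <- grab(shapes[[s]])
    hit <- !done & lengths(mm) > 0
    if (!any(hit)) next
    res$num1[hit] <- as.numeric(vapply(mm[hit], `[`, "", 2))
    if (s != "num") res$unit1[hit] <- vapply(mm[hit], `[`, "", 3)
    if (s == "num_unit_num_unit") {
      res$num2[hit] <- as.numeric(vapply(mm[hit], `[`, "", 4))
      res$unit2[hit] <- vapply(mm[hit], `[`, "", 5)
    }
    res$len[hit] <- nchar(vapply(mm[hit], `[`, "", 1))
    done <- done | hit
  }
  res
}

# Earliest-span-wins overlap resolution within each note.
resolve_overlaps <- function(raw) {
  raw <- raw[order(raw$note_id, raw$start, raw$end), ]
  keep <- rep(TRUE, nrow(raw))
  last_end <- -1L
  last_note <- NULL
  for (i in seq_len(nrow(raw))) {
    if (!identical(raw$note_id[i], last_note)) {
      last_note <- raw$note_id[i]
      last_end <- -1L
    }
    if (raw$start[i] <= last_end) keep[i] <- FALSE else last_end <- raw$end[i]
  }
  rownames(raw) <- NULL
  raw[keep, ]
}

BMI25_RE <- "for\\s+(a\\s+)?bmi\\s+(of\\s+)?2[0-9](\\.[0-9])?"

#' Post-process raw extractions into harmonized vitals
#'
#' Applies the four post-processing steps: unit harmonization into cm / kg
#' / mmHg (compound shapes summed, unitless numbers taken as already
#' canonical), physiological plausibility constraints (91-305 cm,
#' 20-450 kg, 50-300 / 20-200 mmHg), and the "optimal weight ... for BMI
#' of 25" distractor filter (weight extractions followed within
#' `bmi_window` characters by a BMI-25 phrase are discarded).  Blood
#' pressure matches split into systolic (first) and diastolic (second)
#' components.
#'
#' @param raw Output of [label_vitals_rule_based()].
#' @param text The note texts the extractions came from (same vector the
#'   labeler saw), used for the distractor filter.
#' @param note_id Ids aligned with `text`.
#' @param patterns Pattern registry.
#' @param bmi_window Characters after a weight match searched for the
#'   BMI-25 phrase.
#' @return Data frame of `note_id`, `vital` (`height`, `weight`, `sbp`,
#'   `dbp`), `value` (canonical units), `accepted`, `reject_reason`.
#' @export
postprocess_extractions <- function(raw, text, note_id = seq_along(text),
                                    patterns = vital_patterns(),
                                    bmi_window = 30) {
  if (!nrow(raw)) {
    return(data.frame(note_id = raw$note_id, vital = character(0),
                      value = numeric(0), accepted = logical(0),
                      reject_reason = character(0), stringsAsFactors = FALSE))
  }
  low <- tolower(normalize_quotes(text))
  txt_of <- low[match(raw$note_id, note_id)]

  # unit factors: named "vital.unit" lookup built from the registry
  fac <- unlist(lapply(patterns[c("height", "weight")], `[[`, "units"))
  conv <- function(vital, num, unit) {
    out <- num
    has_unit <- !is.na(unit)
    f <- fac[paste(vital[has_unit], unit[has_unit], sep = ".")]
    out[has_unit] <- num[has_unit] * as.numeric(f)   # NA factor -> unknown unit
    out[is.na(num)] <- 0
    out
  }

  is_bp <- raw$vital == "bp"
  hw <- raw[!is_bp, , drop = FALSE]
  bp <- raw[is_bp, , drop = FALSE]

  out_hw <- NULL
  if (nrow(hw)) {
    val <- conv(hw$vital, hw$num1, hw$unit1) + conv(hw$vital, hw$num2, hw$unit2)
    reason <- ifelse(is.na(val), "unknown_unit", "")
    # distractor filter: weight followed by a "for BMI of 25" variant
    wi <- which(hw$vital == "weight" & reason == "")
    if (length(wi)) {
      seg <- substr(txt_of[!is_bp][wi], hw$end[wi] + 1L, hw$end[wi] + bmi_window)
      reason[wi][grepl(BMI25_RE, seg, perl = TRUE)] <- "bmi25_distractor"
    }
    out_hw <- data.frame(note_id = hw$note_id, vital = hw$vital, value = val,
                         accepted = NA, reject_reason = reason,
                         stringsAsFactors = FALSE)
  }
  out_bp <- NULL
  if (nrow(bp)) {
    out_bp <- data.frame(
      note_id = rep(bp$note_id, each = 2),
      vital = rep(c("sbp", "dbp"), nrow(bp)),
      value = as.vector(rbind(bp$num1, bp$num2)),
      accepted = NA, reject_reason = "", stringsAsFactors = FALSE)
  }
  out <- rbind(out_hw, out_bp)
  # physiological constraints
  lo <- c(height = 91, weight = 20, sbp = 50, dbp = 20)
  hi <- c(height = 305, weight = 450, sbp = 300, dbp = 200)
  implaus <- !is.na(out$value) &
    (out$value < lo[out$vital] | out$value > hi[out$vital])
  out$reject_reason[implaus & out$reject_reason == ""] <- "implausible"
  out$accepted <- out$reject_reason == "" & !is.na(out$value)
  rownames(out) <- NULL
  out
}

#' Extract harmonized vitals from a note table
#'
#' Runs the rule-based labeler and post-processing over a notes data frame
#' and returns accepted values joined back to patient and date, ready to
#' merge with tabular vitals.
#'
#' @param notes Data frame with `note_id`, `patient_id`, `date`, `text`.
#' @param patterns Pattern registry.
#' @return Data frame `patient_id`, `date`, `vital`, `value`, `source`
#'   (`"nlp"`), `note_id`, in note order.
#' @export
extract_vitals <- function(notes, patterns = vital_patterns()) {
  raw <- label_vitals_rule_based(notes$text, notes$note_id, patterns)
  post <- postprocess_extractions(raw, notes$text, notes$note_id, patterns)
  acc <- post[post$accepted, , drop = FALSE]
  m <- match(acc$note_id, notes$note_id)
  data.frame(patient_id = notes$patient_id[m], date = notes$date[m],
             vital = acc$vital, value = acc$value, source = "nlp",
             note_id = acc$note_id, stringsAsFactors = FALSE)
}
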