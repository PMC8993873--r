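#' Render a clinical note embedding vital signs
#'
#' Writes free text containing the supplied canonical-unit vitals in one of
#' the configured dialects, drawn from the same pattern registry the
#' extractor uses.  Styles:
#' \describe{
#'   \item{bare}{context word + number in canonical units ("Ht: 161.3").}
#'   \item{unit}{number with an explicit unit token, converted from
#'     canonical ("Patient height is 63.5 inches").}
#'   \item{compound}{two-part unit notation (feet + inches, lbs + oz),
#'     occasionally in quote notation (5'11'').}
#'   \item{failure}{documented unextractable dialects: atypical context
#'     words ("wgt 183", "hgt 163") and ambiguous labels ("VS-142/92").}
#'   \item{distractor}{a valid weight followed by an "optimal weight ...
#'     for BMI of 25" phrase whose value must not be extracted.}
#' }
#' Blood pressure always renders as `NUM/NUM` after a BP context word
#' except under the failure style.
#'
#' @param vitals Named list/vector with any of `height` (cm), `weight`
#'   (kg), `sbp`, `dbp` (mmHg); `sbp`/`dbp` must come together.
#' @param style One of `"bare"`, `"unit"`, `"compound"`, `"failure"`,
#'   `"distractor"`.
#' @param note_type Note type label; `"endoscopy"` notes carry no vitals.
#' @return List with `text` and `truth`, a data frame of the embedded
#'   values (`vital`, `value` in canonical units, `extractable`).
#' @export
render_note <- function(vitals, style = c("bare", "unit", "compound",
                                          "failure", "distractor"),
                        note_type = "history_and_physical") {
  style <- match.arg(style)
  df <- data.frame(height = vitals[["height"]] %||% NA_real_,
                   weight = vitals[["weight"]] %||% NA_real_,
                   sbp = vitals[["sbp"]] %||% NA_real_,
                   dbp = vitals[["dbp"]] %||% NA_real_,
                   style = style, note_type = note_type,
                   stringsAsFactors = FALSE)
  out <- render_notes_vec(df)
  list(text = out$text,
       truth = out$truth[, c("vital", "value", "extractable")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vectorized note renderer: one row of `df` per note, columns height,
# weight, sbp, dbp (NA = not embedded), style, note_type.  Returns
# list(text = character, truth = data.frame(note_row, vital, value,
# extractable)).  Consumes RNG for dialect sub-choices.
render_notes_vec <- function(df) {
  n <- nrow(df)
  filler <- sample(c("Patient seen in clinic today.",
                     "Follow-up visit, no acute distress.",
                     "Reviewed medications and history."), n, replace = TRUE)
  style <- df$style
  endo <- df$note_type == "endoscopy"

  piece <- function(has, build) {
    txt <- rep(NA_character_, n)
    idx <- which(has & !endo)
    if (length(idx)) txt[idx] <- build(idx)
    txt
  }

  h_unit <- sample(c("inches", "cm", "m"), n, replace = TRUE)
  h_quote <- runif(n) < 0.3
  txt_h <- piece(!is.na(df$height), function(i) {
    h <- df$height[i]; s <- style[i]
    out <- sprintf("Ht: %.1f.", h)                        # bare
    u <- h_unit[i]
    k <- s == "unit" & u == "inches"
    out[k] <- sprintf("Patient height is %.1f inches.", h[k] / 2.54)
    k <- s == "unit" & u == "cm" | s == "distractor"
    out[k] <- sprintf("Height: %.1f cm.", h[k])
    k <- s == "unit" & u == "m"
    out[k] <- sprintf("Height %.2f m.", h[k] / 100)
    k <- s == "compound"
    ft <- floor(h / 30.48); inch <- round((h - ft * 30.48) / 2.54, 1)
    out[k & h_quote[i]] <- sprintf("Ht: %d'%.1f''.", ft, inch)[k & h_quote[i]]
    out[k & !h_quote[i]] <- sprintf("Height: %d feet %.1f inches.", ft, inch)[k & !h_quote[i]]
    out[s == "failure"] <- sprintf("hgt %.1f", h[s == "failure"])
    out
  })
  w_kg <- runif(n) < 0.5
  txt_w <- piece(!is.na(df$weight), function(i) {
    w <- df$weight[i]; s <- style[i]
    out <- sprintf("Wt: %.1f.", w)                        # bare
    k <- s == "unit" & w_kg[i]
    out[k] <- sprintf("Current weight is %.1f kg.", w[k])
    k <- s == "unit" & !w_kg[i]
    out[k] <- sprintf("Weight: %.1f lbs.", w[k] / 0.45359237)
    k <- s == "compound"
    lb <- floor(w / 0.45359237)
    oz <- round((w - lb * 0.45359237) / 0.028349523, 1)
    out[k] <- sprintf("Patient's weight is %d lbs %.1f oz.", lb, oz)[k]
    out[s == "failure"] <- sprintf("wgt %d", round(w / 0.45359237))[s == "failure"]
    k <- s == "distractor"
    out[k] <- sprintf(
      "Current weight is %.1f kg. Optimal weight 68.0 kg for BMI of 25.", w[k])
    out
  })
  txt_b <- piece(!is.na(df$sbp) & !is.na(df$dbp), function(i) {
    sv <- round(df$sbp[i]); dv <- round(df$dbp[i]); s <- style[i]
    out <- sprintf("BP: %d/%d.", sv, dv)                  # bare
    k <- s == "unit" | s == "distractor"
    out[k] <- sprintf("Blood pressure is %d/%d.", sv, dv)[k]
    k <- s == "compound"
    out[k] <- sprintf("bp %d/%d today.", sv, dv)[k]
    out[s == "failure"] <- sprintf("VS-%d/%d", sv, dv)[s == "failure"]
    out
  })

  na0 <- function(x) ifelse(is.na(x), "", x)
  text <- trimws(gsub(" {2,}", " ",
                      paste(filler, na0(txt_h), na0(txt_w), na0(txt_b))))
  text[endo] <- paste(filler[endo], "Procedure tolerated well.")
  empty <- is.na(txt_h) & is.na(txt_w) & is.na(txt_b) & !endo
  text[empty] <- paste(filler[empty], "Stable, no measurements recorded.")

  truth_for <- function(vital, col, val = NULL) {
    has <- !is.na(df[[col]]) & !endo
    data.frame(note_row = which(has), vital = vital,
               value = if (is.null(val)) df[[col]][has] else val[has],
               extractable = style[has] != "failure",
               stringsAsFactors = FALSE)
  }
  truth <- rbind(truth_for("height", "height"),
                 truth_for("weight", "weight"),
                 truth_for("sbp", "sbp", round(df$sbp)),
                 truth_for("dbp", "dbp", round(df$dbp)))
  truth <- truth[order(truth$note_row), ]
  rownames(truth) <- NULL
  list(text = text, truth = truth)
}
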