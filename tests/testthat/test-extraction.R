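lab1 <- function(text) label_vitals_rule_based(text)

test_that("the labeler reproduces the reference dialect examples", {
  r <- lab1("Ht: 63.5")
  expect_equal(r$vital, "height"); expect_equal(r$num1, 63.5)
  expect_true(is.na(r$unit1))

  r <- lab1("Patient height is 63.5 inches")
  expect_equal(r$num1, 63.5); expect_equal(r$unit1, "inches")

  r <- lab1("Height: 5 feet 11 inches")
  expect_equal(c(r$num1, r$num2), c(5, 11))
  expect_equal(c(r$unit1, r$unit2), c("feet", "inches"))

  r <- lab1("Wt: 180")
  expect_equal(r$vital, "weight"); expect_equal(r$num1, 180)

  r <- lab1("Current weight is 65.9 kg")
  expect_equal(r$num1, 65.9); expect_equal(r$unit1, "kg")

  r <- lab1("Patient's weight is 170 lbs 9 oz")
  expect_equal(c(r$num1, r$num2), c(170, 9))
  expect_equal(c(r$unit1, r$unit2), c("lbs", "oz"))

  r <- lab1("Blood pressure is 128/70")
  expect_equal(r$vital, "bp")
  expect_equal(c(r$num1, r$num2), c(128, 70))
})

test_that("documented failure dialects yield no extraction", {
  expect_equal(nrow(lab1("wgt 183")), 0)
  expect_equal(nrow(lab1("VS-142/92")), 0)
  expect_equal(nrow(lab1("hgt 161.5")), 0)
  # context word with no number within the window
  expect_equal(nrow(lab1(paste0("height was discussed at length today and ",
                                "documented elsewhere in the chart 63.5"))), 0)
})

test_that("post-processing harmonizes units and sums compound shapes", {
  post <- function(text) {
    raw <- label_vitals_rule_based(text)
    postprocess_extractions(raw, text)
  }
  p <- post("Height: 5 feet 11 inches")
  expect_equal(p$value, 180.34, tolerance = 1e-9)
  expect_true(p$accepted)

  p <- post("Patient height is 63.5 inches")
  expect_equal(p$value, 161.29, tolerance = 1e-9)

  p <- post("Ht: 5'11''")                       # quote notation normalized
  expect_equal(p$value, 180.34, tolerance = 1e-9)

  p <- post("Patient's weight is 170 lbs 9 oz")
  expect_equal(p$value, 170 * 0.45359237 + 9 * 0.028349523, tolerance = 1e-9)

  p <- post("Blood pressure is 128/70")
  expect_equal(p$vital, c("sbp", "dbp"))
  expect_equal(p$value, c(128, 70))
  expect_true(all(p$accepted))
})

test_that("physiological constraints reject implausible values", {
  post <- function(text) {
    postprocess_extractions(label_vitals_rule_based(text), text)
  }
  p <- post("Current weight is 451 kg")
  expect_false(p$accepted)
  expect_equal(p$reject_reason, "implausible")
  expect_true(post("Current weight is 450 kg")$accepted)
  expect_false(post("Ht: 80")$accepted)          # below 91 cm
  p <- post("Blood pressure is 310/70")
  expect_equal(p$accepted, c(FALSE, TRUE))
})

test_that("the BMI-of-25 distractor filter discards only the optimal weight", {
  text <- "Current weight is 80.0 kg. Optimal weight 68 kg for BMI of 25."
  raw <- label_vitals_rule_based(text)
  expect_equal(nrow(raw), 2)
  p <- postprocess_extractions(raw, text)
  expect_equal(p$accepted, c(TRUE, FALSE))
  expect_equal(p$reject_reason[2], "bmi25_distractor")
  expect_equal(p$value[1], 80)
  # variations of the phrase are caught too
  t2 <- "ideal weight 68 kg for a BMI 24.5"
  p2 <- postprocess_extractions(label_vitals_rule_based(t2), t2)
  expect_false(p2$accepted)
})

test_that("baseline selection takes the closest preceding value in window", {
  yr <- 365.25
  vals <- data.frame(date = c(-4 * yr, -1 * yr, -10) + 1000,
                     value = c(70, 75, 80), source = "tabular",
                     stringsAsFactors = FALSE)
  expect_equal(select_baseline_vital(vals, start = 1000, vital = "weight"), 80)
  only_old <- data.frame(date = 1000 - 3.5 * yr, value = 70,
                         source = "tabular", stringsAsFactors = FALSE)
  expect_true(is.na(select_baseline_vital(only_old, 1000, "weight")))
  old_height <- data.frame(date = 1000 - 8 * yr, value = 170,
                           source = "tabular", stringsAsFactors = FALSE)
  expect_equal(select_baseline_vital(old_height, 1000, "height"), 170)
  # same-date tie: tabular wins over nlp; later note wins within nlp
  tie <- data.frame(date = c(900, 900, 900), value = c(1, 2, 3),
                    source = c("nlp", "tabular", "nlp"),
                    stringsAsFactors = FALSE)
  expect_equal(select_baseline_vital(tie, 1000, "weight"), 2)
  expect_equal(select_baseline_vital(tie[c(1, 3), ], 1000, "weight"), 3)
})

test_that("tabular values always win the merge and NLP only fills gaps", {
  tab <- data.frame(patient_id = c("P1", "P2"), vital = "sbp",
                    value = c(120, 130), stringsAsFactors = FALSE)
  nlp <- data.frame(patient_id = c("P1", "P3"), vital = "sbp",
                    value = c(999, 140), stringsAsFactors = FALSE)
  m <- merge_tabular_nlp(tab, nlp)
  expect_equal(m$value[m$patient_id == "P1"], 120)
  expect_equal(m$source[m$patient_id == "P3"], "nlp")
  expect_equal(nrow(m), 3)
  # idempotent on complete data
  m2 <- merge_tabular_nlp(tab, tab)
  expect_equal(nrow(m2), 2)
  expect_true(all(m2$source == "tabular"))
})

test_that("agreement pairs same-day values and recovers the injected spread", {
  set.seed(41)
  n <- 10000
  truth <- rnorm(n, 120, 15)
  tab <- data.frame(patient_id = sprintf("P%05d", 1:n), date = 500,
                    vital = "sbp", value = truth, stringsAsFactors = FALSE)
  nlp <- data.frame(patient_id = sprintf("P%05d", 1:n), date = 500,
                    vital = "sbp", value = truth + rnorm(n, 0, 5),
                    stringsAsFactors = FALSE)
  starts <- data.frame(patient_id = sprintf("P%05d", 1:n), start = 600,
                       stringsAsFactors = FALSE)
  rep <- compute_agreement(tab, nlp, starts)
  expect_equal(rep$n_pairs, n)
  expect_gt(rep$pearson_r, 0.9)
  expect_equal(rep$loa_high, 1.96 * 5, tolerance = 0.1)
  expect_equal(rep$loa_low, -1.96 * 5, tolerance = 0.1)
  expect_gt(rep$pct_within_loa, 93)

  # pairs on different days are excluded
  nlp2 <- nlp; nlp2$date <- 501
  rep2 <- compute_agreement(tab, nlp2, starts)
  expect_equal(nrow(rep2), 0)

  # identical paired values: perfect agreement
  rep3 <- compute_agreement(tab, tab, starts)
  expect_equal(rep3$pearson_r, 1)
  expect_equal(rep3$mean_diff, 0)
  expect_equal(c(rep3$loa_low, rep3$loa_high), c(0, 0))

  # fewer than 3 pairs: underpowered, r undefined
  rep4 <- compute_agreement(tab[1:2, ], nlp[1:2, ], starts)
  expect_true(rep4$underpowered)
  expect_true(is.na(rep4$pearson_r))
})

test_that("generator-extractor round trip is exact within unit rounding", {
  ds <- simulate_ehr(sim_config(n_patients = 400, seed = 44))
  nlp <- extract_vitals(ds$notes)
  tr <- ds$truth$notes
  key_t <- paste(tr$note_id, tr$vital)
  key_n <- paste(nlp$note_id, nlp$vital)
  # 100% of extractable embeddings recovered
  expect_true(all(key_t[tr$extractable] %in% key_n))
  # 0% recovery from failure styles
  expect_false(any(key_t[!tr$extractable] %in% key_n))
  m <- merge(tr[tr$extractable, ], nlp, by = c("note_id", "vital"))
  tol <- c(height = 0.5, weight = 0.5, sbp = 1, dbp = 1)[m$vital]
  expect_true(all(abs(m$value.x - m$value.y) <= tol))
  # all retained values satisfy the physiological constraints
  lo <- c(height = 91, weight = 20, sbp = 50, dbp = 20)[nlp$vital]
  hi <- c(height = 305, weight = 450, sbp = 300, dbp = 200)[nlp$vital]
  expect_true(all(nlp$value >= lo & nlp$value <= hi))
})
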