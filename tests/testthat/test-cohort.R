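test_that("primary care visits are flagged by code AND location", {
  reg <- pcp_registry(cpt_codes = c("99213"), locations = c("PC001"))
  enc <- data.frame(code = c("99213", "99213", "99999"),
                    location_id = c("PC001", "SP001", "PC001"),
                    stringsAsFactors = FALSE)
  expect_equal(identify_pcp_visits(enc, reg), c(TRUE, FALSE, FALSE))
  expect_length(identify_pcp_visits(enc[0, ], reg), 0)
  expect_error(pcp_registry(cpt_codes = character(0)), "non-empty")
})

test_that("the qualifying-pair scan follows the 1-3 year closed interval", {
  expect_equal(find_qualifying_pair(c(0, 500)), 500)
  expect_true(is.na(find_qualifying_pair(c(0, 200))))
  expect_equal(find_qualifying_pair(c(0, 400, 3000)), 400)
  # boundaries inclusive
  expect_equal(find_qualifying_pair(c(0, 365)), 365)
  expect_equal(find_qualifying_pair(c(0, 1095)), 1095)
  expect_true(is.na(find_qualifying_pair(c(0, 364))))
  expect_true(is.na(find_qualifying_pair(c(0, 1096))))
  expect_true(is.na(find_qualifying_pair(1000)))
  # unsorted input, earliest second visit wins
  expect_equal(find_qualifying_pair(c(3000, 400, 0)), 400)
})

test_that("follow-up ends at the earliest applicable terminus", {
  yr <- 365.25
  fi <- define_followup_interval(0, outcome_day = 2 * yr, death_day = NA,
                                 last_enc_day = 4 * yr, age90_day = 50 * yr,
                                 admin_censor_day = 8 * yr)
  expect_equal(fi$time_years, 2)
  expect_equal(fi$event, 1L)
  expect_equal(fi$end_reason, "event")

  fi <- define_followup_interval(0, NA, NA, 3 * yr, 50 * yr, 8 * yr)
  expect_equal(fi$time_years, 3)
  expect_equal(fi$event, 0L)
  expect_equal(fi$end_reason, "last_encounter")

  fi <- define_followup_interval(0, NA, NA, 3 * yr, 1 * yr, 8 * yr)
  expect_equal(fi$end_reason, "age_90")
  expect_equal(fi$time_years, 1)

  # outcome on/before start is not an event during follow-up
  fi <- define_followup_interval(100, outcome_day = 100, death_day = NA,
                                 last_enc_day = 600, age90_day = 1e5,
                                 admin_censor_day = 1e5)
  expect_equal(fi$event, 0L)
  expect_error(define_followup_interval(100, NA, NA, 50, 1e5, 1e5), "precedes")
})

pcp_enc <- function(id, dates) {
  data.frame(patient_id = id, date = dates, code = "99213",
             location_id = "PC001", kind = "primary-care-eligible",
             stringsAsFactors = FALSE)
}

test_that("age and demographic exclusions apply at the start of follow-up", {
  day <- function(age_at_500) 500 - round(age_at_500 * 365.25)
  pats <- rbind(mini_patient("P1", birth_day = day(17.9)),
                mini_patient("P2", birth_day = day(89.5)),
                mini_patient("P3", birth_day = day(50)),
                mini_patient("P4", birth_day = day(50)))
  pats$race[pats$patient_id == "P4"] <- NA
  enc <- rbind(pcp_enc("P1", c(0, 500, 900)), pcp_enc("P2", c(0, 500, 900)),
               pcp_enc("P3", c(0, 500, 900)), pcp_enc("P4", c(0, 500, 900)))
  ds <- make_mini_ds(pats, enc)
  mem <- build_longitudinal_cohort(ds, pcp_registry(), admin_censor_day = 5000,
                                   outcome = "af")
  expect_setequal(mem$patient_id, c("P2", "P3"))   # <18 and missing race out
  expect_equal(unique(mem$start), 500)
})

test_that("cohort membership uses encounters only and is registry-monotone", {
  ds <- simulate_ehr(sim_config(n_patients = 600, seed = 31))
  obs <- observable_tables(ds)
  m1 <- build_longitudinal_cohort(obs, outcome = "af")
  # every start is one of that patient's flagged visit dates
  flg <- identify_pcp_visits(obs$encounters, obs$registry)
  key <- paste(obs$encounters$patient_id[flg], obs$encounters$date[flg])
  expect_true(all(paste(m1$patient_id, m1$start) %in% key))
  # deleting all notes changes nothing
  obs2 <- obs; obs2$notes <- obs$notes[0, ]
  m2 <- build_longitudinal_cohort(obs2, outcome = "af")
  expect_identical(m1, m2)
  # enlarging the registry never shrinks the cohort
  big <- pcp_registry(cpt_codes = c(obs$registry$cpt_codes, "99243", "93000"),
                      locations = c(obs$registry$locations,
                                    sprintf("SP%03d", 1:30)))
  m3 <- build_longitudinal_cohort(obs, registry = big, outcome = "af")
  expect_true(all(m1$patient_id %in% m3$patient_id))
})

test_that("convenience start is the earliest joint component availability", {
  score <- score_definition("charge_af")
  pats <- mini_patient("P1")
  enc <- pcp_enc("P1", c(0, 300, 700, 1200))
  vit <- function(d, v) data.frame(patient_id = "P1", date = d,
                                   encounter_id = 1L, vital = v, value = 100,
                                   source = "tabular", stringsAsFactors = FALSE)
  vitals <- rbind(vit(0, "height"), vit(0, "weight"), vit(300, "sbp"),
                  vit(700, "dbp"))
  ds <- make_mini_ds(pats, enc, vitals = vitals)
  mem <- build_convenience_sample(ds, score, admin_censor_day = 5000)
  expect_equal(mem$start, 700)   # all four first jointly available at day 700

  # components measured >3 years before the only joint candidate date
  # invalidate it: weight/sbp at day 0 are stale at day 1300
  vitals2 <- rbind(vit(0, "height"), vit(0, "weight"), vit(0, "sbp"),
                   vit(1300, "dbp"))
  ds2 <- make_mini_ds(pats, rbind(enc, pcp_enc("P1", 1300)), vitals = vitals2)
  mem2 <- build_convenience_sample(ds2, score, admin_censor_day = 5000)
  expect_equal(nrow(mem2), 0)
  # fresh weight and sbp at day 1300 make it qualify
  vitals3 <- rbind(vitals2, vit(1300, "sbp"), vit(1300, "weight"))
  mem3 <- build_convenience_sample(make_mini_ds(pats, rbind(enc, pcp_enc("P1", c(1300, 1800))),
                                                vitals = vitals3),
                                   score, admin_censor_day = 5000)
  expect_equal(mem3$start, 1300)

  # height is exempt from the 3-year window
  vitals4 <- rbind(vit(0, "height"), vit(2000, "weight"), vit(2000, "sbp"),
                   vit(2000, "dbp"))
  mem4 <- build_convenience_sample(make_mini_ds(pats, rbind(enc, pcp_enc("P1", c(2000, 2500))),
                                                vitals = vitals4),
                                   score, admin_censor_day = 5000)
  expect_equal(mem4$start, 2000)

  # outcome recorded before start excludes the member as prevalent
  diag <- data.frame(patient_id = "P1", condition = "af", recorded_date = 600,
                     stringsAsFactors = FALSE)
  mem5 <- build_convenience_sample(make_mini_ds(pats, enc, vitals = vitals,
                                                diagnoses = diag),
                                   score, admin_censor_day = 5000)
  expect_equal(nrow(mem5), 0)
})

test_that("convenience start dates coincide with measurement dates", {
  ds <- simulate_ehr(sim_config(n_patients = 500, seed = 33))
  obs <- observable_tables(ds)
  score <- score_definition("charge_af")
  mem <- build_convenience_sample(obs, score)
  tab <- rbind(obs$vitals, obs$labs)
  key <- paste(tab$patient_id, tab$date)
  expect_gt(nrow(mem), 0)
  expect_true(all(paste(mem$patient_id, mem$start) %in% key))
})

test_that("zero-length follow-up drops the member", {
  pats <- mini_patient("P1")
  enc <- pcp_enc("P1", c(0, 500))      # last encounter = start
  ds <- make_mini_ds(pats, enc)
  mem <- build_longitudinal_cohort(ds, pcp_registry(), admin_censor_day = 5000,
                                   outcome = "af")
  expect_equal(nrow(mem), 0)
})
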