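#' Write a synthetic EHR to disk
#'
#' Observable tables go to CSV (`patients.csv`, `encounters.csv`,
#' `vitals.csv`, `labs.csv`, `diagnoses.csv`) and notes to JSON lines
#' (`notes.jsonl`, one object per note).  The hidden simulation truth is
#' written separately (`truth_patients.csv`, `truth_notes.csv`,
#' `truth_diagnoses.csv`) so pipeline stages can be restricted to the
#' observable files.
#'
#' @param ds An `ehr_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ehr_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, nm) write.csv(df, file.path(dir, nm), row.names = FALSE)
  wr(ds$patients, "patients.csv")
  wr(ds$encounters, "encounters.csv")
  wr(ds$vitals, "vitals.csv")
  wr(ds$labs, "labs.csv")
  wr(ds$diagnoses, "diagnoses.csv")
  con <- file(file.path(dir, "notes.jsonl"), open = "w")
  on.exit(close(con))
  jsonlite::stream_out(ds$notes, con, verbose = FALSE)
  if (!is.null(ds$truth)) {
    wr(ds$truth$patients, "truth_patients.csv")
    wr(ds$truth$notes, "truth_notes.csv")
    wr(ds$truth$diagnoses, "truth_diagnoses.csv")
  }
  invisible(dir)
}

#' Read a synthetic EHR from disk
#'
#' @param dir Directory written by [write_ehr_dataset()].
#' @param observable_only Skip the truth files even when present.
#' @return An `ehr_dataset` (without `config`).
#' @export
read_ehr_dataset <- function(dir, observable_only = FALSE) {
  rd <- function(nm) read.csv(file.path(dir, nm), stringsAsFactors = FALSE)
  ds <- list(patients = rd("patients.csv"), encounters = rd("encounters.csv"),
             vitals = rd("vitals.csv"), labs = rd("labs.csv"),
             diagnoses = rd("diagnoses.csv"),
             notes = jsonlite::stream_in(file(file.path(dir, "notes.jsonl")),
                                         verbose = FALSE))
  if (!observable_only && file.exists(file.path(dir, "truth_patients.csv"))) {
    ds$truth <- list(patients = rd("truth_patients.csv"),
                     notes = rd("truth_notes.csv"),
                     diagnoses = rd("truth_diagnoses.csv"))
  }
  structure(ds, class = "ehr_dataset")
}
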