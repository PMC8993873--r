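#!/usr/bin/env Rscript
# Stage 2: construct the two analysis samples from the observable tables.
#
# The longitudinal primary-care cohort enters at the second visit of the
# earliest qualifying visit pair (1-3 years apart); the convenience sample
# enters at the earliest date all score components are jointly available.
# Writes per-sample membership summaries to results/tables/.

suppressPackageStartupMessages(library(ehrbias))

obs <- observable_tables(simulate_ehr(sim_config(n_patients = 20000, seed = 1)))
score <- score_definition("charge_af")

coh <- build_longitudinal_cohort(obs)
cnv <- build_convenience_sample(obs, score)

summarize <- function(m, name) {
  data.frame(sample = name, n = nrow(m),
             median_followup_years = round(median(m$time_years), 2),
             events = sum(m$event),
             mean_age_at_start = round(mean(m$age_at_start), 1),
             end_event = mean(m$end_reason == "event"),
             end_death = mean(m$end_reason == "death"),
             end_last_encounter = mean(m$end_reason == "last_encounter"),
             end_administrative = mean(m$end_reason == "administrative"))
}
tab <- rbind(summarize(coh, "longitudinal_cohort"),
             summarize(cnv, "convenience_sample"))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.csv(tab, "results/tables/cohort_summary.csv", row.names = FALSE)
print(tab, row.names = FALSE)

cat(sprintf("\nOverlap: %d patients are in both samples\n",
            length(intersect(coh$patient_id, cnv$patient_id))))
cat(sprintf("Median start day: cohort %d vs convenience %d\n",
            as.integer(median(coh$start)), as.integer(median(cnv$start))))
cat("The convenience sample enters earlier and with shorter streams --\n")
cat("exactly the patients whose data exist because of clinical need.\n")
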