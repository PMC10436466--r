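#!/usr/bin/env Rscript
# Preprocess the simulated clonotype tables the way the sequencing
# toolchain output would be: drop non-productive clonotypes, apply routine
# cross-sample decontamination (frequency ratio 20), and merge the biopsy
# slices of each patient per compartment. Writes the patient-merged tables
# and a per-sample filtering log.

suppressPackageStartupMessages(library(tilrep))

data_dir <- "results/analysis/data"
out <- "results/analysis/processed"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sheet <- readr::read_csv(file.path(data_dir, "sample_sheet.csv"),
                         show_col_types = FALSE)
reps <- lapply(seq_len(nrow(sheet)), function(i) {
  r <- read_clonotype_table(sheet$path[i], "vdjtools",
                            sample_id = sheet$sample_id[i],
                            patient_id = sheet$patient_id[i],
                            compartment = sheet$compartment[i])
  r$pct_cd4 <- sheet$pct_cd4[i]; r$pct_cd8 <- sheet$pct_cd8[i]
  r
})
cohort <- new_cohort(reps)

before <- vapply(cohort$repertoires, function(r) nrow(r$clonotypes),
                 integer(1))
cohort$repertoires <- lapply(cohort$repertoires, filter_productive)
after_prod <- vapply(cohort$repertoires, function(r) nrow(r$clonotypes),
                     integer(1))
cohort <- decontaminate(cohort, ratio = 20)
after_decon <- vapply(cohort$repertoires, function(r) nrow(r$clonotypes),
                      integer(1))

log_tbl <- tibble::tibble(sample_id = names(before), n_input = before,
                          n_productive = after_prod,
                          n_decontaminated = after_decon)
readr::write_tsv(log_tbl, file.path(out, "filtering_log.tsv"))
message(sprintf("productive filter removed %d clonotypes; decontamination %d",
                sum(before - after_prod), sum(after_prod - after_decon)))

for (cp in unique(sheet$compartment)) {
  merged <- merge_by_patient(cohort, cp)
  for (r in merged)
    write_clonotype_table(
      r, file.path(out, sprintf("%s_%s_merged.txt", r$patient_id,
                                gsub("[^A-Za-z0-9+-]", "", cp))),
      "vdjtools")
}
message("patient-merged tables written to ", out)
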