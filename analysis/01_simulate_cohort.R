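#!/usr/bin/env Rscript
# Simulate the study cohort: 4 breast-tumor "patients", 2 biopsy slices
# each, three TIL compartments (initial culture, sorted CD4+, sorted CD8+)
# with the compartment presets (N(D)N length 14.4/11.4/13.8 nt, central
# charge bias +0.06/-0.04/-0.01, diversity 0.38/0.51/0.45), a motif
# planted in the CD4 compartment, two injected public clonotypes, 2%
# non-productive contamination, plus a background reference repertoire and
# a small specificity database. Everything is written as plain TSV/CSV so
# the downstream scripts run from files, exactly as they would on real
# clonotype tables.

suppressPackageStartupMessages(library(tilrep))

out <- "results/analysis/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20230804L

spec <- cohort_spec(
  n_patients = 4, slices_per_patient = 2,
  compartments = list(
    `TILs-initial` = til_initial_preset(600, nonproductive_rate = 0.02),
    `TILs-CD4+` = til_cd4_preset(600, nonproductive_rate = 0.02,
                                 planted_motifs = list(
                                   list(motif = "SLGG%GE", n_carriers = 30))),
    `TILs-CD8+` = til_cd8_preset(600, nonproductive_rate = 0.02)),
  public_injection = list(
    list(cdr3_aa = "CASSLGGSGEQFF", n_patients = 2),
    list(cdr3_aa = "CASSPTGLAGEQYF", n_patients = 3)),
  reference_size = 1000,
  composition = list(compartment = "TILs-initial",
                     nsw_cd4 = 0.38, nsw_cd8 = 0.51),
  seed = seed)

cohort <- generate_cohort(spec)
md <- cohort_metadata(cohort)

paths <- file.path(out, paste0(md$sample_id, ".txt"))
for (i in seq_len(nrow(md)))
  write_clonotype_table(cohort$repertoires[[md$sample_id[i]]], paths[i],
                        "vdjtools")
write_clonotype_table(cohort$reference, file.path(out, "reference.txt"),
                      "vdjtools")

readr::write_csv(
  tibble::tibble(sample_id = md$sample_id, patient_id = md$patient_id,
                 compartment = md$compartment, chain = md$chain,
                 path = paths, pct_cd4 = md$pct_cd4, pct_cd8 = md$pct_cd8),
  file.path(out, "sample_sheet.csv"))

db <- generate_specificity_db(db_spec(
  n_records = c(allergy = 8, autoimmunity = 8, cancer = 15, pathogens = 15),
  overlap = list(list(cdr3_aa = "CASSLGGSGEQFF", category = "cancer")),
  seed = seed + 1L))
write_specificity_db(db, file.path(out, "specificity_db.csv"))

message(sprintf("wrote %d clonotype tables (%d clonotypes total), %s",
                nrow(md), sum(md$n_clonotypes), out))
message(sprintf("specificity database: %d records across %d categories",
                nrow(db), length(unique(db$category))))
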