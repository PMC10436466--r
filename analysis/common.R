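# Shared loader for the analysis scripts: re-reads the simulated tables
# from the sample sheet and applies the preprocessing steps in memory.

load_preprocessed_cohort <- function(data_dir = "results/analysis/data") {
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
  reference <- read_clonotype_table(file.path(data_dir, "reference.txt"),
                                    "vdjtools", compartment = "reference")
  cohort <- new_cohort(reps, reference = reference)
  cohort$repertoires <- lapply(cohort$repertoires, filter_productive)
  decontaminate(cohort, ratio = 20)
}
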