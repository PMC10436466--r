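#!/usr/bin/env Rscript
# Specificity annotation: build the three candidate sets per compartment
# (frequency > 0.1%, public, motif-clustered), match them against the
# specificity database at Levenshtein distance <= 1, and propagate cancer
# annotations across motif clusters ("putatively tumor-associated").

suppressPackageStartupMessages(library(tilrep))
source("analysis/common.R")

out <- "results/analysis"
cohort <- load_preprocessed_cohort()
db <- read_specificity_db("results/analysis/data/specificity_db.csv")
ref_aa <- collapse_by_aa(cohort$reference)

pool_aa <- function(merged) {
  pooled <- dplyr::bind_rows(lapply(merged, function(r) r$clonotypes))
  agg <- pooled |>
    dplyr::group_by(cdr3_aa) |>
    dplyr::summarise(count = sum(count),
                     nt_variant_count = dplyr::n_distinct(cdr3_nt),
                     .groups = "drop")
  agg$freq <- agg$count / sum(agg$count)
  class(agg) <- c("aa_repertoire", class(agg))
  agg
}

withr::with_seed(99992, {
  set_rows <- list(); cnt_rows <- list(); ann_rows <- list()
  for (cp in c("TILs-CD4+", "TILs-CD8+")) {
    merged <- merge_by_patient(cohort, cp)
    clusters <- unlist(lapply(names(merged), function(pid)
      cluster_by_motifs(collapse_by_aa(merged[[pid]]), ref_aa,
                        min_carriers = 3, B = 500, biopsy = pid)),
      recursive = FALSE)
    cs <- candidate_sets(pool_aa(merged), public_sequences(cohort, cp),
                         clusters, freq_threshold = 0.001)
    message(sprintf("%s candidate sets: %d high-frequency, %d public, %d clustered (universe %d)",
                    cp, cs$sizes[["high_freq"]], cs$sizes[["public"]],
                    cs$sizes[["clustered"]], cs$universe_size))
    queries <- unique(c(cs$high_freq, cs$public, cs$clustered))
    matches <- match_database(queries, db, max_dist = 1)
    ann <- annotate_clusters(clusters, matches)
    cnt <- annotation_counts(ann)
    if (nrow(ann)) ann$compartment <- cp
    if (nrow(cnt)) cnt$compartment <- cp
    set_rows[[cp]] <- tibble::tibble(
      compartment = cp, universe = cs$universe_size,
      n_high_freq = cs$sizes[["high_freq"]],
      n_public = cs$sizes[["public"]],
      n_clustered = cs$sizes[["clustered"]],
      n_direct_matches = length(unique(
        matches$query[!is.na(matches$distance)])))
    ann_rows[[cp]] <- ann; cnt_rows[[cp]] <- cnt
    for (i in seq_len(nrow(cnt)))
      message(sprintf("  %-13s direct %d -> with propagation %d",
                      cnt$category[i], cnt$n_direct[i], cnt$n_total[i]))
  }
  readr::write_csv(dplyr::bind_rows(set_rows),
                   file.path(out, "candidate_sets.csv"))
  readr::write_csv(dplyr::bind_rows(ann_rows),
                   file.path(out, "annotations.csv"))
  readr::write_csv(dplyr::bind_rows(cnt_rows),
                   file.path(out, "annotation_counts.csv"))
})
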