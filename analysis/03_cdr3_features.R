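#!/usr/bin/env Rscript
# CDR3 physicochemistry: CDR3nt / N(D)Nnt length statistics per sample and
# frequency-weighted central-5mer charge, hydropathy and polarity profiles
# on the aa-collapsed repertoires, compared across compartments with
# one-way ANOVA + Tukey.

suppressPackageStartupMessages(library(tilrep))
source("analysis/common.R")

out <- "results/analysis"
cohort <- load_preprocessed_cohort()

features <- feature_table(cohort, scales = c("charge", "hydropathy",
                                             "polarity"))
readr::write_tsv(features, file.path(out, "cdr3_features.tsv"))

by_comp <- split(features, features$compartment)
for (cp in names(by_comp))
  message(sprintf("%-14s N(D)N %5.2f nt  charge %+6.3f  hydropathy %+6.3f",
                  cp, mean(by_comp[[cp]]$ndn_mean),
                  mean(by_comp[[cp]]$charge),
                  mean(by_comp[[cp]]$hydropathy)))

rows <- list()
for (feat in c("ndn_mean", "charge", "hydropathy", "polarity")) {
  res <- compare_groups(data.frame(value = features[[feat]],
                                   group = features$compartment),
                        "anova_tukey")
  rows[[feat]] <- tibble::tibble(feature = feat, statistic = res$statistic,
                                 p = res$p_value,
                                 tukey = paste(sprintf("%s:%.3g",
                                                       res$pairwise$contrast,
                                                       res$pairwise$p_adj),
                                               collapse = "; "))
  message(sprintf("ANOVA %-10s F = %6.2f, p = %.3g", feat, res$statistic,
                  res$p_value))
}
readr::write_csv(dplyr::bind_rows(rows),
                 file.path(out, "cdr3_feature_comparisons.csv"))
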