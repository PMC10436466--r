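#!/usr/bin/env Rscript
# Repertoire structure: normalized Shannon-Wiener diversity (nt level) and
# convergent-recombination level per sample; paired CD4-vs-CD8 diversity
# on matching slices; diversity vs %CD4 in the initial cultures; public
# CDR3aa sequences across patient-merged biopsies and the publicity x
# convergence cross-tabulation.

suppressPackageStartupMessages(library(tilrep))
source("analysis/common.R")

out <- "results/analysis"
cohort <- load_preprocessed_cohort()

st <- stats_table(cohort, level = "nt")
readr::write_tsv(st, file.path(out, "diversity_cr.tsv"))
for (cp in unique(st$compartment))
  message(sprintf("%-14s nS-W %.3f +/- %.3f   CR %.3f", cp,
                  mean(st$nsw[st$compartment == cp]),
                  sd(st$nsw[st$compartment == cp]),
                  mean(st$cr_level[st$compartment == cp])))

cd4 <- st[st$compartment == "TILs-CD4+", ]
cd8 <- st[st$compartment == "TILs-CD8+", ]
key <- function(s) sub("TILs-CD[48]\\+_", "", s)
cd8 <- cd8[match(key(cd4$sample_id), key(cd8$sample_id)), ]
paired <- compare_groups(data.frame(x = cd8$nsw, y = cd4$nsw), "paired_t")
message(sprintf("paired slice diversity CD8-CD4: t = %.2f, p = %.3g",
                paired$statistic, paired$p_value))

corr <- correlate_diversity_composition(cohort, "TILs-initial")
message(sprintf("nS-W vs %%CD4: r = %.3f (p = %.3g); vs %%CD8: r = %.3f",
                corr$cd4$statistic, corr$cd4$p_value, corr$cd8$statistic))

pub_rows <- list(); ct_rows <- list()
for (cp in c("TILs-CD4+", "TILs-CD8+")) {
  pb <- public_sequences(cohort, cp)
  ct <- publicity_convergence_crosstab(cohort, cp)
  pub_rows[[cp]] <- tibble::tibble(
    compartment = cp, n_public = pb$n_public,
    percent_public = pb$percent_public, n_biopsies = pb$n_biopsies)
  ct_rows[[cp]] <- tibble::tibble(
    compartment = cp,
    public_convergent = ct$table["public", "convergent"],
    public_nonconvergent = ct$table["public", "non_convergent"],
    private_convergent = ct$table["private", "convergent"],
    private_nonconvergent = ct$table["private", "non_convergent"],
    pct_public_among_convergent = ct$pct_public_convergent,
    pct_public_among_nonconvergent = ct$pct_public_nonconvergent)
  message(sprintf("%s: %d public (%.2f%%); public|convergent %.1f%% vs public|non-convergent %.1f%%",
                  cp, pb$n_public, pb$percent_public,
                  ct$pct_public_convergent, ct$pct_public_nonconvergent))
}
readr::write_csv(dplyr::bind_rows(pub_rows),
                 file.path(out, "publicity.csv"))
readr::write_csv(dplyr::bind_rows(ct_rows),
                 file.path(out, "publicity_convergence_crosstab.csv"))

results <- tibble::tibble(
  panel = c("paired_diversity", "nsw_vs_pct_cd4", "nsw_vs_pct_cd8"),
  method = c(paired$method, corr$cd4$method, corr$cd8$method),
  statistic = c(paired$statistic, corr$cd4$statistic, corr$cd8$statistic),
  p = c(paired$p_value, corr$cd4$p_value, corr$cd8$p_value))
readr::write_csv(results, file.path(out, "diversity_comparisons.csv"))
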