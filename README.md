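# tilrep

TCR repertoire analysis of CD4+ and CD8+ tumor-infiltrating lymphocytes
(TILs), for immunologists comparing the receptor repertoires of sorted
T-cell subsets from tumor biopsies against initial cultures and
peripheral controls. Starting from clonotype tables (VDJTools-dialect or
AIRR Rearrangement TSV), the package covers the full comparison:

* **Preprocessing** — productive filter, cross-sample decontamination,
  biopsy-slice merging per patient, amino-acid collapse.
* **CDR3 physicochemistry** — CDR3nt and N(D)Nnt length statistics and
  frequency-weighted profiles of the central CDR3aa 5-mer
  (`sum_i f_i * score_i` over charge, Kyte–Doolittle hydropathy,
  polarity).
* **Repertoire structure** — normalized Shannon–Wiener diversity
  `nsw = H / log(S)` with `H = -sum f_i log f_i`; convergent
  recombination level `CR = |distinct CDR3nt| / |distinct CDR3aa|`;
  public CDR3aa sequences (shared by ≥ 2 biopsies) and the
  publicity-by-convergence cross-tabulation.
* **Motif discovery** — GLIPH2-style screen of interior CDR3aa k-mers
  (exact 3–5-mers, single-wildcard 5–7-mers such as `SLGG%GE`), scored
  by a one-sided hypergeometric (Fisher) enrichment p-value against a
  reference repertoire and a permutation clonal-expansion p-value, with
  cross-biopsy sharing tables.
* **Annotation** — candidate sets (frequency > 0.1%, public, clustered)
  matched to a specificity database at Levenshtein distance ≤ 1, with
  cancer annotations propagated across motif clusters.
* **Statistics** — one-way ANOVA + Tukey, paired t, two-way ANOVA +
  Sidak, Pearson, as one contract-tested layer.
* **Synthetic cohorts** — a seeded V(D)J generator with controllable
  junction length, central-window charge bias, clone-size law (and hence
  diversity), convergence, publicity, planted motifs and non-productive
  contamination, so every stage is testable against known truth.

See `vignettes/repertoire-methods.Rmd` for the methods account.

## Worked example

Simulate a CD4-like and a CD8-like repertoire at the study presets and
compare them:

```r
library(tilrep)

cd4 <- generate_repertoire(til_cd4_preset(2000, seed = 7), "CD4")
cd8 <- generate_repertoire(til_cd8_preset(2000, seed = 7), "CD8")

mean(ndn_length(cd4), na.rm = TRUE)   # 14.40924
mean(ndn_length(cd8), na.rm = TRUE)   # 11.41623
normalized_shannon_wiener(cd4)$nsw    # 0.3823308
normalized_shannon_wiener(cd8)$nsw    # 0.5111713
repertoire_property_profile(collapse_by_aa(cd4), "charge")  #  0.2205879
repertoire_property_profile(collapse_by_aa(cd8), "charge")  # -0.2875383
```

The CD4-like repertoire shows the longer N(D)N junction (14.4 vs 11.4
nt), the lower diversity (0.38 vs 0.51) and the more positively charged
central 5-mer — the three planted compartment differences, recovered by
the estimators that the real analysis would apply to sequenced TILs.

The numbered scripts under `analysis/` run the full study analogue from
files (simulate → preprocess → features → diversity/publicity → motifs →
annotation → end-to-end pipeline), writing tables under
`results/analysis/`. For example:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/04_diversity_publicity.R
#> TILs-initial   nS-W 0.427 +/- 0.021   CR 1.045
#> TILs-CD4+      nS-W 0.376 +/- 0.007   CR 1.052
#> TILs-CD8+      nS-W 0.505 +/- 0.009   CR 1.049
#> paired slice diversity CD8-CD4: t = 31.51, p = 8.38e-09
#> nS-W vs %CD4: r = -0.991 (p = 1.91e-06); vs %CD8: r = 0.991
#> TILs-CD4+: 28 public (0.60%); public|convergent 10.3% vs public|non-convergent 0.0%
#> TILs-CD8+: 15 public (0.32%); public|convergent 6.2% vs public|non-convergent 0.0%
```

Public sequences concentrate among convergent clonotypes, diversity is
lower in the CD4 compartment and inversely correlated with the CD4
percentage of the initial cultures — the qualitative structure the
pipeline is built to detect. `run_pipeline(demo_config(seed = 1))` runs
the same stages end-to-end from one config and is byte-identical across
runs at a fixed seed.

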