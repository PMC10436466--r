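---
title: "Methods: comparing CD4+ and CD8+ TIL receptor repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing CD4+ and CD8+ TIL receptor repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tilrep` implements a complete comparison of T-cell receptor (TCR)
repertoires between CD4+ and CD8+ tumor-infiltrating lymphocytes (TILs),
starting from clonotype tables (VDJTools-dialect or AIRR Rearrangement
TSV) rather than raw reads. This vignette is the package's own account of
the models and conventions behind each stage, the knobs that matter, and
what the synthetic cohort generator does and does not emulate.

## The analysis model

A *clonotype* is a unique rearrangement keyed by CDR3 nucleotide sequence
plus V/J gene calls, with an abundance. Preprocessing mirrors the
standard repertoire toolchain:

1. **Productive filter** — clonotypes whose CDR3aa contains a stop (`*`)
   or frameshift (`_`) marker, or whose CDR3nt length is not divisible by
   3, are removed and frequencies renormalized. The frame rule serves as
   the productivity proxy because an aligner's out-of-frame flag is not
   available downstream of a clonotype table.
2. **Decontamination** — a clonotype (matched on CDR3nt + V + J) is
   removed from a sample when any other sample carries it at a frequency
   at least 20x higher. The ratio and match key are conventions of the
   VDJTools ecosystem, exposed as configuration because no published
   values exist for them; decisions are taken simultaneously from the
   input frequencies so a single pass is idempotent in practice.
3. **Patient merging** — biopsy-slice samples of one patient are pooled
   by summing counts per clonotype; publicity is only ever computed on
   patient-merged repertoires, so slice-level sharing within one patient
   never counts as "public".
4. **Amino-acid collapse** — nucleotide variants encoding the same CDR3aa
   are summed (the number of distinct variants is retained per CDR3aa).
   Collapse precedes the length, physicochemistry and motif analyses.

### CDR3 physicochemistry

The N(D)N length of a clonotype is `j_start - v_end` in CDR3-local
0-based coordinates: the non-germline nucleotides between the V and J
contributions. Missing reference points propagate as missing values,
never as 0. Property profiles are computed on the central 5-mer of the
CDR3aa, i.e. the window of length 5 starting at `floor((L - 5) / 2)`;
even-length ties shift the window toward the N-terminus (a fixed
convention — none is standard). The per-sample profile is the
frequency-weighted mean of per-peptide mean property values,
`sum_i f_i * score_i`, with frequencies renormalized over the sequences
long enough for the window. Three residue scales ship registered:

* `charge`: K = R = +1, D = E = -1, H = 0 (physiological-pH convention),
  all others 0;
* `hydropathy`: Kyte–Doolittle;
* `polarity`: binary indicator over {N, Q, S, T, Y, C, H, K, R, D, E}.

Published profile magnitudes depend on the (unpublished) scales a given
toolchain uses, so profile values are comparable within an analysis but
not across toolchains; the package treats group *ordering*, not absolute
magnitude, as the reproducible quantity.

### Diversity, convergence, publicity

Diversity is the normalized Shannon–Wiener index `nsw = H / log(S)` with
`H = -sum f_i log f_i` (nats) and `S` the clonotype richness at the
requested level (nucleotide by default; amino-acid optional). A
monoclonal sample is defined to have `nsw = 0`, the limit-consistent
convention that avoids 0/0. No downsampling or rarefaction is applied
before diversity — a caveat worth knowing, since `nsw` is
depth-sensitive; samples compared here are simulated at equal depth.

The convergent-recombination (CR) level of an amino-acid-collapsed
repertoire is (distinct CDR3nt) / (distinct CDR3aa) >= 1; a CDR3aa with
two or more nucleotide variants is flagged convergent. A CDR3aa is
public when present in at least two patient-merged biopsies of a
compartment. The publicity-by-convergence cross-tabulation pools each
compartment's amino-acid universe across patients, counting a sequence
convergent when its patients together carry two or more nucleotide
variants.

### Motif discovery

The motif screen follows the GLIPH2 idea: short local CDR3aa patterns
shared by several clonotypes indicate probable shared antigen
specificity. Motifs are drawn from the CDR3 *interior* — the first 3 and
last 2 residues are excluded, the GLIPH convention that removes the
germline-encoded flanks — as exact k-mers (k = 3, 4, 5) and as
single-wildcard windows (length 5–7) where `%` matches any one residue.
The wildcard may occupy any position except the last; published motifs
such as `%NYSNQP` lead with it.

Each motif with at least `min_carriers` distinct carriers is scored
against an explicit reference repertoire:

* **Fisher score** — the one-sided hypergeometric tail probability of the
  2x2 table (carrier / non-carrier) x (sample / reference), counting
  distinct amino-acid clonotypes. Smaller is stronger.
* **Expansion score** — a permutation p-value that the carriers' summed
  frequency exceeds that of random same-size clonotype sets
  (`(1 + #{null >= observed}) / (B + 1)`, B = 1000 by default). This is
  this package's own formulation of a clonal-expansion criterion that the
  upstream literature names but does not define; it is an approximation
  of the cited tool's behavior, not a reimplementation.

A motif passes when both scores fall at or below their thresholds
(default 0.5 for both — the published description is internally
inconsistent about the direction of its 0.5 cut-offs, and the
p-value-like reading "smaller = stronger, keep <= 0.5" is adopted; both
thresholds are configuration). Exact motifs literally contained in a
passing longer motif with the identical carrier set are suppressed as
redundant. Within one screen the permutation null sums are drawn once
per carrier-set size and shared across motifs of that size: each motif's
p-value is valid against that common null; only independence between
motif scores is traded for an order-of-magnitude speedup. The public
`score_motif()` draws fresh permutations.

### Annotation

Candidate sequences — the union of the high-frequency set
(frequency > 0.1%), the public set, and the motif-clustered set — are
matched to a specificity database (CSV: `cdr3aa,category,source`, with
categories allergy / autoimmunity / cancer / pathogens) at Levenshtein
distance <= 1. The edit distance is the standard unit-cost dynamic
program; matching applies a length pre-filter and, for distance <= 1, an
exact linear-time check. Matching is CDR3aa-only: whether a published
match should also require equal V genes or chain pairing is not
specified upstream, and CDR3-only matching is the more permissive,
screening-oriented choice. A direct cancer match inside a motif cluster
annotates the cluster's remaining members as putatively
tumor-associated ("propagated"); other categories are recorded but not
propagated by default (configurable), and sequences matching several
categories retain all of them.

### Statistical layer

`compare_groups()` wraps the four designs used throughout: one-way ANOVA
with Tukey HSD, paired t, two-way ANOVA with Sidak-adjusted pairwise
contrasts (pooled residual variance, `p_adj = 1 - (1 - p)^m`), and
Pearson correlation. Degenerate inputs (group of size < 2, zero variance
where variance is required) raise explicit errors rather than
propagating NaN; the one deliberate exception is a paired t on identical
pairs, which returns statistic 0 and p = 1 — the correct "no difference"
answer for a comparison that is a fixture of paired designs. Normality
is not tested before the parametric tests, matching common practice in
the source analyses; treat small-sample p-values accordingly. No
multiple-testing control is applied across panels.

## The synthetic cohort generator

Every stage is testable without sequencing data because the generator
emulates the statistical structure of the study's samples. A clonotype
is built as germline V flank + uniform-random N(D)N + germline J flank
from a toy set of 8 V and 6 J CDR3 flanks whose lengths cover all
residue classes mod 3, so any junction length can be kept in frame; stop
codons are removed by resampling the junction. The toy flanks remove any
external reference dependency while preserving V/J-derived
prefix/suffix structure; gene labels are synthetic.

The study-condition presets are the compartment statistics reported for
the system being emulated, and they are fixed:

| preset | N(D)N (nt) | central charge bias | target nS-W |
|---|---|---|---|
| `til_cd4_preset()` | 14.4 ± 3.1 | +0.06 | 0.38 |
| `til_cd8_preset()` | 11.4 ± 2.2 | −0.04 | 0.51 |
| `til_initial_preset()` | 13.8 ± 2.1 | −0.01 | 0.45 |

Mechanisms behind the knobs:

* **Junction length** — rounded Gaussian truncated at 0.
* **Charge bias** — each central-5mer codon lying fully inside the N(D)N
  is replaced by a K/R codon (positive bias) or D/E codon (negative
  bias) with probability `min(1, 5|bias|)`. The mapping from bias to
  replacement probability is a one-time design choice; it reproduces the
  *sign and ordering* of the compartment difference, not any particular
  absolute profile value (which is scale-dependent, see above).
* **Clone sizes / diversity** — geometric counts, or Zipf rank-frequency
  counts realized as `1 +` a multinomial draw of `20 S` reads. For a
  requested `target_nsw` the Zipf exponent is solved numerically from
  the expected count distribution, so a preset's diversity is planted by
  construction and recovered by measurement.
* **Convergence** — with probability `convergence_rate` (default 0.05, so
  baseline CR ≈ 1.05) a clonotype gains one synonymous nucleotide
  variant with a small geometric count.
* **Planted motifs** — embedded at random interior positions of distinct
  carrier sequences, wildcards realized per carrier; infeasible plants
  (motif longer than any interior, or more carriers than clonotypes) are
  rejected with explicit errors.
* **Publicity** — listed CDR3aa sequences are injected into exactly the
  requested number of patients and scrubbed from the rest. Public
  sequences also arise naturally from short-junction clonotypes that
  collide across patients — the convergent-recombination route to
  publicity.
* **Non-productive contamination** — optional in-frame stop codons
  inside the N(D)N, to exercise the productive filter.
* **Composition** — optionally, a per-patient CD4 percentage is drawn
  (uniform on 20–80% unless supplied) and the initial compartment's
  diversity target is the composition-weighted mixture of the CD4 and
  CD8 targets; this plants the inverse diversity-vs-%CD4 correlation
  that the correlation analysis then recovers.

Identical seeds give byte-identical repertoires, cohorts, and pipeline
outputs; a cohort's per-sample seeds are derived from the master seed.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: biological V/D/J gene-usage
frequencies, thymic selection, sequencing error and UMI structure,
read-depth variation between samples, HLA-driven sharing structure, and
any true antigen-specificity signal behind motifs. Planted-parameter
recovery demonstrates that the estimators measure what they claim on
data with known truth, not that real TIL repertoires behave like the
simulator.

## Numerical choices and edge cases

* Frequencies are renormalized after every removal step and validated to
  sum to 1 within 1e-6 before diversity computation.
* Reference points are 0-based, half-open, CDR3-local; missing points are
  `NA` in memory, `-1` in VDJTools files, empty in AIRR files (AIRR
  coordinates are converted from 1-based inclusive).
* Written tables sort by descending count with ties broken by CDR3nt and
  print frequencies with `%.10g`, so outputs are diff-stable;
  frequencies are always recomputed from counts on read.
* `nsw` at S = 1 is 0 by convention; `cr_level` depends only on distinct
  sequence counts and is invariant under count rescaling.
* The Fisher tail uses the exact hypergeometric distribution function;
  the test suite cross-checks it against an independent exact-test
  implementation at 1e-10, the edit distance against an independent DP
  at exactness, and diversity/profiles against brute-force loops at
  1e-12.

## Problem sizes used in the shipped analyses

The `analysis/` scripts simulate 4 patients x 2 slices x 3 compartments
at 600 clonotypes per sample; the acceptance computations use 8-patient
cohorts at 2000 clonotypes per sample, 20-replicate recovery
simulations, and 1000-replicate type-I calibrations. These sizes give
the recovery analyses comfortable power (the planted effects are several
standard errors wide) while keeping a full run in the minutes range on
one core; all of them are configuration, not constants.

## Known limitations

* Depth-sensitivity of `nsw` is unaddressed (no rarefaction), as in the
  emulated workflow.
* The expansion score is a permutation formulation of a criterion whose
  published definition is unavailable; its absolute values should not be
  compared against other tools' "expansion scores".
* Decontamination parameters are conventions; on real multi-run data the
  ratio should be tuned to the observed index-hopping rate.
* The annotation stage inherits the coverage biases of whatever
  specificity database it is pointed at; category counts are only as
  balanced as the database.
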