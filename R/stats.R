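# Diversity, convergent recombination, publicity, and their
# cross-tabulation.

#' Normalized Shannon-Wiener diversity
#'
#' `H = -sum f_i log f_i` over clonotypes at the requested level and
#' `nsw = H / log(S)` for richness `S >= 2`; a monoclonal sample has
#' `nsw = 0` by convention. The default level is `nt` (distinct nucleotide
#' clonotypes); `aa` collapses first.
#'
#' @param rep a `tcr_repertoire` (or, for `level = "aa"`, an
#'   `aa_repertoire`).
#' @param level `"nt"` or `"aa"`.
#' @return list of class `diversity_result`: `H` (nats), `S`, `nsw`.
#' @export
normalized_shannon_wiener <- function(rep, level = c("nt", "aa")) {
  level <- match.arg(level)
  f <- if (inherits(rep, "aa_repertoire")) {
    rep$freq
  } else if (level == "aa") {
    collapse_by_aa(rep)$freq
  } else {
    rep$clonotypes$freq
  }
  if (length(f) == 0) stop("empty repertoire")
  if (abs(sum(f) - 1) > 1e-6)
    stop("frequencies not normalized (sum = ", format(sum(f)), ")")
  S <- length(f)
  H <- -sum(f * log(f))
  structure(list(H = H, S = S, nsw = if (S >= 2) H / log(S) else 0),
            class = "diversity_result")
}

#' Convergent recombination level
#'
#' `cr_level` = (number of distinct CDR3nt) / (number of distinct CDR3aa)
#' = mean nucleotide-variant count per amino-acid clonotype; an amino-acid
#' clonotype is flagged convergent when it is encoded by >= 2 distinct
#' nucleotide sequences.
#'
#' @param aa_rep an `aa_repertoire` with `nt_variant_count` populated.
#' @return list of class `convergence_result`: `cr_level`, `per_aa` tibble
#'   (`cdr3_aa`, `nt_variant_count`, `convergent`).
#' @export
convergence <- function(aa_rep) {
  if (nrow(aa_rep) == 0) stop("empty repertoire")
  per_aa <- tibble::tibble(cdr3_aa = aa_rep$cdr3_aa,
                           nt_variant_count = aa_rep$nt_variant_count,
                           convergent = aa_rep$nt_variant_count >= 2L)
  structure(list(cr_level = sum(per_aa$nt_variant_count) / nrow(per_aa),
                 per_aa = per_aa),
            class = "convergence_result")
}

#' Public CDR3aa sequences across biopsies
#'
#' Sharing is computed over the patient-merged amino-acid repertoires of
#' one compartment: a sequence is public when present in at least
#' `min_share` patients (biopsies); slice-level sharing within one patient
#' never counts.
#'
#' @param cohort a `tcr_cohort` with >= 2 patients in the compartment.
#' @param compartment compartment label.
#' @param min_share minimum number of biopsies for the public flag.
#' @return list of class `publicity_result`: `per_aa` tibble (`cdr3_aa`,
#'   `share`, `public`), `n_biopsies`, `n_public`, `percent_public`.
#' @export
public_sequences <- function(cohort, compartment, min_share = 2L) {
  merged <- merge_by_patient(cohort, compartment)
  if (length(merged) < 2)
    stop("publicity needs >= 2 biopsies; compartment '", compartment,
         "' has ", length(merged))
  aa_sets <- lapply(merged, function(r) unique(r$clonotypes$cdr3_aa))
  share <- table(unlist(aa_sets, use.names = FALSE))
  per_aa <- tibble::tibble(cdr3_aa = names(share),
                           share = as.integer(share))
  per_aa$public <- per_aa$share >= min_share
  per_aa <- per_aa[order(-per_aa$share, per_aa$cdr3_aa), ]
  structure(list(per_aa = per_aa,
                 n_biopsies = length(merged),
                 n_public = sum(per_aa$public),
                 percent_public = 100 * mean(per_aa$public)),
            class = "publicity_result")
}

#' Publicity x convergence cross-tabulation
#'
#' Both properties are computed over the pooled amino-acid universe of one
#' compartment: an amino-acid sequence is convergent when its patients
#' together carry >= 2 distinct nucleotide variants, and public when it
#' occurs in >= `min_share` patients.
#'
#' @param cohort a `tcr_cohort`.
#' @param compartment compartment label.
#' @param min_share publicity threshold.
#' @return list of class `crosstab_result`: `table` (2x2 matrix
#'   public/private x convergent/non-convergent), `pct_public_convergent`,
#'   `pct_public_nonconvergent`.
#' @export
publicity_convergence_crosstab <- function(cohort, compartment,
                                           min_share = 2L) {
  merged <- merge_by_patient(cohort, compartment)
  if (length(merged) < 2) stop("crosstab needs >= 2 biopsies")
  pooled <- dplyr::bind_rows(lapply(merged, function(r)
    tibble::tibble(patient = r$patient_id,
                   cdr3_aa = r$clonotypes$cdr3_aa,
                   cdr3_nt = r$clonotypes$cdr3_nt)))
  per_aa <- pooled |>
    dplyr::group_by(.data$cdr3_aa) |>
    dplyr::summarise(share = dplyr::n_distinct(.data$patient),
                     nt_variants = dplyr::n_distinct(.data$cdr3_nt),
                     .groups = "drop")
  public <- per_aa$share >= min_share
  convergent <- per_aa$nt_variants >= 2L
  tab <- matrix(c(sum(public & convergent), sum(public & !convergent),
                  sum(!public & convergent), sum(!public & !convergent)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("public", "private"),
                                c("convergent", "non_convergent")))
  structure(list(
    table = tab,
    pct_public_convergent =
      if (sum(convergent)) 100 * sum(public & convergent) / sum(convergent)
      else NA_real_,
    pct_public_nonconvergent =
      if (sum(!convergent)) 100 * sum(public & !convergent) / sum(!convergent)
      else NA_real_
  ), class = "crosstab_result")
}

#' Per-sample repertoire statistics table
#'
#' @param cohort a `tcr_cohort`.
#' @param level diversity level, `"nt"` or `"aa"`.
#' @return tibble: `sample_id`, `compartment`, `level`, `S`, `H`, `nsw`,
#'   `cr_level`.
#' @export
stats_table <- function(cohort, level = "nt") {
  dplyr::bind_rows(lapply(cohort$repertoires, function(r) {
    dv <- normalized_shannon_wiener(r, level)
    cr <- convergence(collapse_by_aa(r))
    tibble::tibble(sample_id = r$sample_id, patient_id = r$patient_id,
                   compartment = r$compartment, level = level,
                   S = dv$S, H = dv$H, nsw = dv$nsw,
                   cr_level = cr$cr_level)
  }))
}
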