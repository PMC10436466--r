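#' Construct a repertoire object
#'
#' A repertoire is one sample's clonotype table plus its metadata. The
#' clonotype table must carry `cdr3_nt`, `cdr3_aa`, `v_call`, `d_call`,
#' `j_call`, `count`, `freq` and the CDR3-local reference points `v_end`,
#' `d_start`, `d_end`, `j_start` (0-based nt offsets within `cdr3_nt`;
#' `NA` = unknown, never 0).
#'
#' @param clonotypes data frame of clonotypes (see Details).
#' @param sample_id,patient_id,compartment,chain sample metadata;
#'   `compartment` is a label such as `"TILs-initial"`, `"TILs-CD4+"`,
#'   `"TILs-CD8+"`.
#' @param pct_cd4,pct_cd8 optional flow-cytometry composition of the sample
#'   (percent), used by [correlate_diversity_composition()].
#' @param normalize recompute `freq` as `count / sum(count)`.
#' @return An object of class `tcr_repertoire`.
#' @export
new_repertoire <- function(clonotypes, sample_id, patient_id = sample_id,
                           compartment = "unknown", chain = "TRB",
                           pct_cd4 = NA_real_, pct_cd8 = NA_real_,
                           normalize = FALSE) {
  clonotypes <- tibble::as_tibble(clonotypes)
  required <- c("cdr3_nt", "cdr3_aa", "v_call", "d_call", "j_call",
                "count", "freq", "v_end", "d_start", "d_end", "j_start")
  missing_cols <- setdiff(required, names(clonotypes))
  if ("freq" %in% missing_cols || normalize) {
    clonotypes$freq <- clonotypes$count / sum(clonotypes$count)
    missing_cols <- setdiff(missing_cols, "freq")
  }
  if (length(missing_cols))
    stop("clonotype table lacks column(s): ", paste(missing_cols, collapse = ", "))
  clonotypes <- clonotypes[required]
  validate_clonotypes(clonotypes)
  structure(
    list(sample_id = sample_id, patient_id = patient_id,
         compartment = compartment, chain = chain,
         pct_cd4 = pct_cd4, pct_cd8 = pct_cd8,
         clonotypes = clonotypes),
    class = "tcr_repertoire"
  )
}

validate_clonotypes <- function(cl) {
  if (nrow(cl) == 0) stop("empty clonotype table")
  if (any(cl$count < 0)) stop("negative counts")
  if (any(cl$freq < 0 | cl$freq > 1)) stop("freq outside [0, 1]")
  has_pts <- !is.na(cl$v_end) & !is.na(cl$j_start)
  if (any(has_pts)) {
    ok <- cl$v_end[has_pts] >= 0 &
      cl$v_end[has_pts] <= cl$j_start[has_pts] &
      cl$j_start[has_pts] <= nchar(cl$cdr3_nt[has_pts])
    if (!all(ok)) {
      bad <- which(has_pts)[!ok]
      stop("inconsistent reference points for clonotype(s) ",
           paste(cl$cdr3_nt[head(bad, 3)], collapse = ", "))
    }
  }
  invisible(cl)
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("<tcr_repertoire> %s  patient=%s  %s  %s  %d clonotypes\n",
              x$sample_id, x$patient_id, x$compartment, x$chain,
              nrow(x$clonotypes)))
  invisible(x)
}

renormalize <- function(rep) {
  rep$clonotypes$freq <- rep$clonotypes$count / sum(rep$clonotypes$count)
  rep
}

#' Construct a cohort of repertoires
#'
#' @param repertoires list of [new_repertoire()] objects with unique
#'   `sample_id`s.
#' @param reference optional background repertoire used for motif scoring.
#' @return An object of class `tcr_cohort`.
#' @export
new_cohort <- function(repertoires, reference = NULL) {
  stopifnot(length(repertoires) >= 1)
  ids <- vapply(repertoires, function(r) r$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample_id in cohort")
  names(repertoires) <- ids
  structure(list(repertoires = repertoires, reference = reference),
            class = "tcr_cohort")
}

#' @export
print.tcr_cohort <- function(x, ...) {
  md <- cohort_metadata(x)
  cat(sprintf("<tcr_cohort> %d samples, %d patients, compartments: %s\n",
              nrow(md), length(unique(md$patient_id)),
              paste(unique(md$compartment), collapse = ", ")))
  invisible(x)
}

#' Sample metadata of a cohort
#'
#' @param cohort a `tcr_cohort`.
#' @return tibble with one row per sample: ids, compartment, chain,
#'   composition, clonotype count.
#' @export
cohort_metadata <- function(cohort) {
  dplyr::bind_rows(lapply(cohort$repertoires, function(r) {
    tibble::tibble(sample_id = r$sample_id, patient_id = r$patient_id,
                   compartment = r$compartment, chain = r$chain,
                   pct_cd4 = r$pct_cd4, pct_cd8 = r$pct_cd8,
                   n_clonotypes = nrow(r$clonotypes))
  }))
}

#' Merge all biopsy-slice samples of each patient
#'
#' Pools the slices of every patient within one compartment into a single
#' patient-level repertoire (see [merge_samples()]).
#'
#' @param cohort a `tcr_cohort`.
#' @param compartment compartment label to merge within.
#' @return named list of patient-level `tcr_repertoire`s.
#' @export
merge_by_patient <- function(cohort, compartment) {
  md <- cohort_metadata(cohort)
  keep <- md$sample_id[md$compartment == compartment]
  if (length(keep) == 0) stop("no samples in compartment '", compartment, "'")
  sel <- cohort$repertoires[keep]
  patients <- split(sel, vapply(sel, function(r) r$patient_id, character(1)))
  lapply(patients, merge_samples)
}
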