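# Reading / writing clonotype tables in the two dialects the toolchain
# around MiXCR produces: the VDJTools flat table and the AIRR Rearrangement
# TSV. Reference points are stored 0-based and half-open within the CDR3;
# missing points are -1 on disk (VDJTools) or empty (AIRR) and NA in memory.

VDJTOOLS_COLS <- c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j",
                   "VEnd", "DStart", "DEnd", "JStart")
AIRR_COLS <- c("junction", "junction_aa", "v_call", "d_call", "j_call",
               "duplicate_count")
AIRR_POINT_COLS <- c("v_sequence_end", "d_sequence_start",
                     "d_sequence_end", "j_sequence_start")

#' Read a clonotype table
#'
#' Parses a VDJTools-dialect or AIRR Rearrangement TSV into a repertoire.
#' Frequencies are always recomputed from counts so that files written with
#' rounded frequencies still satisfy the sum-to-one invariant. Metadata not
#' given explicitly is taken from the filename, which by convention is
#' `<patient>_<compartment>_<slice>.<ext>`; a name without underscores is
#' used verbatim as both `sample_id` and `patient_id`.
#'
#' @param path TSV file path.
#' @param dialect `"vdjtools"` or `"airr"`.
#' @param sample_id,patient_id,compartment,chain optional metadata
#'   overriding the filename convention.
#' @return a `tcr_repertoire`.
#' @export
read_clonotype_table <- function(path, dialect = c("vdjtools", "airr"),
                                 sample_id = NULL, patient_id = NULL,
                                 compartment = NULL, chain = "TRB") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) stop("empty clonotype table: ", path)

  if (dialect == "vdjtools") {
    check_header(names(raw), VDJTOOLS_COLS, path)
    cl <- tibble::tibble(
      cdr3_nt = raw$cdr3nt, cdr3_aa = raw$cdr3aa,
      v_call = raw$v, d_call = ifelse(raw$d == ".", NA_character_, raw$d),
      j_call = raw$j,
      count = parse_count(raw$count, path),
      freq = NA_real_,
      v_end = parse_point(raw$VEnd), d_start = parse_point(raw$DStart),
      d_end = parse_point(raw$DEnd), j_start = parse_point(raw$JStart)
    )
  } else {
    base_ok <- all(AIRR_COLS %in% names(raw))
    extra <- setdiff(names(raw), c(AIRR_COLS, AIRR_POINT_COLS))
    if (!base_ok || length(extra))
      check_header(names(raw), AIRR_COLS, path)
    pt <- function(col, shift = 0L) {
      if (col %in% names(raw)) parse_point(raw[[col]]) - shift else NA_integer_
    }
    cl <- tibble::tibble(
      cdr3_nt = raw$junction, cdr3_aa = raw$junction_aa,
      v_call = raw$v_call,
      d_call = ifelse(is.na(raw$d_call) | raw$d_call == "", NA_character_,
                      raw$d_call),
      j_call = raw$j_call,
      count = parse_count(raw$duplicate_count, path),
      freq = NA_real_,
      # AIRR coordinates are 1-based inclusive; internal ones 0-based
      # half-open, so ends map verbatim and starts shift by one.
      v_end = pt("v_sequence_end"),
      d_start = pt("d_sequence_start", 1L),
      d_end = pt("d_sequence_end"),
      j_start = pt("j_sequence_start", 1L)
    )
  }

  meta <- filename_metadata(path)
  new_repertoire(cl,
                 sample_id = sample_id %||% meta$sample_id,
                 patient_id = patient_id %||% meta$patient_id,
                 compartment = compartment %||% meta$compartment,
                 chain = chain, normalize = TRUE)
}

check_header <- function(got, want, path) {
  if (!identical(sort(got), sort(want)) || length(got) != length(want)) {
    stop("unexpected header in ", path, ": got [",
         paste(got, collapse = ", "), "], expected [",
         paste(want, collapse = ", "), "]")
  }
  invisible(TRUE)
}

parse_count <- function(x, path) {
  n <- suppressWarnings(as.numeric(x))
  bad <- is.na(n) | n < 0 | n != round(n)
  if (any(bad)) {
    stop("invalid count '", x[which(bad)[1]], "' at data row ",
         which(bad)[1], " of ", path)
  }
  as.integer(n)
}

parse_point <- function(x) {
  n <- suppressWarnings(as.integer(x))
  n[!is.na(n) & n < 0] <- NA_integer_
  n
}

filename_metadata <- function(path) {
  stem <- tools::file_path_sans_ext(basename(path))
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  list(sample_id = stem,
       patient_id = if (length(parts) >= 2) parts[1] else stem,
       compartment = if (length(parts) >= 2) parts[2] else "unknown")
}

#' Write a clonotype table
#'
#' Emits a deterministic, diff-stable file: clonotypes sorted by descending
#' count with ties broken by `cdr3_nt`, frequencies printed with `%.10g`.
#'
#' @param rep a `tcr_repertoire`.
#' @param path output TSV path.
#' @param dialect `"vdjtools"` or `"airr"`.
#' @export
write_clonotype_table <- function(rep, path, dialect = c("vdjtools", "airr")) {
  dialect <- match.arg(dialect)
  cl <- rep$clonotypes
  if (nrow(cl) == 0) stop("refusing to write an empty repertoire")
  cl <- cl[order(-cl$count, cl$cdr3_nt), ]
  fmt_pt <- function(p, sentinel) ifelse(is.na(p), sentinel, as.character(p))
  if (dialect == "vdjtools") {
    out <- data.frame(
      count = cl$count,
      freq = sprintf("%.10g", cl$freq),
      cdr3nt = cl$cdr3_nt, cdr3aa = cl$cdr3_aa,
      v = cl$v_call, d = ifelse(is.na(cl$d_call), ".", cl$d_call),
      j = cl$j_call,
      VEnd = fmt_pt(cl$v_end, "-1"), DStart = fmt_pt(cl$d_start, "-1"),
      DEnd = fmt_pt(cl$d_end, "-1"), JStart = fmt_pt(cl$j_start, "-1"),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(
      junction = cl$cdr3_nt, junction_aa = cl$cdr3_aa,
      v_call = cl$v_call, d_call = ifelse(is.na(cl$d_call), "", cl$d_call),
      j_call = cl$j_call, duplicate_count = cl$count,
      v_sequence_end = fmt_pt(cl$v_end, ""),
      d_sequence_start = fmt_pt(cl$d_start + 1L, ""),
      d_sequence_end = fmt_pt(cl$d_end, ""),
      j_sequence_start = fmt_pt(cl$j_start + 1L, ""),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Remove non-productive clonotypes
#'
#' Drops clonotypes whose CDR3aa contains a stop (`*`) or frameshift (`_`)
#' marker, or whose CDR3nt length is not divisible by 3 (frame rule, used
#' as the productivity proxy downstream of the aligner). Frequencies are
#' renormalized over the survivors.
#'
#' @param rep a `tcr_repertoire`.
#' @return filtered `tcr_repertoire`.
#' @export
filter_productive <- function(rep) {
  cl <- rep$clonotypes
  keep <- !grepl("[*_]", cl$cdr3_aa) & nchar(cl$cdr3_nt) %% 3 == 0
  if (!any(keep)) stop("no productive clonotypes left in ", rep$sample_id)
  rep$clonotypes <- cl[keep, ]
  renormalize(rep)
}

#' Cross-sample decontamination
#'
#' Removes a clonotype (matched on `cdr3_nt` + `v_call` + `j_call`) from a
#' sample when any other sample in the cohort carries it at a frequency at
#' least `ratio` times higher — the routine guard against index-hopping /
#' carry-over contamination. Decisions are taken simultaneously from the
#' input frequencies; survivors are renormalized per sample.
#'
#' @param cohort a `tcr_cohort` with at least 2 samples.
#' @param ratio frequency ratio above which the low-frequency occurrence is
#'   treated as contamination (> 1).
#' @return decontaminated `tcr_cohort`.
#' @export
decontaminate <- function(cohort, ratio = 20) {
  if (!is.numeric(ratio) || ratio <= 1) stop("`ratio` must be > 1")
  reps <- cohort$repertoires
  if (length(reps) < 2) return(cohort)
  tab <- dplyr::bind_rows(lapply(reps, function(r) {
    tibble::tibble(sample_id = r$sample_id,
                   key = paste(r$clonotypes$cdr3_nt, r$clonotypes$v_call,
                               r$clonotypes$j_call, sep = "|"),
                   freq = r$clonotypes$freq)
  }))
  max_by_key <- tapply(tab$freq, tab$key, max)
  # a clonotype is contamination iff some *other* sample exceeds ratio x freq;
  # using the overall max is equivalent because ratio > 1 excludes self.
  drop_keys <- split(
    tab$key[max_by_key[tab$key] >= ratio * tab$freq],
    tab$sample_id[max_by_key[tab$key] >= ratio * tab$freq]
  )
  cohort$repertoires <- lapply(reps, function(r) {
    bad <- paste(r$clonotypes$cdr3_nt, r$clonotypes$v_call,
                 r$clonotypes$j_call, sep = "|") %in% drop_keys[[r$sample_id]]
    if (!any(bad)) return(r)
    if (all(bad)) stop("decontamination removed every clonotype of ",
                       r$sample_id)
    r$clonotypes <- r$clonotypes[!bad, ]
    renormalize(r)
  })
  cohort
}

#' Collapse a repertoire by CDR3 amino-acid sequence
#'
#' Clonotypes with different nucleotide sequences encoding the same CDR3aa
#' are summed and frequencies recalculated; the number of merged distinct
#' nucleotide variants is retained per amino-acid clonotype.
#'
#' @param rep a `tcr_repertoire`.
#' @return an `aa_repertoire` tibble with columns `cdr3_aa`, `count`,
#'   `freq`, `nt_variant_count`, and the sample's metadata as attributes.
#' @export
collapse_by_aa <- function(rep) {
  cl <- rep$clonotypes
  if (nrow(cl) == 0) stop("empty repertoire")
  agg <- cl |>
    dplyr::group_by(.data$cdr3_aa) |>
    dplyr::summarise(count = sum(.data$count),
                     nt_variant_count = dplyr::n_distinct(.data$cdr3_nt),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$cdr3_aa)
  agg$freq <- agg$count / sum(agg$count)
  out <- agg[c("cdr3_aa", "count", "freq", "nt_variant_count")]
  attr(out, "sample_id") <- rep$sample_id
  attr(out, "patient_id") <- rep$patient_id
  attr(out, "compartment") <- rep$compartment
  class(out) <- c("aa_repertoire", class(out))
  out
}

#' Merge biopsy-slice samples of one patient
#'
#' Counts are summed per (`cdr3_nt`, `v_call`, `j_call`) and frequencies
#' renormalized. All inputs must share `patient_id` and `chain`.
#'
#' @param reps list of `tcr_repertoire`s (a single repertoire is returned
#'   unchanged apart from its `sample_id`).
#' @return merged `tcr_repertoire`; `compartment` is the common label, or
#'   `"merged"` if the inputs disagree.
#' @export
merge_samples <- function(reps) {
  if (inherits(reps, "tcr_repertoire")) reps <- list(reps)
  stopifnot(length(reps) >= 1)
  pats <- unique(vapply(reps, function(r) r$patient_id, character(1)))
  chains <- unique(vapply(reps, function(r) r$chain, character(1)))
  if (length(pats) != 1) stop("cannot merge samples from different patients: ",
                              paste(pats, collapse = ", "))
  if (length(chains) != 1) stop("cannot merge different chains")
  comps <- unique(vapply(reps, function(r) r$compartment, character(1)))
  all_cl <- dplyr::bind_rows(lapply(reps, function(r) r$clonotypes))
  merged <- all_cl |>
    dplyr::group_by(.data$cdr3_nt, .data$v_call, .data$j_call) |>
    dplyr::summarise(cdr3_aa = .data$cdr3_aa[1], d_call = .data$d_call[1],
                     count = sum(.data$count), v_end = .data$v_end[1],
                     d_start = .data$d_start[1], d_end = .data$d_end[1],
                     j_start = .data$j_start[1], .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$cdr3_nt)
  merged$freq <- merged$count / sum(merged$count)
  new_repertoire(merged,
                 sample_id = paste0(pats, "_merged"),
                 patient_id = pats,
                 compartment = if (length(comps) == 1) comps else "merged",
                 chain = chains,
                 pct_cd4 = mean(vapply(reps, function(r) r$pct_cd4, 1)),
                 pct_cd8 = mean(vapply(reps, function(r) r$pct_cd8, 1)))
}
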