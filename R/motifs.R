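# GLIPH2-style discovery of enriched local CDR3aa motifs. A motif is a
# contiguous 3-7 residue pattern from the CDR3 interior (first 3 and last
# 2 residues excluded), optionally with one '%' wildcard at any position
# but the last (published motifs such as %NYSNQP lead with the wildcard). A sequence carries a motif when its interior contains the
# pattern. Enrichment vs. a reference repertoire is scored with a
# one-sided Fisher (hypergeometric) p-value on distinct amino-acid
# clonotypes; clonal-expansion concentration with a permutation p-value.

#' Validate a motif pattern
#'
#' @param pattern candidate motif string.
#' @return `TRUE` or `FALSE`.
#' @export
motif_is_valid <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  n_wild <- sum(chars == "%")
  nchar(pattern) >= 3 && nchar(pattern) <= 7 &&
    n_wild <= 1 &&
    chars[length(chars)] != "%" &&
    all(chars %in% c(AA20, "%"))
}

#' Wildcard-aware motif matching
#'
#' @param pattern motif, `%` matching any single residue.
#' @param sequences peptides to test.
#' @param interior_only restrict matching to the CDR3 interior (first 3 and
#'   last 2 residues excluded), the convention used for carrier counting.
#' @return logical vector.
#' @export
motif_matches <- function(pattern, sequences, interior_only = FALSE) {
  subject <- if (interior_only)
    substr(sequences, 4L, nchar(sequences) - 2L) else sequences
  rx <- gsub("%", "[A-Z]", pattern, fixed = TRUE)
  grepl(rx, subject)
}

#' Enumerate interior motifs and their carriers
#'
#' Exact contiguous k-mers for `k` in `k_exact` and single-wildcard
#' patterns for window lengths in `k_wild` (the wildcard may sit anywhere
#' except the final position), all drawn from the CDR3 interior. Sequences whose interior is shorter
#' than the window contribute nothing.
#'
#' @param aa_sequences character vector of CDR3aa sequences (duplicates
#'   collapsed).
#' @param k_exact exact k-mer lengths.
#' @param k_wild wildcard window lengths.
#' @return named list mapping each motif to its deduplicated carrier
#'   sequences.
#' @export
enumerate_motifs <- function(aa_sequences, k_exact = c(3L, 4L, 5L),
                             k_wild = c(5L, 6L, 7L)) {
  seqs <- unique(aa_sequences)
  interiors <- substr(seqs, 4L, nchar(seqs) - 2L)
  ilen <- nchar(interiors)
  motif_parts <- list()
  sid_parts <- list()
  ri <- 0L
  window_records <- function(k) {
    n_k <- pmax(0L, ilen - k + 1L)
    idx <- rep.int(seq_along(seqs), n_k)
    starts <- sequence(n_k)
    list(idx = idx, win = substring(interiors[idx], starts, starts + k - 1L))
  }
  for (k in k_exact) {
    w <- window_records(k)
    if (!length(w$idx)) next
    ri <- ri + 1L
    motif_parts[[ri]] <- w$win
    sid_parts[[ri]] <- w$idx
  }
  for (k in k_wild) {
    w <- window_records(k)
    if (!length(w$idx)) next
    for (pos in 1:(k - 1L)) {
      m <- w$win
      substr(m, pos, pos) <- "%"
      ri <- ri + 1L
      motif_parts[[ri]] <- m
      sid_parts[[ri]] <- w$idx
    }
  }
  if (ri == 0L) return(structure(list(), names = character(0)))
  motif <- unlist(motif_parts, use.names = FALSE)
  sid <- unlist(sid_parts, use.names = FALSE)
  dup <- duplicated(paste0(motif, "\r", sid))
  split(seqs[sid[!dup]], motif[!dup])
}

#' Score one motif against a reference repertoire
#'
#' The Fisher score is the one-sided hypergeometric tail probability of
#' observing at least the sample's carrier count in the 2x2 table
#' (carrier / non-carrier) x (sample / reference), counting distinct
#' amino-acid clonotypes. The expansion score is the permutation p-value
#' (`B` draws from the current RNG stream; seed upstream for
#' reproducibility) that the summed frequency of the carriers exceeds that
#' of random same-size clonotype sets.
#'
#' @param motif motif pattern.
#' @param sample_aa_rep,reference_aa_rep `aa_repertoire`s (see
#'   [collapse_by_aa()]).
#' @param B number of permutations.
#' @return list of class `motif_score`: `fisher_score`, `expansion_score`,
#'   `support` (named vector).
#' @export
score_motif <- function(motif, sample_aa_rep, reference_aa_rep, B = 1000L) {
  if (nrow(reference_aa_rep) == 0) stop("empty reference repertoire")
  in_sample <- motif_matches(motif, sample_aa_rep$cdr3_aa,
                             interior_only = TRUE)
  if (!any(in_sample)) stop("motif '", motif, "' has no sample carrier")
  in_ref <- motif_matches(motif, reference_aa_rep$cdr3_aa,
                          interior_only = TRUE)
  k <- sum(in_sample); n_s <- nrow(sample_aa_rep)
  k_r <- sum(in_ref); n_r <- nrow(reference_aa_rep)
  fisher <- phyper(k - 1, k + k_r, n_s + n_r - k - k_r, n_s,
                   lower.tail = FALSE)
  expansion <- expansion_pvalue(sample_aa_rep$freq, which(in_sample), B)
  structure(list(fisher_score = fisher, expansion_score = expansion,
                 support = c(sample_carriers = k, sample_size = n_s,
                             reference_carriers = k_r, reference_size = n_r)),
            class = "motif_score")
}

expansion_pvalue <- function(freq, carrier_idx, B) {
  m <- length(carrier_idx)
  S <- length(freq)
  obs <- sum(freq[carrier_idx])
  if (m >= S) return(1)
  null <- vapply(seq_len(B), function(i) sum(freq[sample.int(S, m)]),
                 numeric(1))
  (1 + sum(null >= obs)) / (B + 1)
}

#' Discover motif clusters in a sample
#'
#' Enumerates interior motifs with at least `min_carriers` distinct
#' carriers, computes Fisher scores against the reference in bulk, and
#' permutation expansion scores for the Fisher-passing subset; a motif
#' passes when both scores fall at or below their thresholds (scores are
#' p-value-like: smaller is stronger). Exact motifs literally contained in
#' a passing longer motif with an identical carrier set are suppressed.
#'
#' @param sample_aa_rep,reference_aa_rep `aa_repertoire`s.
#' @param fisher_max,expansion_max pass thresholds in (0, 1].
#' @param k_exact,k_wild motif window sizes (see [enumerate_motifs()]).
#' @param min_carriers minimum distinct sample carriers per motif.
#' @param B permutations for the expansion score.
#' @param biopsy biopsy/patient label recorded on the clusters.
#' @return list of `motif_cluster` objects (possibly empty), each with
#'   fields `motif`, `members` (tibble `cdr3_aa`, `freq`, `biopsy`),
#'   `fisher_score`, `expansion_score`, `support`.
#' @export
cluster_by_motifs <- function(sample_aa_rep, reference_aa_rep,
                              fisher_max = 0.5, expansion_max = 0.5,
                              k_exact = c(3L, 4L, 5L),
                              k_wild = c(5L, 6L, 7L),
                              min_carriers = 2L, B = 1000L,
                              biopsy = attr(sample_aa_rep, "patient_id") %||%
                                "sample") {
  if (fisher_max <= 0 || fisher_max > 1 || expansion_max <= 0 ||
      expansion_max > 1)
    stop("thresholds must lie in (0, 1]")
  if (nrow(reference_aa_rep) == 0) stop("empty reference repertoire")

  sample_map <- enumerate_motifs(sample_aa_rep$cdr3_aa, k_exact, k_wild)
  carriers_n <- lengths(sample_map)
  sample_map <- sample_map[carriers_n >= min_carriers]
  if (!length(sample_map)) return(list())

  ref_map <- enumerate_motifs(reference_aa_rep$cdr3_aa, k_exact, k_wild)
  ref_counts <- lengths(ref_map)

  motifs <- sort(names(sample_map))
  k <- lengths(sample_map)[motifs]
  k_r <- ifelse(motifs %in% names(ref_counts), ref_counts[motifs], 0L)
  n_s <- nrow(sample_aa_rep); n_r <- nrow(reference_aa_rep)
  fisher <- phyper(k - 1, k + k_r, n_s + n_r - k - k_r, n_s,
                   lower.tail = FALSE)

  pass_f <- which(fisher <= fisher_max)
  freq_by_aa <- setNames(sample_aa_rep$freq, sample_aa_rep$cdr3_aa)
  # null sums of random same-size clonotype sets, drawn once per carrier-set
  # size and shared by the motifs of that size (each motif's p-value is
  # valid against the common null; only independence across motifs is
  # traded for speed)
  null_cache <- new.env(parent = emptyenv())
  freq <- sample_aa_rep$freq
  S <- length(freq)
  null_sums <- function(m) {
    key <- as.character(m)
    ns <- get0(key, envir = null_cache)
    if (is.null(ns)) {
      ns <- vapply(seq_len(B), function(i) sum(freq[sample.int(S, m)]),
                   numeric(1))
      assign(key, ns, envir = null_cache)
    }
    ns
  }
  clusters <- list()
  for (i in pass_f) {
    mot <- motifs[i]
    members <- sample_map[[mot]]
    m_sz <- length(members)
    expansion <- if (m_sz >= S) 1 else {
      obs <- sum(freq[match(members, sample_aa_rep$cdr3_aa)])
      (1 + sum(null_sums(m_sz) >= obs)) / (B + 1)
    }
    if (expansion > expansion_max) next
    members <- sort(members)
    clusters[[mot]] <- structure(
      list(motif = mot,
           members = tibble::new_tibble(
             list(cdr3_aa = members,
                  freq = unname(freq_by_aa[members]),
                  biopsy = rep(biopsy, length(members))),
             nrow = length(members)),
           fisher_score = unname(fisher[i]),
           expansion_score = expansion,
           support = c(sample_carriers = unname(k[i]), sample_size = n_s,
                       reference_carriers = unname(k_r[i]),
                       reference_size = n_r)),
      class = "motif_cluster")
  }
  if (!length(clusters)) return(list())

  # suppress exact motifs nested in a passing longer motif with the same
  # carrier set
  nms <- names(clusters)
  keep <- rep(TRUE, length(nms))
  for (a in seq_along(nms)) {
    if (grepl("%", nms[a], fixed = TRUE)) next
    for (b in seq_along(nms)) {
      if (a == b || nchar(nms[b]) <= nchar(nms[a])) next
      if (grepl(nms[a], nms[b], fixed = TRUE) &&
          setequal(clusters[[a]]$members$cdr3_aa,
                   clusters[[b]]$members$cdr3_aa)) {
        keep[a] <- FALSE
        break
      }
    }
  }
  unname(clusters[keep])
}

#' Tabulate motif clusters
#'
#' @param clusters list of `motif_cluster`s.
#' @return tibble: `motif`, `fisher_score`, `expansion_score`, `n_members`,
#'   `biopsies`, `member_cdr3aa` (comma-separated).
#' @export
clusters_table <- function(clusters) {
  if (!length(clusters)) {
    return(tibble::tibble(motif = character(0), fisher_score = numeric(0),
                          expansion_score = numeric(0),
                          n_members = integer(0), biopsies = character(0),
                          member_cdr3aa = character(0)))
  }
  out <- tibble::tibble(
    motif = vapply(clusters, function(cl) cl$motif, character(1)),
    fisher_score = vapply(clusters, function(cl) cl$fisher_score, numeric(1)),
    expansion_score = vapply(clusters, function(cl) cl$expansion_score,
                             numeric(1)),
    n_members = vapply(clusters, function(cl) nrow(cl$members), integer(1)),
    biopsies = vapply(clusters, function(cl)
      paste(sort(unique(cl$members$biopsy)), collapse = ","), character(1)),
    member_cdr3aa = vapply(clusters, function(cl)
      paste(cl$members$cdr3_aa, collapse = ","), character(1)))
  out[order(out$fisher_score, out$motif), ]
}

#' Cross-biopsy motif sharing table
#'
#' @param clusters_by_biopsy named list (biopsy label -> list of
#'   `motif_cluster`s that passed in that biopsy).
#' @return list with `table` (tibble: one row per motif, one 0/1 column per
#'   biopsy, plus `n_biopsies`) and `n_shared` (motifs passing in >= 2
#'   biopsies).
#' @export
motif_sharing <- function(clusters_by_biopsy) {
  biopsies <- names(clusters_by_biopsy)
  if (is.null(biopsies)) stop("clusters_by_biopsy must be a named list")
  rows <- lapply(biopsies, function(b) {
    mots <- vapply(clusters_by_biopsy[[b]], function(cl) cl$motif,
                   character(1))
    if (length(mots)) tibble::tibble(motif = mots, biopsy = b)
  })
  long <- dplyr::bind_rows(rows)
  if (is.null(long) || nrow(long) == 0) {
    return(list(table = tibble::tibble(motif = character(0)), n_shared = 0L))
  }
  wide <- tidyr::pivot_wider(dplyr::mutate(long, present = 1L),
                             names_from = "biopsy",
                             values_from = "present", values_fill = 0L)
  wide <- wide[order(wide$motif), ]
  wide$n_biopsies <- rowSums(wide[biopsies[biopsies %in% names(wide)]])
  list(table = wide, n_shared = sum(wide$n_biopsies >= 2))
}
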