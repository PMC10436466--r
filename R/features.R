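# CDR3nt / N(D)Nnt length statistics and frequency-weighted
# physicochemical profiles of the central CDR3 5-mer.

# Kyte-Doolittle hydropathy
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# net side-chain charge at physiological pH
CHARGE_SCALE <- local({
  s <- setNames(rep(0, 20), AA20)
  s[c("K", "R")] <- 1
  s[c("D", "E")] <- -1
  s
})

# binary polarity indicator
POLARITY_SCALE <- local({
  s <- setNames(rep(0, 20), AA20)
  s[c("N", "Q", "S", "T", "Y", "C", "H", "K", "R", "D", "E")] <- 1
  s
})

property_registry <- new.env(parent = emptyenv())

#' Register or fetch a named residue property scale
#'
#' Three scales ship registered: `charge` (K/R = +1, D/E = -1, H = 0,
#' others 0), `hydropathy` (Kyte-Doolittle) and `polarity` (binary
#' indicator). A scale must assign a value to all 20 standard residues and
#' is immutable once registered.
#'
#' @param name scale name.
#' @param values named numeric vector over the 20-residue alphabet (only
#'   for registration).
#' @return `property_scale()` returns the named numeric vector.
#' @export
property_scale <- function(name) {
  sc <- get0(name, envir = property_registry)
  if (is.null(sc)) stop("unknown property scale '", name, "'")
  sc
}

#' @rdname property_scale
#' @export
register_property_scale <- function(name, values) {
  if (!is.null(get0(name, envir = property_registry)))
    stop("property scale '", name, "' is already registered")
  if (!all(AA20 %in% names(values)))
    stop("scale must cover all 20 standard residues")
  assign(name, values[AA20], envir = property_registry)
  invisible(values[AA20])
}

local({
  assign("charge", CHARGE_SCALE, envir = property_registry)
  assign("hydropathy", KYTE_DOOLITTLE[AA20], envir = property_registry)
  assign("polarity", POLARITY_SCALE, envir = property_registry)
})

#' N(D)N nucleotide length of clonotypes
#'
#' The non-germline stretch between the end of the V contribution and the
#' start of the J contribution: `j_start - v_end`. Clonotypes without
#' reference points yield `NA` (missing, never 0).
#'
#' @param rep a `tcr_repertoire`, or a clonotype data frame with `v_end`
#'   and `j_start` columns.
#' @return integer vector of N(D)N lengths (NA where unknown).
#' @export
ndn_length <- function(rep) {
  cl <- if (inherits(rep, "tcr_repertoire")) rep$clonotypes else rep
  has <- !is.na(cl$v_end) & !is.na(cl$j_start)
  bad <- has & cl$j_start < cl$v_end
  if (any(bad))
    stop("v_end > j_start for clonotype(s): ",
         paste(head(cl$cdr3_nt[bad], 3), collapse = ", "))
  out <- rep(NA_integer_, nrow(cl))
  out[has] <- as.integer(cl$j_start[has] - cl$v_end[has])
  out
}

#' Central k-mer of a CDR3 amino-acid sequence
#'
#' Substring of length `k` starting at `floor((L - k) / 2)` (0-based), so
#' even-length ties shift toward the N-terminus. Sequences shorter than `k`
#' yield `NA` and are skipped by callers.
#'
#' @param cdr3_aa character vector of peptides.
#' @param k window size (default 5).
#' @return character vector of k-mers (NA where too short).
#' @export
central_kmer <- function(cdr3_aa, k = 5L) {
  L <- nchar(cdr3_aa)
  start <- (L - k) %/% 2L
  out <- substr(cdr3_aa, start + 1L, start + k)
  out[L < k] <- NA_character_
  out
}

#' Mean property value of a peptide
#'
#' Sum of per-residue scale values divided by the peptide length
#' (normalization to subregion size).
#'
#' @param peptide character vector of peptides.
#' @param scale scale name (see [property_scale()]) or named numeric vector.
#' @return numeric vector of mean property values.
#' @export
property_score <- function(peptide, scale = "charge") {
  if (is.character(scale)) scale <- property_scale(scale)
  vapply(peptide, function(p) {
    if (is.na(p) || !nzchar(p)) stop("empty peptide")
    res <- strsplit(p, "")[[1]]
    vals <- scale[res]
    if (anyNA(vals))
      stop("unknown residue '", res[which(is.na(vals))[1]], "' in ", p)
    sum(vals) / length(vals)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Frequency-weighted central-window property profile of a repertoire
#'
#' Computes `sum_i f_i * property_score(central_kmer(seq_i, k), scale)`
#' over the amino-acid clonotypes of length >= k, with frequencies
#' renormalized over that retained set.
#'
#' @param aa_rep an `aa_repertoire` (see [collapse_by_aa()]).
#' @param scale scale name or named numeric vector.
#' @param k central window size.
#' @return single numeric profile value.
#' @export
repertoire_property_profile <- function(aa_rep, scale = "charge", k = 5L) {
  if (is.character(scale)) scale <- property_scale(scale)
  keep <- nchar(aa_rep$cdr3_aa) >= k
  if (!any(keep))
    stop("no CDR3aa sequence of length >= ", k)
  if (!all(keep))
    warning(sum(!keep), " sequence(s) shorter than ", k, " skipped")
  f <- aa_rep$freq[keep]
  f <- f / sum(f)
  scores <- property_score(central_kmer(aa_rep$cdr3_aa[keep], k), scale)
  sum(f * scores)
}

#' Length summary of a repertoire
#'
#' Unweighted mean/sd over distinct clonotypes and frequency-weighted mean
#' of both CDR3nt length and N(D)Nnt length. N(D)N statistics use only
#' clonotypes with reference points; if none has them the N(D)N fields are
#' `NA`.
#'
#' @param rep a `tcr_repertoire`.
#' @return one-row tibble: `sample_id`, `compartment`, `n`, `cdr3nt_mean`,
#'   `cdr3nt_sd`, `cdr3nt_wmean`, `n_ndn`, `ndn_mean`, `ndn_sd`,
#'   `ndn_wmean`.
#' @export
length_summary <- function(rep) {
  cl <- rep$clonotypes
  if (nrow(cl) == 0) stop("empty repertoire")
  lens <- nchar(cl$cdr3_nt)
  w <- cl$freq / sum(cl$freq)
  ndn <- ndn_length(rep)
  has <- !is.na(ndn)
  wn <- if (any(has)) w[has] / sum(w[has])
  tibble::tibble(
    sample_id = rep$sample_id, compartment = rep$compartment,
    n = nrow(cl),
    cdr3nt_mean = mean(lens), cdr3nt_sd = sd(lens),
    cdr3nt_wmean = sum(w * lens),
    n_ndn = sum(has),
    ndn_mean = if (any(has)) mean(ndn[has]) else NA_real_,
    ndn_sd = if (any(has)) sd(ndn[has]) else NA_real_,
    ndn_wmean = if (any(has)) sum(wn * ndn[has]) else NA_real_
  )
}

#' Per-sample feature table
#'
#' One row per sample: length summary plus the frequency-weighted central
#' 5-mer profiles for the requested scales, computed on the aa-collapsed
#' repertoire (collapsing precedes the length / property / motif analyses).
#'
#' @param cohort a `tcr_cohort`.
#' @param scales character vector of registered scale names.
#' @param k central window size.
#' @return tibble with one row per sample.
#' @export
feature_table <- function(cohort, scales = c("charge", "hydropathy",
                                             "polarity"), k = 5L) {
  dplyr::bind_rows(lapply(cohort$repertoires, function(r) {
    ls <- length_summary(r)
    aa <- collapse_by_aa(r)
    for (sc in scales)
      ls[[sc]] <- suppressWarnings(repertoire_property_profile(aa, sc, k))
    ls
  }))
}
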