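#' @importFrom rlang %||%
#' @importFrom stats aov cor.test fisher.test p.adjust pf phyper pt rgeom
#'   rmultinom rnorm runif sd setNames t.test uniroot TukeyHSD
#' @importFrom utils head
NULL

# 20-letter amino-acid alphabet (no stop)
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# codon tables derived from the standard genetic code
GENETIC_CODE_TBL <- local({
  gc <- Biostrings::GENETIC_CODE
  list(
    aa_by_codon = setNames(unname(gc), names(gc)),
    codons_by_aa = split(names(gc), unname(gc))
  )
})

SENSE_CODONS <- names(GENETIC_CODE_TBL$aa_by_codon)[GENETIC_CODE_TBL$aa_by_codon != "*"]
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate CDR3 nucleotide sequences
#'
#' Translates in-frame DNA strings with the standard genetic code; stop
#' codons become `*`. Sequences whose length is not a multiple of 3 are an
#' error: the frame of a CDR3 is defined by its first nucleotide.
#'
#' @param nt character vector of DNA sequences (A/C/G/T), lengths divisible
#'   by 3.
#' @return character vector of peptide sequences.
#' @export
translate_cdr3 <- function(nt) {
  if (length(nt) == 0) return(character(0))
  bad <- nchar(nt) %% 3 != 0
  if (any(bad)) {
    stop("cdr3_nt length not divisible by 3 for sequence(s): ",
         paste(head(which(bad), 5), collapse = ", "))
  }
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                     no.init.codon = TRUE))
}

# sample one codon per amino acid (vectorised over aa)
random_codons <- function(aa) {
  vapply(aa, function(a) {
    cods <- GENETIC_CODE_TBL$codons_by_aa[[a]]
    if (is.null(cods)) stop("no codon for residue '", a, "'")
    cods[sample.int(length(cods), 1L)]
  }, character(1), USE.NAMES = FALSE)
}

# random DNA strings of the given lengths, uniform over A/C/G/T
random_dna <- function(lengths) {
  total <- sum(lengths)
  if (total == 0) return(rep("", length(lengths)))
  bases <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  out <- character(length(lengths))
  idx <- cumsum(lengths)
  start <- c(1L, head(idx, -1L) + 1L)
  for (i in seq_along(lengths)) {
    out[i] <- if (lengths[i] == 0) "" else
      paste(bases[start[i]:idx[i]], collapse = "")
  }
  out
}

# synonymous recoding of an in-frame DNA string; returns a string with the
# same translation, differing from the input whenever any codon has a
# synonym.
synonymous_variant <- function(nt) {
  codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  aa <- GENETIC_CODE_TBL$aa_by_codon[codons]
  new <- vapply(aa, function(a) {
    cods <- GENETIC_CODE_TBL$codons_by_aa[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1), USE.NAMES = FALSE)
  out <- paste(new, collapse = "")
  if (out == nt) {
    # force a difference at some degenerate position, if one exists
    k <- which(vapply(aa, function(a)
      length(GENETIC_CODE_TBL$codons_by_aa[[a]]) > 1, logical(1)))
    if (length(k)) {
      i <- k[sample.int(length(k), 1L)]
      alt <- setdiff(GENETIC_CODE_TBL$codons_by_aa[[aa[i]]], codons[i])
      new[i] <- alt[sample.int(length(alt), 1L)]
      out <- paste(new, collapse = "")
    }
  }
  out
}

`%missing%` <- function(x, default) if (is.null(x) || all(is.na(x))) default else x

assert_scalar_int <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
    stop("`", name, "` must be a single integer >= ", min)
  as.integer(x)
}
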