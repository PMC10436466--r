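# In-code fixtures shared across the test files.

# a hand-built repertoire from parallel vectors; nt defaults to a faithful
# back-translation so translation consistency holds
toy_rep <- function(aa, counts = rep(1L, length(aa)), nt = NULL,
                    v_end = NA_integer_, j_start = NA_integer_,
                    sample_id = "T1", patient_id = sample_id,
                    compartment = "TILs-initial") {
  if (is.null(nt)) {
    nt <- vapply(aa, function(a) {
      paste(vapply(strsplit(a, "")[[1]], function(ch) {
        tilrep:::GENETIC_CODE_TBL$codons_by_aa[[ch]][1]
      }, character(1)), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  cl <- tibble::tibble(
    cdr3_nt = nt, cdr3_aa = aa,
    v_call = "TRBVS1", d_call = NA_character_, j_call = "TRBJS1",
    count = as.integer(counts), freq = counts / sum(counts),
    v_end = as.integer(v_end), d_start = NA_integer_,
    d_end = NA_integer_, j_start = as.integer(j_start)
  )
  new_repertoire(cl, sample_id = sample_id, patient_id = patient_id,
                 compartment = compartment)
}

# an aa-collapsed repertoire straight from vectors
toy_aa_rep <- function(aa, freq = NULL, counts = NULL,
                       nt_variants = rep(1L, length(aa))) {
  if (is.null(counts)) counts <- rep(1L, length(aa))
  if (is.null(freq)) freq <- counts / sum(counts)
  out <- tibble::tibble(cdr3_aa = aa, count = as.integer(counts),
                        freq = freq,
                        nt_variant_count = as.integer(nt_variants))
  class(out) <- c("aa_repertoire", class(out))
  out
}

# random CDR3-like peptides C...F
random_peptides <- function(n, min_core = 6, max_core = 10) {
  vapply(seq_len(n), function(i) {
    core <- sample(tilrep:::AA20, sample(min_core:max_core, 1),
                   replace = TRUE)
    paste0("C", paste(core, collapse = ""), "F")
  }, character(1))
}

# small two-compartment cohort used by several tests
small_cohort <- function(seed = 5, n = 250, patients = 3, slices = 1, ...) {
  generate_cohort(cohort_spec(
    n_patients = patients, slices_per_patient = slices,
    compartments = list(`TILs-CD4+` = til_cd4_preset(n),
                        `TILs-CD8+` = til_cd8_preset(n)),
    reference_size = 300, seed = seed, ...))
}
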