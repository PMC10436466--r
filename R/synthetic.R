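# Seeded synthetic V(D)J repertoire generator. Clonotypes are built as
# germline V flank + random N(D)N + germline J flank, kept in frame and
# stop-free by rejection, with knobs for junction length, central-window
# charge bias, clone-size law (and hence diversity), convergent nt
# variants, planted amino-acid motifs, public clonotypes shared across
# patients, and non-productive contamination.

#' Specification of one synthetic repertoire
#'
#' @param n_clonotypes number of base amino-acid clonotypes (>= 1).
#' @param ndn_length_mean,ndn_length_sd N(D)N nucleotide length is drawn
#'   from a rounded Gaussian truncated at 0.
#' @param clone_size_law list; either
#'   `list(family = "geometric", prob = p)` (counts `1 + Geom(p)`) or
#'   `list(family = "powerlaw", exponent = s)` /
#'   `list(family = "powerlaw", target_nsw = d, reads_factor = 20)`
#'   (Zipf rank-frequency counts; with `target_nsw` the exponent is solved
#'   so the expected normalized Shannon-Wiener index equals `d`).
#' @param charge_bias signed probability shift toward positively charged
#'   (K/R, positive values) or negatively charged (D/E, negative values)
#'   residues in the central CDR3 5-mer: each central-window codon lying
#'   fully inside the N(D)N is replaced with probability
#'   `min(1, 5 * abs(charge_bias))`.
#' @param convergence_rate probability in \[0, 1\] that a clonotype gains an
#'   extra synonymous nucleotide variant.
#' @param planted_motifs list of `list(motif = , n_carriers = )`; motifs may
#'   contain one `%` wildcard and are embedded in the CDR3 interior of
#'   `n_carriers` distinct sequences.
#' @param nonproductive_rate probability that a clonotype receives an
#'   in-frame stop codon inside its N(D)N (exercises [filter_productive()]).
#' @param seed optional integer; identical seeds give byte-identical
#'   repertoires.
#' @return a `repertoire_spec` object.
#' @export
repertoire_spec <- function(n_clonotypes = 1000,
                            ndn_length_mean = 13, ndn_length_sd = 2.5,
                            clone_size_law = list(family = "powerlaw",
                                                  target_nsw = 0.45),
                            charge_bias = 0, convergence_rate = 0.05,
                            planted_motifs = list(),
                            nonproductive_rate = 0, seed = NULL) {
  n_clonotypes <- assert_scalar_int(n_clonotypes, "n_clonotypes")
  if (ndn_length_sd < 0) stop("ndn_length_sd must be >= 0")
  if (convergence_rate < 0 || convergence_rate > 1)
    stop("convergence_rate must be in [0, 1]")
  if (nonproductive_rate < 0 || nonproductive_rate > 1)
    stop("nonproductive_rate must be in [0, 1]")
  if (!is.list(clone_size_law) || is.null(clone_size_law$family) ||
      !clone_size_law$family %in% c("geometric", "powerlaw"))
    stop("clone_size_law$family must be 'geometric' or 'powerlaw'")
  for (pm in planted_motifs) {
    if (is.null(pm$motif) || is.null(pm$n_carriers))
      stop("each planted motif needs fields `motif` and `n_carriers`")
  }
  structure(list(n_clonotypes = n_clonotypes,
                 ndn_length_mean = ndn_length_mean,
                 ndn_length_sd = ndn_length_sd,
                 clone_size_law = clone_size_law,
                 charge_bias = charge_bias,
                 convergence_rate = convergence_rate,
                 planted_motifs = planted_motifs,
                 nonproductive_rate = nonproductive_rate,
                 seed = seed),
            class = "repertoire_spec")
}

#' Study-condition presets for TIL compartments
#'
#' Presets encode the compartment-level statistics the generator emulates:
#' N(D)N length 14.4 +/- 3.1 nt, central-window charge bias +0.06 and
#' diversity 0.38 for CD4+ TILs; 11.4 +/- 2.2 nt, -0.04 and 0.51 for CD8+
#' TILs; 13.8 +/- 2.1 nt, -0.01 and 0.45 for the initial (unsorted) TIL
#' cultures.
#'
#' @param n_clonotypes repertoire size.
#' @param ... passed to [repertoire_spec()] (e.g. `seed`, `planted_motifs`).
#' @return a `repertoire_spec`.
#' @export
til_cd4_preset <- function(n_clonotypes = 2000, ...) {
  repertoire_spec(n_clonotypes = n_clonotypes,
                  ndn_length_mean = 14.4, ndn_length_sd = 3.1,
                  charge_bias = 0.06,
                  clone_size_law = list(family = "powerlaw", target_nsw = 0.38),
                  ...)
}

#' @rdname til_cd4_preset
#' @export
til_cd8_preset <- function(n_clonotypes = 2000, ...) {
  repertoire_spec(n_clonotypes = n_clonotypes,
                  ndn_length_mean = 11.4, ndn_length_sd = 2.2,
                  charge_bias = -0.04,
                  clone_size_law = list(family = "powerlaw", target_nsw = 0.51),
                  ...)
}

#' @rdname til_cd4_preset
#' @export
til_initial_preset <- function(n_clonotypes = 2000, ...) {
  repertoire_spec(n_clonotypes = n_clonotypes,
                  ndn_length_mean = 13.8, ndn_length_sd = 2.1,
                  charge_bias = -0.01,
                  clone_size_law = list(family = "powerlaw", target_nsw = 0.45),
                  ...)
}

#' Zipf exponent matching a target normalized Shannon-Wiener index
#'
#' For `S` clonotypes whose expected counts are `1 + (N - S) * p_i` with
#' `p_i` proportional to `i^-s` and `N = reads_factor * S` total reads,
#' solves for the exponent `s` such that the entropy of the expected
#' frequency vector, divided by `log(S)`, equals `target_nsw`.
#'
#' @param target_nsw desired index in (0, 1].
#' @param S number of clonotypes.
#' @param reads_factor reads per clonotype.
#' @return non-negative exponent.
#' @export
zipf_exponent_for_nsw <- function(target_nsw, S, reads_factor = 20) {
  if (target_nsw <= 0 || target_nsw > 1) stop("target_nsw must be in (0, 1]")
  N <- reads_factor * S
  nsw_of <- function(s) {
    p <- (seq_len(S))^(-s)
    p <- p / sum(p)
    q <- (1 + (N - S) * p) / N
    -sum(q * log(q)) / log(S)
  }
  if (nsw_of(0) <= target_nsw) return(0)
  lo <- 0; hi <- 1
  while (nsw_of(hi) > target_nsw && hi < 64) hi <- hi * 2
  if (nsw_of(hi) > target_nsw)
    stop("target_nsw ", target_nsw, " unreachable for S = ", S)
  uniroot(function(s) nsw_of(s) - target_nsw, c(lo, hi), tol = 1e-8)$root
}

draw_counts <- function(law, n) {
  if (law$family == "geometric") {
    prob <- law$prob %||% 0.2
    return(1L + rgeom(n, prob))
  }
  reads_factor <- law$reads_factor %||% 20
  s <- law$exponent %||% zipf_exponent_for_nsw(law$target_nsw, n, reads_factor)
  p <- (seq_len(n))^(-s)
  p <- p / sum(p)
  p <- p[sample.int(n)]  # decouple abundance rank from generation order
  N <- reads_factor * n
  if (N <= n) stop("reads_factor too small")
  as.integer(1L + rmultinom(1, N - n, p)[, 1])
}

#' Generate one synthetic repertoire
#'
#' @param spec a [repertoire_spec()].
#' @param sample_id,patient_id,compartment,chain metadata for the sample.
#' @return a `tcr_repertoire` whose CDR3nt translate exactly to the CDR3aa,
#'   whose reference points bound the simulated N(D)N, and whose
#'   frequencies sum to 1.
#' @export
generate_repertoire <- function(spec, sample_id = "SYN1",
                                patient_id = sample_id,
                                compartment = "TILs-initial", chain = "TRB") {
  stopifnot(inherits(spec, "repertoire_spec"))
  if (!is.null(spec$seed)) withr::local_seed(spec$seed)

  n <- spec$n_clonotypes
  vset <- TOY_V_SEGMENTS; jset <- TOY_J_SEGMENTS
  v_lens <- nchar(vset$nt); j_lens <- nchar(jset$nt)
  j_by_mod <- lapply(0:2, function(m) which(j_lens %% 3 == m))

  v_idx <- sample.int(nrow(vset), n, replace = TRUE)
  v_len <- v_lens[v_idx]
  ndn <- pmax(0L, as.integer(round(rnorm(n, spec$ndn_length_mean,
                                         spec$ndn_length_sd))))
  need_mod <- (3 - (v_len + ndn) %% 3) %% 3
  j_idx <- integer(n)
  for (m in 0:2) {
    rows <- which(need_mod == m)
    if (length(rows))
      j_idx[rows] <- j_by_mod[[m + 1]][sample.int(length(j_by_mod[[m + 1]]),
                                                  length(rows), replace = TRUE)]
  }
  j_len <- j_lens[j_idx]

  ndn_seq <- random_dna(ndn)
  nt <- paste0(vset$nt[v_idx], ndn_seq, jset$nt[j_idx])
  aa <- translate_cdr3(nt)

  # reject stop codons by resampling the N(D)N (germline flanks and pure
  # V-J junctions are stop-free by construction)
  for (iter in 1:100) {
    bad <- which(grepl("*", aa, fixed = TRUE))
    if (!length(bad)) break
    ndn_seq[bad] <- random_dna(ndn[bad])
    nt[bad] <- paste0(vset$nt[v_idx[bad]], ndn_seq[bad], jset$nt[j_idx[bad]])
    aa[bad] <- translate_cdr3(nt[bad])
  }
  if (any(grepl("*", aa, fixed = TRUE)))
    stop("internal: stop-codon rejection did not converge")

  v_end <- v_len
  j_start <- v_len + ndn
  L <- nchar(aa)

  # charge bias: replace central-window codons inside the N(D)N
  if (spec$charge_bias != 0) {
    q <- min(1, 5 * abs(spec$charge_bias))
    pool <- if (spec$charge_bias > 0) {
      unlist(GENETIC_CODE_TBL$codons_by_aa[c("K", "R")], use.names = FALSE)
    } else {
      unlist(GENETIC_CODE_TBL$codons_by_aa[c("D", "E")], use.names = FALSE)
    }
    touched <- logical(n)
    for (i in seq_len(n)) {
      cs <- (L[i] - 5L) %/% 2L
      cod <- cs:(cs + 4L)
      elig <- cod[3L * cod >= v_end[i] & 3L * cod + 3L <= j_start[i]]
      if (!length(elig)) next
      hit <- elig[runif(length(elig)) < q]
      for (ci in hit) {
        substr(nt[i], 3L * ci + 1L, 3L * ci + 3L) <-
          pool[sample.int(length(pool), 1L)]
      }
      if (length(hit)) touched[i] <- TRUE
    }
    if (any(touched)) aa[touched] <- translate_cdr3(nt[touched])
  }

  # planted motifs: embed in the CDR3 interior (first 3 / last 2 residues
  # excluded) of distinct carrier sequences
  total_carriers <- sum(vapply(spec$planted_motifs,
                               function(p) p$n_carriers, numeric(1)))
  if (total_carriers > n)
    stop("n_clonotypes (", n, ") smaller than the number of distinct ",
         "planted carriers (", total_carriers, ")")
  used <- logical(n)
  for (pm in spec$planted_motifs) {
    m <- nchar(pm$motif)
    elig <- which(!used & L >= m + 5L)
    if (length(elig) < pm$n_carriers)
      stop("motif '", pm$motif, "' is longer than the feasible CDR3 ",
           "interior of enough sequences (", length(elig), " eligible, ",
           pm$n_carriers, " required)")
    carriers <- if (length(elig) == 1) elig else
      elig[sample.int(length(elig), pm$n_carriers)]
    used[carriers] <- TRUE
    chars <- strsplit(pm$motif, "")[[1]]
    for (i in carriers) {
      hi <- L[i] - 2L - m
      s <- if (hi <= 3L) 3L else sample(3:hi, 1L)
      realized <- ifelse(chars == "%", sample(AA20, m, replace = TRUE), chars)
      substr(nt[i], 3L * s + 1L, 3L * (s + m)) <-
        paste(random_codons(realized), collapse = "")
    }
    aa[carriers] <- translate_cdr3(nt[carriers])
  }

  # non-productive contamination: in-frame stop inside the N(D)N
  if (spec$nonproductive_rate > 0) {
    for (i in which(runif(n) < spec$nonproductive_rate)) {
      c0 <- ceiling(v_end[i] / 3)
      if (3L * c0 + 3L > j_start[i]) next  # N(D)N holds no whole codon
      substr(nt[i], 3L * c0 + 1L, 3L * c0 + 3L) <-
        STOP_CODONS[sample.int(3L, 1L)]
      aa[i] <- translate_cdr3(nt[i])
    }
  }

  count <- draw_counts(spec$clone_size_law, n)

  base <- tibble::tibble(
    cdr3_nt = nt, cdr3_aa = aa,
    v_call = vset$v_call[v_idx], d_call = NA_character_,
    j_call = jset$j_call[j_idx],
    count = count, freq = NA_real_,
    v_end = as.integer(v_end), d_start = NA_integer_,
    d_end = NA_integer_, j_start = as.integer(j_start)
  )

  # convergent recombination: extra synonymous nt variants
  if (spec$convergence_rate > 0) {
    conv <- which(runif(n) < spec$convergence_rate)
    if (length(conv)) {
      vars <- base[conv, ]
      vars$cdr3_nt <- vapply(vars$cdr3_nt, synonymous_variant, character(1),
                             USE.NAMES = FALSE)
      keep <- vars$cdr3_nt != base$cdr3_nt[conv]
      vars <- vars[keep, ]
      if (nrow(vars)) {
        vars$count <- 1L + rgeom(nrow(vars), 0.5)
        base <- dplyr::bind_rows(base, vars)
      }
    }
  }

  base$freq <- base$count / sum(base$count)
  new_repertoire(base, sample_id = sample_id, patient_id = patient_id,
                 compartment = compartment, chain = chain)
}

#' Specification of a synthetic cohort
#'
#' @param n_patients,slices_per_patient cohort layout: each patient
#'   contributes `slices_per_patient` biopsy-slice samples per compartment.
#' @param compartments named list of [repertoire_spec()] presets, one per
#'   compartment label.
#' @param public_injection list of `list(cdr3_aa = , n_patients = )`: each
#'   amino-acid sequence is injected into exactly `n_patients` patients
#'   (slice 1 of every compartment) and scrubbed from the rest.
#' @param reference_size size of the background repertoire emitted for
#'   motif scoring.
#' @param composition optional
#'   `list(compartment = , nsw_cd4 = , nsw_cd8 = , pct_cd4 = NULL)`: draws
#'   (or takes) a per-patient CD4 percentage and retargets the named
#'   compartment's diversity to the composition-weighted mixture, recording
#'   `pct_cd4`/`pct_cd8` on that patient's samples.
#' @param seed master seed; all per-sample seeds are derived from it.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients, slices_per_patient = 1,
                        compartments, public_injection = list(),
                        reference_size = 1000, composition = NULL,
                        seed = NULL) {
  n_patients <- assert_scalar_int(n_patients, "n_patients")
  slices_per_patient <- assert_scalar_int(slices_per_patient,
                                          "slices_per_patient")
  if (is.null(names(compartments)) || anyDuplicated(names(compartments)))
    stop("`compartments` must be a uniquely named list of repertoire_spec")
  for (cs in compartments) {
    if (!inherits(cs, "repertoire_spec"))
      stop("every compartment preset must be a repertoire_spec")
  }
  for (pi in public_injection) {
    if (is.null(pi$cdr3_aa) || is.null(pi$n_patients))
      stop("public_injection entries need `cdr3_aa` and `n_patients`")
    if (pi$n_patients > n_patients)
      stop("cannot share '", pi$cdr3_aa, "' among ", pi$n_patients,
           " of only ", n_patients, " patients")
  }
  if (!is.null(composition) &&
      !composition$compartment %in% names(compartments))
    stop("composition$compartment must name a compartment")
  structure(list(n_patients = n_patients,
                 slices_per_patient = slices_per_patient,
                 compartments = compartments,
                 public_injection = public_injection,
                 reference_size = reference_size,
                 composition = composition, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return a `tcr_cohort` with one repertoire per
#'   (patient, slice, compartment) and a background `reference` repertoire.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) withr::local_seed(spec$seed)

  pct_cd4 <- NULL
  if (!is.null(spec$composition)) {
    pct_cd4 <- spec$composition$pct_cd4 %||%
      runif(spec$n_patients, 0.2, 0.8)
    if (length(pct_cd4) != spec$n_patients)
      stop("composition$pct_cd4 must have one value per patient")
  }

  n_samples <- spec$n_patients * spec$slices_per_patient *
    length(spec$compartments)
  seeds <- sample.int(.Machine$integer.max - 1L, n_samples + 1L)
  si <- 0L

  reps <- list()
  for (p in seq_len(spec$n_patients)) {
    pid <- sprintf("P%02d", p)
    for (comp in names(spec$compartments)) {
      cspec <- spec$compartments[[comp]]
      if (!is.null(pct_cd4) && comp == spec$composition$compartment) {
        mix <- pct_cd4[p] * spec$composition$nsw_cd4 +
          (1 - pct_cd4[p]) * spec$composition$nsw_cd8
        cspec$clone_size_law <- list(family = "powerlaw", target_nsw = mix)
      }
      for (s in seq_len(spec$slices_per_patient)) {
        si <- si + 1L
        cspec$seed <- seeds[si]
        r <- generate_repertoire(cspec,
                                 sample_id = sprintf("%s_%s_S%d", pid, comp, s),
                                 patient_id = pid, compartment = comp)
        if (!is.null(pct_cd4)) {
          r$pct_cd4 <- 100 * pct_cd4[p]
          r$pct_cd8 <- 100 * (1 - pct_cd4[p])
        }
        reps[[r$sample_id]] <- r
      }
    }
  }

  # public clonotype injection and scrubbing
  for (pi in spec$public_injection) {
    chosen <- sort(sample.int(spec$n_patients, pi$n_patients))
    chosen_ids <- sprintf("P%02d", chosen)
    nt_len_ok <- nchar(pi$cdr3_aa) * 3L
    for (nm in names(reps)) {
      r <- reps[[nm]]
      if (r$patient_id %in% chosen_ids) {
        if (endsWith(nm, "_S1")) {
          row <- tibble::tibble(
            cdr3_nt = paste(random_codons(strsplit(pi$cdr3_aa, "")[[1]]),
                            collapse = ""),
            cdr3_aa = pi$cdr3_aa,
            v_call = TOY_V_SEGMENTS$v_call[1], d_call = NA_character_,
            j_call = TOY_J_SEGMENTS$j_call[1],
            count = 1L + rgeom(1, 0.5), freq = NA_real_,
            v_end = NA_integer_, d_start = NA_integer_,
            d_end = NA_integer_, j_start = NA_integer_
          )
          r$clonotypes <- dplyr::bind_rows(r$clonotypes, row)
          reps[[nm]] <- renormalize(r)
        }
      } else {
        hit <- r$clonotypes$cdr3_aa == pi$cdr3_aa
        if (any(hit)) {
          r$clonotypes <- r$clonotypes[!hit, ]
          reps[[nm]] <- renormalize(r)
        }
      }
    }
  }

  ref_spec <- repertoire_spec(
    n_clonotypes = spec$reference_size,
    ndn_length_mean = 13, ndn_length_sd = 2.5,
    clone_size_law = list(family = "geometric", prob = 0.4),
    charge_bias = 0, convergence_rate = 0,
    seed = seeds[n_samples + 1L]
  )
  reference <- generate_repertoire(ref_spec, sample_id = "REFERENCE",
                                   patient_id = "REFERENCE",
                                   compartment = "reference")

  new_cohort(reps, reference = reference)
}

DB_CATEGORIES <- c("allergy", "autoimmunity", "cancer", "pathogens")

#' Specification of a synthetic specificity database
#'
#' @param n_records named integer vector over the categories
#'   `allergy`, `autoimmunity`, `cancer`, `pathogens`.
#' @param overlap list of `list(cdr3_aa = , category = )` records inserted
#'   verbatim (callers pass exact cohort sequences or 1-mismatch variants).
#' @param seed optional integer seed.
#' @return a `db_spec` object.
#' @export
db_spec <- function(n_records = c(cancer = 10), overlap = list(),
                    seed = NULL) {
  if (length(n_records) && (is.null(names(n_records)) ||
                            !all(names(n_records) %in% DB_CATEGORIES)))
    stop("n_records categories must be among: ",
         paste(DB_CATEGORIES, collapse = ", "))
  for (ov in overlap) {
    if (is.null(ov$cdr3_aa) || is.null(ov$category) ||
        !ov$category %in% DB_CATEGORIES)
      stop("overlap entries need `cdr3_aa` and a valid `category`")
  }
  if (sum(n_records) + length(overlap) == 0)
    stop("empty database specification")
  structure(list(n_records = n_records, overlap = overlap, seed = seed),
            class = "db_spec")
}

#' Generate a synthetic specificity database
#'
#' @param spec a [db_spec()].
#' @return a `specificity_db` tibble with columns `cdr3aa`, `category`,
#'   `source`.
#' @export
generate_specificity_db <- function(spec) {
  stopifnot(inherits(spec, "db_spec"))
  if (!is.null(spec$seed)) withr::local_seed(spec$seed)
  rows <- list()
  for (cat in names(spec$n_records)) {
    k <- spec$n_records[[cat]]
    if (k == 0) next
    lens <- sample(8:13, k, replace = TRUE)
    seqs <- vapply(lens, function(l)
      paste0("C", paste(sample(AA20, l, replace = TRUE), collapse = ""), "F"),
      character(1))
    rows[[cat]] <- tibble::tibble(cdr3aa = seqs, category = cat,
                                  source = sprintf("%s_antigen_%02d", cat,
                                                   seq_len(k)))
  }
  ov <- if (length(spec$overlap)) {
    tibble::tibble(
      cdr3aa = vapply(spec$overlap, function(o) o$cdr3_aa, character(1)),
      category = vapply(spec$overlap, function(o) o$category, character(1)),
      source = "cohort_overlap"
    )
  }
  db <- dplyr::bind_rows(c(rows, list(ov)))
  class(db) <- c("specificity_db", class(db))
  db
}

#' Read / write a specificity database CSV (`cdr3aa,category,source`)
#'
#' @param path CSV path.
#' @return `read_specificity_db()` returns a `specificity_db` tibble.
#' @export
read_specificity_db <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  db <- readr::read_csv(path, col_types = "ccc", progress = FALSE)
  if (!identical(names(db), c("cdr3aa", "category", "source")))
    stop("specificity database must have header cdr3aa,category,source")
  bad <- !db$category %in% DB_CATEGORIES
  if (any(bad)) stop("unknown category '", db$category[which(bad)[1]],
                     "' at row ", which(bad)[1])
  class(db) <- c("specificity_db", class(db))
  db
}

#' @rdname read_specificity_db
#' @param db a `specificity_db` tibble.
#' @export
write_specificity_db <- function(db, path) {
  readr::write_csv(as.data.frame(db), path, progress = FALSE)
  invisible(path)
}
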