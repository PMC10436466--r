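test_that("write/read roundtrips are the identity in both dialects", {
  r <- generate_repertoire(repertoire_spec(n_clonotypes = 120,
                                           convergence_rate = 0.1,
                                           seed = 8), "P1_TILs-CD4+_S1",
                           patient_id = "P1", compartment = "TILs-CD4+")
  for (dialect in c("vdjtools", "airr")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_clonotype_table(r, path, dialect)
    back <- read_clonotype_table(path, dialect, sample_id = r$sample_id,
                                 patient_id = r$patient_id,
                                 compartment = r$compartment)
    a <- dplyr::arrange(r$clonotypes, cdr3_nt, v_call)
    b <- dplyr::arrange(back$clonotypes, cdr3_nt, v_call)
    expect_equal(b, a)
  }
})

test_that("filename convention supplies metadata when not overridden", {
  r <- generate_repertoire(repertoire_spec(n_clonotypes = 20, seed = 1), "x")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "P7_TILs-CD8+_S2.txt")
  write_clonotype_table(r, path, "vdjtools")
  back <- read_clonotype_table(path, "vdjtools")
  expect_equal(back$sample_id, "P7_TILs-CD8+_S2")
  expect_equal(back$patient_id, "P7")
  expect_equal(back$compartment, "TILs-CD8+")
})

test_that("malformed tables are rejected with informative errors", {
  dir <- withr::local_tempdir()
  # negative count, named row
  bad <- file.path(dir, "bad.txt")
  writeLines(c(paste(c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j",
                       "VEnd", "DStart", "DEnd", "JStart"), collapse = "\t"),
               paste(c("-1", "1", "TGTTTC", "CF", "V", ".", "J",
                       "-1", "-1", "-1", "-1"), collapse = "\t")), bad)
  expect_error(read_clonotype_table(bad, "vdjtools"), "row 1")
  # unknown column set
  bad2 <- file.path(dir, "bad2.txt")
  writeLines(c("count\tfreq\tmystery", "1\t1\tx"), bad2)
  expect_error(read_clonotype_table(bad2, "vdjtools"), "header")
  # empty table
  empty <- file.path(dir, "empty.txt")
  writeLines(paste(c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j",
                     "VEnd", "DStart", "DEnd", "JStart"), collapse = "\t"),
             empty)
  expect_error(read_clonotype_table(empty, "vdjtools"), "empty")
  expect_error(read_clonotype_table(file.path(dir, "nothere.txt"),
                                    "vdjtools"), "no such file")
})

test_that("AIRR junction columns map onto cdr3 fields", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "airr.tsv")
  writeLines(c(paste(c("junction", "junction_aa", "v_call", "d_call",
                       "j_call", "duplicate_count"), collapse = "\t"),
               paste(c("TGTGCCAGCTTT", "CASF", "TRBV1", "", "TRBJ1", "4"),
                     collapse = "\t")), path)
  r <- read_clonotype_table(path, "airr")
  expect_equal(r$clonotypes$cdr3_nt, "TGTGCCAGCTTT")
  expect_equal(r$clonotypes$cdr3_aa, "CASF")
  expect_equal(r$clonotypes$count, 4L)
  expect_true(is.na(r$clonotypes$d_call))
  expect_true(is.na(r$clonotypes$v_end))
})

test_that("written tables are sorted and refuse empty repertoires", {
  r <- toy_rep(c("CAF", "CGF", "CDF"), counts = c(1, 5, 5))
  path <- withr::local_tempfile(fileext = ".txt")
  write_clonotype_table(r, path, "vdjtools")
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(tab$count, c(5, 5, 1))
  expect_equal(tab$cdr3nt[1:2], sort(tab$cdr3nt[1:2]))
  r$clonotypes <- r$clonotypes[0, ]
  expect_error(write_clonotype_table(r, path, "vdjtools"), "empty")
})

test_that("the productive filter drops stops and frameshifts, idempotently", {
  cl <- tibble::tibble(
    cdr3_nt = c("TGTGCCAGCTTT", "TGTTAAAGCTTT", "TGTGCCAGCTT"),
    cdr3_aa = c("CASF", "C*SF", "CAS_"),
    v_call = "V", d_call = NA_character_, j_call = "J",
    count = c(3L, 2L, 1L), freq = c(0.5, 1 / 3, 1 / 6),
    v_end = NA_integer_, d_start = NA_integer_, d_end = NA_integer_,
    j_start = NA_integer_)
  r <- new_repertoire(cl, "S")
  f <- filter_productive(r)
  expect_equal(f$clonotypes$cdr3_aa, "CASF")
  expect_equal(f$clonotypes$freq, 1)
  expect_identical(filter_productive(f), f)
  # all-productive input: only a renormalization no-op
  ok <- toy_rep(c("CAF", "CGF"), counts = c(1, 3))
  expect_equal(filter_productive(ok)$clonotypes, ok$clonotypes)
  # everything removed
  r$clonotypes <- r$clonotypes[2, ]
  expect_error(filter_productive(r), "productive")
})

test_that("decontamination applies the frequency-ratio rule", {
  mk <- function(id, aa, counts) toy_rep(aa, counts, sample_id = id,
                                         patient_id = id)
  shared <- "CASSLGYF"
  # A carries the clone at 1e-3 of its mass; B at ~1e-1: ratio 100 >= 20
  a <- mk("A", c(shared, "CAAAF"), c(1L, 999L))
  b <- mk("B", c(shared, "CCCCF"), c(100L, 900L))
  co <- decontaminate(new_cohort(list(a, b)), ratio = 20)
  expect_false(shared %in% co$repertoires$A$clonotypes$cdr3_aa)
  expect_true(shared %in% co$repertoires$B$clonotypes$cdr3_aa)
  expect_equal(sum(co$repertoires$A$clonotypes$freq), 1)
  # 10x apart: below the ratio, kept in both
  a2 <- mk("A", c(shared, "CAAAF"), c(10L, 990L))
  co2 <- decontaminate(new_cohort(list(a2, b)), ratio = 20)
  expect_true(shared %in% co2$repertoires$A$clonotypes$cdr3_aa)
  # idempotence at fixed ratio
  expect_identical(decontaminate(co, ratio = 20), co)
  # single sample: unchanged; bad ratio: error
  solo <- new_cohort(list(a))
  expect_identical(decontaminate(solo, 20), solo)
  expect_error(decontaminate(co, ratio = 1), "ratio")
})

test_that("aa collapse sums nt variants and conserves counts", {
  r <- toy_rep(c("CASSLGYF", "CASSLGYF", "CAAAF"),
               counts = c(3L, 2L, 5L),
               nt = c("TGTGCCAGCAGCCTGGGCTACTTT",
                      "TGCGCCAGCAGCCTGGGCTACTTT",
                      "TGTGCCGCCGCCTTT"))
  aa <- collapse_by_aa(r)
  expect_equal(nrow(aa), 2)
  row <- aa[aa$cdr3_aa == "CASSLGYF", ]
  expect_equal(row$count, 5L)
  expect_equal(row$nt_variant_count, 2L)
  expect_equal(sum(aa$count), sum(r$clonotypes$count))
  expect_lt(abs(sum(aa$freq) - 1), 1e-12)
  # all-unique input
  u <- collapse_by_aa(toy_rep(c("CAF", "CGF", "CHF")))
  expect_equal(nrow(u), 3)
  expect_true(all(u$nt_variant_count == 1))
})

test_that("merging slices pools counts per clonotype", {
  s1 <- toy_rep(c("CASSLGYF", "CAAAF"), c(4L, 1L), sample_id = "P1_a",
                patient_id = "P1")
  s2 <- toy_rep(c("CASSLGYF", "CDDDF"), c(6L, 2L), sample_id = "P1_b",
                patient_id = "P1")
  m <- merge_samples(list(s1, s2))
  expect_equal(sum(m$clonotypes$freq), 1)
  expect_equal(m$clonotypes$count[m$clonotypes$cdr3_aa == "CASSLGYF"], 10L)
  expect_equal(nrow(m$clonotypes), 3)
  # disjoint slices concatenate
  d1 <- toy_rep(paste0("CA", tilrep:::AA20[1:10], "F"), sample_id = "P2_a",
                patient_id = "P2")
  d2 <- toy_rep(paste0("CG", tilrep:::AA20[1:10], "F"), sample_id = "P2_b",
                patient_id = "P2")
  expect_equal(nrow(merge_samples(list(d1, d2))$clonotypes), 20)
  # identity on a single repertoire
  solo <- merge_samples(list(s1))
  expect_equal(dplyr::arrange(solo$clonotypes, cdr3_nt),
               dplyr::arrange(s1$clonotypes, cdr3_nt))
  expect_error(merge_samples(list(s1, d1)), "different patients")
})
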