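test_that("normalized Shannon-Wiener handles the canonical cases", {
  uni <- toy_rep(paste0("CA", tilrep:::AA20[1:4], "F"))
  expect_equal(normalized_shannon_wiener(uni)$nsw, 1.0)
  mono <- toy_rep("CAAAF")
  expect_equal(normalized_shannon_wiener(mono)$nsw, 0.0)
  skew <- toy_rep(c("CAAAF", "CAGAF", "CATAF"), counts = c(2L, 1L, 1L))
  dv <- normalized_shannon_wiener(skew)
  expect_equal(dv$H, 1.039721, tolerance = 1e-6)
  expect_equal(dv$nsw, 0.946395, tolerance = 1e-6)
  bad <- uni
  bad$clonotypes$freq <- bad$clonotypes$freq * 2
  expect_error(normalized_shannon_wiener(bad), "not normalized")
})

test_that("nsw equals a high-precision brute-force evaluation", {
  set.seed(17)
  for (i in 1:100) {
    S <- sample(2:60, 1)
    f <- runif(S)
    f <- f / sum(f)
    r <- toy_aa_rep(random_peptides(S), freq = f)
    dv <- normalized_shannon_wiener(r, "aa")
    # oracle: term-by-term accumulation over sorted frequencies
    H <- 0
    for (x in sort(f)) H <- H - x * log(x)
    expect_equal(dv$H, H, tolerance = 1e-12)
    expect_equal(dv$nsw, H / log(S), tolerance = 1e-12)
    expect_true(dv$nsw >= 0 && dv$nsw <= 1 + 1e-12)
    expect_lte(dv$H, log(dv$S) + 1e-12)
  }
})

test_that("CR level counts nt variants per aa clonotype", {
  r <- toy_aa_rep(paste0("CA", tilrep:::AA20[1:4], "F"),
                  nt_variants = c(2L, 1L, 1L, 1L))
  cr <- convergence(r)
  expect_equal(cr$cr_level, 1.25)
  expect_equal(sum(cr$per_aa$convergent), 1)
  flat <- toy_aa_rep(paste0("CA", tilrep:::AA20[1:5], "F"))
  expect_equal(convergence(flat)$cr_level, 1.0)
  expect_false(any(convergence(flat)$per_aa$convergent))
})

test_that("CR level ignores frequency rescaling", {
  r <- generate_repertoire(repertoire_spec(n_clonotypes = 200,
                                           convergence_rate = 0.3,
                                           seed = 5), "A")
  aa1 <- collapse_by_aa(r)
  r$clonotypes$count <- r$clonotypes$count * 7L
  r <- tilrep:::renormalize(r)
  aa2 <- collapse_by_aa(r)
  expect_equal(convergence(aa2)$cr_level, convergence(aa1)$cr_level)
})

test_that("the convergence knob raises the CR level", {
  crs <- vapply(1:8, function(i) {
    on <- generate_repertoire(repertoire_spec(n_clonotypes = 300,
                                              convergence_rate = 0.3,
                                              seed = 600 + i), "A")
    off <- generate_repertoire(repertoire_spec(n_clonotypes = 300,
                                               convergence_rate = 0,
                                               seed = 600 + i), "B")
    convergence(collapse_by_aa(on))$cr_level -
      convergence(collapse_by_aa(off))$cr_level
  }, numeric(1))
  expect_true(all(crs > 0))
})

test_that("publicity is computed on patient-merged repertoires", {
  co <- small_cohort(seed = 41, patients = 3, slices = 2,
                     public_injection = list(
                       list(cdr3_aa = "CASSPTGLAGEQYF", n_patients = 2),
                       list(cdr3_aa = "CASSTRIPLEQYF", n_patients = 3)))
  pb <- public_sequences(co, "TILs-CD4+")
  tab <- pb$per_aa
  expect_equal(tab$share[tab$cdr3_aa == "CASSPTGLAGEQYF"], 2L)
  expect_equal(tab$share[tab$cdr3_aa == "CASSTRIPLEQYF"], 3L)
  expect_true(all(tab$share <= pb$n_biopsies))
  expect_gte(pb$n_public, 2)
  expect_equal(pb$percent_public, 100 * pb$n_public / nrow(tab))
})

test_that("disjoint repertoires have no public sequences", {
  a <- toy_rep(paste0("CA", tilrep:::AA20[1:5], "F"), sample_id = "A",
               patient_id = "A")
  b <- toy_rep(paste0("CG", tilrep:::AA20[1:5], "F"), sample_id = "B",
               patient_id = "B")
  pb <- public_sequences(new_cohort(list(a, b)), "TILs-initial")
  expect_equal(pb$percent_public, 0)
  expect_error(public_sequences(new_cohort(list(a)), "TILs-initial"),
               ">= 2 biopsies")
})

test_that("merging slices never decreases share counts", {
  co <- small_cohort(seed = 47, patients = 3, slices = 2,
                     public_injection = list(
                       list(cdr3_aa = "CASSPTGLAGEQYF", n_patients = 2)))
  # slice-level sharing treated as if each slice were a biopsy
  slice_reps <- co$repertoires[grepl("CD4", names(co$repertoires))]
  slice_sets <- lapply(slice_reps, function(r) unique(r$clonotypes$cdr3_aa))
  merged_share <- public_sequences(co, "TILs-CD4+")$per_aa
  # every aa present in some slice of k patients has merged share >= k
  aa_patient <- unique(data.frame(
    aa = unlist(slice_sets),
    patient = rep(vapply(slice_reps, function(r) r$patient_id, character(1)),
                  lengths(slice_sets))))
  k_by_aa <- table(aa_patient$aa)
  idx <- match(names(k_by_aa), merged_share$cdr3_aa)
  expect_false(anyNA(idx))
  expect_true(all(merged_share$share[idx] >= as.integer(k_by_aa)))
})

test_that("the publicity x convergence cross-tab counts the toy example", {
  mk <- function(pid, aa, nt) toy_rep(aa, nt = nt, sample_id = pid,
                                      patient_id = pid)
  # publics A, B (convergent: two nt variants across patients),
  # privates C, D, E (one variant each)
  p1 <- mk("P1", c("CAAAAF", "CBBBBF", "CCCCCF"),
           c("TGTGCTGCAGCAGCATTC", "TGTAACAACAACAACTTC",
             "TGTTGTTGCTGTTGCTTT"))
  p2 <- mk("P2", c("CAAAAF", "CBBBBF", "CDDDDF", "CEEEEF"),
           c("TGCGCTGCAGCAGCATTC", "TGTAATAACAACAACTTC",
             "TGTGATGACGATGACTTT", "TGTGAAGAGGAAGAGTTT"))
  ct <- publicity_convergence_crosstab(new_cohort(list(p1, p2)),
                                       "TILs-initial")
  expect_equal(unname(ct$table["public", "convergent"]), 2)
  expect_equal(unname(ct$table["public", "non_convergent"]), 0)
  expect_equal(unname(ct$table["private", "convergent"]), 0)
  expect_equal(unname(ct$table["private", "non_convergent"]), 3)
  expect_equal(sum(ct$table), 5)
  expect_equal(ct$pct_public_convergent, 100)
  expect_equal(ct$pct_public_nonconvergent, 0)
})

test_that("convergence applied to publics shows up in the cross-tab", {
  skewed <- vapply(1:5, function(i) {
    co <- small_cohort(seed = 700 + i, patients = 3,
                       public_injection = list(
                         list(cdr3_aa = "CASSPTGLAGEQYF", n_patients = 3)))
    # give the injected public an extra nt variant in one patient
    r <- co$repertoires[[grep("P01_TILs-CD4\\+", names(co$repertoires))[1]]]
    row <- r$clonotypes[r$clonotypes$cdr3_aa == "CASSPTGLAGEQYF", ][1, ]
    row$cdr3_nt <- tilrep:::synonymous_variant(row$cdr3_nt)
    r$clonotypes <- rbind(r$clonotypes, row)
    co$repertoires[[r$sample_id]] <- tilrep:::renormalize(r)
    ct <- publicity_convergence_crosstab(co, "TILs-CD4+")
    ct$pct_public_convergent - ct$pct_public_nonconvergent
  }, numeric(1))
  expect_true(all(skewed > 0))
})

test_that("paired diversity presets are recovered on simulated slices", {
  wins <- vapply(1:6, function(i) {
    co <- small_cohort(seed = 800 + i, n = 500, patients = 4)
    st <- stats_table(co, "nt")
    cd4 <- st[st$compartment == "TILs-CD4+", ]
    cd8 <- st[st$compartment == "TILs-CD8+", ]
    cd8 <- cd8[match(cd4$patient_id, cd8$patient_id), ]
    res <- compare_groups(data.frame(x = cd8$nsw, y = cd4$nsw), "paired_t")
    res$statistic > 0 && res$p_value < 0.05
  }, logical(1))
  expect_gte(mean(wins), 5 / 6)
})
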