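test_that("interior 4-mer enumeration matches the hand enumeration", {
  map <- enumerate_motifs("CASSLGGSGEQFF", k_exact = 4L, k_wild = integer(0))
  expect_setequal(names(map), c("SLGG", "LGGS", "GGSG", "GSGE", "SGEQ"))
  expect_true(all(vapply(map, function(x)
    identical(x, "CASSLGGSGEQFF"), logical(1))))
})

test_that("the published wildcard motifs fall out of the enumeration", {
  m1 <- enumerate_motifs("CASSLGGSGEQFF")
  expect_true("SLGG%GE" %in% names(m1))
  expect_true(motif_matches("SLGG%GE", "CASSLGGSGEQFF"))
  m2 <- enumerate_motifs("CASTPNYSNQPQHF")
  expect_true("%NYSNQP" %in% names(m2))
  expect_true(motif_matches("%NYSNQP", "CASTPNYSNQPQHF"))
})

test_that("motif validity rules hold for every enumerated motif", {
  set.seed(23)
  map <- enumerate_motifs(random_peptides(40))
  expect_true(all(vapply(names(map), motif_is_valid, logical(1))))
  # sequences with a too-short interior contribute nothing
  expect_length(enumerate_motifs("CASSF"), 0)
})

test_that("a wildcard matches exactly the union of single-residue substitutions", {
  set.seed(29)
  seqs <- random_peptides(60)
  for (motif in c("SL%GE", "GG%S", "A%KQT")) {
    direct <- motif_matches(motif, seqs)
    by_union <- Reduce(`|`, lapply(tilrep:::AA20, function(a)
      grepl(sub("%", a, motif, fixed = TRUE), seqs, fixed = TRUE)))
    expect_identical(direct, by_union)
  }
})

test_that("Fisher scores equal the exact hypergeometric tail", {
  set.seed(37)
  sample_rep <- toy_aa_rep(random_peptides(40))
  ref_rep <- toy_aa_rep(random_peptides(60))
  for (i in 1:200) {
    k <- sample(1:20, 1); n_s <- k + sample(0:30, 1)
    k_r <- sample(0:20, 1); n_r <- k_r + sample(1:40, 1)
    ours <- phyper(k - 1, k + k_r, n_s + n_r - k - k_r, n_s,
                   lower.tail = FALSE)
    oracle <- fisher.test(matrix(c(k, n_s - k, k_r, n_r - k_r), 2,
                                 byrow = TRUE),
                          alternative = "greater")$p.value
    expect_equal(ours, oracle, tolerance = 1e-10)
  }
})

test_that("score_motif is enriched for planted motifs and flat under the null", {
  set.seed(43)
  carriers <- paste0("CASSLGGK",
                     replicate(10, paste(sample(tilrep:::AA20, 4),
                                         collapse = "")), "EQFF")
  sample_rep <- toy_aa_rep(unique(c(carriers, random_peptides(90))))
  ref_rep <- toy_aa_rep(random_peptides(1000))
  sc <- score_motif("SLGGK", sample_rep, ref_rep, B = 200)
  expect_lt(sc$fisher_score, 0.001)
  expect_true(sc$expansion_score > 0 && sc$expansion_score <= 1)
  expect_error(score_motif("WWWWW", sample_rep, ref_rep), "no sample carrier")
  expect_error(score_motif("SSLG", sample_rep, toy_aa_rep(character(0))),
               "empty reference")
})

test_that("adding sample carriers never increases the Fisher score", {
  n_r <- 500; k_r <- 5
  p_prev <- 1
  for (k in 1:30) {
    n_s <- 100
    p <- phyper(k - 1, k + k_r, n_s + n_r - k - k_r, n_s, lower.tail = FALSE)
    expect_lte(p, p_prev + 1e-15)
    p_prev <- p
  }
})

test_that("expansion scores are seed-reproducible and floor at 1/(B+1)", {
  set.seed(51)
  rep <- toy_aa_rep(random_peptides(50), counts = c(100L, 80L,
                                                    rep(1L, 48)))
  top_idx <- 1:2
  withr::with_seed(9, p1 <- tilrep:::expansion_pvalue(rep$freq, top_idx, 400))
  withr::with_seed(9, p2 <- tilrep:::expansion_pvalue(rep$freq, top_idx, 400))
  expect_identical(p1, p2)
  # floor behavior: only a null draw of the carrier set itself can tie
  expect_gte(p1, 1 / 401)
  expect_lte(p1, 5 / 401)
  # convergence in B
  withr::with_seed(10, pa <- tilrep:::expansion_pvalue(rep$freq, c(5, 9), 1000))
  withr::with_seed(11, pb <- tilrep:::expansion_pvalue(rep$freq, c(5, 9), 10000))
  expect_lt(abs(pa - pb), 0.03)
})

test_that("planted motifs come back as passing clusters whose members match", {
  set.seed(57)
  plant_sample <- function(seed, n = 200, frac = 0.15) {
    r <- generate_repertoire(repertoire_spec(
      n_clonotypes = n, convergence_rate = 0,
      planted_motifs = list(list(motif = "SLGGK", n_carriers = round(frac * n))),
      seed = seed), "S")
    aa <- collapse_by_aa(r)
    # carriers are clonally expanded (antigen-driven), 5x over background
    hit <- motif_matches("SLGGK", aa$cdr3_aa, interior_only = TRUE)
    aa$count[hit] <- aa$count[hit] * 5L
    aa$freq <- aa$count / sum(aa$count)
    aa
  }
  ref <- collapse_by_aa(generate_repertoire(repertoire_spec(
    n_clonotypes = 1000, convergence_rate = 0,
    planted_motifs = list(list(motif = "SLGGK", n_carriers = 10)),
    seed = 58), "R"))
  cl <- cluster_by_motifs(plant_sample(59), ref, B = 500)
  mots <- vapply(cl, function(x) x$motif, character(1))
  expect_true("SLGGK" %in% mots)
  # membership contract: every member of every cluster matches its motif
  for (x in cl) {
    expect_true(all(motif_matches(x$motif, x$members$cdr3_aa,
                                  interior_only = TRUE)))
  }
})

test_that("nested exact motifs with identical carriers are suppressed", {
  set.seed(61)
  # sample in which SLGGK and its sub-motifs have exactly the same carriers
  carriers <- paste0("CASS", "LGGKV",
                     replicate(8, paste(sample(c("A", "T", "V", "Q"), 3,
                                               replace = TRUE),
                                        collapse = "")), "EQFF")
  filler <- random_peptides(80)
  filler <- filler[!motif_matches("LGG", filler)]
  rep <- toy_aa_rep(unique(c(carriers, filler)))
  ref <- toy_aa_rep(random_peptides(500))
  cl <- cluster_by_motifs(rep, ref, fisher_max = 0.5, expansion_max = 1,
                          B = 100, min_carriers = 2)
  mots <- vapply(cl, function(x) x$motif, character(1))
  if (any(nchar(mots) >= 5 & !grepl("%", mots))) {
    long5 <- mots[nchar(mots) == 5 & !grepl("%", mots)]
    for (m5 in long5) {
      subs <- c(substr(m5, 1, 4), substr(m5, 2, 5),
                substr(m5, 1, 3), substr(m5, 2, 4), substr(m5, 3, 5))
      carriers5 <- cl[[which(mots == m5)]]$members$cdr3_aa
      for (s in intersect(subs, mots)) {
        expect_false(setequal(cl[[which(mots == s)]]$members$cdr3_aa,
                              carriers5))
      }
    }
  }
  expect_error(cluster_by_motifs(rep, ref, fisher_max = 0), "thresholds")
})

test_that("motif sharing tables count biopsies per motif", {
  fake_cluster <- function(motif, biopsy) {
    structure(list(motif = motif,
                   members = tibble::tibble(cdr3_aa = "CASSLGGKEQFF",
                                            freq = 1, biopsy = biopsy),
                   fisher_score = 0.01, expansion_score = 0.1,
                   support = c(sample_carriers = 1, sample_size = 1,
                               reference_carriers = 0, reference_size = 1)),
              class = "motif_cluster")
  }
  sh <- motif_sharing(list(
    Q14 = list(fake_cluster("SLGG%GE", "Q14"), fake_cluster("AAA", "Q14")),
    Q1 = list(fake_cluster("SLGG%GE", "Q1"))))
  expect_equal(sh$n_shared, 1)
  tab <- sh$table
  expect_equal(tab$n_biopsies[tab$motif == "SLGG%GE"], 2)
  expect_equal(tab$n_biopsies[tab$motif == "AAA"], 1)
  all_private <- motif_sharing(list(A = list(fake_cluster("AAA", "A")),
                                    B = list(fake_cluster("TTT", "B"))))
  expect_equal(all_private$n_shared, 0)
})
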