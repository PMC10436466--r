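test_that("edit distance handles the canonical examples", {
  expect_equal(levenshtein("CASSF", "CASSF"), 0L)
  expect_equal(levenshtein("CASSLGG", "CASSIGG"), 1L)
  expect_equal(levenshtein("kitten", "sitting"), 3L)
  expect_equal(levenshtein("", "CASS"), 4L)
  expect_equal(levenshtein(c("CAF", "CAF"), c("CAF", "CGGF")), c(0L, 2L))
})

test_that("edit distance is a metric and agrees with the DP oracle", {
  set.seed(67)
  for (i in 1:60) {
    tri <- random_peptides(3, min_core = 2, max_core = 8)
    a <- tri[1]; b <- tri[2]; c <- tri[3]
    dab <- levenshtein(a, b)
    expect_equal(dab, as.integer(utils::adist(a, b)))
    expect_equal(dab, levenshtein(b, a))
    expect_equal(levenshtein(a, a), 0L)
    expect_lte(dab, levenshtein(a, c) + levenshtein(c, b))
    if (a != b) expect_gte(dab, 1L)
  }
})

test_that("the fast distance<=1 check is exact", {
  set.seed(71)
  for (i in 1:200) {
    a <- paste(sample(c("A", "S", "G"), sample(3:8, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "S", "G"), sample(3:8, 1), replace = TRUE),
               collapse = "")
    d_true <- as.integer(utils::adist(a, b))
    d_fast <- tilrep:::dist_le1(a, b)
    if (d_true <= 1) expect_equal(d_fast, d_true)
    else expect_true(is.na(d_fast))
  }
})

test_that("database matching reports all pairs within the distance", {
  db <- generate_specificity_db(db_spec(
    n_records = c(pathogens = 5),
    overlap = list(list(cdr3_aa = "CASSLGGSGEQFF", category = "cancer")),
    seed = 3))
  hits <- match_database(c("CASSLGGSGEQFF",   # exact
                           "CASSLGGAGEQFF",   # one substitution
                           "CASSLGGSGEQ",     # two deletions: no match
                           "WWWWWWWW"), db)
  h <- function(q) hits[hits$query == q, ]
  expect_true(any(h("CASSLGGSGEQFF")$distance == 0, na.rm = TRUE))
  expect_true(any(h("CASSLGGAGEQFF")$distance == 1 &
                    h("CASSLGGAGEQFF")$category == "cancer", na.rm = TRUE))
  expect_true(all(is.na(h("CASSLGGSGEQ")$distance)))
  expect_true(all(is.na(h("WWWWWWWW")$distance)))
  # every query appears in the output
  expect_setequal(unique(hits$query),
                  c("CASSLGGSGEQFF", "CASSLGGAGEQFF", "CASSLGGSGEQ",
                    "WWWWWWWW"))
  expect_error(match_database("CASSF", db[0, ]), "empty")
  db_bad <- db
  db_bad$category[1] <- "weird"
  expect_error(match_database("CASSF", db_bad), "malformed")
})

test_that("database matching equals brute-force all-pairs distances", {
  set.seed(73)
  queries <- unique(random_peptides(60, 3, 6))
  db <- tibble::tibble(cdr3aa = unique(random_peptides(80, 3, 6)),
                       category = "pathogens", source = "x")
  class(db) <- c("specificity_db", class(db))
  got <- match_database(queries, db, max_dist = 1)
  got_pairs <- got[!is.na(got$distance), c("query", "cdr3aa", "distance")]
  D <- utils::adist(queries, db$cdr3aa)
  idx <- which(D <= 1, arr.ind = TRUE)
  want <- data.frame(query = queries[idx[, 1]],
                     cdr3aa = db$cdr3aa[idx[, 2]],
                     distance = D[idx])
  expect_equal(nrow(got_pairs), nrow(want))
  expect_setequal(paste(got_pairs$query, got_pairs$cdr3aa, got_pairs$distance),
                  paste(want$query, want$cdr3aa, want$distance))
})

test_that("candidate sets implement the three selection rules", {
  aa <- toy_aa_rep(c("CAHIGHF", "CALOWF", "CAPUBF", "CACLUF"),
                   freq = c(0.7, 0.0005, 0.2495, 0.05))
  pub <- list(per_aa = tibble::tibble(cdr3_aa = c("CAPUBF", "CALOWF"),
                                      share = c(2L, 1L),
                                      public = c(TRUE, FALSE)))
  clus <- list(structure(list(
    motif = "CLU",
    members = tibble::tibble(cdr3_aa = "CACLUF", freq = 0.05, biopsy = "B1"),
    fisher_score = 0.1, expansion_score = 0.1,
    support = c()), class = "motif_cluster"))
  cs <- candidate_sets(aa, pub, clus)
  expect_setequal(cs$high_freq, c("CAHIGHF", "CAPUBF", "CACLUF"))
  expect_equal(cs$public, "CAPUBF")
  expect_equal(cs$clustered, "CACLUF")
  expect_equal(unname(cs$sizes), c(3L, 1L, 1L))
  expect_equal(candidate_sets(aa, pub, list())$sizes[["clustered"]], 0L)
  expect_error(candidate_sets(aa, pub, clus, freq_threshold = 0), "0, 1")
})

test_that("cancer annotations propagate across the cluster, others do not", {
  # members pairwise distance 2, so each db record hits one member only
  members <- c("CASSLGGKAAEQFF", "CASSLGGKTTEQFF", "CASSLGGKWWEQFF",
               "CASSLGGKYYEQFF")
  clus <- list(structure(list(
    motif = "SLGGK",
    members = tibble::tibble(cdr3_aa = members, freq = 0.01, biopsy = "B1"),
    fisher_score = 0.01, expansion_score = 0.01, support = c()),
    class = "motif_cluster"))
  db <- tibble::tibble(
    cdr3aa = c("CASSLGGKAAEQFF", "CASSLGGKTTEQFF"),
    category = c("cancer", "pathogens"),
    source = c("melanoma", "CMV"))
  class(db) <- c("specificity_db", class(db))
  ann <- annotate_clusters(clus, match_database(members, db))
  cancer <- ann[ann$category == "cancer", ]
  expect_equal(sum(cancer$status == "direct"), 1)
  expect_equal(sum(cancer$status == "propagated"), 3)
  expect_true(all(cancer$motif[cancer$status == "propagated"] == "SLGGK"))
  path <- ann[ann$category == "pathogens", ]
  expect_equal(nrow(path), 1)
  expect_equal(path$status, "direct")
  # monotonicity of the count table
  cnt <- annotation_counts(ann)
  expect_true(all(cnt$n_total >= cnt$n_direct))
  expect_equal(cnt$n_total[cnt$category == "cancer"], 4L)
  expect_equal(cnt$n_direct[cnt$category == "cancer"], 1L)
  # no clusters, no matches: empty table
  empty <- annotate_clusters(list(),
                             match_database("CAAAAF", db))
  expect_equal(nrow(empty), 0)
})

test_that("propagation can be widened to all categories", {
  members <- c("CASSLGGKAAEQFF", "CASSLGGKTTEQFF")
  clus <- list(structure(list(
    motif = "SLGGK",
    members = tibble::tibble(cdr3_aa = members, freq = 0.01, biopsy = "B1"),
    fisher_score = 0.01, expansion_score = 0.01, support = c()),
    class = "motif_cluster"))
  db <- tibble::tibble(cdr3aa = "CASSLGGKTTEQFF", category = "pathogens",
                       source = "flu")
  class(db) <- c("specificity_db", class(db))
  m <- match_database(members, db)
  expect_equal(sum(annotate_clusters(clus, m)$status == "propagated"), 0)
  wide <- annotate_clusters(clus, m, propagate = tilrep:::DB_CATEGORIES)
  expect_equal(sum(wide$status == "propagated"), 1)
})
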