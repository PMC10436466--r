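# Edit-distance annotation of candidate CDR3aa sequences against a
# specificity database, and cancer-annotation propagation across motif
# clusters.

#' Levenshtein edit distance
#'
#' Standard unit-cost dynamic-programming edit distance (insertions,
#' deletions, substitutions). Vectorized elementwise with recycling.
#'
#' @param a,b character vectors.
#' @return integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  mapply(function(x, y) {
    cx <- strsplit(x, "")[[1]]
    cy <- strsplit(y, "")[[1]]
    nx <- length(cx); ny <- length(cy)
    if (nx == 0) return(ny)
    if (ny == 0) return(nx)
    prev <- 0:ny
    for (i in seq_len(nx)) {
      cur <- integer(ny + 1)
      cur[1] <- i
      for (j in seq_len(ny)) {
        cur[j + 1] <- min(prev[j] + (cx[i] != cy[j]),
                          prev[j + 1] + 1L,
                          cur[j] + 1L)
      }
      prev <- cur
    }
    prev[ny + 1]
  }, a, b, USE.NAMES = FALSE)
}

# exact distance for small k without the full DP: returns the distance if
# <= 1, otherwise NA
dist_le1 <- function(x, y) {
  nx <- nchar(x); ny <- nchar(y)
  if (abs(nx - ny) > 1) return(NA_integer_)
  if (nx == ny) {
    cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
    mm <- sum(cx != cy)
    return(if (mm <= 1) mm else NA_integer_)
  }
  long <- if (nx > ny) x else y
  short <- if (nx > ny) y else x
  cl <- strsplit(long, "")[[1]]; cs <- strsplit(short, "")[[1]]
  i <- 1L
  while (i <= length(cs) && cl[i] == cs[i]) i <- i + 1L
  if (identical(cl[-i], cs)) 1L else NA_integer_
}

#' Match queries against a specificity database
#'
#' Reports, for every query, all database records within Levenshtein
#' distance `max_dist`. A length pre-filter (`|length difference| <=
#' max_dist`) is applied before any distance computation; for
#' `max_dist <= 1` an exact linear-time check replaces the full dynamic
#' program. Queries without a match are kept as rows with `NA` record
#' fields so the output enumerates every query.
#'
#' @param queries character vector of CDR3aa sequences.
#' @param db a `specificity_db` (columns `cdr3aa`, `category`, `source`).
#' @param max_dist maximum edit distance (default 1).
#' @return tibble: `query`, `cdr3aa`, `category`, `source`, `distance`.
#' @export
match_database <- function(queries, db, max_dist = 1L) {
  if (is.null(db) || nrow(db) == 0) stop("empty specificity database")
  if (!all(c("cdr3aa", "category", "source") %in% names(db)))
    stop("malformed database: needs columns cdr3aa, category, source")
  bad <- !db$category %in% DB_CATEGORIES
  if (any(bad)) stop("malformed database row ", which(bad)[1],
                     ": unknown category '", db$category[which(bad)[1]], "'")
  queries <- unique(queries)
  db_len <- nchar(db$cdr3aa)
  q_out <- character(0); rec_out <- integer(0); d_out <- integer(0)
  for (q in queries) {
    cand <- which(abs(db_len - nchar(q)) <= max_dist)
    hit <- integer(0); d <- integer(0)
    if (length(cand)) {
      d <- if (max_dist <= 1) {
        vapply(db$cdr3aa[cand], function(r) {
          d1 <- dist_le1(q, r)
          if (is.na(d1) || d1 > max_dist) NA_integer_ else d1
        }, integer(1), USE.NAMES = FALSE)
      } else {
        dd <- levenshtein(q, db$cdr3aa[cand])
        dd[dd > max_dist] <- NA_integer_
        as.integer(dd)
      }
      hit <- which(!is.na(d))
    }
    if (length(hit)) {
      q_out <- c(q_out, rep(q, length(hit)))
      rec_out <- c(rec_out, cand[hit])
      d_out <- c(d_out, d[hit])
    } else {
      q_out <- c(q_out, q)
      rec_out <- c(rec_out, NA_integer_)
      d_out <- c(d_out, NA_integer_)
    }
  }
  tibble::tibble(query = q_out,
                 cdr3aa = db$cdr3aa[rec_out],
                 category = db$category[rec_out],
                 source = db$source[rec_out],
                 distance = d_out)
}

#' Candidate sequence sets for database annotation
#'
#' The three (overlapping) candidate sets submitted to the database: the
#' high-frequency set (`freq > freq_threshold` on the pooled aa
#' repertoire), the public set, and the motif-clustered set.
#'
#' @param aa_rep pooled `aa_repertoire` of the compartment.
#' @param publicity a `publicity_result` ([public_sequences()]) on the same
#'   compartment.
#' @param clusters list of `motif_cluster`s for the compartment.
#' @param freq_threshold frequency cut-off in (0, 1); default 0.001, i.e.
#'   0.1%.
#' @return list of class `candidate_sets`: `high_freq`, `public`,
#'   `clustered` (character vectors), `sizes` (named integer vector),
#'   `universe_size`.
#' @export
candidate_sets <- function(aa_rep, publicity, clusters,
                           freq_threshold = 0.001) {
  if (freq_threshold <= 0 || freq_threshold >= 1)
    stop("freq_threshold must lie in (0, 1)")
  high_freq <- sort(aa_rep$cdr3_aa[aa_rep$freq > freq_threshold])
  public <- sort(publicity$per_aa$cdr3_aa[publicity$per_aa$public])
  clustered <- sort(unique(unlist(lapply(clusters,
                                         function(cl) cl$members$cdr3_aa))))
  if (is.null(clustered)) clustered <- character(0)
  structure(list(high_freq = high_freq, public = public,
                 clustered = clustered,
                 sizes = c(high_freq = length(high_freq),
                           public = length(public),
                           clustered = length(clustered)),
                 universe_size = nrow(aa_rep)),
            class = "candidate_sets")
}

#' Propagate database annotations across motif clusters
#'
#' Direct matches annotate their own sequence with the matched categories.
#' When any member of a motif cluster has a direct match in a propagated
#' category (by default only `cancer`: "putatively tumor-associated"), the
#' remaining members of that cluster are annotated with the propagated
#' flag and the propagating motif.
#'
#' @param clusters list of `motif_cluster`s.
#' @param matches output of [match_database()] covering cluster members.
#' @param propagate categories whose direct matches propagate across a
#'   cluster.
#' @return tibble: `cdr3_aa`, `category`, `status`
#'   (`"direct"`/`"propagated"`), `motif` (NA for direct matches).
#' @export
annotate_clusters <- function(clusters, matches,
                              propagate = "cancer") {
  direct <- matches[!is.na(matches$category),
                    c("query", "category", "distance")]
  direct_tab <- if (nrow(direct)) {
    unique(tibble::tibble(cdr3_aa = direct$query,
                          category = direct$category,
                          status = "direct", motif = NA_character_))
  } else {
    tibble::tibble(cdr3_aa = character(0), category = character(0),
                   status = character(0), motif = character(0))
  }
  prop_rows <- list()
  for (cl in clusters) {
    members <- unique(cl$members$cdr3_aa)
    for (cat in propagate) {
      seed_members <- intersect(members,
                                direct_tab$cdr3_aa[direct_tab$category == cat])
      if (!length(seed_members)) next
      rest <- setdiff(members, seed_members)
      if (length(rest)) {
        prop_rows[[length(prop_rows) + 1L]] <-
          tibble::tibble(cdr3_aa = rest, category = cat,
                         status = "propagated", motif = cl$motif)
      }
    }
  }
  out <- dplyr::bind_rows(c(list(direct_tab), prop_rows))
  unique(out[order(out$category, out$status, out$cdr3_aa), ])
}

#' Category counts, direct vs direct + propagated
#'
#' @param annotation output of [annotate_clusters()].
#' @return tibble: `category`, `n_direct`, `n_total` (mirrors the
#'   "clustered" vs "clustered + manual annotation" distinction).
#' @export
annotation_counts <- function(annotation) {
  if (nrow(annotation) == 0) {
    return(tibble::tibble(category = character(0), n_direct = integer(0),
                          n_total = integer(0)))
  }
  annotation |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n_direct = dplyr::n_distinct(.data$cdr3_aa[.data$status == "direct"]),
      n_total = dplyr::n_distinct(.data$cdr3_aa),
      .groups = "drop")
}
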