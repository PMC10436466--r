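# Group-comparison layer: one-way ANOVA + Tukey, paired t, two-way ANOVA
# with Sidak-adjusted pairwise contrasts, and Pearson correlation. Thin,
# contract-tested wrappers over the standard fitting routines with
# explicit degenerate-input errors (never NaN propagation).

#' Compare groups with the design used for a figure panel
#'
#' * `anova_tukey`: `data` has columns `value`, `group` (>= 2 groups of
#'   size >= 2); ordinary one-way ANOVA, Tukey HSD pairwise p-values.
#' * `paired_t`: `data` has columns `x`, `y` (equal-length pairs); rows
#'   with a missing member are dropped with the count reported.
#' * `twoway_sidak`: `data` has columns `value`, `factor1`, `factor2`;
#'   ordinary two-way ANOVA (with interaction); pairwise contrasts of
#'   `factor1` levels within each `factor2` level use the pooled residual
#'   variance and a Sidak adjustment.
#' * `pearson`: `data` has columns `x`, `y` (n >= 3, both non-constant).
#'
#' @param data data frame in the design-appropriate shape.
#' @param design one of `"anova_tukey"`, `"paired_t"`, `"twoway_sidak"`,
#'   `"pearson"`.
#' @return list of class `comparison_result`: `method`, `statistic`,
#'   `p_value`, `pairwise` (tibble or NULL), `groups` (tibble or NULL),
#'   `n_dropped`.
#' @export
compare_groups <- function(data, design = c("anova_tukey", "paired_t",
                                            "twoway_sidak", "pearson")) {
  design <- match.arg(design)
  switch(design,
         anova_tukey = cg_anova_tukey(data),
         paired_t = cg_paired_t(data),
         twoway_sidak = cg_twoway_sidak(data),
         pearson = cg_pearson(data))
}

comparison_result <- function(method, statistic, p_value, pairwise = NULL,
                              groups = NULL, n_dropped = 0L) {
  structure(list(method = method, statistic = unname(statistic),
                 p_value = unname(p_value), pairwise = pairwise,
                 groups = groups, n_dropped = n_dropped),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

cg_anova_tukey <- function(data) {
  stopifnot(all(c("value", "group") %in% names(data)))
  ok <- !is.na(data$value) & !is.na(data$group)
  n_dropped <- sum(!ok)
  data <- data[ok, ]
  data$group <- factor(data$group)
  sizes <- table(data$group)
  if (length(sizes) < 2) stop("anova_tukey needs >= 2 groups")
  if (any(sizes < 2)) stop("group(s) of size < 2: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  if (all(tapply(data$value, data$group, sd) == 0))
    stop("zero variance in every group")
  fit <- aov(value ~ group, data = data)
  sm <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  pairwise <- tibble::tibble(contrast = rownames(tk),
                             estimate = tk[, "diff"],
                             p_adj = tk[, "p adj"])
  groups <- data |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     .groups = "drop")
  comparison_result("one-way ANOVA + Tukey HSD",
                    sm[["F value"]][1], sm[["Pr(>F)"]][1],
                    pairwise, groups, n_dropped)
}

cg_paired_t <- function(data) {
  stopifnot(all(c("x", "y") %in% names(data)))
  ok <- !is.na(data$x) & !is.na(data$y)
  n_dropped <- sum(!ok)
  x <- data$x[ok]; y <- data$y[ok]
  if (length(x) < 2) stop("paired_t needs >= 2 complete pairs")
  d <- x - y
  if (all(d == 0)) {
    return(comparison_result("paired t-test", 0, 1,
                             n_dropped = n_dropped))
  }
  if (sd(d) == 0) stop("zero variance of paired differences")
  tt <- t.test(x, y, paired = TRUE)
  groups <- tibble::tibble(group = c("x", "y"), n = length(x),
                           mean = c(mean(x), mean(y)))
  comparison_result("paired t-test", tt$statistic, tt$p.value,
                    groups = groups, n_dropped = n_dropped)
}

cg_twoway_sidak <- function(data) {
  stopifnot(all(c("value", "factor1", "factor2") %in% names(data)))
  ok <- !is.na(data$value) & !is.na(data$factor1) & !is.na(data$factor2)
  n_dropped <- sum(!ok)
  data <- data[ok, ]
  data$factor1 <- factor(data$factor1)
  data$factor2 <- factor(data$factor2)
  if (nlevels(data$factor1) < 2 || nlevels(data$factor2) < 2)
    stop("twoway_sidak needs two crossed factors with >= 2 levels each")
  cell_n <- table(data$factor1, data$factor2)
  if (any(cell_n < 2)) stop("cell(s) of size < 2")
  fit <- aov(value ~ factor1 * factor2, data = data)
  sm <- summary(fit)[[1]]
  rownames(sm) <- trimws(rownames(sm))
  mse <- sm["Residuals", "Mean Sq"]
  dfr <- sm["Residuals", "Df"]
  if (mse == 0) stop("zero residual variance")
  lv1 <- levels(data$factor1)
  pairs1 <- utils::combn(lv1, 2, simplify = FALSE)
  m <- length(pairs1) * nlevels(data$factor2)
  rows <- list()
  for (l2 in levels(data$factor2)) {
    for (pr in pairs1) {
      s1 <- data$value[data$factor1 == pr[1] & data$factor2 == l2]
      s2 <- data$value[data$factor1 == pr[2] & data$factor2 == l2]
      est <- mean(s1) - mean(s2)
      se <- sqrt(mse * (1 / length(s1) + 1 / length(s2)))
      tstat <- est / se
      p <- 2 * pt(-abs(tstat), dfr)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        contrast = paste0(pr[1], "-", pr[2], " | ", l2),
        estimate = est, p = p,
        p_adj = 1 - (1 - p)^m)
    }
  }
  groups <- data |>
    dplyr::group_by(factor1 = .data$factor1, factor2 = .data$factor2) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     .groups = "drop")
  comparison_result("two-way ANOVA + Sidak",
                    sm["factor1", "F value"], sm["factor1", "Pr(>F)"],
                    dplyr::bind_rows(rows), groups, n_dropped)
}

cg_pearson <- function(data) {
  stopifnot(all(c("x", "y") %in% names(data)))
  ok <- !is.na(data$x) & !is.na(data$y)
  n_dropped <- sum(!ok)
  x <- data$x[ok]; y <- data$y[ok]
  if (length(x) < 3) stop("pearson needs >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson")
  comparison_result("Pearson correlation", ct$estimate, ct$p.value,
                    groups = tibble::tibble(group = "pairs", n = length(x),
                                            mean = NA_real_),
                    n_dropped = n_dropped)
}

#' Correlate diversity with CD4/CD8 composition
#'
#' Pearson correlation of the per-sample normalized Shannon-Wiener index
#' with the percentage of CD4+ and of CD8+ T cells, reported separately,
#' over the samples of one compartment.
#'
#' @param cohort a `tcr_cohort` whose repertoires carry `pct_cd4` /
#'   `pct_cd8` metadata.
#' @param compartment compartment to analyze.
#' @param level diversity level.
#' @return list with `data` (per-sample tibble) and `comparison_result`s
#'   `cd4`, `cd8`.
#' @export
correlate_diversity_composition <- function(cohort,
                                            compartment = "TILs-initial",
                                            level = "nt") {
  md <- cohort_metadata(cohort)
  keep <- md$sample_id[md$compartment == compartment]
  rows <- dplyr::bind_rows(lapply(cohort$repertoires[keep], function(r) {
    tibble::tibble(sample_id = r$sample_id,
                   nsw = normalized_shannon_wiener(r, level)$nsw,
                   pct_cd4 = r$pct_cd4, pct_cd8 = r$pct_cd8)
  }))
  rows <- rows[!is.na(rows$pct_cd4) | !is.na(rows$pct_cd8), ]
  if (nrow(rows) < 3)
    stop("correlation needs >= 3 samples with composition metadata")
  list(data = rows,
       cd4 = compare_groups(data.frame(x = rows$nsw, y = rows$pct_cd4),
                            "pearson"),
       cd8 = compare_groups(data.frame(x = rows$nsw, y = rows$pct_cd8),
                            "pearson"))
}
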