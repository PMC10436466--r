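# End-to-end pipeline: ingest -> productive filter -> decontamination ->
# patient merging -> aa collapse -> features -> diversity / CR / publicity
# -> motif clusters -> candidate sets -> annotation -> group comparisons.
# Synthetic mode is fully deterministic under the master seed.

preset_fun <- function(name) {
  switch(name,
         initial = til_initial_preset,
         cd4 = til_cd4_preset,
         cd8 = til_cd8_preset,
         stop("unknown compartment preset '", name, "'"))
}

#' Built-in demo pipeline configuration
#'
#' A small synthetic cohort (4 patients x 2 slices x 3 compartments) with a
#' planted CD4 motif, an injected public clonotype, and a synthetic
#' specificity database overlapping one planted carrier sequence.
#'
#' @param seed master seed.
#' @param output_dir where the report tables go.
#' @return config list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1L, output_dir = tempfile("tilrep_demo_")) {
  list(
    mode = "synthetic",
    seed = as.integer(seed),
    output_dir = output_dir,
    cohort = list(
      n_patients = 4L, slices_per_patient = 2L,
      n_clonotypes = 400L, reference_size = 800L,
      compartments = list(`TILs-initial` = "initial",
                          `TILs-CD4+` = "cd4",
                          `TILs-CD8+` = "cd8"),
      planted_motifs = list(
        `TILs-CD4+` = list(list(motif = "SLGG%GE", n_carriers = 20L))),
      public_injection = list(
        list(cdr3_aa = "CASSLGGSGEQFF", n_patients = 2L)),
      composition = list(compartment = "TILs-initial",
                         nsw_cd4 = 0.38, nsw_cd8 = 0.51)
    ),
    decontamination_ratio = 20,
    diversity_level = "nt",
    property_scales = c("charge", "hydropathy", "polarity"),
    motifs = list(fisher_max = 0.5, expansion_max = 0.5,
                  min_carriers = 3L, B = 200L,
                  compartments = c("TILs-CD4+", "TILs-CD8+")),
    freq_threshold = 0.001,
    db = list(n_records = list(allergy = 5L, autoimmunity = 5L,
                               cancer = 10L, pathogens = 10L),
              overlap = list(list(cdr3_aa = "CASSLGGSGEQFF",
                                  category = "cancer")))
  )
}

run_stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e) {
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

pool_compartment_aa <- function(merged_reps) {
  pooled <- dplyr::bind_rows(lapply(merged_reps, function(r) r$clonotypes))
  agg <- pooled |>
    dplyr::group_by(.data$cdr3_aa) |>
    dplyr::summarise(count = sum(.data$count),
                     nt_variant_count = dplyr::n_distinct(.data$cdr3_nt),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$cdr3_aa)
  agg$freq <- agg$count / sum(agg$count)
  out <- agg[c("cdr3_aa", "count", "freq", "nt_variant_count")]
  class(out) <- c("aa_repertoire", class(out))
  out
}

build_cohort_spec <- function(cc, seed) {
  comps <- list()
  for (label in names(cc$compartments)) {
    fn <- preset_fun(cc$compartments[[label]])
    pm <- cc$planted_motifs[[label]] %||% list()
    comps[[label]] <- fn(n_clonotypes = cc$n_clonotypes %||% 1000L,
                         planted_motifs = pm)
  }
  composition <- cc$composition
  if (!is.null(composition) && !is.null(composition$pct_cd4))
    composition$pct_cd4 <- as.numeric(composition$pct_cd4)
  cohort_spec(n_patients = cc$n_patients,
              slices_per_patient = cc$slices_per_patient %||% 1L,
              compartments = comps,
              public_injection = cc$public_injection %||% list(),
              reference_size = cc$reference_size %||% 1000L,
              composition = composition,
              seed = seed)
}

read_sample_sheet_cohort <- function(cfg) {
  sheet <- readr::read_csv(cfg$sample_sheet,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  need <- c("sample_id", "patient_id", "compartment", "chain", "path")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns ",
         paste(need, collapse = ", "))
  reps <- lapply(seq_len(nrow(sheet)), function(i) {
    r <- read_clonotype_table(sheet$path[i], dialect = cfg$dialect %||%
                                "vdjtools",
                              sample_id = sheet$sample_id[i],
                              patient_id = sheet$patient_id[i],
                              compartment = sheet$compartment[i],
                              chain = sheet$chain[i])
    if ("pct_cd4" %in% names(sheet))
      r$pct_cd4 <- as.numeric(sheet$pct_cd4[i])
    if ("pct_cd8" %in% names(sheet))
      r$pct_cd8 <- as.numeric(sheet$pct_cd8[i])
    r
  })
  reference <- if (!is.null(cfg$reference_path))
    read_clonotype_table(cfg$reference_path, dialect = cfg$dialect %||%
                           "vdjtools",
                         compartment = "reference")
  new_cohort(reps, reference = reference)
}

#' Run the full repertoire analysis pipeline
#'
#' Executes all stages on a synthetic cohort (`mode: synthetic`) or on
#' clonotype tables listed in a sample sheet (`mode: tables`), writing the
#' report tables and a run manifest under `output_dir`. Synthetic runs are
#' byte-identical for a fixed config.
#'
#' @param config a config list (see [demo_config()]) or the path of a YAML
#'   file containing one.
#' @return invisibly, a list with the output paths (`files`), the manifest,
#'   and the in-memory `cohort`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  outdir <- cfg$output_dir %||% stop("config needs `output_dir`")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "samples"), showWarnings = FALSE)
  files <- character(0)
  emit <- function(tbl, name, csv = FALSE) {
    path <- file.path(outdir, name)
    if (csv) readr::write_csv(tbl, path, progress = FALSE)
    else readr::write_tsv(tbl, path, progress = FALSE)
    files <<- c(files, path)
    path
  }
  manifest_path <- file.path(outdir, "manifest.json")
  write_manifest <- function(status, failed_stage = NULL) {
    cfg_for_hash <- cfg
    cfg_for_hash$output_dir <- NULL
    manifest <- list(status = status,
                     failed_stage = failed_stage,
                     seed = cfg$seed,
                     config_hash = rlang::hash(cfg_for_hash),
                     package_version = as.character(utils::packageVersion("tilrep")),
                     files = basename(files))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }

  result <- tryCatch({
    ## --- ingest ---------------------------------------------------------
    cohort <- run_stage("ingest", {
      mode <- cfg$mode %||% "synthetic"
      if (mode == "synthetic") {
        if (is.null(cfg$seed)) stop("synthetic mode requires a master seed")
        generate_cohort(build_cohort_spec(cfg$cohort, cfg$seed))
      } else {
        read_sample_sheet_cohort(cfg)
      }
    })
    message("ingest: ", length(cohort$repertoires), " samples")

    ## --- filter ---------------------------------------------------------
    cohort <- run_stage("filter", {
      cohort$repertoires <- lapply(cohort$repertoires, filter_productive)
      cohort
    })

    ## --- decontaminate --------------------------------------------------
    cohort <- run_stage("decontaminate",
                        decontaminate(cohort,
                                      cfg$decontamination_ratio %||% 20))
    for (r in cohort$repertoires)
      write_clonotype_table(r, file.path(outdir, "samples",
                                         paste0(r$sample_id, ".txt")),
                            "vdjtools")

    ## --- merge + collapse ----------------------------------------------
    compartments <- unique(cohort_metadata(cohort)$compartment)
    merged <- run_stage("merge", {
      setNames(lapply(compartments, function(cp) merge_by_patient(cohort, cp)),
               compartments)
    })

    ## --- features -------------------------------------------------------
    features <- run_stage("features",
                          feature_table(cohort,
                                        cfg$property_scales %||% "charge"))
    emit(features, "features.tsv")

    ## --- diversity / CR / publicity ------------------------------------
    level <- cfg$diversity_level %||% "nt"
    stats <- run_stage("diversity", stats_table(cohort, level))
    emit(stats, "diversity.tsv")

    publicity <- run_stage("publicity", {
      dplyr::bind_rows(lapply(compartments, function(cp) {
        if (length(merged[[cp]]) < 2) return(NULL)
        pb <- public_sequences(cohort, cp)
        ct <- publicity_convergence_crosstab(cohort, cp)
        tibble::tibble(compartment = cp, n_biopsies = pb$n_biopsies,
                       n_public = pb$n_public,
                       percent_public = pb$percent_public,
                       n_public_convergent = ct$table["public", "convergent"],
                       n_public_nonconvergent =
                         ct$table["public", "non_convergent"],
                       pct_public_among_convergent = ct$pct_public_convergent,
                       pct_public_among_nonconvergent =
                         ct$pct_public_nonconvergent)
      }))
    })
    emit(publicity, "publicity.tsv")

    ## --- motifs ---------------------------------------------------------
    motif_cfg <- cfg$motifs %||% list()
    motif_comps <- motif_cfg$compartments %||%
      intersect(c("TILs-CD4+", "TILs-CD8+"), compartments)
    motif_out <- run_stage("motifs", {
      if (is.null(cohort$reference))
        stop("motif scoring needs a reference repertoire")
      ref_aa <- collapse_by_aa(cohort$reference)
      withr::with_seed((cfg$seed %||% 0L) + 1000003L, {
        out <- list()
        for (cp in motif_comps) {
          by_biopsy <- lapply(merged[[cp]], collapse_by_aa)
          out[[cp]] <- lapply(names(by_biopsy), function(pid) {
            cluster_by_motifs(by_biopsy[[pid]], ref_aa,
                              fisher_max = motif_cfg$fisher_max %||% 0.5,
                              expansion_max = motif_cfg$expansion_max %||% 0.5,
                              min_carriers = motif_cfg$min_carriers %||% 2L,
                              B = motif_cfg$B %||% 1000L,
                              biopsy = pid)
          })
          names(out[[cp]]) <- names(by_biopsy)
        }
        out
      })
    })
    all_clusters <- dplyr::bind_rows(lapply(motif_comps, function(cp) {
      tb <- clusters_table(unlist(motif_out[[cp]], recursive = FALSE))
      if (nrow(tb)) tb$compartment <- cp
      tb
    }))
    emit(all_clusters, "clusters.tsv")
    sharing <- dplyr::bind_rows(lapply(motif_comps, function(cp) {
      sh <- motif_sharing(motif_out[[cp]])$table
      if (nrow(sh)) sh$compartment <- cp
      sh
    }))
    emit(sharing, "motif_sharing.tsv")

    ## --- candidates + annotation ---------------------------------------
    db <- run_stage("annotation", {
      if (!is.null(cfg$db$path)) {
        if (!file.exists(cfg$db$path))
          stop("specificity database not found: ", cfg$db$path)
        read_specificity_db(cfg$db$path)
      } else {
        nr <- unlist(cfg$db$n_records)
        generate_specificity_db(db_spec(n_records = nr,
                                        overlap = cfg$db$overlap %||% list(),
                                        seed = (cfg$seed %||% 0L) + 2000003L))
      }
    })
    annotation_out <- run_stage("annotation", {
      rows_sets <- list(); rows_ann <- list(); rows_cnt <- list()
      for (cp in motif_comps) {
        if (length(merged[[cp]]) < 2) next
        pooled_aa <- pool_compartment_aa(merged[[cp]])
        pb <- public_sequences(cohort, cp)
        clusters <- unlist(motif_out[[cp]], recursive = FALSE)
        cs <- candidate_sets(pooled_aa, pb, clusters,
                             cfg$freq_threshold %||% 0.001)
        rows_sets[[cp]] <- tibble::tibble(
          compartment = cp, universe = cs$universe_size,
          n_high_freq = cs$sizes[["high_freq"]],
          n_public = cs$sizes[["public"]],
          n_clustered = cs$sizes[["clustered"]])
        queries <- unique(c(cs$high_freq, cs$public, cs$clustered))
        matches <- match_database(queries, db, max_dist = 1L)
        ann <- annotate_clusters(clusters, matches)
        if (nrow(ann)) ann$compartment <- cp
        rows_ann[[cp]] <- ann
        cnt <- annotation_counts(ann)
        if (nrow(cnt)) cnt$compartment <- cp
        rows_cnt[[cp]] <- cnt
      }
      list(sets = dplyr::bind_rows(rows_sets),
           annotation = dplyr::bind_rows(rows_ann),
           counts = dplyr::bind_rows(rows_cnt))
    })
    emit(annotation_out$sets, "candidate_sets.tsv")
    emit(annotation_out$annotation, "annotation.csv", csv = TRUE)
    emit(annotation_out$counts, "annotation_counts.csv", csv = TRUE)

    ## --- comparisons ----------------------------------------------------
    comparisons <- run_stage("comparisons", {
      rows <- list()
      add <- function(panel, cr) {
        rows[[length(rows) + 1L]] <<- tibble::tibble(
          panel = panel, method = cr$method,
          statistic = cr$statistic, p = cr$p_value)
      }
      if (length(compartments) >= 2) {
        ndn_df <- data.frame(value = features$ndn_mean,
                             group = features$compartment)
        add("ndn_length", compare_groups(ndn_df, "anova_tukey"))
        if ("charge" %in% names(features)) {
          add("central_charge",
              compare_groups(data.frame(value = features$charge,
                                        group = features$compartment),
                             "anova_tukey"))
        }
      }
      cd4 <- stats[stats$compartment == "TILs-CD4+", ]
      cd8 <- stats[stats$compartment == "TILs-CD8+", ]
      if (nrow(cd4) && nrow(cd4) == nrow(cd8)) {
        key <- function(s) sub("TILs-CD[48]\\+_", "", s$sample_id)
        cd8 <- cd8[match(key(cd4), key(cd8)), ]
        add("diversity_paired",
            compare_groups(data.frame(x = cd4$nsw, y = cd8$nsw), "paired_t"))
      }
      md <- cohort_metadata(cohort)
      n_init_meta <- sum(md$compartment == "TILs-initial" &
                           !is.na(md$pct_cd4))
      if (n_init_meta >= 3) {
        corr <- correlate_diversity_composition(cohort, "TILs-initial",
                                                level)
        add("diversity_vs_pct_cd4", corr$cd4)
        add("diversity_vs_pct_cd8", corr$cd8)
      }
      dplyr::bind_rows(rows)
    })
    emit(comparisons, "comparisons.csv", csv = TRUE)

    write_manifest("OK")
    list(files = c(files, manifest_path),
         manifest = jsonlite::read_json(manifest_path),
         cohort = cohort)
  }, error = function(e) {
    failed <- sub("^\\[stage ([^]]+)\\].*$", "\\1", conditionMessage(e))
    write_manifest("FAILED", failed_stage = failed)
    stop(e)
  })
  invisible(result)
}
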