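#' Run the full heterogeneity and co-evolution analysis
#'
#' Orchestrates every stage over a cohort — repertoire diversity and
#' sharing, infiltration divergence, immunomodulator and biomarker
#' summaries, genomic summaries, co-evolution tests and the
#' group-comparison statistics — and optionally writes tidy TSVs, Newick
#' trees, a machine-readable JSON summary and a run manifest to
#' `outdir`. All randomness (rarefaction, sampled permutations) derives
#' from `seed` through named per-stage sub-streams, so toggling one
#' stage does not perturb another's results, and re-running with the
#' same inputs and seed reproduces the summary byte for byte.
#'
#' @param cohort A cohort bundle: list with `sheet` and any of
#'   `repertoires`, `infiltration`, `expression`, `mutations`,
#'   `segments` (see [simulate_cohort()] / [read_cohort()]), or a
#'   directory path understood by [read_cohort()].
#' @param outdir Output directory, or `NULL` to skip writing.
#' @param stages Character vector choosing stages: any of
#'   `"repertoire"`, `"infiltration"`, `"genomics"`, `"coevolution"`.
#' @param hec_threshold,top_n,rarefy_depth,cyt_pseudocount,n_perm Stage
#'   parameters; `rarefy_depth = NULL` uses the cohort minimum total
#'   reads.
#' @param seed Master seed.
#' @return List of result tables (invisibly when `outdir` is set):
#'   `diversity`, `tcr_pairs`, `tcr_tests`, `blood_overlap`,
#'   `infiltration_pairs`, `infiltration_tests`, `immunomodulators`,
#'   `biomarkers`, `mutation_classes`, `tmb_cis`, `coevolution`,
#'   `summary`.
#' @export
run_all <- function(cohort, outdir = NULL,
                    stages = c("repertoire", "infiltration", "genomics",
                               "coevolution"),
                    hec_threshold = 0.001, top_n = 100, rarefy_depth = NULL,
                    cyt_pseudocount = 0, n_perm = 10000, seed = 1L) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  sheet <- cohort$sheet
  if (is.null(sheet)) stopf("cohort bundle has no sample sheet")
  res <- list()

  if ("repertoire" %in% stages) {
    if (is.null(cohort$repertoires))
      stopf("repertoire stage: no clonotype tables in the cohort bundle")
    tryCatch({
      tables <- cohort$repertoires
      depth <- rarefy_depth %||%
        min(vapply(tables, `[[`, numeric(1), "total_reads"))
      res$diversity <- repertoire_diversity(
        tables, sheet, rarefy_depth = depth, hec_threshold = hec_threshold,
        seed = derive_seed(seed, "rarefy"))
      res$diversity$tissue_class <-
        sheet$tissue_class[match(res$diversity$sample_id, sheet$sample_id)]
      res$tcr_pairs <- tcr_heterogeneity(tables, sheet)
      het <- res$tcr_pairs
      het$value <- het$heterogeneity
      res$tcr_tests <- compare_categories(het, metric = "tcr_heterogeneity")
      blood_ids <- sheet$sample_id[sheet$tissue_class == "blood"]
      rows <- list()
      for (pid in unique(sheet$patient_id)) {
        pb <- intersect(sheet$sample_id[sheet$patient_id == pid], blood_ids)
        pb <- intersect(pb, names(tables))
        if (!length(pb)) next
        tis <- sheet$sample_id[sheet$patient_id == pid &
                                 sheet$tissue_class != "blood"]
        for (sid in intersect(tis, names(tables))) {
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = pid, sample_id = sid,
            tissue_class = sheet$tissue_class[sheet$sample_id == sid],
            top_n_in_blood_pct = top_n_overlap(tables[[sid]], tables[[pb[1]]],
                                               n = top_n),
            stringsAsFactors = FALSE)
        }
      }
      res$blood_overlap <- if (length(rows)) do.call(rbind, rows) else NULL
    }, error = function(e) stopf("repertoire stage failed: %s", conditionMessage(e)))
  }

  if ("infiltration" %in% stages) {
    tryCatch({
      if (!is.null(cohort$infiltration)) {
        res$infiltration_pairs <- infiltration_divergence(cohort$infiltration,
                                                          sheet)
        div <- res$infiltration_pairs
        div$value <- div$divergence
        res$infiltration_tests <- compare_categories(
          div, metric = "infiltration_divergence")
      }
      if (!is.null(cohort$expression)) {
        res$immunomodulators <- immunomodulator_summary(cohort$expression,
                                                        sheet)
        res$biomarkers <- biomarker_panel(cohort$expression, sheet,
                                          cyt_pseudocount = cyt_pseudocount)
      }
    }, error = function(e) stopf("infiltration stage failed: %s",
                                 conditionMessage(e)))
  }

  if ("genomics" %in% stages && !is.null(cohort$mutations)) {
    tryCatch({
      res$mutation_classes <- classify_mutations_cohort(cohort$mutations, sheet)
      tum <- sheet$sample_id[sheet$tissue_class %in% c("primary", "metastasis")]
      rows <- lapply(tum, function(sid) {
        cis <- if (!is.null(cohort$segments) &&
                   sid %in% cohort$segments$sample_id) {
          cis_score(cohort$segments, sid)$cis
        } else NA_real_
        data.frame(sample_id = sid,
                   patient_id = sheet$patient_id[sheet$sample_id == sid],
                   tissue_class = sheet$tissue_class[sheet$sample_id == sid],
                   tmb = tmb(cohort$mutations, sid), cis = cis,
                   stringsAsFactors = FALSE)
      })
      res$tmb_cis <- do.call(rbind, rows)
    }, error = function(e) stopf("genomics stage failed: %s",
                                 conditionMessage(e)))
  }

  if ("coevolution" %in% stages) {
    tryCatch({
      co <- coevolve_patients(tables = cohort$repertoires,
                              mt = cohort$mutations,
                              infl = cohort$infiltration, sheet = sheet,
                              n_perm = n_perm,
                              seed = derive_seed(seed, "coevolution"))
      res$coevolution <- co$tests
      res$coevolution_trees <- co$trees
      res$coevolution_skipped <- co$skipped
    }, error = function(e) stopf("coevolution stage failed: %s",
                                 conditionMessage(e)))
  }

  res$summary <- summarize_run(res, seed)
  if (!is.null(outdir)) {
    write_run(res, outdir, seed)
    return(invisible(res))
  }
  res
}

# Compact machine-readable summary of a run; every number here is
# recomputable from the tidy tables.
#' @noRd
summarize_run <- function(res, seed) {
  s <- list(seed = seed)
  med_by <- function(df, value, group) {
    if (is.null(df)) return(NULL)
    out <- tapply(df[[value]], df[[group]], stats::median)
    as.list(round(out, 6))
  }
  if (!is.null(res$diversity)) {
    s$median_richness_by_class <- med_by(res$diversity, "richness",
                                         "tissue_class")
    s$median_clonality_by_class <- med_by(res$diversity, "clonality",
                                          "tissue_class")
    s$median_entropy_by_class <- med_by(res$diversity, "shannon_entropy",
                                        "tissue_class")
  }
  if (!is.null(res$tcr_pairs))
    s$median_shared_pct_by_category <- med_by(res$tcr_pairs, "shared_pct",
                                              "category")
  if (!is.null(res$blood_overlap))
    s$mean_top_n_blood_overlap_by_class <- as.list(round(
      tapply(res$blood_overlap$top_n_in_blood_pct,
             res$blood_overlap$tissue_class, mean), 6))
  if (!is.null(res$infiltration_pairs))
    s$median_divergence_by_category <- med_by(res$infiltration_pairs,
                                              "divergence", "category")
  if (!is.null(res$mutation_classes)) {
    s$total_mutation_classes <- as.list(colSums(
      res$mutation_classes[, c("trunk", "shared", "private")]))
  }
  if (!is.null(res$tmb_cis)) {
    s$median_tmb <- stats::median(res$tmb_cis$tmb)
    s$median_cis <- round(stats::median(res$tmb_cis$cis, na.rm = TRUE), 6)
  }
  if (!is.null(res$coevolution) && nrow(res$coevolution)) {
    co <- res$coevolution
    pair <- paste(co$modality_a, co$modality_b, sep = "_vs_")
    s$mean_cophenetic_r <- as.list(round(tapply(co$r, pair, mean,
                                                na.rm = TRUE), 6))
    s$n_coevolution_tests <- nrow(co)
  }
  s
}

# Write tidy TSVs, Newick trees, summary JSON and the run manifest.
#' @noRd
write_run <- function(res, outdir, seed) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (is.null(df)) return()
    df <- cbind(df)  # drop attributes
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(res$diversity, "diversity.tsv")
  wt(res$tcr_pairs, "tcr_heterogeneity_pairs.tsv")
  wt(res$tcr_tests, "tcr_heterogeneity_tests.tsv")
  wt(res$blood_overlap, "blood_top_overlap.tsv")
  wt(res$infiltration_pairs, "infiltration_divergence_pairs.tsv")
  wt(res$infiltration_tests, "infiltration_divergence_tests.tsv")
  wt(res$immunomodulators, "immunomodulator_summary.tsv")
  wt(res$biomarkers, "biomarker_panel.tsv")
  wt(res$mutation_classes, "mutation_classes.tsv")
  wt(res$tmb_cis, "tmb_cis.tsv")
  wt(res$coevolution, "coevolution_tests.tsv")
  if (!is.null(res$coevolution_trees)) {
    tree_dir <- file.path(outdir, "trees")
    dir.create(tree_dir, showWarnings = FALSE)
    for (pid in names(res$coevolution_trees))
      for (mod in names(res$coevolution_trees[[pid]]))
        write_newick(res$coevolution_trees[[pid]][[mod]],
                     file.path(tree_dir, sprintf("%s_%s.nwk", pid, mod)))
  }
  jsonlite::write_json(res$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(package = "mrtime",
                   version = as.character(utils::packageVersion("mrtime")),
                   seed = seed,
                   outputs = sort(list.files(outdir, recursive = TRUE)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
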