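#' Euclidean divergence between two infiltration profiles
#'
#' Immune-cell infiltration divergence between a pair of samples is the
#' Euclidean distance between their 22-dimensional fraction vectors.
#' Two samples sharing little infiltrating-cell abundance are far apart
#' and hence more heterogeneous. On the simplex the distance is bounded
#' by `sqrt(2)`.
#'
#' @param f1,f2 Named numeric fraction vectors over the same cell types.
#' @return Non-negative distance.
#' @export
euclidean_divergence <- function(f1, f2) {
  if (!is.null(names(f1)) && !is.null(names(f2))) {
    only1 <- setdiff(names(f1), names(f2))
    only2 <- setdiff(names(f2), names(f1))
    if (length(only1) || length(only2))
      stopf("cell-type sets differ: %s",
            paste(c(only1, only2), collapse = ", "))
    f2 <- f2[names(f1)]
  } else if (length(f1) != length(f2)) {
    stopf("fraction vectors have different lengths (%d vs %d)",
          length(f1), length(f2))
  }
  sqrt(sum((f1 - f2)^2))
}

#' Pairwise infiltration divergence across comparison categories
#'
#' Applies [euclidean_divergence()] to every within-patient sample pair
#' whose members both have infiltration estimates, using the same pair
#' skeletons (and categories) as the TCR heterogeneity analysis.
#'
#' @param infl An [infiltration_matrix()].
#' @param sheet A [sample_sheet()].
#' @return Data frame: `patient_id`, `sample_a`, `sample_b`, `category`,
#'   `divergence`.
#' @export
infiltration_divergence <- function(infl, sheet) {
  pairs <- enumerate_pairs(sheet)
  pairs <- pairs[pairs$sample_a %in% rownames(infl) &
                   pairs$sample_b %in% rownames(infl), , drop = FALSE]
  pairs$divergence <- vapply(seq_len(nrow(pairs)), function(i)
    euclidean_divergence(infl[pairs$sample_a[i], ], infl[pairs$sample_b[i], ]),
    numeric(1))
  rownames(pairs) <- NULL
  pairs
}

#' Cytolytic activity (CYT)
#'
#' Geometric mean of the GZMA and PRF1 expression levels (TPM):
#' `sqrt(GZMA * PRF1)`. No pseudocount is added by default, so a zero in
#' either gene propagates to a zero CYT; set `pseudocount` (e.g. 0.01)
#' to follow the convention of adding a small offset before the mean.
#'
#' @param tpm_gzma,tpm_prf1 Non-negative TPM values (vectorized).
#' @param pseudocount Offset added to both genes before the geometric
#'   mean; default 0 (literal geometric mean).
#' @return Cytolytic activity value(s).
#' @export
cytolytic_activity <- function(tpm_gzma, tpm_prf1, pseudocount = 0) {
  if (any(tpm_gzma < 0) || any(tpm_prf1 < 0))
    stopf("TPM values must be non-negative")
  sqrt((tpm_gzma + pseudocount) * (tpm_prf1 + pseudocount))
}

#' Bundled immunomodulator gene panel
#'
#' The 70-gene immunomodulator panel with its seven super-categories
#' (receptor, ligand, co-stimulator, co-inhibitor, cell adhesion,
#' antigen presentation, other), shipped as editable package data.
#' Category labels are annotation only; no computation depends on them.
#'
#' @return Data frame with columns `gene` and `category`.
#' @export
immunomodulator_genes <- function() {
  path <- system.file("extdata", "immunomodulators.tsv", package = "mrtime")
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}

#' Immunomodulator expression summary by tissue group
#'
#' For each panel gene, the median TPM is computed per tissue group
#' (normal, primary, metastasis) and z-score normalized across the three
#' group medians (sample standard deviation, n-1 denominator; a
#' zero-variance gene gets all-zero z-scores). Genes absent from the
#' matrix are reported as missing, not imputed to zero. Blood samples are
#' excluded.
#'
#' @param expr An [expression_matrix()].
#' @param sheet A [sample_sheet()].
#' @param genes Character vector of panel genes; defaults to the bundled
#'   [immunomodulator_genes()] panel.
#' @return Data frame: `gene`, `missing`, `median_normal`,
#'   `median_primary`, `median_metastasis`, `z_normal`, `z_primary`,
#'   `z_metastasis`.
#' @export
immunomodulator_summary <- function(expr, sheet,
                                    genes = immunomodulator_genes()$gene) {
  groups <- c("normal", "primary", "metastasis")
  samples_by_group <- lapply(groups, function(g) {
    ids <- sheet$sample_id[sheet$tissue_class == g]
    intersect(ids, colnames(expr))
  })
  names(samples_by_group) <- groups
  empty <- groups[lengths(samples_by_group) == 0]
  if (length(empty))
    stopf("no expression samples for tissue group(s): %s (groups found: %s)",
          paste(empty, collapse = ", "),
          paste(groups[lengths(samples_by_group) > 0], collapse = ", "))
  rows <- lapply(genes, function(g) {
    if (!(g %in% rownames(expr))) {
      return(data.frame(gene = g, missing = TRUE,
                        median_normal = NA_real_, median_primary = NA_real_,
                        median_metastasis = NA_real_, z_normal = NA_real_,
                        z_primary = NA_real_, z_metastasis = NA_real_,
                        stringsAsFactors = FALSE))
    }
    med <- vapply(samples_by_group, function(ids)
      stats::median(expr[g, ids]), numeric(1))
    z <- zscore(med)
    data.frame(gene = g, missing = FALSE,
               median_normal = med[["normal"]],
               median_primary = med[["primary"]],
               median_metastasis = med[["metastasis"]],
               z_normal = z[[1]], z_primary = z[[2]], z_metastasis = z[[3]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default immunotherapy biomarker genes
#'
#' CYT (computed from GZMA/PRF1) plus PD-L1 (CD274), PD-L2 (PDCD1LG2),
#' PD-1 (PDCD1), CD39 (ENTPD1), CD8A, CD8B and CD4.
#'
#' @return Named character vector (display name -> gene symbol).
#' @export
biomarker_genes <- function() c(
  "PD-L1" = "CD274", "PD-L2" = "PDCD1LG2", "PD-1" = "PDCD1",
  "CD39" = "ENTPD1", "CD8A" = "CD8A", "CD8B" = "CD8B", "CD4" = "CD4")

#' Per-patient z-scored immunotherapy biomarker panel
#'
#' For each patient, cytolytic activity and the biomarker gene TPMs are
#' z-score normalized across that patient's samples (sample sd, n-1;
#' constant markers map to all-zero rows). Patients are normalized
#' independently. Blood samples are excluded (no tumour expression is
#' expected there); a patient with a single expression sample yields
#' `NA` z-scores flagged in `undefined`.
#'
#' @param expr An [expression_matrix()].
#' @param sheet A [sample_sheet()].
#' @param genes Named character vector of biomarker genes
#'   (default [biomarker_genes()]).
#' @param cyt_pseudocount Pseudocount for [cytolytic_activity()].
#' @return Long data frame: `patient_id`, `sample_id`, `marker`, `tpm`,
#'   `z`, `undefined`.
#' @export
biomarker_panel <- function(expr, sheet, genes = biomarker_genes(),
                            cyt_pseudocount = 0) {
  for (g in c("GZMA", "PRF1", unname(genes)))
    if (!(g %in% rownames(expr)))
      stopf("biomarker gene %s absent from expression matrix", g)
  keep <- sheet[sheet$tissue_class != "blood" &
                  sheet$sample_id %in% colnames(expr), , drop = FALSE]
  out <- list()
  for (pat in split(as.data.frame(keep), keep$patient_id)) {
    ids <- pat$sample_id
    vals <- rbind(CYT = cytolytic_activity(expr["GZMA", ids], expr["PRF1", ids],
                                           pseudocount = cyt_pseudocount),
                  expr[unname(genes), ids, drop = FALSE])
    rownames(vals) <- c("CYT", names(genes))
    single <- length(ids) < 2
    z <- if (single) {
      matrix(NA_real_, nrow(vals), ncol(vals), dimnames = dimnames(vals))
    } else {
      t(apply(vals, 1, zscore))
    }
    out[[length(out) + 1L]] <- data.frame(
      patient_id = pat$patient_id[1],
      sample_id = rep(ids, each = nrow(vals)),
      marker = rep(rownames(vals), length(ids)),
      tpm = as.numeric(vals), z = as.numeric(z),
      undefined = single, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
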