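#' The 22 immune cell types of the infiltration matrix
#'
#' Column order used by the bundled generator and expected (as a set) by
#' [infiltration_matrix()]. These are the cell types of CIBERSORT-style
#' deconvolution output; the deconvolution itself is upstream of this
#' package, which consumes the fractions.
#'
#' @return Character vector of 22 cell-type names.
#' @export
immune_cell_types <- function() c(
  "B cells naive", "B cells memory", "Plasma cells",
  "T cells naive", "T cells CD4 naive", "T cells CD4 memory resting",
  "T cells CD4 memory activated", "T cells CD8",
  "T cells follicular helper", "T cells regulatory",
  "T cells gamma delta",
  "Macrophages M0", "Macrophages M1", "Macrophages M2",
  "Mast cells resting", "Mast cells activated",
  "NK cells resting", "NK cells activated",
  "Eosinophils", "Neutrophils",
  "Dendritic cells resting", "Dendritic cells activated")

# Columns CIBERSORT appends after the fractions; silently ignored on read.
cibersort_extra_cols <- c("P-value", "Correlation", "RMSE",
                          "P.value", "Absolute score")

#' Construct and validate an immune-cell infiltration matrix
#'
#' Samples in rows, 22 immune cell types in columns, fractions on the
#' simplex: non-negative values whose rows sum to 1 within `1e-6`.
#' Rows off by at most `1e-3` can be renormalized (`renormalize = TRUE`);
#' larger deviations always error since deconvolution output sums to 1 by
#' construction and a bigger gap signals corrupt input.
#'
#' @param mat Numeric matrix with sample row names and cell-type columns.
#' @param renormalize Renormalize rows whose sums deviate by at most 1e-3.
#' @return An `infiltration_matrix` (numeric matrix subclass).
#' @export
infiltration_matrix <- function(mat, renormalize = FALSE) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 22)
    stopf("infiltration matrix must have exactly 22 cell-type columns, got %d",
          ncol(mat))
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stopf("infiltration matrix needs unique sample row names")
  if (any(mat < 0))
    stopf("infiltration fractions must be non-negative")
  rs <- rowSums(mat)
  dev <- abs(rs - 1)
  if (any(dev > 1e-6)) {
    worst <- which.max(dev)
    if (all(dev <= 1e-3) && renormalize) {
      mat <- mat / rs
    } else if (all(dev <= 1e-3)) {
      stopf(paste0("infiltration row sums deviate from 1 (max |dev| %.2e in ",
                   "sample %s); pass renormalize = TRUE to rescale"),
            dev[worst], rownames(mat)[worst])
    } else {
      stopf("infiltration row sum off by %.2e in sample %s: input looks corrupt",
            dev[worst], rownames(mat)[worst])
    }
  }
  class(mat) <- c("infiltration_matrix", class(mat))
  mat
}

#' Read an infiltration matrix from TSV
#'
#' First column holds sample ids; trailing CIBERSORT diagnostic columns
#' (P-value, Correlation, RMSE) are dropped if present.
#'
#' @inheritParams infiltration_matrix
#' @param path Path to TSV (optionally .gz).
#' @return An [infiltration_matrix()].
#' @export
read_infiltration_tsv <- function(path, renormalize = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  df <- df[, !(names(df) %in% cibersort_extra_cols), drop = FALSE]
  mat <- as.matrix(df)
  rownames(mat) <- ids
  infiltration_matrix(mat, renormalize = renormalize)
}

#' Construct and validate an expression matrix
#'
#' Genes in rows (unique symbols), samples in columns, TPM values >= 0.
#'
#' @param mat Numeric matrix with gene row names and sample columns.
#' @return An `expression_matrix` (numeric matrix subclass).
#' @export
expression_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stopf("expression matrix needs unique gene row names")
  if (any(mat < 0)) stopf("TPM values must be non-negative")
  class(mat) <- c("expression_matrix", class(mat))
  mat
}

#' Read a gene-expression TPM matrix from TSV
#' @param path Path to TSV (first column gene symbols; optionally .gz).
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- genes
  expression_matrix(mat)
}

#' Write a matrix (infiltration or expression) as TSV
#' @param mat Matrix with row names.
#' @param path Output path.
#' @param index_name Header for the row-name column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, index_name = "id") {
  df <- data.frame(rownames(mat), as.data.frame(unclass(mat),
                                                check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- index_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- mutation table (MAF) ----------------------------------------------

maf_required_cols <- c("Hugo_Symbol", "Chromosome", "Start_Position",
                       "Reference_Allele", "Tumor_Seq_Allele2",
                       "Variant_Classification", "Tumor_Sample_Barcode")

#' Construct a mutation table
#'
#' One row per distinct variant per patient; the samples carrying the
#' variant are held as a list column. Variant identity is the
#' chrom/pos/ref/alt/gene/classification tuple.
#'
#' @param df Data frame with columns `patient_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `variant_classification`, list column `samples`
#'   (character vectors of carrying sample ids) and optional logical
#'   `is_neoantigen`.
#' @param sheet Optional [sample_sheet()]; when given, carrying samples are
#'   checked to exist and blood samples are rejected as carriers.
#' @return A `mutation_table` (data frame subclass).
#' @export
mutation_table <- function(df, sheet = NULL) {
  req <- c("patient_id", "chrom", "pos", "ref", "alt", "gene",
           "variant_classification", "samples")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stopf("mutation table missing column(s): %s", paste(missing, collapse = ", "))
  if (!is.list(df$samples)) df$samples <- as.list(df$samples)
  empty <- lengths(df$samples) == 0
  if (any(empty)) stopf("%d variant(s) have an empty carrying-sample set",
                        sum(empty))
  if (is.null(df$is_neoantigen)) df$is_neoantigen <- NA
  if (!is.null(sheet)) {
    carriers <- unique(unlist(df$samples))
    unknown <- setdiff(carriers, sheet$sample_id)
    if (length(unknown))
      stopf("carrying sample(s) absent from sample sheet: %s",
            paste(unknown, collapse = ", "))
    blood <- sheet$sample_id[sheet$tissue_class == "blood"]
    if (length(intersect(carriers, blood)))
      stopf("blood samples cannot carry somatic variants: %s",
            paste(intersect(carriers, blood), collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("mutation_table", "data.frame")
  df
}

#' Canonical variant keys of a mutation table
#' @param mt A [mutation_table()].
#' @return Character vector of "chrom:pos:ref:alt:gene:class" keys.
#' @export
variant_keys <- function(mt) {
  paste(mt$chrom, mt$pos, mt$ref, mt$alt, mt$gene,
        mt$variant_classification, sep = ":")
}

#' Read a MAF-like TSV into a mutation table
#'
#' Requires the essential MAF columns (Hugo_Symbol, Chromosome,
#' Start_Position, Reference_Allele, Tumor_Seq_Allele2,
#' Variant_Classification, Tumor_Sample_Barcode); rows with the same
#' variant key in different samples collapse into one record whose
#' carrying-sample set is their union. An optional `is_neoantigen`
#' column (TRUE/FALSE) is carried through (it must agree across rows of
#' one variant).
#'
#' @param path Path to the MAF (optionally .gz).
#' @param sheet A [sample_sheet()] mapping barcodes to patients.
#' @return A [mutation_table()].
#' @export
read_maf <- function(path, sheet) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  missing <- setdiff(maf_required_cols, names(df))
  if (length(missing))
    stopf("MAF %s missing column(s): %s", path, paste(missing, collapse = ", "))
  unknown <- setdiff(unique(df$Tumor_Sample_Barcode), sheet$sample_id)
  if (length(unknown))
    stopf("MAF sample barcode(s) not in sample sheet: %s",
          paste(unknown, collapse = ", "))
  pat <- sheet$patient_id[match(df$Tumor_Sample_Barcode, sheet$sample_id)]
  neo <- if ("is_neoantigen" %in% names(df)) as.logical(df$is_neoantigen) else NA
  key <- paste(pat, df$Chromosome, df$Start_Position, df$Reference_Allele,
               df$Tumor_Seq_Allele2, df$Hugo_Symbol,
               df$Variant_Classification, sep = "\r")
  first <- !duplicated(key)
  samples <- split(df$Tumor_Sample_Barcode, factor(key, levels = key[first]))
  out <- data.frame(patient_id = pat[first],
                    chrom = as.character(df$Chromosome[first]),
                    pos = as.integer(df$Start_Position[first]),
                    ref = df$Reference_Allele[first],
                    alt = df$Tumor_Seq_Allele2[first],
                    gene = df$Hugo_Symbol[first],
                    variant_classification = df$Variant_Classification[first],
                    stringsAsFactors = FALSE)
  out$samples <- unname(lapply(samples, unique))
  if (!all(is.na(neo))) {
    agg <- tapply(neo, factor(key, levels = key[first]), function(v) {
      u <- unique(v[!is.na(v)])
      if (length(u) > 1)
        stopf("conflicting is_neoantigen flags for one variant")
      if (length(u)) u else NA
    })
    out$is_neoantigen <- as.logical(agg)
  }
  mutation_table(out, sheet = sheet)
}

#' Write a mutation table as a MAF-like TSV
#'
#' Expands each variant record to one row per carrying sample, the inverse
#' of [read_maf()].
#'
#' @param mt A [mutation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(mt, path) {
  n <- lengths(mt$samples)
  idx <- rep(seq_len(nrow(mt)), n)
  out <- data.frame(Hugo_Symbol = mt$gene[idx],
                    Chromosome = mt$chrom[idx],
                    Start_Position = mt$pos[idx],
                    Reference_Allele = mt$ref[idx],
                    Tumor_Seq_Allele2 = mt$alt[idx],
                    Variant_Classification = mt$variant_classification[idx],
                    Tumor_Sample_Barcode = unlist(mt$samples),
                    stringsAsFactors = FALSE)
  if (!all(is.na(mt$is_neoantigen)))
    out$is_neoantigen <- mt$is_neoantigen[idx]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- segment table (SEG) -----------------------------------------------

#' Construct a copy-number segment table
#'
#' Coordinates are 0-based half-open internally; [read_seg()] converts from
#' the 1-based inclusive convention of SEG files. Segments of one sample
#' must not overlap on a chromosome.
#'
#' @param df Data frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `adjusted_cn` (purity-adjusted segment copy number, >= 0).
#' @return A `segment_table` (data frame subclass).
#' @export
segment_table <- function(df) {
  req <- c("sample_id", "chrom", "start", "end", "adjusted_cn")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stopf("segment table missing column(s): %s", paste(missing, collapse = ", "))
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  if (any(df$end <= df$start)) stopf("segment with end <= start")
  if (any(df$adjusted_cn < 0)) stopf("negative adjusted copy number")
  for (grp in split(df, paste(df$sample_id, df$chrom, sep = "\r"))) {
    o <- order(grp$start)
    if (nrow(grp) > 1 && any(grp$start[o][-1] < grp$end[o][-nrow(grp)]))
      stopf("overlapping segments for sample %s on chromosome %s",
            grp$sample_id[1], grp$chrom[1])
  }
  rownames(df) <- NULL
  class(df) <- c("segment_table", "data.frame")
  df
}

#' Read a SEG file
#'
#' Standard SEG columns (sample, chrom, start, end, value); 1-based
#' inclusive coordinates are converted to the internal 0-based half-open
#' convention. Gzip accepted.
#'
#' @param path Path to the SEG file.
#' @return A [segment_table()].
#' @export
read_seg <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  if (ncol(df) < 5)
    stopf("SEG file %s needs at least 5 columns (sample, chrom, start, end, value)",
          path)
  out <- data.frame(sample_id = as.character(df[[1]]),
                    chrom = as.character(df[[2]]),
                    start = as.numeric(df[[3]]) - 1,
                    end = as.numeric(df[[4]]),
                    adjusted_cn = as.numeric(df[[5]]),
                    stringsAsFactors = FALSE)
  segment_table(out)
}

#' Write a segment table as SEG (1-based inclusive)
#' @param st A [segment_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(st, path) {
  out <- data.frame(sample = st$sample_id, chrom = st$chrom,
                    start = st$start + 1, end = st$end,
                    adjusted_cn = st$adjusted_cn)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- Newick ------------------------------------------------------------

#' Write a dendrogram as Newick
#'
#' Branch lengths are merge-height differences (halved heights on each
#' side of a merge), so path lengths between leaves in the written tree
#' equal the cophenetic distances of the dendrogram and round-trip through
#' [ape::read.tree()].
#'
#' @param hc An `hclust` object (see [complete_linkage()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
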