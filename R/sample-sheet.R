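#' Tissue classes recognised by the pipeline
#'
#' Every sample belongs to one of four classes: spatially separated normal
#' tissue, multi-region primary tumour, metastatic tissue, or blood (the
#' circulating repertoire baseline). All within-patient comparison
#' categories are derived from these classes.
#'
#' @return Character vector of the four class names.
#' @export
tissue_classes <- function() c("normal", "primary", "metastasis", "blood")

#' Construct and validate a sample sheet
#'
#' The sample sheet maps each sample to its patient, tissue class and
#' anatomical site, and optionally carries the relative T-cell fraction
#' used to normalize TCR richness. It drives all within-patient pairwise
#' comparisons.
#'
#' @param df Data frame with columns `sample_id`, `patient_id`,
#'   `tissue_class`, `site_label` and optionally `t_cell_fraction`.
#' @return A `sample_sheet` object (a validated data frame).
#' @export
sample_sheet <- function(df) {
  req <- c("sample_id", "patient_id", "tissue_class", "site_label")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stopf("sample sheet is missing column(s): %s", paste(missing, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$patient_id <- as.character(df$patient_id)
  df$site_label <- as.character(df$site_label)
  df$tissue_class <- tolower(as.character(df$tissue_class))
  bad <- setdiff(unique(df$tissue_class), tissue_classes())
  if (length(bad))
    stopf("unknown tissue_class value(s) %s; allowed values are: %s",
          paste(sQuote(bad), collapse = ", "),
          paste(tissue_classes(), collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stopf("duplicate sample_id(s): %s", paste(unique(dup), collapse = ", "))
  if (is.null(df$t_cell_fraction)) {
    df$t_cell_fraction <- NA_real_
  } else {
    df$t_cell_fraction <- as.numeric(df$t_cell_fraction)
    out_of_range <- !is.na(df$t_cell_fraction) &
      (df$t_cell_fraction < 0 | df$t_cell_fraction > 1)
    if (any(out_of_range))
      stopf("t_cell_fraction outside [0, 1] for sample(s): %s",
            paste(df$sample_id[out_of_range], collapse = ", "))
  }
  df <- df[, c(req, "t_cell_fraction")]
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a sample sheet from a delimited file
#'
#' Accepts tab- or comma-separated files (gzip allowed); `tissue_class`
#' is matched case-insensitively against [tissue_classes()].
#'
#' @param path File path.
#' @return A [sample_sheet()] object.
#' @export
read_sample_sheet <- function(path) {
  df <- read_delim_auto(path)
  sample_sheet(df)
}

#' Write a sample sheet as TSV
#' @param sheet A [sample_sheet()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Read a delimited text file, sniffing tab vs comma from the header line.
#' @noRd
read_delim_auto <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' @export
print.sample_sheet <- function(x, ...) {
  cat(sprintf("Sample sheet: %d samples, %d patients\n",
              nrow(x), length(unique(x$patient_id))))
  tab <- table(x$tissue_class)
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}
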