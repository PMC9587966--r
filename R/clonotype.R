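#' Construct a clonotype table
#'
#' One sample's TCR repertoire: clonotypes keyed by the exact triple
#' (CDR3 amino-acid junction, V call, J call) with the number of reads
#' supporting each. Rows sharing a key are merged by summing counts.
#'
#' Clonotype identity uses the amino-acid junction plus V and J gene calls;
#' D calls are not part of the key because D-segment assignment is
#' unreliable in short-amplicon repertoire data. A nucleotide junction
#' column can be used instead via the `junction_col` argument of
#' [read_airr_tsv()].
#'
#' @param sample_id Sample identifier.
#' @param junction_aa,v_call,j_call Character vectors defining the keys.
#' @param count Positive integer read counts, one per row.
#' @return A `clonotype_table` object: list with `sample_id`, a data frame
#'   `clonotypes` (junction_aa, v_call, j_call, count) and `total_reads`.
#' @export
clonotype_table <- function(sample_id, junction_aa = character(),
                            v_call = character(), j_call = character(),
                            count = integer()) {
  n <- length(junction_aa)
  if (length(v_call) != n || length(j_call) != n || length(count) != n)
    stopf("clonotype_table: field lengths differ")
  count <- as.numeric(count)
  if (any(!is.finite(count)) || any(count < 1) || any(count != round(count)))
    stopf("clonotype_table: counts must be positive integers")
  df <- data.frame(junction_aa = as.character(junction_aa),
                   v_call = as.character(v_call),
                   j_call = as.character(j_call),
                   count = count, stringsAsFactors = FALSE)
  if (nrow(df)) {
    key <- paste(df$junction_aa, df$v_call, df$j_call, sep = "\r")
    if (anyDuplicated(key)) {
      agg <- rowsum(df$count, key, reorder = FALSE)
      first <- !duplicated(key)
      df <- df[first, , drop = FALSE]
      df$count <- agg[match(key[first], rownames(agg)), 1]
    }
    df <- df[order(-df$count, df$junction_aa, df$v_call, df$j_call), ,
             drop = FALSE]
    rownames(df) <- NULL
  }
  structure(list(sample_id = as.character(sample_id),
                 clonotypes = df,
                 total_reads = sum(df$count)),
            class = "clonotype_table")
}

#' Clonotype keys of a table
#'
#' @param x A [clonotype_table()].
#' @return Character vector of canonical "junction|v|j" keys.
#' @export
clonotype_keys <- function(x) {
  stopifnot(inherits(x, "clonotype_table"))
  paste(x$clonotypes$junction_aa, x$clonotypes$v_call, x$clonotypes$j_call,
        sep = "|")
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat(sprintf("Clonotype table for sample %s: %d clonotypes, %d reads\n",
              x$sample_id, nrow(x$clonotypes), x$total_reads))
  invisible(x)
}

#' Read an AIRR rearrangement TSV into a clonotype table
#'
#' Expects the AIRR rearrangement schema column names `junction_aa`,
#' `v_call`, `j_call` and `duplicate_count` (additional columns are
#' ignored; gzip-compressed files are accepted). Rows with an empty or
#' missing junction are dropped and counted in the `dropped` attribute;
#' rows with identical keys are merged by summing counts.
#'
#' @param path Path to the TSV (optionally .gz).
#' @param sample_id Sample identifier to attach.
#' @param junction_col Column holding the junction; default `"junction_aa"`
#'   (set to `"junction"` to key clonotypes on the nucleotide junction).
#' @return A [clonotype_table()] with attribute `dropped` (number of rows
#'   discarded for missing junctions).
#' @export
read_airr_tsv <- function(path, sample_id, junction_col = "junction_aa") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", comment.char = "")
  req <- c(junction_col, "v_call", "j_call", "duplicate_count")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stopf("AIRR file %s is missing mandatory column(s): %s",
          path, paste(missing, collapse = ", "))
  cnt <- suppressWarnings(as.numeric(df$duplicate_count))
  bad <- which(!is.finite(cnt) | cnt != round(cnt) | cnt < 1)
  if (length(bad))
    stopf("AIRR file %s: non-integer duplicate_count at data row %d (value %s)",
          path, bad[1], sQuote(df$duplicate_count[bad[1]]))
  keep <- !is.na(df[[junction_col]]) & nzchar(df[[junction_col]])
  dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  ct <- clonotype_table(sample_id,
                        junction_aa = df[[junction_col]],
                        v_call = df$v_call, j_call = df$j_call,
                        count = cnt[keep])
  attr(ct, "dropped") <- dropped
  ct
}

#' Write a clonotype table as an AIRR rearrangement TSV
#'
#' Emits the four schema columns consumed by [read_airr_tsv()], so a
#' written table re-reads identically.
#'
#' @param x A [clonotype_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_airr_tsv <- function(x, path) {
  stopifnot(inherits(x, "clonotype_table"))
  out <- x$clonotypes
  names(out)[names(out) == "count"] <- "duplicate_count"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
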