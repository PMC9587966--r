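#' Non-synonymous variant classifications counted by TMB
#'
#' @return Character vector of MAF `Variant_Classification` values
#'   treated as non-synonymous alterations.
#' @export
nonsynonymous_classes <- function() c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Splice_Site", "Frame_Shift_Del", "Frame_Shift_Ins",
  "In_Frame_Del", "In_Frame_Ins", "Translation_Start_Site")

# Classifications known to be synonymous or non-coding; anything outside
# the union of the two sets is "unknown" and only counted with strict = FALSE.
known_silent_classes <- c(
  "Silent", "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "IGR",
  "RNA", "Splice_Region", "lincRNA", "Targeted_Region")

#' Classify a patient's variants as trunk, shared or private
#'
#' Over the patient's tumour samples (primary and metastatic; normal and
#' blood samples are excluded from the universe), a variant is trunk when
#' present in all tumour samples, private when present in exactly one,
#' and shared when present in at least two but not all. The three classes
#' are disjoint and exhaustive, so their counts sum to the number of
#' distinct variants.
#'
#' @param mt A [mutation_table()] (one patient's rows are selected via
#'   `patient_id` if the table holds several patients).
#' @param tumour_samples Character vector of the patient's tumour sample
#'   ids (>= 2 for a non-trivial classification).
#' @param patient_id Optional patient filter.
#' @return List with `counts` (`trunk`, `shared`, `private`) and
#'   `per_variant` (data frame with `variant_key`, `n_samples`, `class`).
#' @export
classify_mutations <- function(mt, tumour_samples, patient_id = NULL) {
  if (!is.null(patient_id)) mt <- mt[mt$patient_id == patient_id, , drop = FALSE]
  stray <- setdiff(unique(unlist(mt$samples)), tumour_samples)
  if (length(stray))
    stopf("variant carried by sample(s) outside the patient's tumour set: %s",
          paste(stray, collapse = ", "))
  n_total <- length(tumour_samples)
  n_carry <- vapply(mt$samples, function(s)
    length(intersect(s, tumour_samples)), integer(1))
  cls <- ifelse(n_carry == n_total & n_total > 1, "trunk",
                ifelse(n_carry == 1, "private",
                       ifelse(n_carry == n_total, "trunk", "shared")))
  per_variant <- data.frame(variant_key = variant_keys(mt),
                            n_samples = n_carry, class = cls,
                            stringsAsFactors = FALSE)
  list(counts = c(trunk = sum(cls == "trunk"),
                  shared = sum(cls == "shared"),
                  private = sum(cls == "private")),
       per_variant = per_variant)
}

#' Trunk/shared/private counts for every patient in a cohort
#'
#' @param mt A [mutation_table()].
#' @param sheet A [sample_sheet()]; tumour samples are those of class
#'   primary or metastasis.
#' @return Data frame: `patient_id`, `trunk`, `shared`, `private`,
#'   `n_variants`.
#' @export
classify_mutations_cohort <- function(mt, sheet) {
  rows <- lapply(unique(mt$patient_id), function(pid) {
    tum <- sheet$sample_id[sheet$patient_id == pid &
                             sheet$tissue_class %in% c("primary", "metastasis")]
    counts <- classify_mutations(mt, tum, patient_id = pid)$counts
    data.frame(patient_id = pid, trunk = counts[["trunk"]],
               shared = counts[["shared"]], private = counts[["private"]],
               n_variants = sum(counts), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tumour mutational burden of a sample
#'
#' Count of distinct variants present in the sample whose classification
#' is non-synonymous ([nonsynonymous_classes()]). With `strict = TRUE`
#' (default) a classification outside the known synonymous and
#' non-synonymous sets raises an error; with `strict = FALSE` unknown
#' classifications are counted as non-synonymous.
#'
#' @param mt A [mutation_table()].
#' @param sample_id Sample to count.
#' @param strict Error on unknown classification strings (default TRUE).
#' @return Integer count.
#' @export
tmb <- function(mt, sample_id, strict = TRUE) {
  present <- vapply(mt$samples, function(s) sample_id %in% s, logical(1))
  cls <- mt$variant_classification[present]
  unknown <- setdiff(unique(cls),
                     c(nonsynonymous_classes(), known_silent_classes))
  if (length(unknown)) {
    if (strict)
      stopf("unknown variant classification(s): %s (use strict = FALSE to count them)",
            paste(unknown, collapse = ", "))
    return(sum(cls %in% c(nonsynonymous_classes(), unknown)))
  }
  sum(cls %in% nonsynonymous_classes())
}

#' Chromosome instability score (CIS) of a sample
#'
#' Proportion of the genome with aberrant segmented copy number, a
#' segment being aberrant when its purity-adjusted copy number is `>= 3`
#' or `<= 1` (inclusive bounds). The denominator is the total length
#' covered by the sample's segments (exome segment coverage varies
#' between samples); pass `genome_size` to use a fixed denominator
#' instead.
#'
#' @param st A [segment_table()].
#' @param sample_id Sample to score.
#' @param genome_size Optional fixed denominator in bases.
#' @return List with `sample_id`, `aberrant_length`, `total_length`,
#'   `cis`.
#' @export
cis_score <- function(st, sample_id, genome_size = NULL) {
  seg <- st[st$sample_id == sample_id, , drop = FALSE]
  if (nrow(seg) == 0)
    stopf("CIS undefined: no segments for sample %s", sample_id)
  len <- seg$end - seg$start
  aberrant <- seg$adjusted_cn >= 3 | seg$adjusted_cn <= 1
  total <- genome_size %||% sum(len)
  list(sample_id = sample_id,
       aberrant_length = sum(len[aberrant]),
       total_length = total,
       cis = sum(len[aberrant]) / total)
}

#' Per-sample neoantigen sets
#'
#' Presence/absence sets of predicted-neoantigen variant keys per tumour
#' sample (a flagged variant enters a sample's set only when the sample
#' carries it). These sets feed the co-evolution module's Jaccard
#' distances.
#'
#' @param mt A [mutation_table()] with `is_neoantigen` populated.
#' @param samples Optional character vector restricting/ordering the
#'   samples (defaults to all carrying samples).
#' @return Named list of character vectors of variant keys.
#' @export
neoantigen_sets <- function(mt, samples = NULL) {
  if (all(is.na(mt$is_neoantigen)))
    stopf("is_neoantigen flags are missing from the mutation table")
  samples <- samples %||% sort(unique(unlist(mt$samples)))
  keys <- variant_keys(mt)
  flagged <- which(!is.na(mt$is_neoantigen) & mt$is_neoantigen)
  out <- lapply(samples, function(sid) {
    idx <- flagged[vapply(mt$samples[flagged], function(s) sid %in% s,
                          logical(1))]
    keys[idx]
  })
  names(out) <- samples
  out
}
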