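#' Shannon entropy of clone abundances
#'
#' `H = -sum(p_i * log(p_i))` in nats, with `p_i` the read fraction of
#' clonotype `i`. Accounts for both richness and evenness of the
#' repertoire.
#'
#' @param counts Positive integer read counts, one per clonotype.
#' @param base Logarithm base; natural log (nats) by default, `2` for bits
#'   in reports.
#' @return Entropy (non-negative scalar).
#' @export
shannon_entropy <- function(counts, base = exp(1)) {
  check_counts(counts)
  p <- counts / sum(counts)
  -sum(p * log(p, base = base))
}

#' Pielou evenness
#'
#' `J = H / ln(S)`; 1 means perfectly even clone sizes. A monoclonal
#' repertoire (S = 1) is assigned `J = 0`, the limit of a two-clone
#' repertoire as the minor clone vanishes, so that clonality is 1 there.
#'
#' @inheritParams shannon_entropy
#' @return Evenness in `[0, 1]`.
#' @export
pielou_evenness <- function(counts) {
  check_counts(counts)
  s <- length(counts)
  if (s == 1) return(0)
  shannon_entropy(counts) / log(s)
}

#' TCR clonality
#'
#' Clonality is one minus Pielou evenness. High clonality (low evenness)
#' implies skewing of clonotype abundances towards few expanded clones;
#' low clonality implies near-uniform clone sizes.
#'
#' @inheritParams shannon_entropy
#' @return Clonality in `[0, 1]` (1 for a monoclonal repertoire).
#' @export
clonality <- function(counts) 1 - pielou_evenness(counts)

#' @noRd
check_counts <- function(counts) {
  if (length(counts) == 0)
    stopf("diversity metric undefined for an empty repertoire")
  if (any(!is.finite(counts)) || any(counts < 1))
    stopf("clone counts must be positive")
  invisible(counts)
}

#' Highly expanded clone (HEC) metrics
#'
#' A clonotype is highly expanded when its read fraction strictly exceeds
#' `threshold` (default 0.1% of the sample's total repertoire). Returns
#' the HEC count together with two normalizations of it: the proportion
#' of clonotypes that are HEC, and the proportion of reads carried by
#' HECs. The clone-count proportion is the headline "proportion of HEC".
#'
#' @param x A [clonotype_table()] (or bare count vector).
#' @param threshold Strict read-fraction cutoff; default `0.001`.
#' @return List with `hec_count`, `hec_clone_proportion`,
#'   `hec_mass_proportion`.
#' @export
hec_metrics <- function(x, threshold = 0.001) {
  counts <- if (inherits(x, "clonotype_table")) x$clonotypes$count else x
  check_counts(counts)
  total <- sum(counts)
  hec <- counts / total > threshold
  list(hec_count = sum(hec),
       hec_clone_proportion = sum(hec) / length(counts),
       hec_mass_proportion = sum(counts[hec]) / total)
}

#' Depth- and T-cell-fraction-normalized richness
#'
#' Richness (number of unique clonotypes) is not comparable across samples
#' sequenced to different depths or with different T-cell content.
#' This normalization rarefies the repertoire to a common `target_depth`
#' by seeded uniform subsampling of reads without replacement (averaged
#' over `n_rep` draws to damp sampling noise) and divides by the sample's
#' relative T-cell fraction. When `target_depth` equals the total reads,
#' the "subsample" is the full table and only the fraction scaling
#' applies.
#'
#' @param x A [clonotype_table()].
#' @param t_cell_fraction Relative T-cell fraction in `(0, 1]`.
#' @param target_depth Common rarefaction depth (reads), at most the
#'   sample's total reads.
#' @param n_rep Number of rarefaction replicates averaged (default 10).
#' @param seed Seed for the subsampling.
#' @return Normalized richness (non-negative scalar).
#' @export
normalized_richness <- function(x, t_cell_fraction = 1, target_depth,
                                n_rep = 10, seed = 1L) {
  stopifnot(inherits(x, "clonotype_table"))
  if (is.na(t_cell_fraction) || t_cell_fraction <= 0 || t_cell_fraction > 1)
    stopf("normalized richness undefined: t_cell_fraction must be in (0, 1]")
  if (target_depth > x$total_reads)
    stopf(paste0("target_depth (%d) exceeds total reads (%d) for sample %s; ",
                 "lower the common rarefaction depth"),
          target_depth, x$total_reads, x$sample_id)
  counts <- x$clonotypes$count
  s <- if (target_depth == x$total_reads) {
    length(counts)
  } else {
    mean(with_seed(seed, replicate(n_rep, rarefied_richness(counts, target_depth))))
  }
  s / t_cell_fraction
}

# Richness of one uniform without-replacement subsample of `depth` reads.
#' @noRd
rarefied_richness <- function(counts, depth) {
  total <- sum(counts)
  picked <- sample.int(total, depth)
  bounds <- cumsum(counts)
  sum(tabulate(findInterval(picked - 1, c(0, bounds)), length(counts)) > 0)
}

#' Clonotype sharing and TCR heterogeneity between two samples
#'
#' Jaccard similarity on clonotype key sets (presence/absence; abundance
#' ignored): `|A intersect B| / |A union B|`. Heterogeneity is one minus
#' Jaccard similarity.
#'
#' @param a,b [clonotype_table()] objects.
#' @return List with `jaccard` and `heterogeneity`, both in `[0, 1]`.
#' @export
jaccard_shared <- function(a, b) {
  ka <- unique(clonotype_keys(a)); kb <- unique(clonotype_keys(b))
  if (length(ka) == 0 || length(kb) == 0)
    stopf("Jaccard sharing undefined for an empty repertoire")
  inter <- sum(ka %in% kb)
  j <- inter / (length(ka) + length(kb) - inter)
  list(jaccard = j, heterogeneity = 1 - j)
}

#' Percentage of a tissue sample's top clones found in blood
#'
#' Takes the `n` most abundant clonotypes of the tissue sample (all of
#' them if it has fewer than `n`) and reports the percentage whose key is
#' present in the blood repertoire. Ties at the n-th rank are broken by
#' descending count then lexicographic clonotype key, for determinism.
#'
#' @param tissue,blood [clonotype_table()] objects.
#' @param n Number of top clones to consider (default 100).
#' @return Percentage in `[0, 100]`.
#' @export
top_n_overlap <- function(tissue, blood, n = 100) {
  df <- tissue$clonotypes
  if (nrow(df) == 0) stopf("tissue repertoire is empty")
  keys <- clonotype_keys(tissue)
  ord <- order(-df$count, keys)
  top <- keys[ord][seq_len(min(n, length(keys)))]
  bk <- clonotype_keys(blood)
  if (length(bk) == 0) {
    warnf("blood repertoire is empty; top-%d overlap reported as 0%%", n)
    return(0)
  }
  100 * sum(top %in% bk) / length(top)
}

# ---- pairwise comparison categories ------------------------------------

#' Comparison category of a pair of tissue classes
#'
#' @param class_a,class_b Tissue classes (see [tissue_classes()]).
#' @return Category name, or `NA` for pairs that are not compared
#'   (blood-blood).
#' @export
pair_category <- function(class_a, class_b) {
  cl <- sort(c(class_a, class_b))
  key <- paste(cl[1], cl[2])
  switch(key,
         "normal normal" = "inter-normal",
         "primary primary" = "intra-primary",
         "metastasis metastasis" = "inter-metastasis",
         "normal primary" = "inter-primary-normal",
         "metastasis primary" = "inter-primary-metastasis",
         "metastasis normal" = "inter-normal-metastasis",
         "blood normal" = "blood-normal",
         "blood primary" = "blood-primary",
         "blood metastasis" = "blood-metastasis",
         "blood blood" = NA_character_,
         stopf("unknown tissue class pair: %s", key))
}

#' Enumerate within-patient sample pairs with their comparison category
#'
#' All unordered pairs of samples from the same patient, labelled with the
#' comparison category derived from the two tissue classes (intra-primary,
#' inter-metastasis, blood-primary, ...). Pairs are never formed across
#' patients; blood samples pair only with non-blood samples. Pairs are
#' canonically ordered by sample id.
#'
#' @param sheet A [sample_sheet()].
#' @return Data frame with columns `patient_id`, `sample_a`, `sample_b`,
#'   `category`.
#' @export
enumerate_pairs <- function(sheet) {
  out <- list()
  for (pat in split(as.data.frame(sheet), sheet$patient_id)) {
    n <- nrow(pat)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        cat_ij <- pair_category(pat$tissue_class[i], pat$tissue_class[j])
        if (is.na(cat_ij)) next
        ab <- sort(c(pat$sample_id[i], pat$sample_id[j]))
        out[[length(out) + 1L]] <- data.frame(
          patient_id = pat$patient_id[1], sample_a = ab[1], sample_b = ab[2],
          category = cat_ij, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(patient_id = character(), sample_a = character(),
                      sample_b = character(), category = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Per-sample diversity summary
#'
#' One row per sample: richness, Shannon entropy, Pielou evenness,
#' clonality and the HEC metrics; optionally normalized richness when a
#' rarefaction depth is given.
#'
#' @param tables Named list of [clonotype_table()] objects.
#' @param sheet Optional [sample_sheet()] supplying `t_cell_fraction`.
#' @param rarefy_depth Common rarefaction depth; `NULL` skips
#'   normalization. Use [min()] over total reads for the cohort-common
#'   depth.
#' @param hec_threshold Strict HEC read-fraction cutoff.
#' @param seed Seed for rarefaction.
#' @return Data frame with one row per sample.
#' @export
repertoire_diversity <- function(tables, sheet = NULL, rarefy_depth = NULL,
                                 hec_threshold = 0.001, seed = 1L) {
  rows <- lapply(tables, function(ct) {
    counts <- ct$clonotypes$count
    hec <- hec_metrics(ct, threshold = hec_threshold)
    tcf <- if (!is.null(sheet)) {
      sheet$t_cell_fraction[match(ct$sample_id, sheet$sample_id)]
    } else NA_real_
    nr <- if (!is.null(rarefy_depth)) {
      normalized_richness(ct, t_cell_fraction = ifelse(is.na(tcf), 1, tcf),
                          target_depth = rarefy_depth,
                          seed = derive_seed(seed, ct$sample_id))
    } else NA_real_
    data.frame(sample_id = ct$sample_id,
               richness = length(counts),
               total_reads = ct$total_reads,
               shannon_entropy = shannon_entropy(counts),
               pielou_evenness = pielou_evenness(counts),
               clonality = clonality(counts),
               hec_count = hec$hec_count,
               hec_clone_proportion = hec$hec_clone_proportion,
               hec_mass_proportion = hec$hec_mass_proportion,
               normalized_richness = nr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise TCR heterogeneity across within-patient comparison categories
#'
#' Applies [jaccard_shared()] to every within-patient non-blood-blood
#' sample pair and returns tidy rows carrying the shared percentage
#' (100 x Jaccard) and heterogeneity.
#'
#' @param tables Named list of [clonotype_table()] objects (names =
#'   sample ids).
#' @param sheet A [sample_sheet()].
#' @return Data frame: `patient_id`, `sample_a`, `sample_b`, `category`,
#'   `jaccard`, `shared_pct`, `heterogeneity`.
#' @export
tcr_heterogeneity <- function(tables, sheet) {
  pairs <- enumerate_pairs(sheet)
  pairs <- pairs[pairs$sample_a %in% names(tables) &
                   pairs$sample_b %in% names(tables), , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    jaccard_shared(tables[[pairs$sample_a[i]]], tables[[pairs$sample_b[i]]])
  })
  pairs$jaccard <- vapply(res, `[[`, numeric(1), "jaccard")
  pairs$shared_pct <- 100 * pairs$jaccard
  pairs$heterogeneity <- vapply(res, `[[`, numeric(1), "heterogeneity")
  pairs
}

# ---- VJ usage ----------------------------------------------------------

#' VJ segment usage frequencies of one repertoire
#'
#' Read-weighted frequency of every (V, J) gene pair:
#' reads with that VJ divided by total reads. Frequencies sum to 1.
#'
#' @param x A [clonotype_table()].
#' @return Data frame `v_call`, `j_call`, `freq`.
#' @export
vj_usage <- function(x) {
  stopifnot(inherits(x, "clonotype_table"))
  df <- x$clonotypes
  if (nrow(df) == 0)
    return(data.frame(v_call = character(), j_call = character(),
                      freq = numeric(), stringsAsFactors = FALSE))
  key <- paste(df$v_call, df$j_call, sep = "\r")
  agg <- rowsum(df$count, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(v_call = vapply(parts, `[`, "", 1),
                    j_call = vapply(parts, `[`, "", 2),
                    freq = agg[, 1] / x$total_reads,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$freq, out$v_call, out$j_call), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differential VJ segment usage between two groups of samples
#'
#' Per-sample VJ frequencies ([vj_usage()]; a VJ absent from a sample has
#' frequency 0) are compared per VJ pair with a two-sided Wilcoxon
#' rank-sum test, and Benjamini-Hochberg correction is applied across all
#' VJ pairs tested.
#'
#' @param group_a,group_b Lists of [clonotype_table()] objects (>= 2
#'   samples each).
#' @return Data frame `v_call`, `j_call`, per-group mean frequencies,
#'   `statistic`, `p_value`, `p_adjusted`, sorted by adjusted p.
#' @export
differential_vj <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stopf("differential VJ usage needs at least 2 samples per group")
  freq_list <- function(grp) lapply(grp, vj_usage)
  fa <- freq_list(group_a); fb <- freq_list(group_b)
  all_vj <- unique(do.call(rbind, lapply(c(fa, fb), function(d)
    d[, c("v_call", "j_call")])))
  vj_key <- paste(all_vj$v_call, all_vj$j_call, sep = "\r")
  get_freqs <- function(fl) {
    vapply(fl, function(d) {
      m <- match(vj_key, paste(d$v_call, d$j_call, sep = "\r"))
      ifelse(is.na(m), 0, d$freq[m])
    }, numeric(length(vj_key)))
  }
  ma <- matrix(get_freqs(fa), nrow = length(vj_key))
  mb <- matrix(get_freqs(fb), nrow = length(vj_key))
  tests <- lapply(seq_along(vj_key), function(i)
    wilcoxon_rank_sum(ma[i, ], mb[i, ]))
  out <- data.frame(v_call = all_vj$v_call, j_call = all_vj$j_call,
                    mean_freq_a = rowMeans(ma), mean_freq_b = rowMeans(mb),
                    statistic = vapply(tests, `[[`, numeric(1), "statistic"),
                    p_value = vapply(tests, `[[`, numeric(1), "p_value"),
                    stringsAsFactors = FALSE)
  out$p_adjusted <- bh_fdr(out$p_value)
  out <- out[order(out$p_adjusted, out$p_value, out$v_call, out$j_call), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
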