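#' Distance matrix over a patient's samples for one modality
#'
#' Jaccard distance (1 - Jaccard similarity on presence/absence sets) for
#' neoantigen and TCR features, Euclidean distance for immune-cell
#' infiltration vectors. At least three samples are required downstream:
#' a two-leaf tree has a single merge height and the cophenetic
#' correlation is undefined.
#'
#' @param features Named list of character sets (`kind = "jaccard"`), or
#'   a numeric matrix with sample rows (`kind = "euclidean"`).
#' @param kind `"jaccard"` or `"euclidean"`.
#' @return A symmetric `dist` object with zero diagonal.
#' @export
distance_matrix <- function(features, kind = c("jaccard", "euclidean")) {
  kind <- match.arg(kind)
  if (kind == "jaccard") {
    stopifnot(is.list(features), !is.null(names(features)))
    ids <- names(features)
    n <- length(ids)
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        a <- unique(features[[i]]); b <- unique(features[[j]])
        u <- length(a) + length(b) - sum(a %in% b)
        d <- if (u == 0) 0 else 1 - sum(a %in% b) / u
        m[i, j] <- m[j, i] <- d
      }
    }
    stats::as.dist(m)
  } else {
    stopifnot(is.matrix(features) || is.data.frame(features))
    stats::dist(as.matrix(features), method = "euclidean")
  }
}

#' Complete-linkage hierarchical clustering
#'
#' Standard complete-linkage agglomeration over a symmetric distance
#' matrix. Labels are put in canonical (sorted) order before clustering
#' so that the merge sequence — including tie resolution — is a
#' deterministic function of the distances alone.
#'
#' @param d A `dist` object or symmetric matrix with labels.
#' @return An `hclust` object (the package's dendrogram representation:
#'   n-1 merges with non-decreasing heights; the cophenetic distance of
#'   two leaves is the height of their lowest common merge).
#' @export
complete_linkage <- function(d) {
  m <- as.matrix(d)
  if (any(is.na(m)) || any(!is.finite(m)))
    stopf("distance matrix contains NA/NaN/Inf")
  if (is.null(rownames(m)))
    rownames(m) <- colnames(m) <- paste0("S", seq_len(nrow(m)))
  ord <- order(rownames(m))
  stats::hclust(stats::as.dist(m[ord, ord]), method = "complete")
}

#' Cophenetic distances of a dendrogram
#' @param hc An `hclust` object.
#' @return A `dist` of leaf-pair merge heights, labelled by leaf.
#' @export
cophenetic_distances <- function(hc) stats::cophenetic(hc)

#' Cophenetic correlation between two dendrograms
#'
#' Pearson correlation between the cophenetic distances of the two trees
#' over all unordered leaf pairs, matched by leaf label (leaf order is
#' irrelevant). Both trees must be over the same leaf set with at least
#' three leaves. If either tree has constant cophenetic distances the
#' correlation is undefined and `NA` is returned.
#'
#' @param t1,t2 `hclust` objects on the same leaf labels.
#' @return Correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
cophenetic_correlation <- function(t1, t2) {
  v <- matched_cophenetic_vectors(t1, t2)
  if (stats::sd(v$v1) == 0 || stats::sd(v$v2) == 0) return(NA_real_)
  stats::cor(v$v1, v$v2)
}

# Cophenetic matrices aligned on a common (sorted) leaf order, returned
# as lower-triangle vectors.
#' @noRd
matched_cophenetic_vectors <- function(t1, t2) {
  l1 <- sort(t1$labels); l2 <- sort(t2$labels)
  if (!identical(l1, l2))
    stopf("dendrograms have different leaf sets (%s vs %s)",
          paste(setdiff(l1, l2), collapse = ","),
          paste(setdiff(l2, l1), collapse = ","))
  if (length(l1) < 3)
    stopf("cophenetic correlation needs at least 3 leaves")
  m1 <- as.matrix(stats::cophenetic(t1))[l1, l1]
  m2 <- as.matrix(stats::cophenetic(t2))[l1, l1]
  list(labels = l1,
       v1 = m1[lower.tri(m1)], v2 = m2[lower.tri(m2)],
       m1 = m1, m2 = m2)
}

#' Permutation p-value for the cophenetic correlation
#'
#' Null distribution: the cophenetic correlation after random
#' permutation of the second tree's leaf labels. The test is one-sided
#' by default (co-evolution means a large positive correlation); set
#' `two_sided = TRUE` to test `|r|`. For trees with up to
#' `exhaustive_max` leaves all `n!` label permutations are enumerated
#' and the p-value is exact; otherwise `n_perm` permutations are sampled
#' and the add-one estimator `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)`
#' is used, which is never smaller than `1/(n_perm + 1)`.
#'
#' @param t1,t2 `hclust` objects on the same leaf labels (>= 3 leaves).
#' @param n_perm Number of sampled permutations (default 10000).
#' @param seed Seed for the sampled mode.
#' @param two_sided Test the magnitude of r instead of positive r.
#' @param exhaustive_max Maximum leaf count for exhaustive enumeration
#'   (default 7; 7! = 5040 permutations).
#' @return List with `r`, `p_value`, `n_perm` (permutations actually
#'   used) and `exhaustive`.
#' @export
permutation_pvalue <- function(t1, t2, n_perm = 10000, seed = 1L,
                               two_sided = FALSE, exhaustive_max = 7) {
  v <- matched_cophenetic_vectors(t1, t2)
  if (stats::sd(v$v1) == 0 || stats::sd(v$v2) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n_perm = 0L,
                exhaustive = FALSE))
  stat <- function(r) if (two_sided) abs(r) else r
  n <- length(v$labels)
  r_obs <- stats::cor(v$v1, v$v2)
  perm_r <- function(p) {
    mp <- v$m2[p, p]
    stats::cor(v$v1, mp[lower.tri(mp)])
  }
  tol <- 1e-12
  if (n <= exhaustive_max) {
    perms <- all_permutations(n)
    rs <- vapply(perms, perm_r, numeric(1))
    p <- mean(stat(rs) >= stat(r_obs) - tol)
    list(r = r_obs, p_value = p, n_perm = length(perms), exhaustive = TRUE)
  } else {
    rs <- with_seed(seed, vapply(seq_len(n_perm), function(k)
      perm_r(sample.int(n)), numeric(1)))
    p <- (1 + sum(stat(rs) >= stat(r_obs) - tol)) / (1 + n_perm)
    list(r = r_obs, p_value = p, n_perm = n_perm, exhaustive = FALSE)
  }
}

#' Co-evolution test between two modalities of one patient
#'
#' Builds complete-linkage dendrograms from the two distance matrices
#' and reports the cophenetic correlation with its permutation p-value.
#' No significance verdict is attached: raw `r` and `p` are reported.
#'
#' @param d1,d2 `dist` objects over the same samples (>= 3).
#' @param modalities Length-2 character vector naming the modalities.
#' @inheritParams permutation_pvalue
#' @return One-row data frame: `modality_a`, `modality_b`, `n_leaves`,
#'   `r`, `p_value`, `n_perm`, `exhaustive`.
#' @export
coevolution_test <- function(d1, d2, modalities = c("a", "b"),
                             n_perm = 10000, seed = 1L, two_sided = FALSE) {
  t1 <- complete_linkage(d1); t2 <- complete_linkage(d2)
  res <- permutation_pvalue(t1, t2, n_perm = n_perm, seed = seed,
                            two_sided = two_sided)
  data.frame(modality_a = modalities[1], modality_b = modalities[2],
             n_leaves = length(t1$labels), r = res$r, p_value = res$p_value,
             n_perm = res$n_perm, exhaustive = res$exhaustive,
             stringsAsFactors = FALSE)
}

#' Per-patient co-evolution analysis across modalities
#'
#' For each patient with at least three tumour samples (primary and
#' metastatic; blood and normal are excluded), builds dendrograms from
#' the available modalities — neoantigen sets (Jaccard), TCR clonotype
#' sets (Jaccard) and infiltration fractions (Euclidean) — and tests
#' every modality pair by cophenetic correlation. Patients with fewer
#' than three tumour samples, or with no flagged neoantigens, are
#' skipped with the reason recorded.
#'
#' @param tables Named list of [clonotype_table()] objects (or `NULL`).
#' @param mt A [mutation_table()] with neoantigen flags (or `NULL`).
#' @param infl An [infiltration_matrix()] (or `NULL`).
#' @param sheet A [sample_sheet()].
#' @inheritParams permutation_pvalue
#' @return List with `tests` (data frame: patient_id + columns of
#'   [coevolution_test()]), `trees` (nested list of `hclust` objects per
#'   patient per modality) and `skipped` (data frame of reasons).
#' @export
coevolve_patients <- function(tables = NULL, mt = NULL, infl = NULL, sheet,
                              n_perm = 10000, seed = 1L, two_sided = FALSE) {
  tests <- list(); trees <- list()
  skipped <- data.frame(patient_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  skip <- function(pid, why)
    rbind(skipped, data.frame(patient_id = pid, reason = why,
                              stringsAsFactors = FALSE))
  for (pid in sort(unique(sheet$patient_id))) {
    tum <- sheet$sample_id[sheet$patient_id == pid &
                             sheet$tissue_class %in% c("primary", "metastasis")]
    # restrict every modality to the tumour samples all provided
    # modalities cover, so the trees share one leaf set
    if (!is.null(tables)) tum <- intersect(tum, names(tables))
    if (!is.null(infl)) tum <- intersect(tum, rownames(infl))
    if (length(tum) < 3) {
      skipped <- skip(pid, "fewer than 3 tumour samples")
      next
    }
    dists <- list()
    if (!is.null(tables))
      dists$tcr <- distance_matrix(
        lapply(tables[tum], clonotype_keys), kind = "jaccard")
    if (!is.null(mt) && any(mt$patient_id == pid)) {
      sub <- mt[mt$patient_id == pid, , drop = FALSE]
      if (!all(is.na(sub$is_neoantigen)) &&
          any(sub$is_neoantigen, na.rm = TRUE)) {
        sets <- neoantigen_sets(sub, samples = tum)
        dists$neoantigen <- distance_matrix(sets, "jaccard")
      } else {
        skipped <- skip(pid, "no flagged neoantigens")
        warnf("patient %s has no flagged neoantigens; neoantigen tree skipped",
              pid)
      }
    }
    if (!is.null(infl))
      dists$infiltration <- distance_matrix(infl[tum, , drop = FALSE],
                                            "euclidean")
    if (length(dists) < 2) next
    trees[[pid]] <- lapply(dists, complete_linkage)
    mods <- names(dists)
    for (i in seq_len(length(mods) - 1)) {
      for (j in seq((i + 1), length(mods))) {
        row <- coevolution_test(dists[[i]], dists[[j]],
                                modalities = c(mods[i], mods[j]),
                                n_perm = n_perm,
                                seed = derive_seed(seed, paste(pid, i, j)),
                                two_sided = two_sided)
        tests[[length(tests) + 1L]] <- cbind(patient_id = pid, row)
      }
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(patient_id = character(), modality_a = character(),
               modality_b = character(), n_leaves = integer(), r = numeric(),
               p_value = numeric(), n_perm = integer(), exhaustive = logical(),
               stringsAsFactors = FALSE)
  rownames(tests) <- NULL
  list(tests = tests, trees = trees, skipped = skipped)
}
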