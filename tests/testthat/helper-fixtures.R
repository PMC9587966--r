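# Small in-code fixtures shared across the suite.

# Clonotype table from a named count vector; names become junctions,
# V/J calls cycle through a couple of genes deterministically.
ct_from_counts <- function(counts, sample_id = "S1",
                           junctions = NULL, v = NULL, j = NULL) {
  n <- length(counts)
  clonotype_table(
    sample_id,
    junction_aa = junctions %||% sprintf("CASS%03dF", seq_len(n)),
    v_call = v %||% rep_len(c("TRBV9", "TRBV28"), n),
    j_call = j %||% rep_len(c("TRBJ2-1", "TRBJ1-5"), n),
    count = counts)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Clonotype table whose key set is exactly `keys` (all counts 1).
ct_from_keys <- function(keys, sample_id = "S1") {
  if (length(keys) == 0) return(clonotype_table(sample_id))
  clonotype_table(sample_id, junction_aa = paste0("CASS", keys, "F"),
                  v_call = rep("TRBV9", length(keys)),
                  j_call = rep("TRBJ2-1", length(keys)),
                  count = rep(1, length(keys)))
}

# Nine-sample single-patient sheet: 2 normal, 3 primary, 3 metastasis,
# 1 blood.
one_patient_sheet <- function(pid = "P1") {
  sample_sheet(data.frame(
    sample_id = paste0(pid, "_", c("N1", "N2", "T1", "T2", "T3",
                                   "M1", "M2", "M3", "B1")),
    patient_id = pid,
    tissue_class = c("normal", "normal", "primary", "primary", "primary",
                     "metastasis", "metastasis", "metastasis", "blood"),
    site_label = "x", stringsAsFactors = FALSE))
}

# hclust over an explicit labelled distance matrix.
hc_from_dists <- function(labels, d_vec) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- d_vec
  m <- m + t(m)
  complete_linkage(m)
}

# Brute-force independent oracles -----------------------------------------

brute_entropy <- function(counts) {
  p <- counts / sum(counts)
  acc <- 0
  for (pi in p) acc <- acc - pi * log(pi)
  acc
}

brute_jaccard <- function(a, b) {
  inter <- 0
  for (x in unique(a)) if (x %in% b) inter <- inter + 1
  uni <- length(unique(c(a, b)))
  inter / uni
}

brute_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running <- Inf
  for (i in seq_len(m)) {
    k <- o[i]
    rank_k <- max(which(sort(p) <= p[k]))  # ties share the largest rank
    running <- min(running, p[k] * m / rank_k)
    adj[k] <- min(1, running)
  }
  adj
}

# Exact two-sided rank-sum p-value by full enumeration of group
# assignments (no ties).
brute_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  ns <- min(length(a), length(b))
  r <- rank(pooled)
  w_obs <- if (length(a) <= length(b)) sum(r[seq_along(a)]) else
    sum(r[seq_along(b) + length(a)])
  splits <- utils::combn(n, ns)
  ws <- apply(splits, 2, function(idx) sum(r[idx]))
  p_lo <- mean(ws <= w_obs)
  p_hi <- mean(ws >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Cophenetic distance of two leaves computed straight from the merge
# description of an hclust object (recursive cluster membership).
brute_cophenetic <- function(hc) {
  n <- length(hc$labels)
  m <- matrix(0, n, n, dimnames = list(hc$labels, hc$labels))
  clusters <- list()
  for (k in seq_len(nrow(hc$merge))) {
    get_leaves <- function(id) {
      if (id < 0) -id else clusters[[id]]
    }
    a <- get_leaves(hc$merge[k, 1]); b <- get_leaves(hc$merge[k, 2])
    for (i in a) for (j in b) m[i, j] <- m[j, i] <- hc$height[k]
    clusters[[k]] <- c(a, b)
  }
  stats::as.dist(m)
}
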