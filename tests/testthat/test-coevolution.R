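test_that("distance matrices implement Jaccard and Euclidean kinds", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = c("x"))
  d <- as.matrix(distance_matrix(sets, "jaccard"))
  expect_equal(d["A", "B"], 0.5)
  expect_equal(d["A", "C"], 1)
  expect_equal(diag(d), c(A = 0, B = 0, C = 0))
  expect_equal(d, t(d))
  same <- list(A = "a", B = "a", C = "a")
  expect_true(all(as.matrix(distance_matrix(same, "jaccard")) == 0))
  m <- rbind(A = c(0, 0), B = c(3, 4), C = c(0, 1))
  dm <- as.matrix(distance_matrix(m, "euclidean"))
  expect_equal(dm["A", "B"], 5)
})

test_that("complete linkage reproduces the hand-derived 3-leaf merge sequence", {
  hc <- hc_from_dists(c("A", "B", "C"), c(0.2, 0.6, 0.8))
  # d(A,B)=0.2, d(A,C)=0.6, d(B,C)=0.8: merge (A,B)@0.2 then +C@0.8
  expect_equal(hc$height, c(0.2, 0.8))
  coph <- as.matrix(cophenetic_distances(hc))
  expect_equal(coph["A", "B"], 0.2)
  expect_equal(coph["A", "C"], 0.8)
  expect_equal(coph["B", "C"], 0.8)
  expect_error(complete_linkage(matrix(c(0, NaN, NaN, 0), 2)), "NaN")
})

test_that("cophenetic distances agree with a from-scratch merge-tree traversal", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    v <- runif(n * (n - 1) / 2)
    m[lower.tri(m)] <- v
    m <- m + t(m)
    hc <- complete_linkage(m)
    expect_equal(as.matrix(cophenetic_distances(hc)),
                 as.matrix(brute_cophenetic(hc)), tolerance = 1e-12)
  }
})

test_that("ultrametric inputs are reproduced exactly by complete linkage", {
  set.seed(33)
  for (i in 1:10) {
    # build a random ultrametric via a random dendrogram's cophenetic matrix
    n <- sample(4:7, 1)
    m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    m[lower.tri(m)] <- runif(n * (n - 1) / 2)
    m <- m + t(m)
    ultra <- as.matrix(cophenetic_distances(complete_linkage(m)))
    hc2 <- complete_linkage(ultra)
    expect_equal(as.matrix(cophenetic_distances(hc2)), ultra,
                 tolerance = 1e-12)
  }
})

test_that("cophenetic correlation handles self, frozen and degenerate cases", {
  t1 <- hc_from_dists(c("A", "B", "C"), c(0.2, 0.8, 0.8))
  expect_equal(cophenetic_correlation(t1, t1), 1)
  # swap A and B roles in the second tree: vectors (0.2,0.8,0.8) vs
  # (0.8,0.2,0.8) correlate at exactly -0.5
  t2 <- hc_from_dists(c("A", "B", "C"), c(0.8, 0.2, 0.8))
  expect_equal(cophenetic_correlation(t1, t2), -0.5, tolerance = 1e-12)
  # matching is by label, not leaf order
  t2b <- hc_from_dists(c("C", "A", "B"), c(0.2, 0.8, 0.8))
  expect_equal(cophenetic_correlation(t1, t2b),
               cophenetic_correlation(t1, t2))
  # constant trees are undefined
  flat <- hc_from_dists(c("A", "B", "C"), c(0.5, 0.5, 0.5))
  expect_true(is.na(cophenetic_correlation(flat, flat)))
  # leaf-set mismatch errors
  t3 <- hc_from_dists(c("A", "B", "D"), c(0.2, 0.8, 0.8))
  expect_error(cophenetic_correlation(t1, t3), "leaf")
})

test_that("correlation is invariant under consistent relabelling of both trees", {
  set.seed(41)
  n <- 6
  mk <- function() {
    m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    m[lower.tri(m)] <- runif(n * (n - 1) / 2)
    m + t(m)
  }
  m1 <- mk(); m2 <- mk()
  r0 <- cophenetic_correlation(complete_linkage(m1), complete_linkage(m2))
  perm <- sample(n)
  relab <- function(m) {
    rownames(m) <- colnames(m) <- letters[perm]
    m
  }
  r1 <- cophenetic_correlation(complete_linkage(relab(m1)),
                               complete_linkage(relab(m2)))
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("3-leaf permutation p-values are exhaustive with support k/6", {
  t1 <- hc_from_dists(c("A", "B", "C"), c(0.2, 0.8, 0.8))
  t2 <- hc_from_dists(c("A", "B", "C"), c(0.3, 0.9, 0.9))
  res <- permutation_pvalue(t1, t2)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 6)
  expect_equal(res$p_value * 6, round(res$p_value * 6))
  expect_gt(res$p_value, 0)
})

test_that("identical strongly structured 6-leaf trees are significant exhaustively", {
  # distinct pairwise structure: chained distances
  n <- 6
  m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  for (i in 1:n) for (j in 1:n) m[i, j] <- abs(i - j) / n
  t1 <- complete_linkage(m)
  res <- permutation_pvalue(t1, t1)
  expect_true(res$exhaustive)
  expect_equal(res$r, 1)
  expect_lte(res$p_value, 0.05)
})

test_that("sampled p-values are seed-reproducible and track the exhaustive value", {
  set.seed(55)
  n <- 5
  mk <- function() {
    m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    m[lower.tri(m)] <- runif(n * (n - 1) / 2)
    m + t(m)
  }
  t1 <- complete_linkage(mk()); t2 <- complete_linkage(mk())
  exact <- permutation_pvalue(t1, t2)
  samp1 <- permutation_pvalue(t1, t2, n_perm = 4000, seed = 3,
                              exhaustive_max = 3)
  samp2 <- permutation_pvalue(t1, t2, n_perm = 4000, seed = 3,
                              exhaustive_max = 3)
  expect_false(samp1$exhaustive)
  expect_identical(samp1$p_value, samp2$p_value)
  expect_gte(samp1$p_value, 1 / 4001)
  # sampled and exhaustive agree within 2 Monte-Carlo standard errors
  mc_se <- sqrt(exact$p_value * (1 - exact$p_value) / 4000)
  expect_lt(abs(samp1$p_value - exact$p_value), 2 * mc_se + 1e-3)
})

test_that("per-patient driver builds matched trees and skips sparse patients", {
  co <- simulate_cohort(cohort_config(n_patients = 2, seed = 13))
  cv <- coevolve_patients(tables = co$repertoires, mt = co$mutations,
                          infl = co$infiltration, sheet = co$sheet,
                          seed = 13)
  expect_equal(sort(unique(cv$tests$patient_id)), c("P01", "P02"))
  # three modalities -> three pairwise tests per patient
  expect_equal(nrow(cv$tests), 6)
  expect_true(all(cv$tests$n_leaves == 6))
  expect_true(all(cv$tests$exhaustive))
  expect_true(all(cv$tests$r >= -1 & cv$tests$r <= 1, na.rm = TRUE))
  # a patient with <3 tumour samples is skipped with a reason
  small <- sample_sheet(data.frame(
    sample_id = c("q1", "q2"), patient_id = "Q",
    tissue_class = c("primary", "metastasis"), site_label = "x"))
  tabs <- list(q1 = ct_from_keys(c("a", "b")), q2 = ct_from_keys(c("b", "c")))
  cv2 <- coevolve_patients(tables = tabs, sheet = small, seed = 1)
  expect_equal(nrow(cv2$tests), 0)
  expect_match(cv2$skipped$reason, "fewer than 3")
})

test_that("coupled cohorts show stronger TCR-neoantigen co-evolution than independent ones", {
  r_for <- function(gamma, seed) {
    co <- simulate_cohort(cohort_config(
      n_patients = 8, coupling = gamma, seed = seed,
      n_background_genes = 5))
    cv <- coevolve_patients(tables = co$repertoires, mt = co$mutations,
                            sheet = co$sheet, seed = seed)
    cv$tests$r[cv$tests$modality_a == "tcr" &
                 cv$tests$modality_b == "neoantigen"]
  }
  r_coupled <- r_for(1, 501)
  r_indep <- r_for(0, 502)
  expect_gt(mean(r_coupled), mean(r_indep))
})
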