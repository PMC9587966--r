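test_that("Shannon entropy matches closed forms and the brute-force sum", {
  expect_equal(shannon_entropy(c(1, 1, 1, 1)), log(4))
  expect_equal(shannon_entropy(7), 0)
  expect_equal(shannon_entropy(c(5, 3, 2)), brute_entropy(c(5, 3, 2)),
               tolerance = 1e-12)
  # frozen high-precision value for the worked example
  expect_equal(shannon_entropy(c(5, 3, 2)), 1.0296530140645737,
               tolerance = 1e-10)
  expect_error(shannon_entropy(numeric()), "undefined")
})

test_that("clonality is 1 - Pielou with the monoclonal convention", {
  expect_equal(clonality(c(3, 3, 3)), 0)
  expect_equal(clonality(c(9, 1)), 1 - brute_entropy(c(9, 1)) / log(2),
               tolerance = 1e-12)
  expect_equal(clonality(c(9, 1)), 0.5310044, tolerance = 1e-6)
  expect_equal(clonality(42), 1)
  expect_equal(pielou_evenness(42), 0)
})

test_that("diversity invariants hold over random repertoires", {
  set.seed(71)
  for (i in 1:100) {
    counts <- sample(1:50, sample(1:40, 1), replace = TRUE)
    h <- shannon_entropy(counts)
    expect_gte(h, 0)
    expect_lte(h, log(length(counts)) + 1e-12)
    cc <- clonality(counts)
    expect_gte(cc, 0); expect_lte(cc, 1)
    expect_equal(cc, 1 - pielou_evenness(counts), tolerance = 1e-12)
  }
  # doubling one clone of an even multi-clone repertoire raises clonality
  even <- rep(10, 5)
  skewed <- c(20, rep(10, 4))
  expect_gt(clonality(skewed), clonality(even))
})

test_that("HEC metrics use a strict threshold and both normalizations", {
  expect_equal(hec_metrics(c(50, 30, 20))$hec_count, 3)
  expect_equal(hec_metrics(c(50, 30, 20))$hec_clone_proportion, 1)
  expect_equal(hec_metrics(rep(1, 2000))$hec_count, 0)  # 0.05% each
  big <- c(20, rep(1, 1980))  # total 2000; singletons sit exactly at 0.05%
  res <- hec_metrics(big)
  expect_equal(res$hec_count, 1)
  expect_equal(res$hec_clone_proportion, 1 / 1981, tolerance = 1e-12)
  expect_equal(res$hec_mass_proportion, 20 / 2000)
  # boundary: exactly at threshold is not an HEC (strict >)
  expect_equal(hec_metrics(c(1, 999))$hec_count, 1)
})

test_that("normalized richness rarefies and scales by T-cell fraction", {
  ct <- ct_from_counts(rep(2, 100))
  expect_equal(normalized_richness(ct, 1, target_depth = 200), 100)
  expect_equal(normalized_richness(ct, 0.5, target_depth = 200), 200)
  expect_error(normalized_richness(ct, 1, target_depth = 500), "lower")
  expect_error(normalized_richness(ct, 0, target_depth = 100), "undefined")
  # rarefied richness can only shrink, for any seed
  zipf <- simulate_repertoire(200, 1.2, 5000, seed = 4)
  full_s <- nrow(zipf$clonotypes)
  for (s in 1:5)
    expect_lte(normalized_richness(zipf, 1, target_depth = 2500, seed = s),
               full_s)
})

test_that("rarefied richness tracks the exact hypergeometric expectation", {
  # 10-clone toy where the expectation is computable in closed form
  counts <- c(40, 20, 10, 8, 6, 6, 4, 3, 2, 1)
  total <- sum(counts)
  depth <- 30
  exact <- sum(1 - exp(lchoose(total - counts, depth) - lchoose(total, depth)))
  ct <- ct_from_counts(counts)
  obs <- normalized_richness(ct, 1, target_depth = depth, n_rep = 3000,
                             seed = 9)
  expect_equal(obs, exact, tolerance = 0.02)
})

test_that("rarefied richness is non-decreasing in target depth", {
  ct <- simulate_repertoire(150, 1.0, 4000, seed = 2)
  depths <- c(500, 1000, 2000, 3000, ct$total_reads)
  vals <- vapply(depths, function(d)
    normalized_richness(ct, 1, target_depth = d, seed = 11), numeric(1))
  expect_true(all(diff(vals) >= -1e-9))
})

test_that("Jaccard sharing matches set arithmetic, including the exhaustive case", {
  a <- ct_from_keys(c("a", "b", "c"))
  b <- ct_from_keys(c("b", "c", "d"))
  res <- jaccard_shared(a, b)
  expect_equal(res$jaccard, 0.5)
  expect_equal(res$heterogeneity, 0.5)
  expect_equal(jaccard_shared(a, a)$jaccard, 1)
  expect_equal(jaccard_shared(a, ct_from_keys(c("x", "y")))$jaccard, 0)
  expect_error(jaccard_shared(a, ct_from_keys(character())), "undefined")
  # exhaustive oracle over all non-empty subsets of a 6-element universe
  universe <- letters[1:6]
  subsets <- unlist(lapply(1:6, function(k)
    combn(universe, k, simplify = FALSE)), recursive = FALSE)
  set.seed(5)
  idx <- sample(length(subsets), 40, replace = TRUE)
  jdx <- sample(length(subsets), 40, replace = TRUE)
  for (k in seq_along(idx)) {
    sa <- subsets[[idx[k]]]; sb <- subsets[[jdx[k]]]
    got <- jaccard_shared(ct_from_keys(sa), ct_from_keys(sb))
    expect_equal(got$jaccard, brute_jaccard(sa, sb), tolerance = 1e-12)
    # symmetry
    expect_equal(got$jaccard,
                 jaccard_shared(ct_from_keys(sb), ct_from_keys(sa))$jaccard)
  }
})

test_that("top-n blood overlap counts top tissue clones found in blood", {
  tissue <- ct_from_counts(c(50, 40, 30, 20, 5, 4),
                           junctions = paste0("CASSJ", 1:6, "F"),
                           v = rep("TRBV9", 6), j = rep("TRBJ2-1", 6))
  blood_all <- ct_from_keys(paste0("J", 1:6))
  expect_equal(top_n_overlap(tissue, blood_all, n = 4), 100)
  blood_none <- ct_from_keys(c("z1", "z2"))
  expect_equal(top_n_overlap(tissue, blood_none, n = 4), 0)
  blood_half <- ct_from_keys(c("J1", "J3", "J6"))
  # top-4 are J1..J4, two of them (J1, J3) in blood
  expect_equal(top_n_overlap(tissue, blood_half, n = 4), 50)
  expect_warning(
    expect_equal(top_n_overlap(tissue, ct_from_keys(character())), 0),
    "empty")
})

test_that("ct_from_keys junctions match tissue keys used for overlap", {
  # guard: the helper encodes keys the same way in tissue and blood
  tissue <- ct_from_keys(c("J1", "J2"))
  expect_equal(top_n_overlap(tissue, tissue), 100)
})

test_that("pair enumeration yields the expected category counts", {
  sheet <- one_patient_sheet()
  pairs <- enumerate_pairs(sheet)
  counts <- table(pairs$category)
  expect_equal(unname(counts["inter-normal"]), 1L)
  expect_equal(unname(counts["intra-primary"]), 3L)
  expect_equal(unname(counts["inter-metastasis"]), 3L)
  expect_equal(unname(counts["inter-primary-normal"]), 6L)
  expect_equal(unname(counts["inter-primary-metastasis"]), 9L)
  expect_equal(unname(counts["inter-normal-metastasis"]), 6L)
  expect_equal(unname(counts["blood-normal"]), 2L)
  expect_equal(unname(counts["blood-primary"]), 3L)
  expect_equal(unname(counts["blood-metastasis"]), 3L)
  # total = C(8,2) + 1*8
  n_nonblood <- 8; n_blood <- 1
  expect_equal(nrow(pairs), choose(n_nonblood, 2) + n_blood * n_nonblood)
})

test_that("pairs stay within patients and single samples yield none", {
  two <- rbind(as.data.frame(one_patient_sheet("P1")),
               as.data.frame(one_patient_sheet("P2")))
  pairs <- enumerate_pairs(sample_sheet(two))
  ab <- cbind(pairs$sample_a, pairs$sample_b)
  expect_true(all(substr(ab[, 1], 1, 2) == substr(ab[, 2], 1, 2)))
  single <- sample_sheet(data.frame(sample_id = "s", patient_id = "P",
                                    tissue_class = "primary",
                                    site_label = "x"))
  expect_equal(nrow(enumerate_pairs(single)), 0)
})

test_that("VJ usage frequencies sum to one and respond to group differences", {
  ct <- ct_from_counts(c(6, 3, 1))
  u <- vj_usage(ct)
  expect_equal(sum(u$freq), 1)

  # identical groups: all adjusted p-values are 1
  g <- lapply(1:3, function(i) ct_from_counts(c(5, 5), junctions = c("A", "B")))
  res <- differential_vj(g, g)
  expect_true(all(res$p_adjusted == 1))

  # one discriminating VJ gets the smallest adjusted p
  mk <- function(f_target) {
    clonotype_table("s",
                    junction_aa = c("CASSAF", "CASSBF"),
                    v_call = c("TRBV9", "TRBV28"),
                    j_call = c("TRBJ2-1", "TRBJ1-5"),
                    count = c(round(100 * f_target), 100 - round(100 * f_target)))
  }
  ga <- lapply(c(0.5, 0.5, 0.5), mk)
  gb <- lapply(c(0.01, 0.02, 0.01), mk)
  res2 <- differential_vj(ga, gb)
  expect_equal(min(res2$p_adjusted[res2$v_call == "TRBV9"]),
               min(res2$p_adjusted))
  expect_lt(min(res2$p_adjusted), 1)
  expect_error(differential_vj(ga[1], gb), "2 samples")
})

test_that("higher Zipf exponents give higher clonality (rank correlation)", {
  exponents <- c(0.6, 0.9, 1.2, 1.5)
  vals <- do.call(rbind, lapply(exponents, function(s) {
    cl <- vapply(1:20, function(i) {
      ct <- simulate_repertoire(300, s, 3000, seed = 7000 + round(100 * s) + i)
      clonality(ct$clonotypes$count)
    }, numeric(1))
    data.frame(s = s, cl = cl)
  }))
  expect_gt(cor(vals$s, vals$cl, method = "spearman"), 0.9)
})
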