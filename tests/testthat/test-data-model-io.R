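test_that("AIRR reader merges duplicate keys, drops empty junctions, logs drops", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("junction_aa\tv_call\tj_call\tduplicate_count",
               "CASSLF\tTRBV9\tTRBJ2-1\t5",
               "CASSGF\tTRBV9\tTRBJ2-1\t3",
               "CASSLF\tTRBV9\tTRBJ2-1\t2",
               "\tTRBV9\tTRBJ2-1\t4"), f)
  ct <- read_airr_tsv(f, "S1")
  expect_equal(nrow(ct$clonotypes), 2)
  expect_equal(ct$total_reads, 10)
  expect_equal(ct$clonotypes$count[ct$clonotypes$junction_aa == "CASSLF"], 7)
  expect_equal(attr(ct, "dropped"), 1)
})

test_that("AIRR reader errors name the missing column and the bad row", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("junction_aa\tv_call\tduplicate_count",
               "CASSLF\tTRBV9\t5"), f)
  expect_error(read_airr_tsv(f, "S1"), "j_call")
  writeLines(c("junction_aa\tv_call\tj_call\tduplicate_count",
               "CASSLF\tTRBV9\tTRBJ2-1\t5",
               "CASSGF\tTRBV9\tTRBJ2-1\t2.5"), f)
  expect_error(read_airr_tsv(f, "S1"), "row 2")
})

test_that("empty AIRR file yields an empty table with zero reads", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("junction_aa\tv_call\tj_call\tduplicate_count", f)
  ct <- read_airr_tsv(f, "S1")
  expect_equal(nrow(ct$clonotypes), 0)
  expect_equal(ct$total_reads, 0)
})

test_that("clonotype tables round-trip through AIRR TSV, conserving reads", {
  ct <- simulate_repertoire(50, 1.0, 2000, seed = 3, sample_id = "S7")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_airr_tsv(ct, f)
  back <- read_airr_tsv(f, "S7")
  expect_equal(back$clonotypes, ct$clonotypes)
  expect_equal(back$total_reads, ct$total_reads)
})

test_that("reader accepts gzip-compressed AIRR files", {
  ct <- ct_from_counts(c(5, 3))
  f <- withr::local_tempfile(fileext = ".tsv.gz")
  con <- gzfile(f, "w")
  writeLines(c("junction_aa\tv_call\tj_call\tduplicate_count",
               "CASSLF\tTRBV9\tTRBJ2-1\t5"), con)
  close(con)
  expect_equal(read_airr_tsv(f, "S1")$total_reads, 5)
})

test_that("sample sheet validates classes case-insensitively and rejects bad rows", {
  df <- data.frame(sample_id = c("a", "b"), patient_id = "P1",
                   tissue_class = c("Metastasis", "BLOOD"), site_label = "x")
  sheet <- sample_sheet(df)
  expect_equal(sheet$tissue_class, c("metastasis", "blood"))

  df$tissue_class <- c("primary", "tumour")
  expect_error(sample_sheet(df), "normal, primary, metastasis, blood")

  df2 <- data.frame(sample_id = c("a", "a"), patient_id = "P1",
                    tissue_class = "primary", site_label = "x")
  expect_error(sample_sheet(df2), "duplicate")

  df3 <- data.frame(sample_id = "a", patient_id = "P1",
                    tissue_class = "primary", site_label = "x",
                    t_cell_fraction = 1.2)
  expect_error(sample_sheet(df3), "t_cell_fraction")
})

test_that("nine-sample sheet parses to nine records with classes intact", {
  sheet <- one_patient_sheet()
  expect_equal(nrow(sheet), 9)
  expect_equal(as.integer(table(sheet$tissue_class)[c("normal", "primary",
                                                      "metastasis", "blood")]),
               c(2L, 3L, 3L, 1L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sample_sheet(sheet, f)
  expect_equal(as.data.frame(read_sample_sheet(f)), as.data.frame(sheet))
})

test_that("infiltration matrix enforces the simplex and the renormalize flag", {
  m <- matrix(1 / 22, 2, 22,
              dimnames = list(c("s1", "s2"), immune_cell_types()))
  expect_silent(infiltration_matrix(m))
  m2 <- m; m2[1, 1] <- m2[1, 1] + 5e-4
  expect_error(infiltration_matrix(m2), "renormalize")
  fixed <- infiltration_matrix(m2, renormalize = TRUE)
  expect_equal(unname(rowSums(fixed)), c(1, 1))
  m3 <- m; m3[1, 1] <- m3[1, 1] + 0.1
  expect_error(infiltration_matrix(m3, renormalize = TRUE), "corrupt")
  expect_error(infiltration_matrix(m[, 1:10]), "22")
})

test_that("SEG round-trips through the 1-based/0-based conversion", {
  st <- segment_table(data.frame(
    sample_id = "s1", chrom = c("1", "1"), start = c(0, 1000),
    end = c(1000, 2500), adjusted_cn = c(2, 4)))
  f <- withr::local_tempfile(fileext = ".seg")
  write_seg(st, f)
  raw <- read.delim(f)
  expect_equal(raw$start, c(1, 1001))  # 1-based inclusive on disk
  back <- read_seg(f)
  expect_equal(as.data.frame(back), as.data.frame(st))
  expect_error(segment_table(data.frame(
    sample_id = "s1", chrom = "1", start = c(0, 500), end = c(1000, 1500),
    adjusted_cn = 2)), "overlap")
})

test_that("MAF rows sharing a variant key collapse into one record", {
  sheet <- one_patient_sheet()
  f <- withr::local_tempfile(fileext = ".maf")
  hdr <- paste("Hugo_Symbol", "Chromosome", "Start_Position",
               "Reference_Allele", "Tumor_Seq_Allele2",
               "Variant_Classification", "Tumor_Sample_Barcode", sep = "\t")
  rows <- c("TP53\t17\t100\tC\tT\tMissense_Mutation\tP1_T1",
            "TP53\t17\t100\tC\tT\tMissense_Mutation\tP1_T2",
            "KRAS\t12\t200\tG\tA\tMissense_Mutation\tP1_T1",
            "ERBB2\t17\t300\tA\tG\tMissense_Mutation\tP1_M1",
            "CDH1\t16\t400\tG\tC\tSilent\tP1_M2")
  writeLines(c(hdr, rows), f)
  mt <- read_maf(f, sheet)
  expect_equal(nrow(mt), 4)
  tp53 <- mt[mt$gene == "TP53", ]
  expect_setequal(tp53$samples[[1]], c("P1_T1", "P1_T2"))
  f2 <- withr::local_tempfile(fileext = ".maf")
  write_maf(mt, f2)
  back <- read_maf(f2, sheet)
  expect_equal(variant_keys(back), variant_keys(mt))
  expect_equal(back$samples, mt$samples)
})

test_that("mutation table rejects blood carriers and unknown samples", {
  sheet <- one_patient_sheet()
  df <- data.frame(patient_id = "P1", chrom = "1", pos = 1, ref = "A",
                   alt = "T", gene = "G1",
                   variant_classification = "Missense_Mutation",
                   stringsAsFactors = FALSE)
  df$samples <- list("P1_B1")
  expect_error(mutation_table(df, sheet), "blood")
  df$samples <- list("NOPE")
  expect_error(mutation_table(df, sheet), "NOPE")
})

test_that("dendrograms round-trip through Newick with cophenetic distances intact", {
  hc <- hc_from_dists(c("A", "B", "C"), c(0.2, 0.6, 0.8))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc, f)
  tree <- ape::read.tree(f)
  coph_file <- ape::cophenetic.phylo(tree)
  coph_hc <- as.matrix(cophenetic_distances(hc))
  expect_equal(coph_file[rownames(coph_hc), colnames(coph_hc)], coph_hc,
               tolerance = 1e-8)
})

test_that("matrix TSV writer/reader round-trips expression and infiltration", {
  co <- simulate_cohort(cohort_config(n_patients = 1, seed = 5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(co$infiltration, f, index_name = "sample_id")
  back <- read_infiltration_tsv(f)
  expect_equal(unclass(back), unclass(co$infiltration), tolerance = 1e-12)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(co$expression, f2, index_name = "gene")
  back2 <- read_expression_tsv(f2)
  expect_equal(unclass(back2), unclass(co$expression), tolerance = 1e-6)
})
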