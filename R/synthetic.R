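# Seeded generator of complete multi-region cohorts with the statistical
# structure the analysis assumes: Zipf clone abundances with
# class-specific clone-pool overlap, Dirichlet infiltration fractions
# with class-specific dispersion, constructive trunk/shared/private
# mutation trees with Bernoulli neoantigen flags, and log-normal TPM.

# TRB V/J gene names used for synthetic clonotypes, so that real AIRR
# tooling can parse generator output.
trbv_genes <- function() c(
  "TRBV2", "TRBV3-1", "TRBV4-1", "TRBV5-1", "TRBV6-1", "TRBV7-2",
  "TRBV9", "TRBV10-3", "TRBV11-2", "TRBV12-3", "TRBV13", "TRBV14",
  "TRBV15", "TRBV16", "TRBV18", "TRBV19", "TRBV20-1", "TRBV24-1",
  "TRBV25-1", "TRBV27", "TRBV28", "TRBV29-1", "TRBV30")

trbj_genes <- function() c(
  "TRBJ1-1", "TRBJ1-2", "TRBJ1-3", "TRBJ1-4", "TRBJ1-5", "TRBJ1-6",
  "TRBJ2-1", "TRBJ2-2", "TRBJ2-3", "TRBJ2-4", "TRBJ2-5", "TRBJ2-6",
  "TRBJ2-7")

# n random CDR3-beta-like clonotype identities (junction, v, j).
#' @noRd
random_clonotypes <- function(n) {
  if (n == 0)
    return(data.frame(junction_aa = character(), v_call = character(),
                      j_call = character(), stringsAsFactors = FALSE))
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  core_len <- sample(6:10, n, replace = TRUE)
  core <- vapply(core_len, function(k)
    paste(sample(aa, k, replace = TRUE), collapse = ""), "")
  data.frame(junction_aa = paste0("CASS", core, "F"),
             v_call = sample(trbv_genes(), n, replace = TRUE),
             j_call = sample(trbj_genes(), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Zipf(s) clone-size probabilities for S ranks.
#' @noRd
zipf_probs <- function(s, n) {
  p <- (1 / seq_len(n))^s
  p / sum(p)
}

# Multinomial read counts for `ids` rows: Zipf ranks assigned uniformly
# at random among the clones, then reads drawn at the given depth.
# Clones receiving zero reads are unobserved and dropped.
#' @noRd
zipf_counts <- function(n_clones, zipf_s, depth) {
  p <- zipf_probs(zipf_s, n_clones)[sample.int(n_clones)]
  as.integer(stats::rmultinom(1, depth, p))
}

#' Simulate one TCR repertoire
#'
#' Clonotype identities are drawn as a `mix_weight` share from a shared
#' clone pool (uniformly, without replacement) and the rest fresh;
#' abundances follow a Zipf(`zipf_s`) law with ranks assigned uniformly,
#' and reads are multinomial at `depth`. Clones drawing zero reads are
#' unobserved, so the returned richness can fall below `richness` when
#' `depth` is small relative to it.
#'
#' @param richness Number of clonotypes drawn.
#' @param zipf_s Zipf exponent of the clone-size law.
#' @param depth Total reads.
#' @param clone_pool Data frame of pool clonotypes (`junction_aa`,
#'   `v_call`, `j_call`), or `NULL` for a fully fresh repertoire.
#' @param mix_weight Share of clones drawn from the pool, in `[0, 1]`.
#' @param seed Seed.
#' @param sample_id Sample id for the returned table.
#' @return A [clonotype_table()].
#' @export
simulate_repertoire <- function(richness, zipf_s, depth, clone_pool = NULL,
                                mix_weight = 0, seed = 1L,
                                sample_id = "sample") {
  stopifnot(mix_weight >= 0, mix_weight <= 1)
  with_seed(seed, {
    n_pool <- round(mix_weight * richness)
    if (n_pool > 0) {
      if (is.null(clone_pool) || nrow(clone_pool) < n_pool)
        stopf("clone pool too small: need %d clonotypes", n_pool)
      shared <- clone_pool[sample.int(nrow(clone_pool), n_pool), , drop = FALSE]
    } else {
      shared <- random_clonotypes(0)
    }
    fresh <- random_clonotypes(richness - n_pool)
    ids <- rbind(shared, fresh)
    if (depth < richness)
      warnf("depth %d below richness %d: some clones will be unobserved",
            depth, richness)
    counts <- zipf_counts(nrow(ids), zipf_s, depth)
    keep <- counts > 0
    clonotype_table(sample_id, ids$junction_aa[keep], ids$v_call[keep],
                    ids$j_call[keep], counts[keep])
  })
}

# ---- arc-overlap machinery ---------------------------------------------
# Samples of a tissue class share clones through a patient-level pool.
# The pool is split into `n_bands` bands; each pool clone has a position
# on the unit circle, and a sample includes the clones of band b lying
# within an arc of width w centred at the sample's band-b centre. Band
# centres derive from the sample's latent position plus independent
# per-band noise, so with independent samples the expected intersection
# of a same-class pair is pool_size * w^2 (as for independent mixing)
# while averaging over bands keeps the pair-to-pair variance low; with
# the cohort coupling switched on, all band centres move together with
# the latent position and sharing decays with latent divergence.

n_pool_bands <- 8L

#' @noRd
circ_dist <- function(a, b) {
  d <- abs(a - b) %% 1
  pmin(d, 1 - d)
}

# Band assignment and positions for a patient clone pool.
#' @noRd
pool_coords <- function(pool_size) {
  data.frame(pos = stats::runif(pool_size),
             band = sample.int(n_pool_bands, pool_size, replace = TRUE))
}

# Band centres for one sample: latent position u plus per-band noise
# scaled by (1 - coupling), wrapped on the circle.
#' @noRd
band_centres <- function(u, coupling) {
  (u + (1 - coupling) * stats::runif(n_pool_bands)) %% 1
}

# Pool-row indices a sample includes: per band, the clones within the
# arc of width w centred at that band's centre.
#' @noRd
arc_members <- function(pool, centres, w) {
  which(circ_dist(pool$pos, centres[pool$band]) <= w / 2)
}

# One sample's clone identities: arc members (subsampled if they exceed
# `richness`) topped up with fresh clones.
#' @noRd
arc_sample_ids <- function(pool, centres, w, richness) {
  idx <- arc_members(pool, centres, w)
  if (length(idx) > richness) idx <- sample(idx, richness)
  shared <- pool[idx, c("junction_aa", "v_call", "j_call"), drop = FALSE]
  rbind(shared, random_clonotypes(richness - length(idx)))
}

# Mean observed Jaccard between two independent same-class samples at
# arc width w, simulated under the banded mechanism with integer clone
# ids.
#' @noRd
sim_pair_jaccard <- function(w, richness, pool_size, zipf_s, depth, n_rep) {
  mean(vapply(seq_len(n_rep), function(r) {
    pool <- pool_coords(pool_size)
    obs <- lapply(1:2, function(k) {
      idx <- arc_members(pool, band_centres(stats::runif(1), 0), w)
      if (length(idx) > richness) idx <- sample(idx, richness)
      n_fresh <- richness - length(idx)
      # fresh clones get ids disjoint from the pool and the other sample
      ids <- c(idx, if (n_fresh > 0) -seq_len(n_fresh) - k * 10 * richness)
      counts <- zipf_counts(length(ids), zipf_s, depth)
      ids[counts > 0]
    })
    inter <- sum(obs[[1]] %in% obs[[2]])
    inter / (length(obs[[1]]) + length(obs[[2]]) - inter)
  }, numeric(1)))
}

#' Calibrate the clone-pool arc width for a target Jaccard index
#'
#' The observed Jaccard between two samples depends on depth truncation
#' as well as on the share of pooled clones, so the mapping from target
#' Jaccard to arc width (the pool mixing parameter) is built empirically:
#' mean observed Jaccard is simulated over a grid of widths and inverted
#' by monotone interpolation.
#'
#' @param target_jaccard Target mean observed Jaccard for same-class
#'   pairs.
#' @param richness,zipf_s,depth Repertoire parameters of the class.
#' @param pool_size Patient clone-pool size.
#' @param n_rep Simulated pairs per grid point (default 20).
#' @param seed Seed.
#' @return Arc width in `(0, 1)`.
#' @export
calibrate_overlap_width <- function(target_jaccard, richness, zipf_s, depth,
                                    pool_size = 600, n_rep = 50, seed = 1L) {
  with_seed(seed, {
    grid <- seq(0.02, 0.95, length.out = 20)
    j <- vapply(grid, sim_pair_jaccard, numeric(1), richness = richness,
                pool_size = pool_size, zipf_s = zipf_s, depth = depth,
                n_rep = n_rep)
    # least-squares monotone smoothing of the noisy calibration curve
    j <- stats::isoreg(grid, j)$yf
    if (target_jaccard > max(j))
      stopf("target Jaccard %.3f not achievable (max %.3f at width %.2f)",
            target_jaccard, max(j), grid[which.max(j)])
    stats::approx(j, grid, xout = target_jaccard, ties = "ordered")$y
  })
}

#' Simulate Dirichlet infiltration fractions
#'
#' Rows are independent Dirichlet draws with concentration vector
#' `alpha`; higher total concentration gives rows closer to the mean
#' profile (lower between-sample divergence).
#'
#' @param alpha Concentration vector (length 22 for the standard cell
#'   panel; a scalar is recycled).
#' @param n Number of samples.
#' @param seed Seed.
#' @param sample_ids Optional row names.
#' @return Matrix of fractions with rows summing to 1.
#' @export
simulate_infiltration <- function(alpha, n, seed = 1L, sample_ids = NULL) {
  k <- if (length(alpha) == 1) 22 else length(alpha)
  alpha <- rep_len(alpha, k)
  with_seed(seed, {
    g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
    m <- g / rowSums(g)
    rownames(m) <- sample_ids %||% paste0("S", seq_len(n))
    colnames(m) <- if (k == 22) immune_cell_types() else paste0("C", seq_len(k))
    m
  })
}

# Mean infiltration profile the class concentrations scale (sums to 1);
# loosely shaped like deconvolution output: macrophages and resting
# CD4 memory cells dominate, naive/rare subsets are small.
#' @noRd
base_infiltration_profile <- function() {
  p <- c(0.05, 0.03, 0.06, 0.01, 0.02, 0.12, 0.04, 0.10, 0.05, 0.05,
         0.02, 0.10, 0.05, 0.09, 0.04, 0.01, 0.04, 0.03, 0.01, 0.03,
         0.03, 0.02)
  names(p) <- immune_cell_types()
  p / sum(p)
}

#' Simulate a patient's mutation tree with exact class counts
#'
#' Constructs `trunk` variants present in all tumour samples, `shared`
#' variants present in at least two but not all, and `private` variants
#' present in exactly one, by placement (not rejection), so
#' [classify_mutations()] recovers the configured counts exactly.
#' Carrier subsets for shared and private variants are the samples whose
#' latent position is nearest the variant's random position, which ties
#' neoantigen overlap to the latent divergence used for TCR sharing when
#' the cohort coupling is switched on. Neoantigen flags are Bernoulli
#' draws restricted to non-synonymous variants.
#'
#' @param tumour_samples Character vector of tumour sample ids.
#' @param trunk,shared,private Exact class counts (shared needs at least
#'   3 tumour samples).
#' @param neoantigen_rate Probability a non-synonymous variant is flagged.
#' @param patient_id Patient id.
#' @param latent_pos Latent circle positions of the tumour samples
#'   (defaults to independent uniforms).
#' @param seed Seed.
#' @return A [mutation_table()].
#' @export
simulate_mutation_tree <- function(tumour_samples, trunk, shared, private,
                                   neoantigen_rate = 0.3, patient_id = "P1",
                                   latent_pos = NULL, seed = 1L) {
  n <- length(tumour_samples)
  if (shared > 0 && n < 3)
    stopf("shared variants need at least 3 tumour samples (got %d)", n)
  if ((trunk > 0 || private > 0) && n < 1)
    stopf("no tumour samples")
  with_seed(seed, {
    if (is.null(latent_pos)) latent_pos <- stats::runif(n)
    total <- trunk + shared + private
    cls_plan <- rep(c("trunk", "shared", "private"), c(trunk, shared, private))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, total, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    vc_pool <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
                 "Frame_Shift_Ins", "In_Frame_Del", "Splice_Site",
                 "Silent", "Intron", "3'UTR")
    vc <- sample(vc_pool, total, replace = TRUE,
                 prob = c(0.50, 0.06, 0.05, 0.04, 0.03, 0.05, 0.15, 0.07, 0.05))
    b <- stats::runif(total)
    carriers <- lapply(seq_len(total), function(i) {
      switch(cls_plan[i],
             trunk = tumour_samples,
             private = tumour_samples[which.min(circ_dist(latent_pos, b[i]))],
             shared = {
               k <- if (n == 3) 2 else sample(2:(n - 1), 1)
               tumour_samples[order(circ_dist(latent_pos, b[i]))[seq_len(k)]]
             })
    })
    nonsyn <- vc %in% nonsynonymous_classes()
    df <- data.frame(patient_id = patient_id,
                     chrom = as.character(sample(1:22, total, replace = TRUE)),
                     pos = sample.int(1e8, total),
                     ref = ref, alt = alt,
                     gene = sprintf("GENE%04d", sample.int(5000, total,
                                                           replace = TRUE)),
                     variant_classification = vc,
                     stringsAsFactors = FALSE)
    df$samples <- carriers
    df$is_neoantigen <- nonsyn & stats::runif(total) < neoantigen_rate
    mutation_table(df)
  })
}

#' Simulate log-normal TPM expression
#'
#' Per-gene log-normal TPM with a class-specific location shift for a
#' "metastasis-modulated" gene subset (by default the immunomodulator
#' panel, emulating heavier immunomodulation in metastases).
#'
#' @param sheet A [sample_sheet()] (blood samples get no expression).
#' @param genes Character vector of gene symbols.
#' @param modulated Subset of `genes` up-shifted in metastasis samples.
#' @param meanlog,sdlog Baseline log-normal parameters.
#' @param metastasis_shift Added to `meanlog` of modulated genes in
#'   metastasis samples.
#' @param seed Seed.
#' @return An [expression_matrix()] (genes x non-blood samples).
#' @export
simulate_expression <- function(sheet, genes, modulated = character(),
                                meanlog = 2.5, sdlog = 0.6,
                                metastasis_shift = 1, seed = 1L) {
  ids <- sheet$sample_id[sheet$tissue_class != "blood"]
  cls <- sheet$tissue_class[match(ids, sheet$sample_id)]
  with_seed(seed, {
    gene_mu <- stats::rnorm(length(genes), meanlog, 0.8)
    mu <- matrix(gene_mu, length(genes), length(ids))
    mu[genes %in% modulated, cls == "metastasis"] <-
      mu[genes %in% modulated, cls == "metastasis"] + metastasis_shift
    m <- matrix(stats::rlnorm(length(mu), meanlog = mu, sdlog = sdlog),
                nrow = length(genes), dimnames = list(genes, ids))
    expression_matrix(m)
  })
}

# Copy-number segments: 22 chromosomes of 1e8 bp (a down-scaled synthetic
# genome), each split into 1-4 segments; a segment is aberrant with a
# class-specific probability.
#' @noRd
simulate_segments <- function(sheet, aberrant_frac, seed = 1L) {
  ids <- sheet$sample_id[sheet$tissue_class != "blood"]
  cls <- sheet$tissue_class[match(ids, sheet$sample_id)]
  chrom_len <- 1e8
  with_seed(seed, {
    rows <- list()
    for (k in seq_along(ids)) {
      p_ab <- aberrant_frac[[cls[k]]] %||% 0
      for (chr in 1:22) {
        n_seg <- sample(1:4, 1)
        cuts <- sort(sample.int(chrom_len - 1, n_seg - 1))
        bounds <- c(0, cuts, chrom_len)
        for (s in seq_len(n_seg)) {
          aberrant <- stats::runif(1) < p_ab
          cn <- if (aberrant) {
            if (stats::runif(1) < 0.5) stats::runif(1, 0, 1)
            else stats::runif(1, 3, 5.5)
          } else {
            stats::runif(1, 1.6, 2.4)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = ids[k], chrom = as.character(chr),
            start = bounds[s], end = bounds[s + 1],
            adjusted_cn = round(cn, 3), stringsAsFactors = FALSE)
        }
      }
    }
    segment_table(do.call(rbind, rows))
  })
}

#' Cohort generator configuration
#'
#' Defaults describe a five-patient multi-region gastro-oesophageal
#' cohort at desk scale: per patient 2 normal, 3 primary, 3 metastatic
#' and 1 blood sample; metastases have the richest, most even
#' repertoires and the most dispersed infiltration; clonotype-sharing
#' targets put intra-primary sharing (0.10) well above inter-metastasis
#' sharing (0.04). `coupling` in `[0, 1]` ties TCR and neoantigen
#' overlap to a common per-patient latent divergence (0 = independent
#' modalities, 1 = fully coupled).
#'
#' @param n_patients Number of patients.
#' @param samples_per_patient Named counts for normal/primary/metastasis/
#'   blood.
#' @param richness,zipf_s Named per-class repertoire parameters.
#' @param depth Reads per repertoire.
#' @param overlap_targets Target same-class observed Jaccard per tissue
#'   class.
#' @param blood_top_rate Probability a tissue sample's top clone enters
#'   the blood repertoire, per class.
#' @param dirichlet_conc Infiltration Dirichlet concentration per class.
#' @param n_mutations,trunk_frac,shared_frac,private_frac Mutation-tree
#'   size and class fractions (fractions must sum to 1).
#' @param neoantigen_rate Bernoulli flag rate for non-synonymous variants.
#' @param coupling Latent-divergence coupling in `[0, 1]`.
#' @param aberrant_frac Per-class probability that a copy-number segment
#'   is aberrant.
#' @param pool_size Patient clone-pool size.
#' @param n_background_genes Unmodulated filler genes in the expression
#'   matrix.
#' @param seed Master seed; all stages derive named sub-streams from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 5,
                          samples_per_patient = c(normal = 2, primary = 3,
                                                  metastasis = 3, blood = 1),
                          richness = c(normal = 450, primary = 450,
                                       metastasis = 600, blood = 300),
                          zipf_s = c(normal = 1.0, primary = 1.1,
                                     metastasis = 0.8, blood = 1.2),
                          depth = 4000,
                          overlap_targets = c(normal = 0.08, primary = 0.10,
                                              metastasis = 0.04),
                          blood_top_rate = c(normal = 0.19, primary = 0.38,
                                             metastasis = 0.565),
                          dirichlet_conc = c(normal = 100, primary = 50,
                                             metastasis = 2),
                          n_mutations = 60, trunk_frac = 0.4,
                          shared_frac = 0.25, private_frac = 0.35,
                          neoantigen_rate = 0.4, coupling = 0,
                          aberrant_frac = c(normal = 0.02, primary = 0.25,
                                            metastasis = 0.4),
                          pool_size = 600, n_background_genes = 60,
                          seed = 1L) {
  fr <- c(trunk_frac, shared_frac, private_frac)
  if (abs(sum(fr) - 1) > 1e-8)
    stopf("mutation class fractions must sum to 1 (got %.4f)", sum(fr))
  if (any(fr < 0) || coupling < 0 || coupling > 1)
    stopf("fractions must lie in [0, 1]")
  if (any(samples_per_patient < 0) || n_patients < 1 || depth < 1)
    stopf("counts must be positive")
  structure(list(n_patients = n_patients,
                 samples_per_patient = samples_per_patient,
                 richness = richness, zipf_s = zipf_s, depth = depth,
                 overlap_targets = overlap_targets,
                 blood_top_rate = blood_top_rate,
                 dirichlet_conc = dirichlet_conc,
                 n_mutations = n_mutations, trunk_frac = trunk_frac,
                 shared_frac = shared_frac, private_frac = private_frac,
                 neoantigen_rate = neoantigen_rate, coupling = coupling,
                 aberrant_frac = aberrant_frac, pool_size = pool_size,
                 n_background_genes = n_background_genes,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a complete multi-region cohort
#'
#' Generates the sample sheet, per-sample TCR repertoires, infiltration
#' and expression matrices, mutation and segment tables, and a ground
#' truth record, all deterministically from `config$seed`. Use
#' [write_cohort()] to lay the bundle out on disk as the file formats
#' the readers consume.
#'
#' @param config A [cohort_config()].
#' @return List with elements `sheet`, `repertoires` (named list of
#'   [clonotype_table()]), `infiltration`, `expression`, `mutations`,
#'   `segments`, `truth`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- config$seed
  spp <- config$samples_per_patient
  met_sites <- c("lymph node", "liver", "peritoneum", "ovary")

  # sample sheet ---------------------------------------------------------
  rows <- list()
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    add <- function(class, i, site) {
      code <- c(normal = "N", primary = "T", metastasis = "M", blood = "B")
      data.frame(sample_id = sprintf("%s_%s%d", pid, code[[class]], i),
                 patient_id = pid, tissue_class = class, site_label = site,
                 stringsAsFactors = FALSE)
    }
    for (i in seq_len(spp[["normal"]]))
      rows[[length(rows) + 1L]] <- add("normal", i, "gastric normal")
    for (i in seq_len(spp[["primary"]]))
      rows[[length(rows) + 1L]] <- add("primary", i, "gastric primary")
    for (i in seq_len(spp[["metastasis"]]))
      rows[[length(rows) + 1L]] <- add("metastasis", i,
                                       met_sites[(i - 1) %% length(met_sites) + 1])
    for (i in seq_len(spp[["blood"]]))
      rows[[length(rows) + 1L]] <- add("blood", i, "peripheral blood")
  }
  sheet <- do.call(rbind, rows)
  tcf_mean <- c(normal = 0.30, primary = 0.25, metastasis = 0.15, blood = 0.60)
  sheet$t_cell_fraction <- with_seed(derive_seed(seed, "tcf"), {
    m <- tcf_mean[sheet$tissue_class]
    round(stats::rbeta(nrow(sheet), m * 50, (1 - m) * 50), 4)
  })
  sheet <- sample_sheet(sheet)

  # arc widths calibrated to the class sharing targets --------------------
  widths <- vapply(names(config$overlap_targets), function(cl)
    calibrate_overlap_width(config$overlap_targets[[cl]],
                            richness = config$richness[[cl]],
                            zipf_s = config$zipf_s[[cl]],
                            depth = config$depth,
                            pool_size = config$pool_size,
                            seed = derive_seed(seed, paste0("cal_", cl))),
    numeric(1))

  # repertoires, mutations -----------------------------------------------
  repertoires <- list()
  mut_list <- list()
  truth_counts <- list()
  latent <- list()
  gamma <- config$coupling
  for (pid in unique(sheet$patient_id)) {
    psheet <- sheet[sheet$patient_id == pid, , drop = FALSE]
    pseed <- derive_seed(seed, paste0("patient_", pid))
    pool <- with_seed(derive_seed(pseed, "pool"), {
      cbind(random_clonotypes(config$pool_size),
            pool_coords(config$pool_size))
    })
    nonblood <- psheet[psheet$tissue_class != "blood", , drop = FALSE]
    u <- with_seed(derive_seed(pseed, "latent"),
                   stats::runif(nrow(nonblood)))
    names(u) <- nonblood$sample_id
    centres_tcr <- with_seed(derive_seed(pseed, "vtcr"),
                             lapply(u, band_centres, coupling = gamma))
    v_neo <- with_seed(derive_seed(pseed, "vneo"),
                       (u + (1 - gamma) * stats::runif(length(u))) %% 1)
    latent[[pid]] <- list(u = u, v_neo = v_neo)

    for (k in seq_len(nrow(nonblood))) {
      sid <- nonblood$sample_id[k]
      cl <- nonblood$tissue_class[k]
      repertoires[[sid]] <- with_seed(derive_seed(pseed, paste0("rep_", sid)), {
        ids <- arc_sample_ids(pool, centres_tcr[[sid]], widths[[cl]],
                              config$richness[[cl]])
        counts <- zipf_counts(nrow(ids), config$zipf_s[[cl]], config$depth)
        keep <- counts > 0
        clonotype_table(sid, ids$junction_aa[keep], ids$v_call[keep],
                        ids$j_call[keep], counts[keep])
      })
    }

    # blood: own clones plus tissue top clones at class-specific rates
    for (sid in psheet$sample_id[psheet$tissue_class == "blood"]) {
      repertoires[[sid]] <- with_seed(derive_seed(pseed, paste0("rep_", sid)), {
        picked <- list()
        for (k in seq_len(nrow(nonblood))) {
          tt <- repertoires[[nonblood$sample_id[k]]]$clonotypes
          top <- utils::head(tt, 100)
          rate <- config$blood_top_rate[[nonblood$tissue_class[k]]]
          picked[[k]] <- top[stats::runif(nrow(top)) < rate,
                             c("junction_aa", "v_call", "j_call")]
        }
        shared <- unique(do.call(rbind, picked))
        n_fresh <- max(0, config$richness[["blood"]] - nrow(shared))
        ids <- rbind(shared, random_clonotypes(n_fresh))
        counts <- zipf_counts(nrow(ids), config$zipf_s[["blood"]],
                              config$depth)
        keep <- counts > 0
        clonotype_table(sid, ids$junction_aa[keep], ids$v_call[keep],
                        ids$j_call[keep], counts[keep])
      })
    }

    tum <- psheet$sample_id[psheet$tissue_class %in% c("primary", "metastasis")]
    counts <- round(config$n_mutations *
                      c(config$trunk_frac, config$shared_frac,
                        config$private_frac))
    mut_list[[pid]] <- simulate_mutation_tree(
      tum, trunk = counts[1], shared = counts[2], private = counts[3],
      neoantigen_rate = config$neoantigen_rate, patient_id = pid,
      latent_pos = v_neo[tum], seed = derive_seed(pseed, "mut"))
    truth_counts[[pid]] <- c(trunk = counts[1], shared = counts[2],
                             private = counts[3])
  }
  mutations <- mutation_table(do.call(rbind, mut_list), sheet = sheet)

  # infiltration ----------------------------------------------------------
  nonblood <- sheet[sheet$tissue_class != "blood", , drop = FALSE]
  base <- base_infiltration_profile()
  infl <- do.call(rbind, lapply(seq_len(nrow(nonblood)), function(k) {
    cl <- nonblood$tissue_class[k]
    simulate_infiltration(config$dirichlet_conc[[cl]] * base * 22, n = 1,
                          seed = derive_seed(seed, paste0("infl_",
                                                          nonblood$sample_id[k])),
                          sample_ids = nonblood$sample_id[k])
  }))
  infl <- infiltration_matrix(infl, renormalize = TRUE)

  # expression ------------------------------------------------------------
  panel <- immunomodulator_genes()$gene
  extra <- unique(c("GZMA", "PRF1", unname(biomarker_genes())))
  genes <- unique(c(panel, extra,
                    sprintf("BG%04d", seq_len(config$n_background_genes))))
  expr <- simulate_expression(sheet, genes, modulated = panel,
                              seed = derive_seed(seed, "expr"))

  segments <- simulate_segments(sheet, as.list(config$aberrant_frac),
                                seed = derive_seed(seed, "seg"))

  list(sheet = sheet, repertoires = repertoires, infiltration = infl,
       expression = expr, mutations = mutations, segments = segments,
       truth = list(config = unclass(config), arc_widths = widths,
                    mutation_counts = truth_counts, latent = latent))
}

#' Write a simulated cohort to disk
#'
#' Lays the bundle out as the external formats the readers consume:
#' `sample_sheet.tsv`, `airr/<sample>.tsv`, `infiltration.tsv`,
#' `expression.tsv`, `mutations.maf`, `segments.seg` and `truth.json`.
#' Output is byte-identical for identical config and seed.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "airr"), recursive = TRUE, showWarnings = FALSE)
  write_sample_sheet(cohort$sheet, file.path(dir, "sample_sheet.tsv"))
  for (sid in names(cohort$repertoires))
    write_airr_tsv(cohort$repertoires[[sid]],
                   file.path(dir, "airr", paste0(sid, ".tsv")))
  write_matrix_tsv(cohort$infiltration, file.path(dir, "infiltration.tsv"),
                   index_name = "sample_id")
  write_matrix_tsv(cohort$expression, file.path(dir, "expression.tsv"),
                   index_name = "gene")
  write_maf(cohort$mutations, file.path(dir, "mutations.maf"))
  write_seg(cohort$segments, file.path(dir, "segments.seg"))
  truth <- cohort$truth
  truth$latent <- lapply(truth$latent, function(l) lapply(l, as.list))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @param renormalize Passed to [read_infiltration_tsv()].
#' @return List with `sheet`, `repertoires`, `infiltration`, `expression`,
#'   `mutations`, `segments` (missing files yield `NULL` entries).
#' @export
read_cohort <- function(dir, renormalize = FALSE) {
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  airr <- list.files(file.path(dir, "airr"), pattern = "\\.tsv(\\.gz)?$",
                     full.names = TRUE)
  repertoires <- lapply(airr, function(f)
    read_airr_tsv(f, sub("\\.tsv(\\.gz)?$", "", basename(f))))
  names(repertoires) <- vapply(repertoires, `[[`, "", "sample_id")
  maybe <- function(f, reader, ...) {
    if (file.exists(file.path(dir, f))) reader(file.path(dir, f), ...) else NULL
  }
  list(sheet = sheet, repertoires = repertoires,
       infiltration = maybe("infiltration.tsv", read_infiltration_tsv,
                            renormalize = renormalize),
       expression = maybe("expression.tsv", read_expression_tsv),
       mutations = if (file.exists(file.path(dir, "mutations.maf")))
         read_maf(file.path(dir, "mutations.maf"), sheet) else NULL,
       segments = maybe("segments.seg", read_seg))
}
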