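#' Configuration for the synthetic trial cohort generator
#'
#' Bundles every knob of the synthetic cohort: sample size, intrinsic
#' subtype mixture, expression noise, the planted ERBB2-vs-17q12
#' copy-number correlation, per-subtype TP53 mutation probabilities, the
#' logistic response model on (proliferation, -ERBB2, TP53), and the
#' baseline/day-21 biopsy dynamics. Defaults emulate the shape of a
#' window-of-opportunity HR+/HER2- cohort: 77 patients, a luminal-heavy
#' subtype mixture, ~18% TP53 prevalence, ~34% CelTIL response, and an
#' ERBB2/17q12 correlation of 0.55.
#'
#' @param n_patients Cohort size (default 77).
#' @param subtype_mix Named mixture proportions over `LumA`, `LumB`,
#'   `Her2E`, `Basal`, `Normal`; must sum to 1.
#' @param noise_sd Per-gene expression noise SD on the log2 scale (> 0).
#' @param latent_sd SD of the per-sample proliferation/luminal latent
#'   deviations around their subtype means.
#' @param erbb2_sd,seg17q12_sd SDs of the ERBB2 expression latent and of
#'   the 17q12 copy-number signal.
#' @param erbb2_17q12_correlation Planted Pearson correlation between the
#'   ERBB2 expression latent and the 17q12 segment signal (|rho| < 1).
#' @param tp53_prob Named per-subtype TP53 mutation probabilities.
#' @param mutation_rates Named background somatic mutation probabilities
#'   for the remaining recurrent genes (independent of response).
#' @param beta0,beta_prolif,beta_erbb2,beta_tp53 Logistic response-model
#'   coefficients: `eta = beta0 + beta_prolif * prolif + beta_erbb2 *
#'   (-erbb2) + beta_tp53 * tp53`.
#' @param responder_delta_mean,responder_delta_sd Scaled-CelTIL change
#'   distribution for responders (truncated to land at or above 20).
#' @param nonresponder_delta_mean,nonresponder_delta_sd As above for
#'   non-responders (truncated below 20).
#' @param immune_effect Direct expression shift (log2) of the immune
#'   module in responders.
#' @param clinical_response_rates Named probabilities of clinical response
#'   given CelTIL responder / non-responder status.
#' @param her2_ihc_props Named marginal proportions of HER2 IHC `0`, `1+`,
#'   `2+` (labels are driven by the ERBB2 latent plus noise, cut at these
#'   quantiles).
#' @param cluster_noise Probability that a sample's copy-number cluster is
#'   reassigned uniformly at random instead of following its subtype.
#' @param cn_noise SD of segment-level copy-number noise.
#' @param artifact_rate Expected number of filter-failing artifact variant
#'   records per sample (Poisson).
#' @param hk_level Expected housekeeping count level.
#' @param n_segments,n_signatures,cn_model_seed Size and seed of the
#'   synthetic copy-number model (see [synthetic_cn_model()]).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(
    n_patients = 77,
    subtype_mix = c(LumA = 0.57, LumB = 0.20, Her2E = 0.12, Basal = 0.06, Normal = 0.05),
    noise_sd = 0.5,
    latent_sd = 0.4,
    erbb2_sd = 0.8,
    seg17q12_sd = 0.6,
    erbb2_17q12_correlation = 0.55,
    tp53_prob = c(LumA = 0.107, LumB = 0.2, Her2E = 0.2, Basal = 1.0, Normal = 0.1),
    mutation_rates = c(PIK3CA = 0.33, GATA3 = 0.29, ATM = 0.24, CDH1 = 0.20,
                       KMT2C = 0.16, KMT2D = 0.16, MAP3K1 = 0.14, ERBB2 = 0.082),
    beta0 = -1.0,
    beta_prolif = 1.3,
    beta_erbb2 = 1.2,
    beta_tp53 = log(4),
    responder_delta_mean = 30,
    responder_delta_sd = 8,
    nonresponder_delta_mean = 0,
    nonresponder_delta_sd = 8,
    immune_effect = 1.0,
    clinical_response_rates = c(responder = 0.55, nonresponder = 0.22),
    her2_ihc_props = c(`0` = 0.32, `1+` = 0.38, `2+` = 0.30),
    cluster_noise = 0.1,
    cn_noise = 0.3,
    artifact_rate = 0.5,
    hk_level = 500,
    n_segments = 40,
    n_signatures = 20,
    cn_model_seed = 101) {
  cfg <- as.list(environment())
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_patients < 1) {
    stop_celtilr("`n_patients` must be >= 1.", "celtilr_validation_error")
  }
  if (abs(sum(cfg$subtype_mix) - 1) > 1e-8 || any(cfg$subtype_mix < 0)) {
    stop_celtilr("`subtype_mix` must be non-negative and sum to 1.",
                 "celtilr_validation_error")
  }
  if (abs(cfg$erbb2_17q12_correlation) >= 1) {
    stop_celtilr("`erbb2_17q12_correlation` must lie strictly within (-1, 1).",
                 "celtilr_validation_error")
  }
  probs <- c(cfg$tp53_prob, cfg$mutation_rates, cfg$clinical_response_rates,
             cfg$cluster_noise)
  if (any(probs < 0 | probs > 1)) {
    stop_celtilr("Probabilities must lie in [0, 1].", "celtilr_validation_error")
  }
  if (cfg$noise_sd <= 0 || cfg$cn_noise <= 0) {
    stop_celtilr("Noise SDs must be positive.", "celtilr_validation_error")
  }
  missing_subtypes <- setdiff(names(cfg$subtype_mix), names(cfg$tp53_prob))
  if (length(missing_subtypes)) {
    stop_celtilr("`tp53_prob` must cover every subtype in the mixture.",
                 "celtilr_validation_error")
  }
  invisible(cfg)
}

# invert a scaled-CelTIL target back to a feasible (cellularity, TILs) pair:
# clamp the target raw score into [-80, 130], split the change between a
# cellularity drop and a TILs rise, then push residual change into the
# other axis when a bound is hit
solve_day21_biopsy <- function(cell0, tils0, raw_target, share = 0.5) {
  raw1 <- pmin(pmax(raw_target, -80), 130)
  raw0 <- -0.8 * cell0 + 1.3 * tils0
  d <- raw1 - raw0
  cell1 <- pmin(pmax(cell0 - share * d / 0.8, 0), 100)
  tils1 <- (raw1 + 0.8 * cell1) / 1.3
  hit <- tils1 < 0 | tils1 > 100
  tils1 <- pmin(pmax(tils1, 0), 100)
  cell1[hit] <- pmin(pmax((1.3 * tils1[hit] - raw1[hit]) / 0.8, 0), 100)
  list(cellularity = cell1, tils = tils1)
}

#' Generate a synthetic trial-shaped cohort
#'
#' Draws a full synthetic dataset with planted effect structure:
#' intrinsic subtypes from the configured mixture; 192-gene panel counts
#' with subtype/module structure and housekeeping baselines; a 17q12
#' copy-number signal jointly drawn with the ERBB2 expression latent at
#' the target correlation; TP53 mutations enriched in Basal-like samples;
#' CelTIL responder status from a logistic model on proliferation,
#' -ERBB2 and TP53; and day-21 biopsies whose scaled-CelTIL change
#' concentrates at or above 20 points for responders and below for
#' non-responders. Fully reproducible given `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (the caller's RNG state is preserved).
#' @return A `cohort_bundle` list: `clinical` (long biopsy table),
#'   `counts` (192-gene count tibble), `seg` (SEG records),
#'   `variants` (somatic calls incl. planted filter-failing artifacts),
#'   `expression_model`, `cn_model_set`, `ground_truth` (per-sample
#'   latent variables and planted labels), `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  validate_cohort_config(config)
  with_local_seed(seed, generate_cohort_impl(config, seed))
}

generate_cohort_impl <- function(cfg, seed) {
  n <- cfg$n_patients
  ids <- sprintf("PT%03d", seq_len(n))
  subtypes <- names(cfg$subtype_mix)
  subtype <- sample(subtypes, n, replace = TRUE, prob = cfg$subtype_mix)
  means <- subtype_module_means()

  prolif <- means[subtype, "prolif"] + rnorm(n, sd = cfg$latent_sd)
  luminal <- means[subtype, "luminal"] + rnorm(n, sd = cfg$latent_sd)
  rho <- cfg$erbb2_17q12_correlation
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  erbb2_z <- cfg$erbb2_sd * z1
  seg17 <- cfg$seg17q12_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
  tp53 <- rbinom(n, 1, cfg$tp53_prob[subtype])

  eta <- cfg$beta0 + cfg$beta_prolif * prolif + cfg$beta_erbb2 * (-erbb2_z) +
    cfg$beta_tp53 * tp53
  response_prob <- plogis(eta)
  responder <- rbinom(n, 1, response_prob) == 1

  # --- expression ------------------------------------------------------
  mods <- panel_modules()
  module_of <- rep(names(mods), lengths(mods))
  genes <- unlist(mods, use.names = FALSE)
  Z <- t(means[subtype, module_of, drop = FALSE])
  rownames(Z) <- genes
  Z[mods$prolif, ] <- matrix(prolif, nrow = length(mods$prolif),
                             ncol = n, byrow = TRUE)
  Z[mods$luminal, ] <- matrix(luminal, nrow = length(mods$luminal),
                              ncol = n, byrow = TRUE)
  Z[mods$immune, ] <- Z[mods$immune, ] +
    matrix(cfg$immune_effect * responder, nrow = length(mods$immune),
           ncol = n, byrow = TRUE)
  Z <- Z + matrix(rnorm(length(Z), sd = cfg$noise_sd), nrow = nrow(Z))
  Z["ERBB2", ] <- erbb2_z + rnorm(n, sd = 0.3 * cfg$noise_sd)
  Z["GRB7", ] <- 0.6 * erbb2_z + rnorm(n, sd = 0.8 * cfg$noise_sd)

  hk <- matrix(
    round(2^(log2(cfg$hk_level) + rnorm(7 * n, sd = 0.1))),
    nrow = 7, dimnames = list(HOUSEKEEPING_GENES, ids)
  )
  lbar <- colMeans(log2(hk + 1))
  counts_mat <- pmax(round(2^sweep(Z, 2, lbar, "+") - 1), 0)
  colnames(counts_mat) <- ids
  counts <- dplyr::bind_rows(
    dplyr::bind_cols(tibble(gene = genes), as_tibble(counts_mat)),
    dplyr::bind_cols(tibble(gene = HOUSEKEEPING_GENES), as_tibble(hk))
  )

  # --- copy number -----------------------------------------------------
  cn_set <- synthetic_cn_model(cfg$n_segments, cfg$n_signatures, cfg$cn_model_seed)
  # cluster-3 captures basal-like biology and the high-proliferation tail,
  # cluster-4 the HER2-enriched tumors, clusters 1/2 the luminal A/B bulk
  cluster_map <- c(LumA = "cluster1", LumB = "cluster2", Her2E = "cluster4",
                   Basal = "cluster3", Normal = "cluster1")
  cluster <- cluster_map[subtype]
  cluster[subtype != "Basal" & prolif > 0.8] <- "cluster3"
  flip <- runif(n) < cfg$cluster_noise
  cluster[flip] <- sample(rownames(cn_set$seg_centroids), sum(flip), replace = TRUE)
  seg_ids <- colnames(cn_set$seg_centroids)
  sig_mat <- cn_set$seg_centroids[cluster, , drop = FALSE] +
    matrix(rnorm(n * length(seg_ids), sd = cfg$cn_noise), nrow = n)
  sig_mat[, "17q12"] <- seg17
  seg <- tibble(
    sample_id = rep(ids, each = length(seg_ids)),
    segment = rep(seg_ids, times = n),
    seg_mean = as.numeric(t(sig_mat))
  ) |>
    dplyr::left_join(cn_set$segments, by = "segment") |>
    dplyr::select("sample_id", "chrom", "start", "end", "seg_mean")

  # --- somatic variants ------------------------------------------------
  variants <- simulate_variants(ids, subtype, tp53, cfg)

  # --- paired biopsies -------------------------------------------------
  cell0 <- 100 * stats::rbeta(n, 2.6, 2.6)
  tils0 <- 100 * stats::rbeta(n, 1.2, 10.8)
  delta_target <- ifelse(
    responder,
    pmin(pmax(rnorm(n, cfg$responder_delta_mean, cfg$responder_delta_sd), 20.5), 60),
    pmin(rnorm(n, cfg$nonresponder_delta_mean, cfg$nonresponder_delta_sd), 19)
  )
  raw0 <- -0.8 * cell0 + 1.3 * tils0
  day21 <- solve_day21_biopsy(cell0, tils0, raw0 + delta_target * 2.1)

  her2_latent <- erbb2_z + rnorm(n, sd = 0.8)
  cuts <- quantile(her2_latent, cumsum(cfg$her2_ihc_props))
  her2_ihc <- cut(her2_latent, breaks = c(-Inf, cuts[1], cuts[2], Inf),
                  labels = names(cfg$her2_ihc_props))
  p_clin <- ifelse(responder, cfg$clinical_response_rates["responder"],
                   cfg$clinical_response_rates["nonresponder"])
  clinical_response <- rbinom(n, 1, p_clin) == 1

  per_sample <- tibble(
    sample_id = ids,
    hr_status = ifelse(subtype == "Basal", "TNBC", "HR+/HER2-"),
    her2_ihc = as.character(her2_ihc),
    clinical_response = clinical_response
  )
  clinical <- dplyr::bind_rows(
    dplyr::mutate(per_sample, timepoint = "baseline",
                  cellularity_pct = cell0, tils_pct = tils0),
    dplyr::mutate(per_sample, timepoint = "day21",
                  cellularity_pct = day21$cellularity, tils_pct = day21$tils)
  ) |>
    dplyr::select("sample_id", "timepoint", "cellularity_pct", "tils_pct",
                  "hr_status", "her2_ihc", "clinical_response") |>
    dplyr::arrange(.data$sample_id, .data$timepoint)

  ground_truth <- tibble(
    sample_id = ids,
    subtype = subtype,
    cluster = unname(cluster),
    prolif_latent = unname(prolif),
    luminal_latent = unname(luminal),
    erbb2_z = erbb2_z,
    seg_17q12 = seg17,
    tp53 = tp53,
    eta = unname(eta),
    response_prob = unname(response_prob),
    responder = responder,
    delta_target = delta_target
  )

  structure(
    list(
      clinical = clinical,
      counts = counts,
      seg = seg,
      variants = variants,
      expression_model = synthetic_expression_model(),
      cn_model_set = cn_set,
      ground_truth = ground_truth,
      config = cfg,
      seed = seed
    ),
    class = "cohort_bundle"
  )
}

# fixed pseudo-coordinates for recurrently mutated genes
mutated_gene_positions <- function() {
  tibble(
    gene = c("TP53", "PIK3CA", "GATA3", "ATM", "CDH1", "KMT2C", "KMT2D",
             "MAP3K1", "ERBB2"),
    chrom = c("17", "3", "10", "11", "16", "7", "12", "5", "17"),
    pos = c(7578406L, 178936091L, 8111563L, 108175462L, 68847258L,
            151874147L, 49431107L, 56177843L, 37880220L)
  )
}

simulate_variants <- function(ids, subtype, tp53, cfg) {
  n <- length(ids)
  pos_tbl <- mutated_gene_positions()
  records <- list()
  add_gene <- function(gene, mutated) {
    idx <- which(mutated)
    if (!length(idx)) return(NULL)
    k <- length(idx)
    info <- pos_tbl[pos_tbl$gene == gene, ]
    is_indel <- runif(k) < 0.15
    vaf0 <- stats::rbeta(k, 6, 14)
    depth0 <- rpois(k, 500)
    alt0 <- pmax(1L, as.integer(round(vaf0 * depth0)))
    tibble(
      sample_id = ids[idx],
      gene = gene,
      chrom = info$chrom,
      pos = info$pos,
      ref = ifelse(is_indel, "AT", "A"),
      alt = ifelse(is_indel, "A", "G"),
      variant_class = ifelse(is_indel, "INDEL", "SNV"),
      alt_reads = alt0,
      depth = depth0,
      vaf = alt0 / depth0,
      population_af = ifelse(runif(k) < 0.2, runif(k) * 1e-4, NA_real_)
    )
  }
  records$TP53 <- add_gene("TP53", tp53 == 1)
  for (g in names(cfg$mutation_rates)) {
    records[[g]] <- add_gene(g, rbinom(n, 1, cfg$mutation_rates[g]) == 1)
  }
  # artifact records designed to fail the filters
  n_art <- rpois(n, cfg$artifact_rate)
  art_idx <- rep(seq_len(n), n_art)
  if (length(art_idx)) {
    kind <- sample(c("low_reads", "low_vaf", "common_snp"), length(art_idx),
                   replace = TRUE, prob = c(0.4, 0.35, 0.25))
    depth0 <- rpois(length(art_idx), 500)
    vaf0 <- dplyr::case_when(
      kind == "low_reads" ~ runif(length(art_idx), 0.001, 0.01),
      kind == "low_vaf" ~ runif(length(art_idx), 0.02, 0.045),
      TRUE ~ runif(length(art_idx), 0.35, 0.65)
    )
    alt0 <- pmax(1L, as.integer(round(vaf0 * depth0)))
    records$artifacts <- tibble(
      sample_id = ids[art_idx],
      gene = sample(panel_modules()$filler, length(art_idx), replace = TRUE),
      chrom = "1",
      pos = 1000000L + seq_along(art_idx),
      ref = "C",
      alt = "T",
      variant_class = "SNV",
      alt_reads = alt0,
      depth = depth0,
      vaf = alt0 / depth0,
      population_af = ifelse(kind == "common_snp",
                             runif(length(art_idx), 0.001, 0.05), NA_real_)
    )
  }
  out <- dplyr::bind_rows(records)
  dplyr::arrange(out, .data$sample_id, .data$gene, .data$pos)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Synthetic cohort bundle:", x$config$n_patients, "patients",
      sprintf("(seed %s)\n", format(x$seed)))
  cat("  counts:", nrow(x$counts), "genes;",
      "seg records:", nrow(x$seg), ";",
      "variant records:", nrow(x$variants), "\n")
  cat("  planted responders:", sum(x$ground_truth$responder), "of",
      nrow(x$ground_truth), "\n")
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Emits the observed files (clinical CSV, counts TSV, SEG, MAF-like
#' mutation TSV), the model files, and `ground_truth.json` holding the
#' per-sample latent variables and the generator configuration. Output is
#' deterministic: two writes of the same bundle are byte-identical.
#'
#' @param bundle A `cohort_bundle` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    clinical = file.path(dir, "clinical.csv"),
    counts = file.path(dir, "counts.tsv"),
    seg = file.path(dir, "copy_number.seg"),
    variants = file.path(dir, "mutations.tsv"),
    centroids = file.path(dir, "expression_centroids.tsv"),
    signatures = file.path(dir, "expression_signatures.tsv"),
    cn_coefficients = file.path(dir, "cn_coefficients.tsv"),
    cn_centroids = file.path(dir, "cn_cluster_centroids.tsv"),
    cn_defs = file.path(dir, "cn_segment_defs.tsv"),
    annotation = file.path(dir, "gene_annotation.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  readr::write_csv(bundle$clinical, paths["clinical"], progress = FALSE)
  readr::write_tsv(bundle$counts, paths["counts"], progress = FALSE)
  seg_out <- tibble(
    ID = bundle$seg$sample_id, chrom = bundle$seg$chrom,
    loc.start = bundle$seg$start, loc.end = bundle$seg$end,
    seg.mean = bundle$seg$seg_mean
  )
  readr::write_tsv(seg_out, paths["seg"], progress = FALSE)
  maf_out <- tibble(
    Tumor_Sample_Barcode = bundle$variants$sample_id,
    Hugo_Symbol = bundle$variants$gene,
    Chromosome = bundle$variants$chrom,
    Start_Position = bundle$variants$pos,
    Reference_Allele = bundle$variants$ref,
    Tumor_Seq_Allele2 = bundle$variants$alt,
    Variant_Type = ifelse(bundle$variants$variant_class == "INDEL",
                          "INDEL", "SNP"),
    t_alt_count = bundle$variants$alt_reads,
    t_depth = bundle$variants$depth,
    gnomAD_AF = bundle$variants$population_af
  )
  readr::write_tsv(maf_out, paths["variants"], progress = FALSE)
  readr::write_tsv(bundle$expression_model$centroids, paths["centroids"],
                   progress = FALSE)
  readr::write_tsv(bundle$expression_model$signatures, paths["signatures"],
                   progress = FALSE)
  cn <- bundle$cn_model_set
  coef_tbl <- dplyr::bind_cols(
    tibble(signature = rownames(cn$model$coefficients)),
    as_tibble(cn$model$coefficients)
  )
  readr::write_tsv(coef_tbl, paths["cn_coefficients"], progress = FALSE)
  cent_tbl <- dplyr::bind_cols(
    tibble(cluster = rownames(cn$model$centroids)),
    as_tibble(cn$model$centroids)
  )
  readr::write_tsv(cent_tbl, paths["cn_centroids"], progress = FALSE)
  readr::write_tsv(cn$defs, paths["cn_defs"], progress = FALSE)
  readr::write_tsv(cn$annotation, paths["annotation"], progress = FALSE)
  jsonlite::write_json(
    list(
      seed = bundle$seed,
      config = unclass(bundle$config),
      samples = bundle$ground_truth,
      seg_centroids = as.data.frame(cn$seg_centroids),
      segments = cn$segments
    ),
    paths["ground_truth"], digits = NA, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}

#' Read a bundle directory back into memory
#'
#' Inverse of [write_bundle()]: re-reads the observed tables, model files
#' and ground truth from a bundle directory.
#'
#' @param dir Directory written by [write_bundle()].
#' @return A `cohort_bundle` list with the same structure as
#'   [generate_cohort()] output.
#' @export
read_bundle <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  coef_tbl <- readr::read_tsv(file.path(dir, "cn_coefficients.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  coefs <- as.matrix(coef_tbl[-1])
  rownames(coefs) <- coef_tbl$signature
  cent_tbl <- readr::read_tsv(file.path(dir, "cn_cluster_centroids.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  cents <- as.matrix(cent_tbl[-1])
  rownames(cents) <- cent_tbl$cluster
  seg_centroids <- as.matrix(gt$seg_centroids)
  rownames(seg_centroids) <- rownames(cents)
  cfg <- gt$config
  cfg_args <- cfg[names(cfg) %in% names(formals(cohort_config))]
  config <- do.call(cohort_config, cfg_args)
  structure(
    list(
      clinical = read_clinical(file.path(dir, "clinical.csv")),
      counts = read_counts(file.path(dir, "counts.tsv")),
      seg = read_seg(file.path(dir, "copy_number.seg")),
      variants = read_maf(file.path(dir, "mutations.tsv")),
      expression_model = list(
        centroids = read_centroids(file.path(dir, "expression_centroids.tsv")),
        signatures = read_signatures(file.path(dir, "expression_signatures.tsv"))
      ),
      cn_model_set = list(
        model = cn_model(coefs, cents),
        defs = readr::read_tsv(file.path(dir, "cn_segment_defs.tsv"),
                               show_col_types = FALSE, progress = FALSE),
        annotation = read_gene_annotation(file.path(dir, "gene_annotation.tsv")),
        segments = as_tibble(gt$segments),
        seg_centroids = seg_centroids
      ),
      ground_truth = as_tibble(gt$samples),
      config = config,
      seed = gt$seed
    ),
    class = "cohort_bundle"
  )
}
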