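test_that("each filter rule drops its offending record from the six-record fixture", {
  v <- toy_variants()
  res <- filter_variants(v)
  # hand application of the rules:
  #  s1: 3 alt reads < 7              -> dropped (read support)
  #  s2: SNV vaf 0.06 >= 0.05         -> kept
  #  s3: SNV vaf 0.20                 -> kept
  #  s4: INDEL vaf 0.08 < 0.10        -> dropped (vaf)
  #  s5: INDEL vaf 0.12               -> kept
  #  s6: population AF 0.01 > 1e-4    -> dropped (population)
  expect_equal(res$sample_id, c("s2", "s3", "s5"))
  drops <- variant_filter_summary(res)
  expect_equal(drops$n_dropped[drops$rule == "alt_reads"], 1L)
  expect_equal(drops$n_dropped[drops$rule == "vaf"], 1L)
  expect_equal(drops$n_dropped[drops$rule == "population_af"], 1L)
})

test_that("all filter thresholds are inclusive", {
  boundary <- tibble::tibble(
    sample_id = "s", gene = "G", chrom = "1", pos = 1L, ref = "A", alt = "G",
    variant_class = "SNV", alt_reads = 7L, depth = 140L, vaf = 0.05,
    population_af = 1e-4
  )
  expect_equal(nrow(filter_variants(boundary)), 1L)
  indel <- dplyr::mutate(boundary, variant_class = "INDEL", vaf = 0.10)
  expect_equal(nrow(filter_variants(indel)), 1L)
})

test_that("filtering is idempotent and monotone in its thresholds", {
  set.seed(31)
  n <- 200
  v <- tibble::tibble(
    sample_id = paste0("s", sample(20, n, replace = TRUE)),
    gene = paste0("G", sample(10, n, replace = TRUE)),
    chrom = "1", pos = seq_len(n), ref = "A", alt = "G",
    variant_class = sample(c("SNV", "INDEL"), n, replace = TRUE),
    depth = 100L,
    alt_reads = sample(0:30, n, replace = TRUE),
    vaf = runif(n, 0, 0.4),
    population_af = ifelse(runif(n) < 0.3, runif(n, 0, 0.01), NA)
  )
  once <- filter_variants(v)
  twice <- filter_variants(once)
  expect_equal(strip_drops(once), strip_drops(twice))
  # tightening any threshold never enlarges the survivor set
  base_ids <- paste(once$sample_id, once$pos)
  tighter <- list(
    filter_variants(v, min_alt_reads = 10),
    filter_variants(v, min_vaf_snv = 0.10),
    filter_variants(v, min_vaf_indel = 0.20),
    filter_variants(v, max_pop_af = 1e-6)
  )
  for (tt in tighter) {
    expect_true(all(paste(tt$sample_id, tt$pos) %in% base_ids))
  }
})

test_that("empty input, unknown classes and inconsistent reads are handled", {
  empty <- filter_variants(toy_variants()[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(sum(variant_filter_summary(empty)$n_dropped), 0L)
  bad_class <- dplyr::mutate(toy_variants(), variant_class = "MNV")
  expect_error(filter_variants(bad_class), "variant class",
               class = "celtilr_validation_error")
  bad_reads <- dplyr::mutate(toy_variants()[1, ], alt_reads = 200L, depth = 100L)
  expect_error(filter_variants(bad_reads), class = "celtilr_validation_error")
})

test_that("the VAF filter can be disabled", {
  v <- toy_variants()
  res <- filter_variants(v, vaf_filter = FALSE)
  # only the read-support and population rules apply
  expect_equal(res$sample_id, c("s2", "s3", "s4", "s5"))
})

test_that("mutation frequency counts distinct mutated samples over the cohort", {
  v <- tibble::tibble(
    sample_id = c(paste0("s", 1:9), "s1"),
    gene = c(rep("TP53", 9), "TP53"), # s1 mutated twice, still one sample
    chrom = "17", pos = 1:10, ref = "A", alt = "G",
    variant_class = "SNV", alt_reads = 20L, depth = 100L, vaf = 0.2,
    population_af = NA_real_
  )
  freq <- mutation_frequency(v, n_samples = 49)
  expect_equal(freq$n_mutated, 9L)
  expect_equal(freq$frequency, 9 / 49, tolerance = 1e-12) # 18.4%
  withg <- mutation_frequency(v, n_samples = 49, genes = c("TP53", "PIK3CA"))
  expect_equal(withg$frequency[withg$gene == "PIK3CA"], 0)
  expect_error(mutation_frequency(v, n_samples = 0),
               class = "celtilr_validation_error")
})

test_that("mutation-by-response tables conserve margins and flag degeneracy", {
  status <- tibble::tibble(
    sample_id = paste0("p", 1:49),
    mutated = c(rep(TRUE, 9), rep(FALSE, 40)),
    responder = c(rep(TRUE, 6), rep(FALSE, 3), rep(TRUE, 10), rep(FALSE, 30))
  )
  tab <- mutation_response_table(status)
  expect_equal(unname(tab), matrix(c(6, 3, 10, 30), 2, byrow = TRUE))
  expect_equal(sum(tab), 49)
  no_mut <- dplyr::mutate(status, mutated = FALSE)
  expect_warning(tab0 <- mutation_response_table(no_mut),
                 class = "celtilr_degenerate_table")
  expect_equal(unname(tab0["mutant", ]), c(0, 0))
  all_resp <- dplyr::mutate(status, responder = TRUE)
  expect_equal(unname(mutation_response_table(all_resp)[, "non-responder"]),
               c(0, 0))
})

test_that("status building rejects samples without responder calls", {
  v <- toy_variants()
  response <- tibble::tibble(sample_id = c("s1", "s2"), responder = c(TRUE, FALSE))
  expect_error(gene_mutation_status(v, "G3", response), "responder status",
               class = "celtilr_validation_error")
  ok <- gene_mutation_status(v, "G1", response)
  expect_equal(ok$mutated, c(TRUE, FALSE))
})

test_that("MAF round trip preserves records through the reader", {
  b <- generate_cohort(cohort_config(n_patients = 10), seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  back <- read_maf(file.path(dir, "mutations.tsv"))
  expect_equal(as.data.frame(back), as.data.frame(b$variants), tolerance = 1e-12)
})
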