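test_that("normalization centers log2 counts on the housekeeping mean", {
  counts <- toy_counts(c(g1 = 7, g2 = 3, g3 = 12), hk = 3)
  norm <- normalize_counts(counts)
  # log2(7+1) - log2(3+1) = 1 for g1; g2 equals the housekeeping level -> 0
  expect_equal(norm$s1[norm$gene == "g1"], 1)
  expect_equal(norm$s1[norm$gene == "g2"], 0)
  expect_false(any(HOUSEKEEPING_GENES %in% norm$gene))
})

test_that("a full 192-gene panel normalizes to 185 analysis genes", {
  bundle <- generate_cohort(cohort_config(n_patients = 4), seed = 1)
  norm <- normalize_counts(bundle$counts)
  expect_equal(nrow(norm), 185)
})

test_that("normalization is approximately scale-invariant at large counts", {
  set.seed(10)
  genes <- c(paste0("g", 1:5), HOUSEKEEPING_GENES)
  counts <- tibble::tibble(gene = genes, s1 = round(runif(12, 5e3, 5e4)))
  scaled <- dplyr::mutate(counts, s1 = s1 * 64)
  expect_equal(normalize_counts(counts)$s1, normalize_counts(scaled)$s1,
               tolerance = 1e-3)
})

test_that("missing or all-zero housekeeping genes abort normalization", {
  counts <- toy_counts()
  expect_error(normalize_counts(counts[counts$gene != "ACTB", ]),
               "ACTB", class = "celtilr_normalization_error")
  zero_hk <- counts
  zero_hk$s1[zero_hk$gene %in% HOUSEKEEPING_GENES] <- 0
  expect_error(normalize_counts(zero_hk), "s1",
               class = "celtilr_normalization_error")
})

test_that("nearest-centroid assignment recovers exact and rejects negated centroids", {
  cents <- toy_centroids()
  prof <- as_profile(setNames(cents$A, cents$gene))
  res <- assign_subtype(prof, cents)
  expect_equal(res$subtype, "A")
  expect_equal(res$cor_A, 1)
  expect_false(res$tie)
  anti <- as_profile(setNames(-cents$A, cents$gene))
  expect_false(assign_subtype(anti, cents)$subtype == "A")
})

test_that("exact centroid ties break by declaration order and are flagged", {
  cents <- toy_centroids()
  cents$B <- cents$A # duplicate centroid
  prof <- as_profile(setNames(cents$A, cents$gene))
  res <- assign_subtype(prof, cents)
  expect_equal(res$subtype, "A")
  expect_true(res$tie)
})

test_that("subtype assignment is invariant to monotone transforms (Spearman)", {
  cents <- toy_centroids()
  set.seed(11)
  x <- setNames(rnorm(20), cents$gene)
  r1 <- assign_subtype(as_profile(x), cents)
  r2 <- assign_subtype(as_profile(exp(2 * x) + 5), cents)
  expect_equal(r1$subtype, r2$subtype)
  expect_equal(r1$cor_A, r2$cor_A, tolerance = 1e-12)
})

test_that("low gene coverage and constant profiles raise subtyping errors", {
  cents <- toy_centroids()
  few <- as_profile(setNames(cents$A[1:10], cents$gene[1:10]))
  expect_error(assign_subtype(few, cents), "covers",
               class = "celtilr_subtyping_error")
  flat <- as_profile(setNames(rep(1, 20), cents$gene))
  expect_error(assign_subtype(flat, cents), "constant",
               class = "celtilr_subtyping_error")
})

test_that("signature scores are renormalized weighted means", {
  sigs <- tibble::tibble(
    signature = c("w", "w", "single"),
    gene = c("g1", "g2", "g1"),
    weight = c(2, 1, 1)
  )
  prof <- as_profile(c(g1 = 3, g2 = 0))
  sc <- signature_score(prof, sigs)
  expect_equal(sc$score[sc$signature == "w"], 2) # (2*3 + 1*0) / 3
  expect_equal(sc$score[sc$signature == "single"], 3) # single-gene = that value
  # constant profile with equal weights returns the constant
  sc2 <- signature_score(as_profile(c(g1 = 1.5, g2 = 1.5)),
                         sigs[sigs$signature == "w", ])
  expect_equal(sc2$score, 1.5)
  # absent genes are dropped with weight renormalization
  sc3 <- signature_score(as_profile(c(g1 = 3)), sigs[sigs$signature == "w", ])
  expect_equal(sc3$score, 3)
  expect_equal(sc3$n_genes, 1L)
  expect_error(signature_score(as_profile(c(zz = 1)), sigs),
               class = "celtilr_scoring_error")
})

test_that("signature scores are linear in the profile", {
  sigs <- tibble::tibble(signature = "s", gene = paste0("g", 1:4),
                         weight = c(1, -2, 0.5, 3))
  set.seed(12)
  x <- setNames(rnorm(4), paste0("g", 1:4))
  y <- setNames(rnorm(4), paste0("g", 1:4))
  s <- function(v) signature_score(as_profile(v), sigs)$score
  expect_equal(s(2 * x + 3 * y), 2 * s(x) + 3 * s(y), tolerance = 1e-12)
})

test_that("tertile fit reproduces the 26/26/25 split at n = 77 and hand cases", {
  set.seed(13)
  m77 <- fit_tertiles(rnorm(77))
  expect_equal(unname(m77$sizes), c(26, 26, 25))
  m9 <- fit_tertiles(1:9)
  expect_equal(unname(m9$sizes), c(3, 3, 3))
  lab <- apply_tertiles(1:9, m9)
  expect_equal(as.character(lab), rep(c("low", "medium", "high"), each = 3))
  # boundary convention: exactly at the low cutpoint -> low
  expect_equal(as.character(apply_tertiles(m9$cutpoint_low, m9)), "low")
  expect_error(fit_tertiles(c(1, 1, 1)), class = "celtilr_validation_error")
})

test_that("re-applying fitted tertiles to the reference recovers group sizes", {
  set.seed(14)
  for (n in c(7, 20, 77, 100)) {
    x <- rnorm(n)
    m <- fit_tertiles(x)
    expect_equal(as.integer(table(apply_tertiles(x, m))), unname(m$sizes))
  }
})

test_that("tertile model tidiers expose cutpoints and sizes", {
  m <- fit_tertiles(1:9)
  td <- tidy(m)
  expect_equal(td$n, c(3L, 3L, 3L))
  gl <- glance(m)
  expect_equal(gl$cutpoint_low, 3.5)
  expect_equal(gl$cutpoint_high, 6.5)
})
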