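test_that("genes take the copy number of their maximal-overlap segment", {
  w <- toy_cn_world()
  res <- map_segments_to_genes(w$seg, w$annotation)
  # fully inside segment 1
  expect_equal(res$cn[res$gene == "inA"], 0.5)
  # spans both chr1 segments: overlap 501 bp vs 900 bp -> second segment
  expect_equal(res$cn[res$gene == "spans"], -0.3)
  # chromosome with no segments -> absent
  expect_false("nowhere" %in% res$gene)
  expect_equal(res$cn[res$gene == "inC"], 0.2)
})

test_that("segment signals are means over present member genes with flags", {
  w <- toy_cn_world()
  gene_cn <- tibble::tibble(
    sample_id = "s1",
    gene = c("inA", "spans", "inC"),
    cn = c(0.2, 0.4, 0.7)
  )
  sig <- segment_signal(gene_cn, w$defs)
  expect_equal(sig$signal[sig$segment == "segX"], 0.3) # mean(0.2, 0.4)
  expect_equal(sig$signal[sig$segment == "segY"], 0.7)
  # ghost gene never observed -> missing and flagged via n_genes = 0
  expect_true(is.na(sig$signal[sig$segment == "segZ"]))
  expect_equal(sig$n_genes[sig$segment == "segZ"], 0L)
  # all-constant member genes return the constant
  cc <- segment_signal(dplyr::mutate(gene_cn, cn = 0.9), w$defs)
  expect_equal(cc$signal[cc$segment == "segX"], 0.9)
})

test_that("a sample with no usable segments is an error", {
  defs <- tibble::tibble(segment = "s", gene = "ghost")
  gene_cn <- tibble::tibble(sample_id = "s1", gene = "other", cn = 1)
  expect_error(segment_signal(gene_cn, defs), class = "celtilr_validation_error")
})

test_that("signature scores are the coefficient-weighted sums of segment signals", {
  coefs <- matrix(c(1, -2), nrow = 1,
                  dimnames = list("sig1", c("segA", "segB")))
  cents <- matrix(0, nrow = 4, ncol = 1,
                  dimnames = list(paste0("cluster", 1:4), "sig1"))
  m <- cn_model(coefs, cents)
  segsig <- tibble::tibble(
    sample_id = "s1", segment = c("segA", "segB"), signal = c(0.5, 0.25)
  )
  sc <- score_cn_signatures(segsig, m)
  expect_equal(sc$score, 1 * 0.5 + (-2) * 0.25)
  # zero coefficients give zero scores; doubling signals doubles scores
  sc2 <- score_cn_signatures(dplyr::mutate(segsig, signal = signal * 2), m)
  expect_equal(sc2$score, 2 * sc$score)
})

test_that("signature scoring is linear in the segment signals", {
  m <- toy_cn_model()
  segs <- colnames(m$coefficients)
  set.seed(21)
  x <- rnorm(4); y <- rnorm(4)
  make <- function(v) tibble::tibble(sample_id = "s", segment = segs, signal = v)
  s <- function(v) score_cn_signatures(make(v), m)$score
  expect_equal(s(2 * x + 5 * y), 2 * s(x) + 5 * s(y), tolerance = 1e-12)
})

test_that("excess missing segments raise a quality error, tolerated ones score as zero", {
  m <- toy_cn_model()
  segs <- colnames(m$coefficients)
  partial <- tibble::tibble(sample_id = "s", segment = segs[1],
                            signal = 1)
  expect_error(score_cn_signatures(partial, m), "missing",
               class = "celtilr_quality_error")
  one_missing <- tibble::tibble(sample_id = "s", segment = segs,
                                signal = c(1, 2, 3, NA))
  sc <- score_cn_signatures(one_missing, m, max_missing = 0.5)
  manual <- as.numeric(m$coefficients %*% c(1, 2, 3, 0))
  expect_equal(sc$score, manual)
  miss <- attr(sc, "missingness")
  expect_equal(miss$n_missing, 1L)
})

test_that("cluster assignment is the nearest centroid with deterministic ties", {
  m <- toy_cn_model()
  segs <- colnames(m$coefficients)
  scores <- tibble::tibble(
    sample_id = "s",
    signature = colnames(m$centroids),
    score = m$centroids["cluster3", ]
  )
  res <- assign_cn_cluster(scores, m)
  expect_equal(res$cluster, "cluster3")
  expect_equal(res$dist_cluster3, 0)
  # equidistant midpoint between clusters 1 and 2 -> cluster 1, tie flag
  # (use a 2-cluster model so no third centroid can sit closer)
  mid <- (m$centroids["cluster1", ] + m$centroids["cluster2", ]) / 2
  m2 <- cn_model(m$coefficients,
                 m$centroids[c("cluster1", "cluster2"), , drop = FALSE])
  res2 <- assign_cn_cluster(
    tibble::tibble(sample_id = "s", signature = colnames(m$centroids), score = mid),
    m2
  )
  expect_equal(res2$cluster, "cluster1")
  expect_true(res2$tie)
  expect_false(res$tie)
})

test_that("assignment matches a brute-force distance enumeration on random data", {
  set.seed(22)
  for (rep in 1:5) {
    k <- sample(2:6, 1)
    cents <- matrix(rnorm(4 * k), nrow = 4,
                    dimnames = list(paste0("cluster", 1:4), paste0("s", seq_len(k))))
    coefs <- matrix(rnorm(k * 3), nrow = k,
                    dimnames = list(paste0("s", seq_len(k)), paste0("seg", 1:3)))
    m <- cn_model(coefs, cents)
    scores_mat <- matrix(rnorm(10 * k), nrow = 10,
                         dimnames = list(paste0("x", 1:10), paste0("s", seq_len(k))))
    long <- tidyr::pivot_longer(
      dplyr::bind_cols(tibble::tibble(sample_id = rownames(scores_mat)),
                       tibble::as_tibble(scores_mat)),
      -sample_id, names_to = "signature", values_to = "score"
    )
    res <- assign_cn_cluster(long, m)
    expect_equal(res$cluster[match(rownames(scores_mat), res$sample_id)],
                 unname(brute_nearest(scores_mat, cents)))
  }
})

test_that("missing signature scores abort cluster assignment", {
  m <- toy_cn_model()
  scores <- tibble::tibble(
    sample_id = "s", signature = colnames(m$centroids),
    score = c(NA, 1, 2)
  )
  expect_error(assign_cn_cluster(scores, m), class = "celtilr_validation_error")
})

test_that("the SEG pipeline is deterministic end to end", {
  b <- generate_cohort(cohort_config(n_patients = 6), seed = 3)
  run <- function() {
    gene_cn <- map_segments_to_genes(b$seg, b$cn_model_set$annotation)
    segsig <- segment_signal(gene_cn, b$cn_model_set$defs)
    sc <- score_cn_signatures(segsig, b$cn_model_set$model)
    assign_cn_cluster(sc, b$cn_model_set$model)
  }
  expect_identical(run(), run())
})

test_that("cluster recovery is perfect at zero noise and degrades with noise", {
  cnw <- synthetic_cn_model(n_segments = 20, n_signatures = 8, seed = 9)
  segs <- colnames(cnw$seg_centroids)
  truth <- rep(rownames(cnw$seg_centroids), each = 15)
  recover <- function(noise_sd) {
    set.seed(30)
    sig <- cnw$seg_centroids[truth, , drop = FALSE] +
      matrix(rnorm(length(truth) * length(segs), sd = noise_sd),
             nrow = length(truth))
    ids <- paste0("p", seq_along(truth))
    long <- tibble::tibble(
      sample_id = rep(ids, times = length(segs)),
      segment = rep(segs, each = length(truth)),
      signal = as.numeric(sig)
    )
    sc <- score_cn_signatures(long, cnw$model)
    res <- assign_cn_cluster(sc, cnw$model)
    mean(res$cluster[match(ids, res$sample_id)] == truth)
  }
  acc0 <- recover(0)
  acc_mid <- recover(0.3)
  acc_high <- recover(1.5)
  expect_equal(acc0, 1)
  expect_true(acc_mid >= acc_high)
  expect_true(acc0 >= acc_mid)
})

test_that("SEG reading converts dialects and validates coordinates", {
  path <- withr::local_tempfile(fileext = ".seg")
  readr::write_tsv(
    tibble::tibble(ID = "s1", chrom = "1", loc.start = 1L, loc.end = 100L,
                   num.mark = 5L, seg.mean = 0.3),
    path
  )
  seg <- read_seg(path)
  expect_equal(seg$seg_mean, 0.3)
  expect_equal(names(seg), c("sample_id", "chrom", "start", "end", "seg_mean"))
  bad <- withr::local_tempfile(fileext = ".seg")
  readr::write_tsv(
    tibble::tibble(ID = "s1", chrom = "1", loc.start = 100L, loc.end = 100L,
                   seg.mean = 0.3),
    bad
  )
  expect_error(read_seg(bad), class = "celtilr_validation_error")
})
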