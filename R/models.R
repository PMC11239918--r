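# Synthetic 192-gene panel and model files.
#
# The published centroid and signature coefficient values are external and
# proprietary, so the package ships a synthetic model with the same schema
# instead: a 185-analysis-gene panel organised into biology modules
# (proliferation, luminal, basal-like, HER2 amplicon, immune, ERBB3,
# inert filler), subtype centroids over those genes, and weighted-sum
# signature definitions. User-supplied model files with the same layout
# drop in directly.

panel_modules <- function() {
  list(
    prolif = c("MKI67", "AURKA", "CCNE1", "CCNB1", "BIRC5", "CDC20",
               "UBE2C", "RRM2", "TYMS", "EXO1", "CENPF", "KIF2C"),
    luminal = c("ESR1", "PGR", "NAT1", "SLC39A6", "MAGED2", "THSD4",
                "FOXA1", "MLPH", "BCL2", "BAG1", "CXXC5", "GPR160"),
    basal = c("KRT5", "KRT14", "KRT17", "SFRP1", "MIA", "FOXC1",
              "EGFR", "CDH3"),
    her2 = c("ERBB2", "GRB7"),
    immune = c("CD8A", "CD3D", "PTPRC", "GZMB", "IGKC", "IGJ"),
    erbb3 = "ERBB3",
    filler = sprintf("BC%03d", 1:144)
  )
}

#' Genes of the synthetic 192-gene expression panel
#'
#' 185 analysis genes plus the 7 housekeeping genes. The analysis genes
#' are grouped into biology modules used by the synthetic cohort
#' generator (`module` column).
#'
#' @return A tibble with columns `gene`, `module` (`housekeeping` for the
#'   normalization genes).
#' @export
panel_genes <- function() {
  mods <- panel_modules()
  dplyr::bind_rows(
    purrr::imap(mods, function(genes, name) tibble(gene = genes, module = name)),
    tibble(gene = HOUSEKEEPING_GENES, module = "housekeeping")
  )
}

# per-subtype module means on the housekeeping-relative log2 scale
subtype_module_means <- function() {
  m <- rbind(
    LumA  = c(luminal = 1.2, prolif = -0.8, basal = -1.0, her2 = 0, immune = -0.2, erbb3 = 0.3, filler = 0),
    LumB  = c(luminal = 0.8, prolif = 0.7, basal = -1.0, her2 = 0, immune = -0.1, erbb3 = 0.3, filler = 0),
    Her2E = c(luminal = -0.3, prolif = 0.8, basal = -0.3, her2 = 0, immune = 0.0, erbb3 = 0.2, filler = 0),
    Basal = c(luminal = -1.2, prolif = 1.5, basal = 1.5, her2 = 0, immune = 0.3, erbb3 = -0.2, filler = 0),
    Normal = c(luminal = 0.2, prolif = -0.5, basal = 0.0, her2 = 0, immune = 0.0, erbb3 = 0.0, filler = 0)
  )
  m
}

#' Synthetic expression model (centroids and signature definitions)
#'
#' Builds the synthetic stand-in for the external subtype-centroid and
#' signature model files: centroids are the generator's per-subtype mean
#' profiles over the 185 analysis genes; signatures are equal-weight
#' module scores plus the single-gene ERBB2 mRNA score.
#'
#' @return A list with elements `centroids` (tibble: `gene` + one column
#'   per subtype) and `signatures` (tibble: `signature`, `gene`,
#'   `weight`).
#' @export
synthetic_expression_model <- function() {
  mods <- panel_modules()
  means <- subtype_module_means()
  genes <- unlist(mods, use.names = FALSE)
  module_of <- rep(names(mods), lengths(mods))
  centroids <- tibble(gene = genes)
  for (st in rownames(means)) {
    centroids[[st]] <- means[st, module_of]
  }
  signatures <- dplyr::bind_rows(
    tibble(signature = "proliferation", gene = mods$prolif, weight = 1),
    tibble(signature = "luminal", gene = mods$luminal, weight = 1),
    tibble(signature = "basal_like", gene = mods$basal, weight = 1),
    tibble(signature = "her2_amplicon", gene = mods$her2, weight = 1),
    tibble(signature = "immune_igg", gene = mods$immune, weight = 1),
    tibble(signature = "erbb2", gene = "ERBB2", weight = 1)
  )
  list(centroids = centroids, signatures = signatures)
}

#' Synthetic copy-number signature model
#'
#' Builds a reduced synthetic stand-in for the external copy-number model
#' (the full published model has 519 segments, 150 linear signatures and
#' 4 cluster centroids): named genomic segments with member genes, a
#' sparse coefficient matrix, and 4 cluster centroids defined at the
#' segment level and propagated through the coefficients. The `17q12`
#' segment carries the ERBB2 and GRB7 genes and is given zero weight in
#' the cluster structure so its signal is free to track ERBB2 expression.
#'
#' @param n_segments Number of segments (default 40; one of them is
#'   `17q12`).
#' @param n_signatures Number of linear signatures (default 20; one of
#'   them, `her2_amplicon_cn`, loads only on `17q12`).
#' @param seed Seed fixing the synthetic model (default 101); the same
#'   seed always yields the same model.
#' @return A list with elements `model` (a [cn_model()]), `defs`
#'   (segment/gene membership tibble), `annotation` (gene coordinates),
#'   `segments` (segment coordinates), `seg_centroids` (segment-level
#'   cluster means, used by the generator).
#' @export
synthetic_cn_model <- function(n_segments = 40, n_signatures = 20, seed = 101) {
  stopifnot(n_segments >= 4, n_signatures >= 2)
  with_local_seed(seed, {
    seg_ids <- c("17q12", sprintf("seg%03d", seq_len(n_segments - 1)))
    chroms <- as.character(rep_len(c(1:16, 18:22), n_segments - 1))
    seg_tbl <- tibble(
      segment = seg_ids,
      chrom = c("17", chroms),
      start = c(37500001L, 10000001L +
                  20000000L * (seq_len(n_segments - 1) %/% 22L)),
      end = c(39500000L, 10000001L +
                20000000L * (seq_len(n_segments - 1) %/% 22L) + 9999999L)
    )
    # 3 member genes per segment, placed inside it; 17q12 carries ERBB2/GRB7
    defs <- purrr::pmap_dfr(seg_tbl, function(segment, chrom, start, end) {
      genes <- if (segment == "17q12") {
        c("ERBB2", "GRB7", "PGAP3")
      } else {
        paste0("CN_", segment, "_", 1:3)
      }
      width <- (end - start) %/% 4L
      tibble(
        segment = segment, chrom = chrom,
        gene = genes,
        gstart = start + width * (seq_along(genes) - 1L) + 1000L,
        gend = start + width * seq_along(genes) - 1000L
      )
    })
    annotation <- tibble(
      gene = defs$gene, chrom = defs$chrom,
      start = defs$gstart, end = defs$gend
    )
    coefs <- matrix(
      rnorm(n_signatures * n_segments) *
        (runif(n_signatures * n_segments) < 0.3),
      nrow = n_signatures,
      dimnames = list(
        c("her2_amplicon_cn", sprintf("cnsig%03d", seq_len(n_signatures - 1))),
        seg_ids
      )
    )
    coefs["her2_amplicon_cn", ] <- 0
    coefs["her2_amplicon_cn", "17q12"] <- 1
    # segment-level cluster means; 17q12 kept cluster-neutral
    seg_centroids <- matrix(
      rnorm(4 * n_segments, sd = 0.5) * (runif(4 * n_segments) < 0.5),
      nrow = 4,
      dimnames = list(paste0("cluster", 1:4), seg_ids)
    )
    seg_centroids[, "17q12"] <- 0
    centroids <- seg_centroids %*% t(coefs)
    list(
      model = cn_model(coefs, centroids),
      defs = dplyr::select(defs, "segment", "gene"),
      annotation = annotation,
      segments = seg_tbl,
      seg_centroids = seg_centroids
    )
  })
}
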