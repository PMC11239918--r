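#' Read a SEG-format segmented copy-number file
#'
#' Standard SEG columns `ID`, `chrom`, `loc.start`, `loc.end`, `seg.mean`
#' (an optional `num.mark` column is tolerated and dropped). Coordinates
#' are treated as 1-based inclusive.
#'
#' @param path Path to the SEG file (tab-delimited).
#' @return A tibble with columns `sample_id`, `chrom`, `start`, `end`,
#'   `seg_mean` (mean log2 copy-number ratio of the segment).
#' @export
read_seg <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  nm <- tolower(names(raw))
  pick <- function(...) {
    for (cand in c(...)) {
      hit <- which(nm == cand)
      if (length(hit)) return(raw[[hit[1]]])
    }
    stop_celtilr(sprintf("SEG file misses a '%s' column.", ..1),
                 "celtilr_validation_error")
  }
  out <- tibble(
    sample_id = as.character(pick("id", "sample", "sample_id")),
    chrom = as.character(pick("chrom", "chromosome", "chr")),
    start = as.integer(pick("loc.start", "start")),
    end = as.integer(pick("loc.end", "end")),
    seg_mean = as.numeric(pick("seg.mean", "seg_mean", "mean"))
  )
  validate_seg(out)
  out
}

validate_seg <- function(seg) {
  if (any(seg$start >= seg$end)) {
    stop_celtilr("SEG records must satisfy start < end.", "celtilr_validation_error")
  }
  invisible(seg)
}

#' Read a gene annotation table
#'
#' Either a 4+ column BED file (`chrom`, `start`, `end`, `name`; 0-based
#' half-open, converted to 1-based inclusive) or a TSV with columns
#' `gene`, `chrom`, `start`, `end` already 1-based.
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_annotation <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
    out <- tibble(
      gene = as.character(raw[[4]]),
      chrom = as.character(raw[[1]]),
      start = as.integer(raw[[2]]) + 1L,
      end = as.integer(raw[[3]])
    )
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    out <- tibble(
      gene = as.character(raw$gene),
      chrom = as.character(raw$chrom),
      start = as.integer(raw$start),
      end = as.integer(raw$end)
    )
  }
  if (anyDuplicated(out$gene)) {
    stop_celtilr("Gene annotation has duplicated gene ids.", "celtilr_validation_error")
  }
  out
}

#' Map segmented copy number onto genes
#'
#' Each gene receives the `seg_mean` of the segment it overlaps most
#' (maximal overlap in base pairs; exact ties broken by the segment with
#' the smaller start coordinate). Genes overlapping no segment of a sample
#' are absent from that sample's output.
#'
#' @param seg SEG tibble from [read_seg()].
#' @param annotation Gene annotation from [read_gene_annotation()].
#' @return A tibble `sample_id`, `gene`, `cn` (log2-ratio scale).
#' @export
map_segments_to_genes <- function(seg, annotation) {
  seg <- as_tibble(seg)
  annotation <- as_tibble(annotation)
  validate_seg(seg)
  if (!nrow(seg) || !nrow(annotation)) {
    return(tibble(sample_id = character(), gene = character(), cn = numeric()))
  }
  seg_gr <- GenomicRanges::GRanges(
    seqnames = seg$chrom,
    ranges = IRanges::IRanges(start = seg$start, end = seg$end)
  )
  gene_gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end)
  )
  hits <- GenomicRanges::findOverlaps(gene_gr, seg_gr)
  if (!length(hits)) {
    return(tibble(sample_id = character(), gene = character(), cn = numeric()))
  }
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gene_gr)[qh], IRanges::ranges(seg_gr)[sh]
  ))
  cand <- tibble(
    sample_id = seg$sample_id[sh],
    gene = annotation$gene[qh],
    cn = seg$seg_mean[sh],
    overlap = ov,
    seg_start = seg$start[sh]
  )
  out <- cand |>
    dplyr::arrange(.data$sample_id, .data$gene,
                   dplyr::desc(.data$overlap), .data$seg_start) |>
    dplyr::distinct(.data$sample_id, .data$gene, .keep_all = TRUE) |>
    dplyr::select("sample_id", "gene", "cn")
  out
}

#' Per-segment copy-number signal
#'
#' The signal of each model segment is the arithmetic mean of the
#' gene-level copy-number values over the segment's member genes present
#' in the input; a segment with no member gene present gets `NA` and is
#' flagged in the `n_genes` column.
#'
#' @param gene_cn Gene-level copy number (`sample_id`, `gene`, `cn`), e.g.
#'   from [map_segments_to_genes()].
#' @param defs Segment definitions: tibble with columns `segment`, `gene`
#'   listing each segment's member genes.
#' @return A tibble `sample_id`, `segment`, `signal`, `n_genes` with one
#'   row per sample and model segment.
#' @export
segment_signal <- function(gene_cn, defs) {
  gene_cn <- as_tibble(gene_cn)
  defs <- as_tibble(defs)
  if (!nrow(defs)) {
    stop_celtilr("Segment definition set is empty.", "celtilr_validation_error")
  }
  segments <- unique(defs$segment)
  samples <- unique(gene_cn$sample_id)
  joined <- dplyr::inner_join(defs, gene_cn, by = "gene",
                              relationship = "many-to-many")
  agg <- joined |>
    dplyr::group_by(.data$sample_id, .data$segment) |>
    dplyr::summarise(signal = mean(.data$cn), n_genes = dplyr::n(),
                     .groups = "drop")
  grid <- tidyr::expand_grid(sample_id = samples, segment = segments)
  out <- dplyr::left_join(grid, agg, by = c("sample_id", "segment")) |>
    dplyr::mutate(n_genes = dplyr::coalesce(.data$n_genes, 0L))
  all_missing <- out |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(none = all(is.na(.data$signal)), .groups = "drop")
  if (any(all_missing$none)) {
    stop_celtilr(
      sprintf("Sample '%s' has no signal for any model segment.",
              all_missing$sample_id[which(all_missing$none)[1]]),
      "celtilr_validation_error"
    )
  }
  out
}

#' Construct a copy-number signature model
#'
#' Bundles the linear segment-to-signature coefficients and the cluster
#' centroids used for nearest-centroid subtype assignment. The full-scale
#' published model has 150 signatures over 519 segments and 4 cluster
#' centroids; any consistent dimensions are accepted, so reduced synthetic
#' models can be used for testing.
#'
#' @param coefficients Numeric matrix, signatures x segments, with
#'   dimnames.
#' @param centroids Numeric matrix, clusters x signatures, with dimnames;
#'   signature columns must match `coefficients` rows.
#' @param center,scale Optional per-signature standardization means / SDs
#'   applied to signature scores before Euclidean distances (default:
#'   none).
#' @return A `cn_model` object.
#' @export
cn_model <- function(coefficients, centroids, center = NULL, scale = NULL) {
  stopifnot(is.matrix(coefficients), is.matrix(centroids))
  if (is.null(rownames(coefficients)) || is.null(colnames(coefficients)) ||
      is.null(rownames(centroids)) || is.null(colnames(centroids))) {
    stop_celtilr("Model matrices need full dimnames.", "celtilr_validation_error")
  }
  if (!identical(colnames(centroids), rownames(coefficients))) {
    stop_celtilr("Centroid signatures must match coefficient rows.",
                 "celtilr_validation_error")
  }
  if (!is.null(center)) stopifnot(length(center) == nrow(coefficients))
  if (!is.null(scale)) stopifnot(length(scale) == nrow(coefficients))
  structure(
    list(coefficients = coefficients, centroids = centroids,
         center = center, scale = scale),
    class = "cn_model"
  )
}

#' @export
print.cn_model <- function(x, ...) {
  cat("Copy-number signature model:",
      nrow(x$coefficients), "signatures x", ncol(x$coefficients), "segments;",
      nrow(x$centroids), "cluster centroids",
      if (is.null(x$center)) "(no standardization)\n" else "(standardized)\n")
  invisible(x)
}

#' Linear copy-number signature scores
#'
#' Each signature score is the weighted sum of segment signals:
#' coefficient of segment A x signal of segment A + coefficient of segment
#' B x signal of segment B + ... Missing segment signals contribute zero
#' (the linear model is not renormalized, which would distort scores);
#' samples missing more than `max_missing` of the model segments raise a
#' quality error instead.
#'
#' @param segsig Per-segment signal tibble (`sample_id`, `segment`,
#'   `signal`) from [segment_signal()].
#' @param model A [cn_model()].
#' @param max_missing Maximum tolerated fraction of missing segments per
#'   sample (default 0.2).
#' @return A tibble `sample_id`, `signature`, `score`; the per-sample
#'   missingness report is attached as attribute `"missingness"`.
#' @export
score_cn_signatures <- function(segsig, model, max_missing = 0.2) {
  stopifnot(inherits(model, "cn_model"))
  segsig <- as_tibble(segsig)
  segs <- colnames(model$coefficients)
  wide <- tidyr::pivot_wider(
    dplyr::select(segsig, "sample_id", "segment", "signal"),
    names_from = "segment", values_from = "signal"
  )
  samples <- wide$sample_id
  mat <- matrix(NA_real_, nrow = length(samples), ncol = length(segs),
                dimnames = list(samples, segs))
  present_cols <- intersect(segs, names(wide))
  mat[, present_cols] <- as.matrix(wide[present_cols])
  n_missing <- rowSums(is.na(mat))
  frac_missing <- n_missing / length(segs)
  if (any(frac_missing > max_missing)) {
    bad <- which(frac_missing > max_missing)[1]
    stop_celtilr(
      sprintf("Sample '%s' is missing %.0f%% of model segments (max %.0f%%).",
              samples[bad], 100 * frac_missing[bad], 100 * max_missing),
      "celtilr_quality_error"
    )
  }
  mat[is.na(mat)] <- 0
  scores <- mat %*% t(model$coefficients)
  out <- tibble(
    sample_id = rep(samples, times = ncol(scores)),
    signature = rep(colnames(scores), each = nrow(scores)),
    score = as.numeric(scores)
  )
  attr(out, "missingness") <- tibble(
    sample_id = samples,
    n_missing = as.integer(n_missing),
    frac_missing = frac_missing
  )
  out
}

#' Nearest-centroid cluster assignment for copy-number signatures
#'
#' Computes the Euclidean distance from each sample's signature-score
#' vector to every cluster centroid and assigns the nearest one. If the
#' model carries per-signature standardization means/SDs they are applied
#' to the scores first. Exact ties go to the lowest-numbered (first
#' declared) cluster and are flagged.
#'
#' @param scores Signature scores (`sample_id`, `signature`, `score`) from
#'   [score_cn_signatures()].
#' @param model A [cn_model()].
#' @return A tibble `sample_id`, `cluster`, `tie`, plus one
#'   `dist_<cluster>` column per centroid.
#' @export
assign_cn_cluster <- function(scores, model) {
  stopifnot(inherits(model, "cn_model"))
  scores <- as_tibble(scores)
  sigs <- colnames(model$centroids)
  wide <- tidyr::pivot_wider(
    dplyr::select(scores, "sample_id", "signature", "score"),
    names_from = "signature", values_from = "score"
  )
  if (!all(sigs %in% names(wide))) {
    stop_celtilr("Scores do not cover all model signatures.",
                 "celtilr_validation_error")
  }
  mat <- as.matrix(wide[sigs])
  if (anyNA(mat)) {
    stop_celtilr("Missing signature scores; impute or fix upstream.",
                 "celtilr_validation_error")
  }
  if (!is.null(model$center)) mat <- sweep(mat, 2, model$center, "-")
  if (!is.null(model$scale)) mat <- sweep(mat, 2, model$scale, "/")
  cents <- model$centroids
  d <- vapply(seq_len(nrow(cents)), function(k) {
    sqrt(rowSums(sweep(mat, 2, cents[k, ], "-")^2))
  }, numeric(nrow(mat)))
  d <- matrix(d, nrow = nrow(mat))
  colnames(d) <- rownames(cents)
  nearest <- apply(d, 1, function(row) {
    best <- min(row)
    winners <- which(row <= best + 1e-12)
    c(winners[1], length(winners) > 1L)
  })
  out <- tibble(
    sample_id = wide$sample_id,
    cluster = rownames(cents)[nearest[1, ]],
    tie = as.logical(nearest[2, ])
  )
  dist_tbl <- as_tibble(as.data.frame(d))
  names(dist_tbl) <- paste0("dist_", rownames(cents))
  dplyr::bind_cols(out, dist_tbl)
}
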