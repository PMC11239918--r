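#' Housekeeping genes of the 192-gene expression panel
#'
#' The targeted nCounter-style panel carries 185 analysis genes plus these
#' 7 housekeeping genes used for normalization.
#' @format Character vector of 7 gene symbols.
#' @export
HOUSEKEEPING_GENES <- c("ACTB", "MRPL19", "GAPD", "PSMC4", "PUM1", "RPLP0", "SF3A1")

#' Read a gene-by-sample count matrix
#'
#' TSV with the gene identifier in the first column (named `gene`) and one
#' column of non-negative integer counts per sample.
#'
#' @param path Path to the TSV file.
#' @return A tibble with a `gene` column and one numeric column per sample.
#' @export
read_counts <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(out)[1] <- "gene"
  validate_counts(out)
  out
}

validate_counts <- function(counts) {
  if (!"gene" %in% names(counts)) {
    stop_celtilr("Count table must have a `gene` column.", "celtilr_validation_error")
  }
  if (anyDuplicated(counts$gene)) {
    stop_celtilr("Duplicated gene identifiers in count table.", "celtilr_validation_error")
  }
  sample_cols <- setdiff(names(counts), "gene")
  if (anyDuplicated(sample_cols)) {
    stop_celtilr("Duplicated sample identifiers in count table.", "celtilr_validation_error")
  }
  vals <- as.matrix(counts[sample_cols])
  if (any(vals < 0, na.rm = TRUE)) {
    stop_celtilr("Counts must be non-negative.", "celtilr_validation_error")
  }
  invisible(counts)
}

#' Normalize panel counts against the housekeeping genes
#'
#' Per sample, each gene's `log2(count + 1)` is centered by the arithmetic
#' mean of `log2(count + 1)` over the 7 housekeeping genes; housekeeping
#' rows are dropped from the output, leaving the analysis genes (185 for
#' the full panel) on a log2 scale relative to the housekeeping baseline.
#'
#' @param counts A count tibble as returned by [read_counts()]: a `gene`
#'   column plus one column per sample. All housekeeping genes must be
#'   present.
#' @param housekeeping Character vector of housekeeping gene symbols
#'   (default [HOUSEKEEPING_GENES]).
#' @return A tibble with a `gene` column and one normalized (log2-scale)
#'   column per sample; housekeeping genes removed.
#' @export
normalize_counts <- function(counts, housekeeping = HOUSEKEEPING_GENES) {
  counts <- as_tibble(counts)
  validate_counts(counts)
  missing_hk <- setdiff(housekeeping, counts$gene)
  if (length(missing_hk)) {
    stop_celtilr(
      paste0("Missing housekeeping gene(s): ", paste(missing_hk, collapse = ", ")),
      "celtilr_normalization_error"
    )
  }
  sample_cols <- setdiff(names(counts), "gene")
  mat <- as.matrix(counts[sample_cols])
  rownames(mat) <- counts$gene
  hk <- mat[housekeeping, , drop = FALSE]
  zero_hk <- colSums(hk) == 0
  if (any(zero_hk)) {
    stop_celtilr(
      sprintf("Sample '%s' has all-zero housekeeping counts; cannot normalize.",
              sample_cols[which(zero_hk)[1]]),
      "celtilr_normalization_error"
    )
  }
  log_mat <- log2(mat + 1)
  hk_mean <- colMeans(log_mat[housekeeping, , drop = FALSE])
  norm <- sweep(log_mat, 2, hk_mean, "-")
  norm <- norm[setdiff(counts$gene, housekeeping), , drop = FALSE]
  dplyr::bind_cols(tibble(gene = rownames(norm)), as_tibble(norm))
}

#' Read a centroid model file
#'
#' TSV with a `gene` column and one numeric column per subtype centroid.
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_centroids <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(out)[1] <- "gene"
  out
}

#' Read a signature-definition model file
#'
#' TSV with columns `signature`, `gene`, `weight`.
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_signatures <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("signature", "gene", "weight")
  if (!all(required %in% names(out))) {
    stop_celtilr("Signature file must have columns signature, gene, weight.",
                 "celtilr_validation_error")
  }
  out
}

#' Nearest-centroid molecular subtype assignment
#'
#' Research-based intrinsic subtyping: each sample's normalized profile is
#' correlated (Spearman by default) with every subtype centroid over the
#' genes they share; the subtype with the highest correlation wins. Exact
#' ties are broken deterministically by centroid declaration order and
#' flagged.
#'
#' @param normalized Normalized expression tibble (`gene` column + one
#'   column per sample), e.g. from [normalize_counts()].
#' @param centroids Centroid tibble: `gene` column + one numeric column per
#'   subtype.
#' @param method Correlation type, `"spearman"` (default) or `"pearson"`.
#' @param min_coverage Minimum fraction of centroid genes that must be
#'   present in the profile (default 0.9).
#' @return A tibble with one row per sample: `sample_id`, `subtype`, `tie`
#'   (logical), and one `cor_<subtype>` column per centroid.
#' @export
assign_subtype <- function(normalized, centroids,
                           method = c("spearman", "pearson"),
                           min_coverage = 0.9) {
  method <- match.arg(method)
  normalized <- as_tibble(normalized)
  centroids <- as_tibble(centroids)
  subtype_names <- setdiff(names(centroids), "gene")
  if (anyDuplicated(subtype_names)) {
    stop_celtilr("Centroid names must be unique.", "celtilr_validation_error")
  }
  shared <- intersect(centroids$gene, normalized$gene)
  coverage <- length(shared) / nrow(centroids)
  if (coverage < min_coverage) {
    stop_celtilr(
      sprintf("Profile covers %.1f%% of centroid genes; %.1f%% required.",
              100 * coverage, 100 * min_coverage),
      "celtilr_subtyping_error"
    )
  }
  cmat <- as.matrix(centroids[match(shared, centroids$gene), subtype_names])
  sample_cols <- setdiff(names(normalized), "gene")
  pmat <- as.matrix(normalized[match(shared, normalized$gene), sample_cols, drop = FALSE])
  rows <- lapply(seq_along(sample_cols), function(j) {
    prof <- pmat[, j]
    if (sd(prof) == 0) {
      stop_celtilr(
        sprintf("Profile for sample '%s' is constant; correlation undefined.",
                sample_cols[j]),
        "celtilr_subtyping_error"
      )
    }
    cors <- vapply(seq_along(subtype_names),
                   function(k) cor(prof, cmat[, k], method = method),
                   numeric(1))
    best <- max(cors)
    winners <- which(cors >= best - 1e-12)
    row <- tibble(
      sample_id = sample_cols[j],
      subtype = subtype_names[winners[1]],
      tie = length(winners) > 1L
    )
    cor_tbl <- as_tibble(as.list(setNames(cors, paste0("cor_", subtype_names))))
    dplyr::bind_cols(row, cor_tbl)
  })
  dplyr::bind_rows(rows)
}

#' Weighted-mean signature scores
#'
#' For each signature, the score of a sample is the weighted mean of its
#' normalized expression over the signature genes present in the profile,
#' with weights renormalized to the present genes:
#' \eqn{\sum_g w_g x_g / \sum_g w_g}. A single-gene signature (such as the
#' ERBB2 mRNA score) therefore returns that gene's normalized value.
#'
#' @param normalized Normalized expression tibble (`gene` + sample columns).
#' @param signatures Signature definition tibble with columns `signature`,
#'   `gene`, `weight`.
#' @return A long tibble: `sample_id`, `signature`, `score`, `n_genes`
#'   (genes used).
#' @export
signature_score <- function(normalized, signatures) {
  normalized <- as_tibble(normalized)
  signatures <- as_tibble(signatures)
  if (any(!is.finite(signatures$weight))) {
    stop_celtilr("Signature weights must be finite.", "celtilr_validation_error")
  }
  sample_cols <- setdiff(names(normalized), "gene")
  out <- lapply(split(signatures, signatures$signature), function(sig) {
    present <- sig[sig$gene %in% normalized$gene, ]
    if (!nrow(present)) {
      stop_celtilr(
        sprintf("No gene of signature '%s' present in the profile.",
                sig$signature[1]),
        "celtilr_scoring_error"
      )
    }
    vals <- as.matrix(
      normalized[match(present$gene, normalized$gene), sample_cols, drop = FALSE]
    )
    w <- present$weight
    scores <- as.numeric(crossprod(vals, w) / sum(w))
    tibble(
      sample_id = sample_cols,
      signature = sig$signature[1],
      score = scores,
      n_genes = nrow(present)
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$signature, .data$sample_id)
}

#' Fit tertile cutpoints on a reference cohort
#'
#' Rank-based three-way split used to carry reference-cohort group
#' boundaries to new samples: with `n` reference values sorted ascending,
#' the low group takes ranks `1..ceiling(n/3)`, the medium group the next
#' `ceiling(2n/3) - ceiling(n/3)` ranks, and the high group the rest (at
#' `n = 77` this yields groups of 26/26/25). Cutpoints are midpoints
#' between the boundary order statistics; new values at or below a
#' cutpoint fall in the lower group.
#'
#' @param scores Numeric reference scores (at least 3 distinct values).
#' @return A `tertile_model` object with elements `cutpoint_low`,
#'   `cutpoint_high`, `n`, and the fitted group sizes.
#' @export
fit_tertiles <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(unique(scores)) < 3L) {
    stop_celtilr("Need at least 3 distinct reference values to fit tertiles.",
                 "celtilr_validation_error")
  }
  n <- length(scores)
  s <- sort(scores)
  k1 <- ceiling(n / 3)
  k2 <- ceiling(2 * n / 3)
  structure(
    list(
      cutpoint_low = (s[k1] + s[k1 + 1]) / 2,
      cutpoint_high = (s[k2] + s[k2 + 1]) / 2,
      n = n,
      sizes = c(low = as.integer(k1), medium = as.integer(k2 - k1),
                high = as.integer(n - k2))
    ),
    class = "tertile_model"
  )
}

#' Label scores with fitted tertile groups
#'
#' @param scores Numeric scores to classify.
#' @param model A `tertile_model` from [fit_tertiles()].
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
apply_tertiles <- function(scores, model) {
  stopifnot(inherits(model, "tertile_model"))
  lab <- ifelse(scores <= model$cutpoint_low, "low",
                ifelse(scores <= model$cutpoint_high, "medium", "high"))
  factor(lab, levels = c("low", "medium", "high"))
}

#' @export
print.tertile_model <- function(x, ...) {
  cat("Tertile model (n =", x$n, ")\n")
  cat("  cutpoints:", format(x$cutpoint_low), "/", format(x$cutpoint_high), "\n")
  cat("  group sizes:", paste(names(x$sizes), x$sizes, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.tertile_model <- function(x, ...) {
  tibble(
    group = c("low", "medium", "high"),
    n = as.integer(x$sizes),
    upper_cutpoint = c(x$cutpoint_low, x$cutpoint_high, NA_real_)
  )
}

#' @export
glance.tertile_model <- function(x, ...) {
  tibble(
    n = x$n,
    cutpoint_low = x$cutpoint_low,
    cutpoint_high = x$cutpoint_high
  )
}
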