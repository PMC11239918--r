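#' Run the full translational analysis pipeline on a cohort bundle
#'
#' Orchestrates the stages end to end: CelTIL scoring and response calls,
#' expression normalization with subtype and signature scoring and
#' ERBB2-score tertiles, copy-number signature scoring and cluster
#' assignment (when SEG data are present), somatic-variant filtering and
#' mutation summaries (when a mutation table is present), and the
#' biomarker association battery (SAM over the panel genes, logistic and
#' ROC analyses of the ERBB2 score, TP53-by-response and
#' cluster-by-response contingency statistics). Deterministic given
#' `seed`.
#'
#' @param bundle A `cohort_bundle` (from [generate_cohort()] or
#'   [read_bundle()]); `seg` and/or `variants` may be `NULL` for an
#'   RNA-only run.
#' @param cutoff CelTIL response cutoff in points (default 20).
#' @param fdr_threshold SAM FDR threshold (default 0.10).
#' @param n_permutations SAM permutations (default 1000).
#' @param seed Seed for the permutation draws.
#' @param out_dir Optional directory; when given, stage tables are
#'   written as TSV plus a `report.json` summary.
#' @return A `run_report` list with elements `celtil`, `expression`,
#'   `cn`, `variants`, `associations`, `summary`.
#' @export
run_pipeline <- function(bundle, cutoff = 20, fdr_threshold = 0.10,
                         n_permutations = 1000, seed = 1, out_dir = NULL) {
  # --- stage 1: CelTIL -------------------------------------------------
  celtil <- celtil_pairs(bundle$clinical, cutoff = cutoff)
  per_sample <- bundle$clinical |>
    dplyr::filter(.data$timepoint == "baseline") |>
    dplyr::select(-"timepoint", -"cellularity_pct", -"tils_pct")
  celtil <- dplyr::left_join(celtil, per_sample, by = "sample_id")

  # --- stage 2: expression --------------------------------------------
  norm <- normalize_counts(bundle$counts)
  subtypes <- assign_subtype(norm, bundle$expression_model$centroids)
  sig_scores <- signature_score(norm, bundle$expression_model$signatures)
  erbb2 <- sig_scores |>
    dplyr::filter(.data$signature == "erbb2") |>
    dplyr::select("sample_id", erbb2_score = "score")
  tert_model <- fit_tertiles(erbb2$erbb2_score)
  erbb2$erbb2_tertile <- apply_tertiles(erbb2$erbb2_score, tert_model)
  expression <- list(normalized = norm, subtypes = subtypes,
                     signature_scores = sig_scores, erbb2 = erbb2,
                     tertile_model = tert_model)

  samples <- celtil |>
    dplyr::left_join(dplyr::select(subtypes, "sample_id", "subtype"),
                     by = "sample_id") |>
    dplyr::left_join(erbb2, by = "sample_id")

  # --- stage 3: copy number -------------------------------------------
  cn <- NULL
  if (!is.null(bundle$seg)) {
    gene_cn <- map_segments_to_genes(bundle$seg, bundle$cn_model_set$annotation)
    segsig <- segment_signal(gene_cn, bundle$cn_model_set$defs)
    cn_scores <- score_cn_signatures(segsig, bundle$cn_model_set$model)
    clusters <- assign_cn_cluster(cn_scores, bundle$cn_model_set$model)
    seg17 <- segsig |>
      dplyr::filter(.data$segment == "17q12") |>
      dplyr::select("sample_id", seg_17q12 = "signal")
    cn <- list(gene_cn = gene_cn, segment_signal = segsig,
               scores = cn_scores, clusters = clusters, seg17q12 = seg17)
    samples <- samples |>
      dplyr::left_join(dplyr::select(clusters, "sample_id", "cluster"),
                       by = "sample_id") |>
      dplyr::left_join(seg17, by = "sample_id")
  }

  # --- stage 4: variants ----------------------------------------------
  variants <- NULL
  if (!is.null(bundle$variants)) {
    filtered <- filter_variants(bundle$variants)
    freq <- mutation_frequency(filtered, n_samples = nrow(samples))
    tp53_status <- gene_mutation_status(
      filtered, "TP53",
      dplyr::select(samples, "sample_id", "responder")
    )
    variants <- list(filtered = filtered,
                     filter_summary = variant_filter_summary(filtered),
                     frequency = freq, tp53_status = tp53_status)
    samples <- dplyr::left_join(
      samples, dplyr::select(tp53_status, "sample_id", tp53_mutated = "mutated"),
      by = "sample_id"
    )
  }

  # --- stage 5: associations ------------------------------------------
  assoc <- list()
  assoc$erbb2_logistic <- logistic_fit(samples, responder, erbb2_score)
  assoc$erbb2_auc <- roc_auc(-samples$erbb2_score, samples$responder)
  assoc$sam <- sam_two_class(norm, samples$responder[match(
    setdiff(names(norm), "gene"), samples$sample_id
  )], n_permutations = n_permutations, fdr_threshold = fdr_threshold,
  seed = seed)
  tert_counts <- samples |>
    dplyr::group_by(.data$erbb2_tertile) |>
    dplyr::summarise(n = dplyr::n(), responders = sum(.data$responder),
                     rate = mean(.data$responder), .groups = "drop")
  assoc$erbb2_tertile_response <- tert_counts
  if ("clinical_response" %in% names(samples) &&
      length(unique(samples$clinical_response)) == 2) {
    assoc$celtil_vs_clinical_auc <- roc_auc(
      as.numeric(samples$responder), samples$clinical_response
    )
  }
  if (!is.null(variants)) {
    tab <- mutation_response_table(variants$tp53_status)
    assoc$tp53_table <- tab
    assoc$tp53_fisher <- fisher_exact(tab)
    assoc$tp53_or <- odds_ratio(tab)
  }
  if (!is.null(cn)) {
    in3 <- samples$cluster == "cluster3"
    tab3 <- matrix(
      c(sum(in3 & samples$responder), sum(in3 & !samples$responder),
        sum(!in3 & samples$responder), sum(!in3 & !samples$responder)),
      nrow = 2, byrow = TRUE,
      dimnames = list(c("cluster3", "cluster1/2/4"),
                      c("responder", "non-responder"))
    )
    assoc$cluster3_table <- tab3
    assoc$cluster3_or <- odds_ratio(tab3)
    assoc$cluster3_fisher <- fisher_exact(tab3)
    assoc$erbb2_17q12_cor <- cor(samples$erbb2_score, samples$seg_17q12,
                                 use = "complete.obs")
  }

  summary <- tibble(
    n_samples = nrow(samples),
    n_responders = sum(samples$responder),
    response_rate = mean(samples$responder),
    mean_delta = mean(samples$delta),
    cutoff = cutoff,
    sam_significant = sum(assoc$sam$genes$significant),
    seed = seed
  )

  report <- structure(
    list(samples = samples, celtil = celtil, expression = expression,
         cn = cn, variants = variants, associations = assoc,
         summary = summary),
    class = "run_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat("Pipeline run:", s$n_samples, "samples;",
      s$n_responders, sprintf("responders (%.1f%%) at cutoff %s\n",
                              100 * s$response_rate, format(s$cutoff)))
  cat("  mean scaled-CelTIL change:", sprintf("%.2f", s$mean_delta), "\n")
  cat("  SAM significant genes:", s$sam_significant, "\n")
  cat("  sections:", paste(names(Filter(Negate(is.null), x)), collapse = ", "), "\n")
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$samples, file.path(out_dir, "samples.tsv"),
                   progress = FALSE)
  readr::write_tsv(tidy(report$associations$sam),
                   file.path(out_dir, "sam_genes.tsv"), progress = FALSE)
  if (!is.null(report$variants)) {
    readr::write_tsv(report$variants$frequency,
                     file.path(out_dir, "mutation_frequency.tsv"),
                     progress = FALSE)
  }
  summary <- c(
    as.list(report$summary),
    list(
      erbb2_or = report$associations$erbb2_logistic$effect,
      erbb2_p = report$associations$erbb2_logistic$p_value,
      erbb2_auc = report$associations$erbb2_auc$effect
    ),
    if (!is.null(report$associations$tp53_or)) {
      list(tp53_or = report$associations$tp53_or$effect,
           tp53_fisher_p = report$associations$tp53_fisher$p_value)
    },
    if (!is.null(report$associations$cluster3_or)) {
      list(cluster3_or = report$associations$cluster3_or$effect,
           erbb2_17q12_cor = report$associations$erbb2_17q12_cor)
    }
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' CelTIL-cutoff sensitivity scan
#'
#' Re-runs the response classification and the key biomarker associations
#' at each cutoff of the sensitivity set, by default
#' `(>0, >=10, >=20, >=30, >=40)`; the `0` cutoff is strict (see
#' [celtil_responder()]).
#'
#' @param bundle A `cohort_bundle`.
#' @param cutoffs Numeric cutoffs to scan (default `c(0, 10, 20, 30, 40)`).
#' @param seed Seed passed to each run.
#' @return A tibble with one row per cutoff: responder counts, the ERBB2
#'   logistic odds ratio and p-value, and (when variants are present) the
#'   TP53 odds ratio.
#' @export
sensitivity_scan <- function(bundle, cutoffs = c(0, 10, 20, 30, 40), seed = 1) {
  purrr::map_dfr(cutoffs, function(co) {
    celtil <- celtil_pairs(bundle$clinical, cutoff = co)
    norm <- normalize_counts(bundle$counts)
    sig <- signature_score(norm, bundle$expression_model$signatures)
    erbb2 <- sig |>
      dplyr::filter(.data$signature == "erbb2") |>
      dplyr::select("sample_id", erbb2_score = "score")
    df <- dplyr::left_join(celtil, erbb2, by = "sample_id")
    fit <- tryCatch(
      logistic_fit(df, responder, erbb2_score),
      celtilr_error = function(e) NULL
    )
    tp53_or <- NA_real_
    if (!is.null(bundle$variants)) {
      filtered <- filter_variants(bundle$variants)
      status <- gene_mutation_status(
        filtered, "TP53", dplyr::select(df, "sample_id", "responder")
      )
      tab <- suppressWarnings(mutation_response_table(status))
      if (all(rowSums(tab) > 0) && all(tab[, 1] + tab[, 2] > 0)) {
        tp53_or <- odds_ratio(tab)$effect
      }
    }
    tibble(
      cutoff = co,
      n_responders = sum(celtil$responder),
      n_total = nrow(celtil),
      erbb2_or = if (is.null(fit)) NA_real_ else fit$effect,
      erbb2_p = if (is.null(fit)) NA_real_ else fit$p_value,
      tp53_or = tp53_or
    )
  })
}
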