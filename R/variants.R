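#' Read a MAF-like somatic mutation table
#'
#' Expects the common MAF column names `Tumor_Sample_Barcode`,
#' `Hugo_Symbol`, `Chromosome`, `Start_Position`, `Reference_Allele`,
#' `Tumor_Seq_Allele2`, `Variant_Type`, `t_alt_count`, `t_depth` and
#' (optionally) `gnomAD_AF`. `Variant_Type` values `SNP`/`SNV` are mapped
#' to `SNV`; `INS`/`DEL`/`INDEL` to `INDEL`. The variant allele frequency
#' is `t_alt_count / t_depth`.
#'
#' @param path Path to the tab-delimited file.
#' @return A tibble with columns `sample_id`, `gene`, `chrom`, `pos`,
#'   `ref`, `alt`, `variant_class`, `alt_reads`, `depth`, `vaf`,
#'   `population_af`.
#' @export
read_maf <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome",
            "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
            "Variant_Type", "t_alt_count", "t_depth")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop_celtilr(paste0("MAF file misses column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 "celtilr_validation_error")
  }
  tibble(
    sample_id = as.character(raw$Tumor_Sample_Barcode),
    gene = as.character(raw$Hugo_Symbol),
    chrom = as.character(raw$Chromosome),
    pos = as.integer(raw$Start_Position),
    ref = as.character(raw$Reference_Allele),
    alt = as.character(raw$Tumor_Seq_Allele2),
    variant_class = normalize_variant_class(raw$Variant_Type),
    alt_reads = as.integer(raw$t_alt_count),
    depth = as.integer(raw$t_depth),
    vaf = as.numeric(raw$t_alt_count) / as.numeric(raw$t_depth),
    population_af = if ("gnomAD_AF" %in% names(raw)) {
      as.numeric(raw$gnomAD_AF)
    } else {
      NA_real_
    }
  )
}

normalize_variant_class <- function(x) {
  x <- toupper(as.character(x))
  out <- dplyr::case_when(
    x %in% c("SNP", "SNV") ~ "SNV",
    x %in% c("INS", "DEL", "INDEL") ~ "INDEL",
    TRUE ~ NA_character_
  )
  if (anyNA(out)) {
    stop_celtilr(sprintf("Unknown variant class '%s'.", x[which(is.na(out))[1]]),
                 "celtilr_validation_error")
  }
  out
}

#' Filter somatic variants by read support, VAF and population frequency
#'
#' A variant is kept when it has at least `min_alt_reads` reads supporting
#' the alternate allele, a variant allele frequency at or above the
#' class-specific assay sensitivity (`min_vaf_snv` for SNVs,
#' `min_vaf_indel` for INDELs), and is rare in the population: missing
#' population AF, or AF at most `max_pop_af` (frequent polymorphisms are
#' removed). All thresholds are inclusive. Each dropped record is
#' attributed to the first failing rule, in the order read support, VAF,
#' population frequency.
#'
#' @param variants Variant tibble as from [read_maf()]; must carry
#'   `variant_class` in `{SNV, INDEL}`, `alt_reads`, `vaf`,
#'   `population_af`.
#' @param min_alt_reads Minimum alternate-allele read count (default 7).
#' @param min_vaf_snv,min_vaf_indel Minimum VAF for SNVs (default 0.05)
#'   and INDELs (default 0.10).
#' @param max_pop_af Maximum population allele frequency (default 1e-4).
#' @param vaf_filter Set `FALSE` to disable the VAF sensitivity filter.
#' @return The surviving rows as a tibble; per-rule drop counts are
#'   attached as attribute `"drops"` (see [variant_filter_summary()]).
#' @export
filter_variants <- function(variants, min_alt_reads = 7, min_vaf_snv = 0.05,
                            min_vaf_indel = 0.10, max_pop_af = 1e-4,
                            vaf_filter = TRUE) {
  variants <- as_tibble(variants)
  if (!nrow(variants)) {
    out <- variants
    attr(out, "drops") <- c(alt_reads = 0L, vaf = 0L, population_af = 0L)
    return(out)
  }
  cls <- normalize_variant_class(variants$variant_class)
  if (any(variants$alt_reads > variants$depth, na.rm = TRUE)) {
    stop_celtilr("alt_reads exceeds depth for some record.",
                 "celtilr_validation_error")
  }
  check_range(variants$vaf, "vaf", 0, 1)
  pass_reads <- variants$alt_reads >= min_alt_reads
  min_vaf <- ifelse(cls == "SNV", min_vaf_snv, min_vaf_indel)
  pass_vaf <- if (vaf_filter) variants$vaf >= min_vaf else rep(TRUE, nrow(variants))
  pass_pop <- is.na(variants$population_af) | variants$population_af <= max_pop_af
  first_fail <- dplyr::case_when(
    !pass_reads ~ "alt_reads",
    !pass_vaf ~ "vaf",
    !pass_pop ~ "population_af",
    TRUE ~ NA_character_
  )
  keep <- is.na(first_fail)
  drops <- c(
    alt_reads = sum(first_fail == "alt_reads", na.rm = TRUE),
    vaf = sum(first_fail == "vaf", na.rm = TRUE),
    population_af = sum(first_fail == "population_af", na.rm = TRUE)
  )
  out <- variants[keep, , drop = FALSE]
  attr(out, "drops") <- drops
  out
}

#' Per-rule drop counts from a variant filter run
#'
#' @param filtered Output of [filter_variants()].
#' @return A tibble with columns `rule`, `n_dropped`.
#' @export
variant_filter_summary <- function(filtered) {
  drops <- attr(filtered, "drops")
  if (is.null(drops)) {
    stop_celtilr("No filter metadata found; pass the output of filter_variants().",
                 "celtilr_validation_error")
  }
  tibble(rule = names(drops), n_dropped = as.integer(drops))
}

#' Per-gene somatic mutation frequency
#'
#' The frequency of a gene is the number of distinct samples carrying at
#' least one (filtered) variant in it, divided by the cohort size.
#'
#' @param variants Variant tibble (typically after [filter_variants()]).
#' @param n_samples Cohort size (>= 1); may exceed the number of samples
#'   present in `variants`.
#' @param genes Optional gene set to report (absent genes get frequency
#'   0); default: all genes observed.
#' @return A tibble `gene`, `n_mutated`, `frequency`, sorted by
#'   decreasing frequency.
#' @export
mutation_frequency <- function(variants, n_samples, genes = NULL) {
  if (n_samples < 1) {
    stop_celtilr("`n_samples` must be >= 1.", "celtilr_validation_error")
  }
  variants <- as_tibble(variants)
  counts <- variants |>
    dplyr::distinct(.data$gene, .data$sample_id) |>
    dplyr::count(.data$gene, name = "n_mutated")
  if (!is.null(genes)) {
    counts <- dplyr::left_join(tibble(gene = genes), counts, by = "gene") |>
      dplyr::mutate(n_mutated = dplyr::coalesce(.data$n_mutated, 0L))
  }
  counts |>
    dplyr::mutate(frequency = .data$n_mutated / n_samples) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$gene)
}

#' Mutation-by-response 2x2 contingency table for one gene
#'
#' Cross-tabulates per-sample mutation status against responder status.
#' Rows are `mutant` / `wild-type`, columns `responder` /
#' `non-responder`; the cell sum equals the cohort size. A degenerate row
#' (no mutants or no wild-types) is allowed but flagged with a warning.
#'
#' @param status A data frame with one row per sample and logical columns
#'   `mutated` and `responder` (plus `sample_id`). Every sample must have
#'   both statuses defined.
#' @return A 2x2 integer matrix with dimnames.
#' @export
mutation_response_table <- function(status) {
  status <- as_tibble(status)
  need <- c("sample_id", "mutated", "responder")
  if (!all(need %in% names(status))) {
    stop_celtilr("`status` needs columns sample_id, mutated, responder.",
                 "celtilr_validation_error")
  }
  if (anyNA(status$mutated) || anyNA(status$responder)) {
    stop_celtilr("Mutation or responder status missing for some sample.",
                 "celtilr_validation_error")
  }
  if (anyDuplicated(status$sample_id)) {
    stop_celtilr("Duplicated sample_id in status table.", "celtilr_validation_error")
  }
  tab <- matrix(
    c(
      sum(status$mutated & status$responder),
      sum(status$mutated & !status$responder),
      sum(!status$mutated & status$responder),
      sum(!status$mutated & !status$responder)
    ),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("mutant", "wild-type"), c("responder", "non-responder"))
  )
  if (any(rowSums(tab) == 0)) {
    rlang::warn("Degenerate mutation-by-response table: an empty status row.",
                class = "celtilr_degenerate_table")
  }
  tab
}

#' Join mutation calls and responder calls into a status table
#'
#' Convenience builder for [mutation_response_table()]: marks each sample
#' of `samples` as mutated when it carries a variant in `gene`.
#'
#' @param variants Filtered variant tibble.
#' @param gene Gene symbol.
#' @param response Tibble with columns `sample_id` and `responder`
#'   covering the whole cohort.
#' @return A status tibble (`sample_id`, `mutated`, `responder`).
#' @export
gene_mutation_status <- function(variants, gene, response) {
  response <- as_tibble(response)
  mutated_samples <- unique(variants$sample_id[variants$gene == gene])
  unknown <- setdiff(mutated_samples, response$sample_id)
  if (length(unknown)) {
    stop_celtilr(
      sprintf("Sample '%s' has variants but no responder status.", unknown[1]),
      "celtilr_validation_error"
    )
  }
  tibble(
    sample_id = response$sample_id,
    mutated = response$sample_id %in% mutated_samples,
    responder = response$responder
  )
}
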