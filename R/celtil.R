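#' Raw CelTIL score
#'
#' The CelTIL score combines tumor cellularity and stromal
#' tumor-infiltrating lymphocytes (TILs) from a single H&E-stained biopsy
#' into one measure of early drug activity:
#' \deqn{\mathrm{CelTIL}_{raw} = -0.8 \times \mathrm{cellularity}\% + 1.3 \times \mathrm{TILs}\%}
#' High scores identify tumors that are highly immune infiltrated with
#' reduced tumor cellularity. Over the valid input square the raw score
#' spans \eqn{[-80, 130]}.
#'
#' @param cellularity Tumor cellularity as a percentage in \[0, 100\]
#'   (percentage of tumor cells relative to tumor area).
#' @param tils Stromal TILs as a percentage in \[0, 100\], scored per the
#'   International TILs Working Group guidelines.
#' @return A numeric vector of raw CelTIL scores.
#' @seealso [celtil_scaled()] for the 0-100 rescaling, [celtil_score()] for
#'   the data-frame interface.
#' @examples
#' celtil_raw(50, 10) # -27
#' @export
celtil_raw <- function(cellularity, tils) {
  check_range(cellularity, "cellularity", 0, 100)
  check_range(tils, "tils", 0, 100)
  -0.8 * cellularity + 1.3 * tils
}

#' Scale a raw CelTIL score to 0-100 points
#'
#' Affine rescaling of the raw score from its theoretical range
#' \eqn{[-80, 130]} (width 210) onto \eqn{[0, 100]} points:
#' \eqn{(raw + 80) / 210 \times 100}.
#'
#' @param raw Raw CelTIL score(s) in \[-80, 130\].
#' @return Scaled score(s) in \[0, 100\].
#' @examples
#' celtil_scaled(celtil_raw(50, 10))
#' @export
celtil_scaled <- function(raw) {
  check_range(raw, "raw", -80, 130)
  (raw + 80) / 210 * 100
}

#' CelTIL response call from a score change
#'
#' A sample is a CelTIL responder when the scaled score increased by at
#' least `cutoff` points from baseline to day 21. The default cutoff of 20
#' points is the primary definition; the sensitivity set
#' `{>0, >=10, >=20, >=30, >=40}` is supported, with the `0` cutoff applied
#' strictly (`delta > 0`) and all others inclusively (`delta >= cutoff`).
#'
#' @param delta Change in scaled CelTIL (day 21 minus baseline), in points.
#' @param cutoff Response cutoff in points (default 20).
#' @return Logical vector of responder calls.
#' @export
celtil_responder <- function(delta, cutoff = 20) {
  stopifnot(is.numeric(delta), length(cutoff) == 1L, is.numeric(cutoff))
  if (cutoff == 0) delta > 0 else delta >= cutoff
}

#' Score CelTIL on a clinical/pathology table
#'
#' Data-frame interface over [celtil_raw()] and [celtil_scaled()]: appends
#' `celtil_raw` and `celtil` (scaled, 0-100 points) columns.
#'
#' @param data A data frame with cellularity and TILs percentage columns.
#' @param cellularity,tils Columns holding the percentages
#'   (tidy-eval; defaults `cellularity_pct`, `tils_pct`).
#' @return `data` as a tibble with `celtil_raw` and `celtil` columns added.
#' @examples
#' df <- tibble::tibble(sample_id = "s1", cellularity_pct = 80, tils_pct = 5)
#' celtil_score(df)
#' @export
celtil_score <- function(data, cellularity = cellularity_pct, tils = tils_pct) {
  cellularity <- rlang::enquo(cellularity)
  tils <- rlang::enquo(tils)
  out <- dplyr::mutate(
    as_tibble(data),
    celtil_raw = celtil_raw(!!cellularity, !!tils),
    celtil = celtil_scaled(.data$celtil_raw)
  )
  out
}

#' Pair baseline and day-21 biopsies and compute CelTIL change
#'
#' Takes a long clinical table (one row per biopsy) and returns one row per
#' sample with baseline and day-21 scaled CelTIL, their difference
#' (`delta`, day 21 minus baseline) and the responder call at `cutoff`.
#'
#' @param data Long data frame with columns `sample_id`, `timepoint`
#'   (values `"baseline"` and `"day21"`), `cellularity_pct`, `tils_pct`.
#' @param cutoff Response cutoff in points; see [celtil_responder()].
#' @return A tibble with one row per sample: `sample_id`,
#'   `celtil_baseline`, `celtil_day21`, `delta`, `responder`, `cutoff`.
#' @examples
#' df <- tibble::tibble(
#'   sample_id = c("s1", "s1"),
#'   timepoint = c("baseline", "day21"),
#'   cellularity_pct = c(80, 30),
#'   tils_pct = c(5, 20)
#' )
#' celtil_pairs(df)
#' @export
celtil_pairs <- function(data, cutoff = 20) {
  data <- as_tibble(data)
  required <- c("sample_id", "timepoint", "cellularity_pct", "tils_pct")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop_celtilr(
      paste0("Missing columns: ", paste(missing_cols, collapse = ", ")),
      "celtilr_validation_error"
    )
  }
  bad_tp <- setdiff(unique(data$timepoint), c("baseline", "day21"))
  if (length(bad_tp)) {
    stop_celtilr(
      paste0("Unknown timepoint label(s): ", paste(bad_tp, collapse = ", ")),
      "celtilr_validation_error"
    )
  }
  counts <- dplyr::count(data, .data$sample_id, .data$timepoint)
  dup <- counts[counts$n > 1L, ]
  if (nrow(dup)) {
    stop_celtilr(
      sprintf(
        "Duplicated timepoint '%s' for sample '%s'.",
        dup$timepoint[1], dup$sample_id[1]
      ),
      "celtilr_pairing_error"
    )
  }
  per_sample <- dplyr::count(data, .data$sample_id)
  unpaired <- per_sample$sample_id[per_sample$n != 2L]
  if (length(unpaired)) {
    stop_celtilr(
      sprintf(
        "Sample '%s' does not have both a baseline and a day21 assessment.",
        unpaired[1]
      ),
      "celtilr_pairing_error"
    )
  }
  scored <- celtil_score(data)
  wide <- tidyr::pivot_wider(
    dplyr::select(scored, "sample_id", "timepoint", "celtil"),
    names_from = "timepoint", values_from = "celtil"
  )
  tibble(
    sample_id = wide$sample_id,
    celtil_baseline = wide$baseline,
    celtil_day21 = wide$day21,
    delta = wide$day21 - wide$baseline,
    responder = celtil_responder(wide$day21 - wide$baseline, cutoff),
    cutoff = cutoff
  )
}

#' Summarize a set of responder calls
#'
#' @param x Either a logical vector of responder calls or a data frame with
#'   a `responder` column (e.g. the output of [celtil_pairs()]).
#' @return A one-row tibble: `n_responders`, `n_total`, `proportion`.
#' @examples
#' response_rate(c(TRUE, FALSE, TRUE))
#' @export
response_rate <- function(x) {
  if (is.data.frame(x)) {
    if (!"responder" %in% names(x)) {
      stop_celtilr("`x` must contain a `responder` column.", "celtilr_validation_error")
    }
    x <- x$responder
  }
  if (!length(x)) {
    stop_celtilr("Cannot compute a response rate from an empty set.",
                 "celtilr_validation_error")
  }
  x <- as.logical(x)
  if (anyNA(x)) {
    stop_celtilr("Responder calls contain missing values.", "celtilr_validation_error")
  }
  tibble(
    n_responders = sum(x),
    n_total = length(x),
    proportion = sum(x) / length(x)
  )
}

#' Read a clinical/pathology table
#'
#' Expects a delimited file (TSV or CSV, sniffed from the extension) with
#' columns `sample_id`, `timepoint`, `cellularity_pct`, `tils_pct`;
#' percentages as numbers 0-100, not fractions. Extra columns (hormone
#' receptor status, HER2 IHC, clinical response, ...) pass through.
#'
#' @param path Path to the file.
#' @return A tibble.
#' @export
read_clinical <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  out <- reader(path, show_col_types = FALSE, progress = FALSE)
  as_tibble(out)
}
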