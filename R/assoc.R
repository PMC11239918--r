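assoc_result <- function(effect, ci_low, ci_high, p_value, method, n,
                         flag = NA_character_) {
  tibble(
    effect = effect, ci_low = ci_low, ci_high = ci_high,
    p_value = p_value, method = method, n = n, flag = flag
  )
}

check_contingency <- function(tab) {
  if (!is.matrix(tab) || !is.numeric(tab)) {
    stop_celtilr("Contingency table must be a numeric matrix.",
                 "celtilr_validation_error")
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop_celtilr("Contingency cells must be non-negative integers.",
                 "celtilr_validation_error")
  }
  if (nrow(tab) < 2 || ncol(tab) < 2 || sum(tab) == 0) {
    stop_celtilr("Need at least a 2x2 table with positive total.",
                 "celtilr_validation_error")
  }
  invisible(tab)
}

#' Two-sided Fisher's exact test
#'
#' Exact conditional test on an r x c contingency table with the standard
#' two-sided convention: the p-value sums the probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (probability-mass ordering). 2x2 tables use the
#' hypergeometric distribution; larger tables the Freeman-Halton
#' extension. For tables too large to enumerate (`sum(tab) > max_total`),
#' set `mc = TRUE` for a seeded Monte Carlo p-value.
#'
#' @param tab Integer matrix (at least 2x2).
#' @param mc Use Monte Carlo simulation instead of full enumeration.
#' @param B Number of Monte Carlo replicates (when `mc = TRUE`).
#' @param seed Seed for the Monte Carlo draw.
#' @param max_total Largest table total for which full enumeration is
#'   attempted (default 200).
#' @return A one-row tibble: `effect` (cross-product odds ratio, 2x2
#'   only), `ci_low`/`ci_high` (`NA`; see [odds_ratio()]), `p_value`,
#'   `method`, `n`, `flag`.
#' @examples
#' fisher_exact(matrix(c(6, 3, 10, 30), 2, 2, byrow = TRUE))
#' @export
fisher_exact <- function(tab, mc = FALSE, B = 10000, seed = NULL,
                         max_total = 200) {
  check_contingency(tab)
  total <- sum(tab)
  is_2x2 <- nrow(tab) == 2 && ncol(tab) == 2
  if (total > max_total && !mc) {
    stop_celtilr(
      sprintf(paste0("Table total %d exceeds the enumeration limit %d; ",
                     "re-run with mc = TRUE (and a seed) for a Monte Carlo ",
                     "p-value."), total, max_total),
      "celtilr_validation_error"
    )
  }
  if (mc) {
    res <- with_local_seed(seed, fisher.test(tab, simulate.p.value = TRUE, B = B))
    method <- "fisher_mc"
  } else {
    res <- fisher.test(tab)
    method <- if (is_2x2) "fisher_2x2" else "fisher_freeman_halton"
  }
  effect <- if (is_2x2) {
    cross_product_or(tab)
  } else {
    NA_real_
  }
  assoc_result(effect, NA_real_, NA_real_, res$p.value, method, total)
}

cross_product_or <- function(tab) {
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

#' Odds ratio of a 2x2 table with Wald confidence interval
#'
#' Cross-product (unconditional) odds ratio `ad / bc` with the Wald
#' 95% interval on the log scale. With a zero cell the odds ratio is 0 or
#' infinite and the interval undefined; setting `correction = TRUE`
#' applies the Haldane-Anscombe 0.5 continuity correction to every cell
#' instead, and the result is flagged either way.
#'
#' @param tab 2x2 integer matrix (rows: exposure; columns: outcome).
#' @param conf_level Confidence level (default 0.95).
#' @param correction Apply the Haldane-Anscombe 0.5 correction when a cell
#'   is zero.
#' @return A one-row association tibble; `effect` is the odds ratio.
#' @examples
#' odds_ratio(matrix(c(6, 3, 10, 30), 2, 2, byrow = TRUE))
#' @export
odds_ratio <- function(tab, conf_level = 0.95, correction = FALSE) {
  check_contingency(tab)
  if (nrow(tab) != 2 || ncol(tab) != 2) {
    stop_celtilr("odds_ratio() needs a 2x2 table.", "celtilr_validation_error")
  }
  n <- sum(tab)
  flag <- NA_character_
  work <- tab
  if (any(tab == 0)) {
    if (correction) {
      work <- tab + 0.5
      flag <- "haldane_anscombe"
    } else {
      flag <- "zero_cell"
    }
  }
  or <- (work[1, 1] * work[2, 2]) / (work[1, 2] * work[2, 1])
  if (!is.finite(or) || or == 0) {
    return(assoc_result(or, NA_real_, NA_real_, NA_real_, "odds_ratio", n, flag))
  }
  se <- sqrt(sum(1 / work))
  z <- qnorm(1 - (1 - conf_level) / 2)
  assoc_result(or, exp(log(or) - z * se), exp(log(or) + z * se),
               2 * pnorm(-abs(log(or) / se)), "odds_ratio", n, flag)
}

#' Uni- or bivariable logistic regression for a binary outcome
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()], convergence tolerance 1e-8, up to 100
#' iterations). Reports one row per covariate with the odds ratio
#' `exp(coefficient)`, the Wald confidence interval and p-value. Complete
#' or quasi-complete separation is detected from non-convergence or
#' runaway coefficients and flagged rather than silently reported.
#'
#' @param data Data frame holding outcome and covariates.
#' @param response Outcome column (tidy-eval); logical or 0/1.
#' @param ... One or more covariate columns (tidy-eval).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with one row per covariate: `term`, `estimate`
#'   (log-odds scale), `effect` (odds ratio), `ci_low`, `ci_high`
#'   (odds-ratio scale), `p_value`, `method`, `n`, `flag`.
#' @export
logistic_fit <- function(data, response, ..., conf_level = 0.95) {
  data <- as_tibble(data)
  y <- as.numeric(rlang::eval_tidy(rlang::enquo(response), data))
  terms_q <- rlang::enquos(...)
  if (!length(terms_q)) {
    stop_celtilr("Supply at least one covariate.", "celtilr_validation_error")
  }
  X <- lapply(terms_q, function(q) rlang::eval_tidy(q, data))
  term_names <- vapply(terms_q, rlang::as_label, character(1))
  names(X) <- term_names
  df <- tibble::as_tibble(X)
  df$.y <- y
  df <- df[complete.cases(df), , drop = FALSE]
  if (length(unique(df$.y)) < 2) {
    stop_celtilr("Outcome needs at least one event and one non-event.",
                 "celtilr_validation_error")
  }
  for (nm in term_names) {
    v <- df[[nm]]
    if (is.numeric(v) && sd(v) == 0) {
      stop_celtilr(sprintf("Covariate '%s' is constant.", nm),
                   "celtilr_validation_error")
    }
  }
  # separation is detected and flagged below; muffle glm's fitted-probability
  # warning so callers see the flag, not a loose warning
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial(),
        control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  separated <- !fit$converged || any(abs(est[-1]) > 15) ||
    all(abs(fit$fitted.values - 0.5) > 0.5 - 1e-6)
  flag <- if (separated) "separation" else NA_character_
  z <- qnorm(1 - (1 - conf_level) / 2)
  idx <- setdiff(names(est), "(Intercept)")
  # map model-matrix coefficient names back to user terms where possible
  out <- tibble(
    term = idx,
    estimate = unname(est[idx]),
    effect = exp(unname(est[idx])),
    ci_low = exp(unname(est[idx] - z * se[idx])),
    ci_high = exp(unname(est[idx] + z * se[idx])),
    p_value = unname(2 * pnorm(-abs(est[idx] / se[idx]))),
    method = "logistic",
    n = nrow(df),
    flag = flag
  )
  attr(out, "fit") <- fit
  out
}

#' Rank-based ROC AUC (Mann-Whitney)
#'
#' The area under the ROC curve computed from midranks:
#' \eqn{AUC = (R_1 - n_1(n_1+1)/2) / (n_1 n_0)} where \eqn{R_1} is the
#' rank sum of the positive class. For a binary predictor this reduces to
#' `(sensitivity + specificity) / 2`. The p-value is the normal
#' approximation to the Mann-Whitney test with tie correction; the
#' confidence interval uses the Hanley-McNeil standard error.
#'
#' @param scores Numeric predictor (higher predicts the positive class).
#' @param labels Binary outcome (logical or 0/1).
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row association tibble; `effect` is the AUC.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop_celtilr("Both outcome classes must be present.", "celtilr_validation_error")
  }
  r <- rank(scores) # midranks
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  p <- suppressWarnings(
    wilcox.test(scores[labels], scores[!labels],
                exact = FALSE, correct = FALSE)$p.value
  )
  # Hanley & McNeil (1982) SE
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  assoc_result(auc, max(0, auc - z * se), min(1, auc + z * se), p,
               "roc_auc", n1 + n0)
}

#' Two-tailed t test as an association result
#'
#' Unpaired tests use the Welch variant by default (`var_equal = TRUE`
#' for the pooled-variance test); `paired = TRUE` runs a paired test.
#'
#' @param x,y Numeric vectors (for `paired = TRUE`, matched pairs).
#' @param paired Paired test flag.
#' @param var_equal Assume equal variances (unpaired only).
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row association tibble; `effect` is the mean difference
#'   (`mean(x) - mean(y)`).
#' @export
assoc_t_test <- function(x, y, paired = FALSE, var_equal = FALSE,
                         conf_level = 0.95) {
  if (sd(x, na.rm = TRUE) == 0 && sd(y, na.rm = TRUE) == 0 &&
      !(paired && sd(x - y, na.rm = TRUE) > 0)) {
    stop_celtilr("Zero variance in both groups; t test undefined.",
                 "celtilr_validation_error")
  }
  res <- t.test(x, y, paired = paired, var.equal = var_equal,
                conf.level = conf_level)
  assoc_result(
    unname(if (paired) res$estimate else res$estimate[1] - res$estimate[2]),
    res$conf.int[1], res$conf.int[2], res$p.value,
    if (paired) "t_paired" else if (var_equal) "t_pooled" else "t_welch",
    sum(!is.na(x)) + if (paired) 0L else sum(!is.na(y))
  )
}
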