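#' Two-class significance analysis of microarrays (SAM)
#'
#' Moderated two-class comparison with permutation-based false discovery
#' control. For gene \eqn{i} the statistic is
#' \eqn{d_i = (\bar x_{i2} - \bar x_{i1}) / (s_i + s_0)} with \eqn{s_i}
#' the pooled standard error and \eqn{s_0} a fudge factor chosen over a
#' percentile grid of the \eqn{s_i} to minimize the coefficient of
#' variation of the median absolute deviation of \eqn{d} across
#' \eqn{s_i}-windows. Expected order statistics \eqn{\bar d_{(i)}} come
#' from label permutations; for a threshold \eqn{\Delta} genes are called
#' outside the slab where the observed order statistics depart from the
#' expected ones by more than \eqn{\Delta}. The FDR at \eqn{\Delta} is
#' \eqn{\hat\pi_0 \times} (mean permutation call count) / (observed call
#' count), with \eqn{\hat\pi_0} estimated from the central 50% of the
#' permuted statistics. The reported gene set uses the smallest
#' \eqn{\Delta} on the search grid whose estimated FDR is at or below
#' `fdr_threshold`; per-gene q-values are the smallest FDR at which each
#' gene is called.
#'
#' @param expr Normalized expression: numeric matrix (genes x samples,
#'   rownames = genes) or a tibble with a `gene` column.
#' @param labels Binary class labels, one per sample; the statistic is
#'   class 2 minus class 1 (`TRUE`/second level minus `FALSE`/first).
#' @param n_permutations Number of label permutations (default 1000). If
#'   the number of distinct label assignments is smaller, all are
#'   enumerated.
#' @param fdr_threshold Target FDR for the significant set (default 0.10).
#' @param seed Optional seed for the permutation draw; the calling RNG
#'   state is left untouched.
#' @param s0_grid Percentiles of `s` searched for the fudge factor
#'   (default `seq(0, 1, 0.05)`).
#' @param n_delta Number of thresholds on the `delta` search grid.
#' @return A `sam_fit` object; see [tidy.sam_fit()] and
#'   [glance.sam_fit()]. Key elements: `genes` (per-gene tibble with `d`,
#'   `q_value`, `significant`), `s0`, `delta`, `fdr`, `pi0`,
#'   `delta_table`.
#' @export
sam_two_class <- function(expr, labels, n_permutations = 1000,
                          fdr_threshold = 0.10, seed = NULL,
                          s0_grid = seq(0, 1, 0.05), n_delta = 60) {
  X <- as_sam_matrix(expr)
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop_celtilr("`fdr_threshold` must be in (0, 1).", "celtilr_validation_error")
  }
  if (n_permutations < 1) {
    stop_celtilr("`n_permutations` must be >= 1.", "celtilr_validation_error")
  }
  cls <- as.integer(as.factor(labels))
  if (length(cls) != ncol(X)) {
    stop_celtilr("One label per sample required.", "celtilr_validation_error")
  }
  if (length(unique(cls)) != 2 || min(table(cls)) < 2) {
    stop_celtilr("Two classes with at least 2 samples each are required.",
                 "celtilr_validation_error")
  }
  z_obs <- as.numeric(cls == 2L)
  p <- nrow(X)
  obs <- sam_d_stats(X, z_obs)
  s0 <- sam_choose_s0(obs$r, obs$s, s0_grid)
  d <- obs$r / (obs$s + s0$s0)

  perms <- sam_permutations(length(z_obs), sum(z_obs), n_permutations, seed)
  dperm <- sam_permuted_d(X, perms, s0$s0) # genes x B
  B <- ncol(dperm)
  dbar <- rowMeans(apply(dperm, 2, sort)) # expected order statistics
  qs <- quantile(dperm, c(0.25, 0.75))
  pi0 <- min(1, sum(d > qs[1] & d < qs[2]) / (0.5 * p))

  ord <- order(d)
  dsort <- d[ord]
  diffs <- dsort - dbar
  delta_grid <- sort(unique(c(0, quantile(abs(diffs), probs = seq(0, 1, length.out = n_delta)))))
  delta_table <- purrr::map_dfr(delta_grid, function(del) {
    cuts <- sam_cutoffs(dsort, dbar, del)
    called <- sum(d >= cuts$cutup) + sum(d <= cuts$cutlow)
    fp <- colSums(dperm >= cuts$cutup) + colSums(dperm <= cuts$cutlow)
    # mean permutation call count: the median is unstable when only a
    # handful of genes are called and loses type-I control on null data
    exp_fp <- mean(fp)
    fdr <- if (called == 0) 0 else min(1, pi0 * exp_fp / called)
    tibble(delta = del, cutlow = cuts$cutlow, cutup = cuts$cutup,
           n_called = called, expected_false = exp_fp, fdr = fdr)
  })

  ok <- delta_table$fdr <= fdr_threshold
  delta_row <- if (any(ok)) delta_table[which(ok)[1], ] else delta_table[nrow(delta_table), ]
  significant <- d >= delta_row$cutup | d <= delta_row$cutlow
  if (!any(ok)) significant[] <- FALSE

  # q-value: smallest estimated FDR among grid thresholds calling the gene
  q <- rep(1, p)
  for (k in seq_len(nrow(delta_table))) {
    hit <- d >= delta_table$cutup[k] | d <= delta_table$cutlow[k]
    q[hit] <- pmin(q[hit], delta_table$fdr[k])
  }

  genes <- tibble(
    gene = rownames(X),
    d = d,
    mean_diff = obs$r,
    s = obs$s,
    q_value = q,
    significant = significant,
    direction = ifelse(d >= 0, "up", "down")
  )
  structure(
    list(
      genes = genes, s0 = s0$s0, s0_percentile = s0$alpha,
      delta = delta_row$delta, cutlow = delta_row$cutlow,
      cutup = delta_row$cutup, fdr = delta_row$fdr,
      fdr_threshold = fdr_threshold, pi0 = pi0,
      n_permutations = B, delta_table = delta_table,
      dbar = dbar, d_order = ord,
      n1 = sum(z_obs == 0), n2 = sum(z_obs == 1)
    ),
    class = "sam_fit"
  )
}

as_sam_matrix <- function(expr) {
  if (is.data.frame(expr)) {
    if (!"gene" %in% names(expr)) {
      stop_celtilr("Expression tibble needs a `gene` column.",
                   "celtilr_validation_error")
    }
    m <- as.matrix(expr[setdiff(names(expr), "gene")])
    rownames(m) <- expr$gene
    m
  } else {
    m <- as.matrix(expr)
    if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
    m
  }
}

# class-2-minus-class-1 numerator and pooled standard error per gene
sam_d_stats <- function(X, z) {
  n <- length(z)
  n2 <- sum(z)
  n1 <- n - n2
  rs <- rowSums(X)
  rs2 <- rowSums(X^2)
  s2sum <- as.numeric(X %*% z)
  s2sq <- as.numeric(X^2 %*% z)
  m2 <- s2sum / n2
  m1 <- (rs - s2sum) / n1
  ss2 <- s2sq - n2 * m2^2
  ss1 <- (rs2 - s2sq) - n1 * m1^2
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(r = m2 - m1, s = s)
}

# Tusher-style fudge factor: percentile of s minimizing the coefficient of
# variation of window-wise mad(d) across windows of s
sam_choose_s0 <- function(r, s, s0_grid) {
  p <- length(s)
  n_windows <- min(100L, max(2L, floor(p / 10)))
  br <- unique(quantile(s, seq(0, 1, length.out = n_windows + 1)))
  win <- cut(s, breaks = br, include.lowest = TRUE)
  cvs <- vapply(s0_grid, function(alpha) {
    s0 <- if (alpha == 0) 0 else unname(quantile(s, alpha))
    dd <- r / (s + s0)
    v <- tapply(dd, win, mad)
    v <- v[!is.na(v)]
    if (mean(v) == 0) Inf else sd(v) / mean(v)
  }, numeric(1))
  alpha <- s0_grid[which.min(cvs)]
  list(s0 = if (alpha == 0) 0 else unname(quantile(s, alpha)), alpha = alpha)
}

# balanced label permutations as an n x B indicator matrix
sam_permutations <- function(n, n2, B, seed = NULL) {
  total <- choose(n, n2)
  draw <- function() {
    if (total <= B) {
      idx <- utils::combn(n, n2, simplify = FALSE)
    } else {
      idx <- replicate(B, sample.int(n, n2), simplify = FALSE)
    }
    Z <- vapply(idx, function(i) {
      z <- numeric(n)
      z[i] <- 1
      z
    }, numeric(n))
    Z
  }
  with_local_seed(seed, draw())
}

sam_permuted_d <- function(X, Z, s0) {
  n <- nrow(Z)
  n2 <- colSums(Z)
  n1 <- n - n2
  rs <- rowSums(X)
  rs2 <- rowSums(X^2)
  S1 <- X %*% Z        # genes x B sums in class 2
  S2 <- X^2 %*% Z
  m2 <- sweep(S1, 2, n2, "/")
  m1 <- sweep(sweep(-S1, 1, rs, "+"), 2, n1, "/") # (rs - S1) / n1
  ss2 <- S2 - sweep(m2^2, 2, n2, "*")
  ss1 <- sweep(-S2, 1, rs2, "+") - sweep(m1^2, 2, n1, "*")
  fac <- (1 / n1 + 1 / n2) / (n - 2) # per-permutation scaling
  s <- sqrt(sweep(ss1 + ss2, 2, fac, "*"))
  (m2 - m1) / (s + s0)
}

# slab rule: walking out from the origin of the quantile-quantile display,
# the first departures exceeding delta set the calling cutoffs
sam_cutoffs <- function(dsort, dbar, delta) {
  diffs <- dsort - dbar
  origin <- which.min(abs(dbar))
  up_candidates <- which(diffs >= delta & seq_along(dsort) >= origin)
  cutup <- if (length(up_candidates)) dsort[min(up_candidates)] else Inf
  low_candidates <- which(diffs <= -delta & seq_along(dsort) <= origin)
  cutlow <- if (length(low_candidates)) dsort[max(low_candidates)] else -Inf
  list(cutup = cutup, cutlow = cutlow)
}

#' @export
print.sam_fit <- function(x, ...) {
  cat("SAM two-class fit:", nrow(x$genes), "genes,", x$n1, "vs", x$n2,
      "samples,", x$n_permutations, "permutations\n")
  cat(sprintf("  s0 = %.4g (percentile %.2f), pi0 = %.3f\n",
              x$s0, x$s0_percentile, x$pi0))
  cat(sprintf("  delta = %.4g -> %d significant genes (estimated FDR %.3f, target < %.2f)\n",
              x$delta, sum(x$genes$significant), x$fdr, x$fdr_threshold))
  invisible(x)
}

#' Per-gene SAM results
#'
#' @param x A `sam_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per gene: `gene`, `d`, `mean_diff`, `s`,
#'   `q_value`, `significant`, `direction`.
#' @export
tidy.sam_fit <- function(x, ...) {
  x$genes
}

#' One-row SAM fit summary
#'
#' @param x A `sam_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `n_genes`, `n_significant`, `delta`, `fdr`,
#'   `pi0`, `s0`, `n_permutations`.
#' @export
glance.sam_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes),
    n_significant = sum(x$genes$significant),
    delta = x$delta,
    fdr = x$fdr,
    pi0 = x$pi0,
    s0 = x$s0,
    n_permutations = x$n_permutations
  )
}

#' SAM quantile-quantile plot
#'
#' Observed ordered statistics against their permutation expectation with
#' the `delta` slab; genes outside the slab are the significant calls.
#'
#' @param object A `sam_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sam_fit <- function(object, ...) {
  df <- tibble(
    expected = object$dbar,
    observed = sort(object$genes$d),
    significant = object$genes$significant[object$d_order]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_abline(slope = 1, intercept = object$delta,
                         linetype = 3, colour = "grey30") +
    ggplot2::geom_abline(slope = 1, intercept = -object$delta,
                         linetype = 3, colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "Expected order statistic (permutations)",
      y = "Observed SAM statistic d",
      colour = "Significant"
    ) +
    ggplot2::theme_minimal()
}
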