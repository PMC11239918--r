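test_that("2x2 Fisher p-values match hypergeometric enumeration on random tables", {
  set.seed(41)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2, 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab)$p_value, enum_fisher_2x2(tab),
                 tolerance = 1e-9)
  }
})

test_that("tables with a zero margin give p = 1", {
  expect_equal(fisher_exact(matrix(c(0, 0, 5, 7), 2, byrow = TRUE))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(3, 0, 5, 0), 2))$p_value, 1)
})

test_that("the Freeman-Halton extension matches enumeration and reduces to 2x2", {
  set.seed(42)
  for (i in 1:10) {
    tab <- matrix(rpois(6, 4), 3, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value, enum_fisher_rxc(tab),
                 tolerance = 1e-7)
  }
  t22 <- matrix(c(5, 2, 3, 9), 2, byrow = TRUE)
  expect_equal(fisher_exact(t22)$p_value, enum_fisher_2x2(t22), tolerance = 1e-9)
  # identical rows carry no association
  flat <- matrix(c(4, 6, 4, 6, 4, 6), 3, 2, byrow = TRUE)
  expect_equal(fisher_exact(flat)$p_value, 1, tolerance = 1e-9)
})

test_that("oversized tables demand the seeded Monte Carlo fallback", {
  big <- matrix(c(80, 40, 60, 70), 2, byrow = TRUE)
  expect_error(fisher_exact(big), "mc = TRUE", class = "celtilr_validation_error")
  mc1 <- fisher_exact(big, mc = TRUE, B = 2000, seed = 1)
  mc2 <- fisher_exact(big, mc = TRUE, B = 2000, seed = 1)
  expect_equal(mc1$p_value, mc2$p_value)
  expect_equal(mc1$method, "fisher_mc")
})

test_that("odds ratios use the cross product with a Wald interval", {
  tab <- matrix(c(6, 3, 10, 30), 2, byrow = TRUE)
  res <- odds_ratio(tab)
  expect_equal(res$effect, 6, tolerance = 1e-12)
  expect_true(res$ci_low < 6 && res$ci_high > 6)
  expect_equal(odds_ratio(matrix(c(10, 1, 6, 32), 2, byrow = TRUE))$effect,
               160 / 3, tolerance = 1e-12)
  expect_equal(odds_ratio(matrix(5, 2, 2))$effect, 1)
  zero <- matrix(c(0, 4, 6, 3), 2, byrow = TRUE)
  expect_equal(odds_ratio(zero)$flag, "zero_cell")
  corrected <- odds_ratio(zero, correction = TRUE)
  expect_equal(corrected$flag, "haldane_anscombe")
  expect_equal(corrected$effect, (0.5 * 3.5) / (4.5 * 6.5), tolerance = 1e-12)
})

test_that("univariate logistic odds ratio equals the cross-product ratio", {
  df <- tibble::tibble(
    y = c(rep(TRUE, 6), rep(FALSE, 3), rep(TRUE, 10), rep(FALSE, 30)),
    x = c(rep(1, 9), rep(0, 40))
  )
  fit <- logistic_fit(df, y, x)
  expect_equal(fit$effect, 6, tolerance = 1e-6)
  expect_true(is.na(fit$flag))
})

test_that("logistic regression is consistent under independence and flags separation", {
  set.seed(43)
  df <- tibble::tibble(y = rbinom(10000, 1, 0.4), x = rnorm(10000))
  fit <- logistic_fit(df, y, x)
  expect_equal(fit$effect, 1, tolerance = 0.1)
  sep <- tibble::tibble(y = c(0, 0, 0, 1, 1, 1), x = 1:6)
  expect_equal(logistic_fit(sep, y, x)$flag, "separation")
  expect_error(logistic_fit(tibble::tibble(y = c(0, 1), x = c(1, 1)), y, x),
               "constant", class = "celtilr_validation_error")
  expect_error(logistic_fit(tibble::tibble(y = c(1, 1), x = c(1, 2)), y, x),
               class = "celtilr_validation_error")
})

test_that("bivariate fits report one row per covariate", {
  set.seed(44)
  df <- tibble::tibble(
    x1 = rnorm(200), x2 = rbinom(200, 1, 0.5)
  )
  df$y <- rbinom(200, 1, plogis(-0.5 + df$x1 - 0.8 * df$x2))
  fit <- logistic_fit(df, y, x1, x2)
  expect_equal(nrow(fit), 2L)
  expect_equal(fit$term, c("x1", "x2"))
})

test_that("AUC handles perfect separation, binary predictors and null scores", {
  labels <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(roc_auc(c(6:10, 1:5), labels)$effect, 1)
  # binary predictor identity: AUC = (sensitivity + specificity) / 2
  set.seed(45)
  lab <- rbinom(100, 1, 0.4) == 1
  pred <- rbinom(100, 1, ifelse(lab, 0.7, 0.3))
  sens <- mean(pred[lab] == 1)
  spec <- mean(pred[!lab] == 0)
  expect_equal(roc_auc(pred, lab)$effect, (sens + spec) / 2, tolerance = 1e-12)
  # independent scores: AUC near 1/2
  set.seed(46)
  expect_equal(roc_auc(rnorm(4000), rbinom(4000, 1, 0.5))$effect, 0.5,
               tolerance = 0.05)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), class = "celtilr_validation_error")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(47)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, plogis(scores))
  a1 <- roc_auc(scores, labels)
  for (f in list(function(x) 3 * x - 7, exp, function(x) x^3,
                 function(x) atan(x))) {
    expect_equal(roc_auc(f(scores), labels)$effect, a1$effect, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(48)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, plogis(2 * scores))
  ours <- roc_auc(scores, labels)$effect
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("t tests cover identical groups, closed forms and pairing", {
  x <- c(1, 2, 3, 4)
  expect_equal(assoc_t_test(x, x)$p_value, 1)
  # closed-form Welch check
  set.seed(49)
  a <- rnorm(12, 1); b <- rnorm(15)
  res <- assoc_t_test(a, b)
  se <- sqrt(var(a) / 12 + var(b) / 15)
  tstat <- (mean(a) - mean(b)) / se
  df <- se^4 / ((var(a) / 12)^2 / 11 + (var(b) / 15)^2 / 14)
  expect_equal(res$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-12)
  expect_equal(res$effect, mean(a) - mean(b), tolerance = 1e-12)
  # paired with constant nonzero difference: p decreases with n
  p5 <- assoc_t_test(rnorm(5) + 1, rnorm(5), paired = FALSE)$p_value
  y1 <- rnorm(30); y2 <- y1 - 1 + rnorm(30, sd = 0.1)
  expect_lt(assoc_t_test(y1, y2, paired = TRUE)$p_value, 1e-6)
  expect_error(assoc_t_test(c(1, 1, 1), c(1, 1, 1)),
               class = "celtilr_validation_error")
})

test_that("odds ratio and univariate logistic agree to six significant figures", {
  set.seed(50)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 10) + 1, 2) # +1 keeps cells positive
    df <- tibble::tibble(
      y = rep(c(TRUE, FALSE, TRUE, FALSE), times = as.numeric(tab)),
      x = rep(c(1, 1, 0, 0), times = as.numeric(tab))
    )
    or <- cross_or <- (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2])
    fit <- logistic_fit(df, y, x)
    expect_equal(fit$effect, or, tolerance = 1e-6)
  }
})
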