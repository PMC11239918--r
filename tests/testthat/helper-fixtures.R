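# Fixture builders and independent oracles shared across the suite.

# small count table: 3 analysis genes + the 7 housekeeping genes
toy_counts <- function(s1 = c(g1 = 7, g2 = 3, g3 = 12), hk = 3) {
  tibble::tibble(
    gene = c(names(s1), HOUSEKEEPING_GENES),
    s1 = c(unname(s1), rep(hk, 7))
  )
}

toy_centroids <- function() {
  set.seed(42)
  genes <- paste0("g", 1:20)
  tibble::tibble(
    gene = genes,
    A = rnorm(20),
    B = rnorm(20),
    C = rnorm(20)
  )
}

# one-sample normalized tibble from a named vector
as_profile <- function(x, sample = "s1") {
  out <- tibble::tibble(gene = names(x))
  out[[sample]] <- unname(x)
  out
}

# tiny copy-number world: two chromosomes, two segments each
toy_cn_world <- function() {
  seg <- tibble::tibble(
    sample_id = "s1",
    chrom = c("1", "1", "2"),
    start = c(1L, 2001L, 1L),
    end = c(2000L, 5000L, 3000L),
    seg_mean = c(0.5, -0.3, 0.2)
  )
  annotation <- tibble::tibble(
    gene = c("inA", "spans", "inC", "nowhere"),
    chrom = c("1", "1", "2", "9"),
    start = c(100L, 1500L, 10L, 1L),
    end = c(900L, 2900L, 500L, 100L)
  )
  defs <- tibble::tibble(
    segment = c("segX", "segX", "segY", "segZ"),
    gene = c("inA", "spans", "inC", "ghost")
  )
  list(seg = seg, annotation = annotation, defs = defs)
}

toy_cn_model <- function(k_sig = 3, k_seg = 4, seed = 5) {
  set.seed(seed)
  coefs <- matrix(rnorm(k_sig * k_seg), nrow = k_sig,
                  dimnames = list(paste0("sig", seq_len(k_sig)),
                                  paste0("seg", seq_len(k_seg))))
  cents <- matrix(rnorm(4 * k_sig), nrow = 4,
                  dimnames = list(paste0("cluster", 1:4),
                                  paste0("sig", seq_len(k_sig))))
  cn_model(coefs, cents)
}

# variant fixture exercising each filter rule once
toy_variants <- function() {
  tibble::tibble(
    sample_id = paste0("s", 1:6),
    gene = paste0("G", 1:6),
    chrom = "1",
    pos = 1:6,
    ref = "A",
    alt = "G",
    variant_class = c("SNV", "SNV", "SNV", "INDEL", "INDEL", "INDEL"),
    alt_reads = c(3L, 7L, 10L, 8L, 9L, 12L),
    depth = 100L,
    vaf = c(0.04, 0.06, 0.20, 0.08, 0.12, 0.50),
    population_af = c(NA, NA, NA, NA, NA, 0.01)
  )
}

# drop filter bookkeeping before frame comparisons
strip_drops <- function(x) {
  attr(x, "drops") <- NULL
  as.data.frame(x)
}

# --- independent oracles ----------------------------------------------

# exhaustive 2x2 Fisher p by hypergeometric enumeration
enum_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ]) # margin of row 1
  n <- sum(tab[2, ])
  k <- sum(tab[, 1]) # margin of column 1
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exhaustive r x c Freeman-Halton p by recursive enumeration
enum_fisher_rxc <- function(tab) {
  rs <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  log_prob <- function(m) {
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n) -
      sum(lfactorial(m))
  }
  obs <- log_prob(tab)
  total <- 0
  recurse <- function(row, remaining_cols) {
    if (row == length(rs)) {
      m <- rbind(do.call(rbind, built), remaining_cols)
      if (any(m < 0)) return()
      lp <- log_prob(m)
      if (lp <= obs + 1e-7) total <<- total + exp(lp)
      return()
    }
    cells <- enumerate_row(rs[row], remaining_cols)
    for (i in seq_len(nrow(cells))) {
      built[[row]] <<- cells[i, ]
      recurse(row + 1, remaining_cols - cells[i, ])
    }
  }
  enumerate_row <- function(total_row, caps) {
    # all compositions of total_row into length(caps) cells bounded by caps
    if (length(caps) == 1) {
      if (total_row <= caps) return(matrix(total_row, 1, 1))
      return(matrix(numeric(0), 0, 1))
    }
    out <- list()
    for (x in 0:min(total_row, caps[1])) {
      rest <- enumerate_row(total_row - x, caps[-1])
      if (nrow(rest)) out[[length(out) + 1]] <- cbind(x, rest)
    }
    if (!length(out)) return(matrix(numeric(0), 0, length(caps)))
    do.call(rbind, out)
  }
  built <- vector("list", length(rs) - 1)
  recurse(1, cs)
  total
}

# brute-force nearest-centroid assignment
brute_nearest <- function(scores, centroids) {
  apply(scores, 1, function(x) {
    dists <- apply(centroids, 1, function(cen) sqrt(sum((x - cen)^2)))
    rownames(centroids)[which.min(dists)]
  })
}
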