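# Independent brute-force oracles. These re-derive each quantity from its
# definition, never calling the package code paths they check.

# Benjamini-Hochberg step-up by the O(m^2) definition:
# q_(i) = min_{j >= i} p_(j) * m / j, clipped at 1, in input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# Upper-tail hypergeometric P(X >= k) by direct pmf summation.
hyper_oracle <- function(N, K, n, k) {
  js <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(vapply(js, function(j)
    choose(K, j) * choose(N - K, n - j) / choose(N, n), numeric(1)))
}

# Exact two-sided rank-sum p by full enumeration of group assignments.
wilcox_enum_p <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  ranks <- rank(v)
  obs <- sum(ranks[seq_len(n1)])
  combs <- combn(length(v), n1)
  stats <- apply(combs, 2, function(idx) sum(ranks[idx]))
  mu <- n1 * (length(v) + 1) / 2
  p <- mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
  min(1, p)
}

# Median-of-ratios size factors from the definition: for each well, the
# median over genes with all-positive counts of count / geometric mean.
mor_oracle <- function(counts) {
  lg <- log(counts)
  geo_ok <- apply(counts, 1, function(r) all(r > 0))
  loggeo <- rowMeans(lg)
  vapply(seq_len(ncol(counts)), function(j) {
    r <- lg[, j] - loggeo
    exp(median(r[geo_ok & counts[, j] > 0]))
  }, numeric(1))
}

# TMM factors re-derived from the published rule: M/A double trimming by
# ranks with precision weighting, reference = well whose upper-quartile
# proportion is closest to the mean.
tmm_oracle <- function(counts, logratio_trim = 0.3, abundance_trim = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  one_factor <- function(obs, nO, refv, nR) {
    logR <- log2((obs / nO) / (refv / nR))
    absE <- (log2(obs / nO) + log2(refv / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refv) / nR / refv
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (length(logR) == 0 || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * abundance_trim) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    f <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
    if (!is.finite(f)) f <- 0
    2^f
  }
  f <- vapply(seq_len(ncol(counts)), function(j)
    one_factor(counts[, j], lib[j], counts[, ref], lib[ref]), numeric(1))
  f / exp(mean(log(f)))
}

# Exclusive-overlap counts by iterating elements one at a time.
overlap_oracle <- function(sets) {
  universe <- unique(unlist(sets))
  combos <- list()
  for (el in universe) {
    memb <- names(sets)[vapply(sets, function(s) el %in% s, logical(1))]
    key <- paste(memb, collapse = "&")
    combos[[key]] <- (combos[[key]] %||% 0L) + 1L
  }
  combos
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-gene sequential ANOVA fractions via stats::anova on individual lm fits.
anova_frac_oracle <- function(y, factors) {
  df <- as.data.frame(lapply(factors, factor))
  fml <- stats::as.formula(paste("v ~", paste(names(df), collapse = " + ")))
  t(apply(y, 1, function(v) {
    d <- cbind(df, v = v)
    a <- anova(lm(fml, data = d))
    ss <- a[["Sum Sq"]]
    ss / sum(ss)
  }))
}

# Weighted-KS enrichment score by a literal walk over the ranking.
es_walk_oracle <- function(stat_sorted_desc, hit_logical, p = 1) {
  N <- length(stat_sorted_desc)
  K <- sum(hit_logical)
  wts <- unname(abs(stat_sorted_desc)^p)
  NR <- sum(wts[hit_logical])
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit_logical[i]) wts[i] / NR else -1 / (N - K)
    if (abs(run) > abs(best)) best <- run
  }
  best
}
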