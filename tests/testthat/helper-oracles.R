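# Independent brute-force oracles and shared fixtures. Each oracle applies
# the defining rules/formulas literally with naive loops, independent of the
# package implementation it checks.

# replicate-triage oracle: enumerate the replicate pairs and apply the
# consistency rules verbatim
oracle_triage <- function(cqs) {
  x <- cqs[!is.na(cqs)]
  if (length(x) < 2L) return("INVALID")
  if (length(x) == 2L) {
    d <- abs(x[1L] - x[2L])
    if (d > 0.8) return("INVALID")
    if (d <= 0.5) return("GOLD")
    return("FFPE_ACCEPTED")
  }
  pairs <- combn(3L, 2L)
  diffs <- apply(pairs, 2L, function(p) abs(x[p[1L]] - x[p[2L]]))
  if (min(diffs) > 0.8) return("INVALID")
  cand <- which(diffs == min(diffs))
  if (length(cand) > 1L) {
    med <- median(x)
    dd <- sapply(cand, function(i) abs(mean(x[pairs[, i]]) - med))
    cand <- cand[which.min(dd)]
  }
  best <- pairs[, cand[1L]]
  third <- x[-best]
  if (abs(third - mean(x[best])) > 0.5) return("OUTLIER_REMOVED")
  spread <- max(x) - min(x)
  if (spread <= 0.5) return("GOLD")
  if (spread <= 0.8) return("FFPE_ACCEPTED")
  "INVALID"
}

# geNorm M by an explicit double loop over gene pairs and samples
oracle_genorm_m <- function(cq) {
  g <- nrow(cq)
  m <- numeric(g)
  for (j in 1:g) {
    acc <- c()
    for (k in setdiff(1:g, j)) {
      ratios <- c()
      for (s in 1:ncol(cq)) ratios <- c(ratios, -cq[j, s] - (-cq[k, s]))
      acc <- c(acc, sd(ratios))
    }
    m[j] <- mean(acc)
  }
  names(m) <- rownames(cq)
  m
}

# ungrouped NormFinder stability by explicit two-way centering loops
oracle_normfinder <- function(cq) {
  q <- -cq
  g <- nrow(q); n <- ncol(q)
  res <- matrix(0, g, n)
  gene_mean <- rowMeans(q)
  for (j in 1:g) for (s in 1:n) res[j, s] <- q[j, s] - gene_mean[j]
  samp_mean <- colMeans(res)
  for (j in 1:g) for (s in 1:n) res[j, s] <- res[j, s] - samp_mean[s]
  out <- numeric(g)
  for (j in 1:g) out[j] <- sd(res[j, ])
  names(out) <- rownames(cq)
  out
}

# BestKeeper SD/CV by direct formulas
oracle_bestkeeper <- function(cq) {
  list(sd = apply(cq, 1L, sd),
       cv = 100 * apply(cq, 1L, sd) / apply(cq, 1L, mean),
       index = apply(cq, 2L, mean))
}

# tie-corrected Kruskal-Wallis H by the rank formula
oracle_kw_h <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) sum(ri)^2 / length(ri))) -
    3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# exact Mann-Whitney two-sided p by full combn enumeration (small n only)
oracle_mwu_exact <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_along(a)])
  all_w <- apply(combn(n, length(a)), 2L, function(idx) sum(r[idx]))
  p_le <- mean(all_w <= w_obs + 1e-9)
  p_ge <- mean(all_w >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# small deterministic Cq matrix used across stability tests
toy_cq_matrix <- function() {
  m <- rbind(
    G1 = c(24.0, 24.5, 25.0, 24.2, 24.8, 24.4),
    G2 = c(26.1, 26.4, 27.2, 26.0, 26.9, 26.3),
    G3 = c(22.3, 23.5, 23.0, 22.1, 23.3, 22.6),
    G4 = c(28.0, 27.2, 28.9, 28.3, 27.5, 28.6))
  colnames(m) <- paste0("S", 1:6)
  m
}

# fixture records with the excluded sample removed (statistics universe)
fixture_stats_records <- function() {
  fx <- fixture_table2()
  excl <- fx$samples$sample_id[fx$samples$is_excluded]
  fx$records[!fx$records$sample_id %in% excl, , drop = FALSE]
}
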