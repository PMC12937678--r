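test_that("geNorm M matches the brute-force pairwise oracle", {
  cq <- toy_cq_matrix()
  res <- genorm_stability(cq, rownames(cq))
  expect_equal(res$m, oracle_genorm_m(cq))

  # small integer matrix, hand-checkable
  small <- rbind(A = c(24, 25, 26, 24), B = c(26, 27, 28, 27),
                 C = c(22, 24, 23, 22))
  colnames(small) <- paste0("S", 1:4)
  expect_equal(genorm_stability(small, rownames(small))$m,
               oracle_genorm_m(small))
})

test_that("a constant-ratio gene pair has M = 0", {
  cq <- rbind(G1 = c(24, 25, 26, 23.5), G2 = c(26.2, 27.2, 28.2, 25.7))
  colnames(cq) <- paste0("S", 1:4)
  res <- genorm_stability(cq, rownames(cq))
  expect_equal(unname(res$m), c(0, 0))
})

test_that("a noisy gene gets a higher M than every stable gene", {
  set.seed(21)
  wins <- 0L
  for (i in 1:100) {
    n <- 10L
    loading <- rnorm(n, 0, 0.5)
    stable <- t(sapply(1:3, function(j)
      24 + 2 * j + loading + rnorm(n, 0, 0.05)))
    noisy <- 27 + loading + rnorm(n, 0, 2)
    cq <- rbind(stable, noisy)
    rownames(cq) <- c("R1", "R2", "R3", "NOISY")
    colnames(cq) <- paste0("S", 1:n)
    m <- genorm_stability(cq, rownames(cq))$m
    if (m["NOISY"] > max(m[c("R1", "R2", "R3")])) wins <- wins + 1L
  }
  expect_equal(wins, 100L)
})

test_that("pairwise variation V(n/n+1) matches the normalization-factor oracle", {
  cq <- toy_cq_matrix()
  ord <- names(sort(genorm_stability(cq, rownames(cq))$m))
  v <- genorm_pairwise_variation(cq, ord)
  expect_length(v, 2L)
  expect_true(all(v >= 0))

  # oracle: explicit normalization factors
  q <- -cq[ord, ]
  v23 <- sd(colMeans(q[1:2, ]) - colMeans(q[1:3, ]))
  v34 <- sd(colMeans(q[1:3, ]) - colMeans(q[1:4, ]))
  expect_equal(unname(v), c(v23, v34))

  # three identical genes: V2/3 = 0
  same <- rbind(A = c(24, 25, 26), B = c(24, 25, 26), C = c(24, 25, 26))
  colnames(same) <- paste0("S", 1:3)
  expect_equal(unname(genorm_pairwise_variation(same, rownames(same))), 0)

  # duplicating an already-included gene cannot increase V
  dup <- rbind(cq[ord[1:3], ], DUP = cq[ord[1], ] + 0.5)
  v_dup <- genorm_pairwise_variation(dup, rownames(dup))
  expect_lte(v_dup["V3/4"], v_dup["V2/3"] + 1e-12)
})

test_that("ungrouped NormFinder matches the double-centering oracle", {
  cq <- toy_cq_matrix()
  expect_equal(normfinder_stability(cq, rownames(cq)), oracle_normfinder(cq))

  # a gene equal to the per-sample candidate mean has stability 0
  base <- toy_cq_matrix()[1:3, ]
  avg <- colMeans(base)
  cq2 <- rbind(base, AVG = avg)
  nf <- normfinder_stability(cq2, rownames(cq2))
  expect_equal(unname(nf["AVG"]), 0, tolerance = 1e-12)
})

test_that("grouped NormFinder penalizes a group-shifted candidate", {
  set.seed(31)
  last_rank <- 0L
  for (i in 1:100) {
    n_per <- 5L
    groups <- rep(c("G1", "G2"), each = n_per)
    loading <- rnorm(2 * n_per, 0, 0.5)
    cq <- t(sapply(1:3, function(j) 24 + j + loading + rnorm(2 * n_per, 0, 0.1)))
    shifted <- 28 + loading + rnorm(2 * n_per, 0, 0.1) -
      1.5 * (groups == "G2")   # +1.5 log2 expression shift in G2
    cq <- rbind(cq, shifted)
    rownames(cq) <- c("R1", "R2", "R3", "SHIFTED")
    colnames(cq) <- paste0("S", 1:(2 * n_per))
    nf <- normfinder_stability(cq, rownames(cq), groups = groups)
    if (which.max(nf) == 4L) last_rank <- last_rank + 1L
  }
  expect_gte(last_rank, 99L)

  expect_error(
    normfinder_stability(toy_cq_matrix(), rownames(toy_cq_matrix()),
                         groups = c("a", "a", "a", "a", "a", "b")),
    class = "relqpcr_argument_error")
})

test_that("BestKeeper statistics match direct formulas", {
  cq <- toy_cq_matrix()
  bk <- bestkeeper_stats(cq, rownames(cq))
  o <- oracle_bestkeeper(cq)
  expect_equal(setNames(bk$sd, bk$gene), o$sd)
  expect_equal(setNames(bk$cv, bk$gene), o$cv)
  expect_equal(attr(bk, "index"), o$index)

  # mirrored pair: constant index, correlation undefined, SDs 1.0
  mir <- rbind(A = c(24, 25, 26), B = c(30, 29, 28))
  colnames(mir) <- paste0("S", 1:3)
  bk2 <- bestkeeper_stats(mir, rownames(mir))
  expect_equal(unname(attr(bk2, "index")), c(27, 27, 27))
  expect_true(all(is.na(bk2$r)))
  expect_equal(bk2$sd, c(1, 1))

  # constant gene: SD 0, CV 0, best rank
  cst <- rbind(toy_cq_matrix()[1:2, ], CONST = rep(25, 6))
  bk3 <- bestkeeper_stats(cst, rownames(cst))
  expect_equal(bk3$sd[bk3$gene == "CONST"], 0)
  expect_equal(bk3$cv[bk3$gene == "CONST"], 0)
})

test_that("delta-Cq stability equals geNorm M and is 0 for duplicates", {
  cq <- toy_cq_matrix()
  expect_equal(deltacq_stability(cq, rownames(cq)),
               genorm_stability(cq, rownames(cq))$m)

  dup <- rbind(A = c(24, 25, 26), B = c(24.8, 25.8, 26.8))
  colnames(dup) <- paste0("S", 1:3)
  expect_equal(unname(deltacq_stability(dup, rownames(dup))), c(0, 0))
})

test_that("log-ratio stability scores ignore per-sample loading offsets", {
  cq <- toy_cq_matrix()
  loading <- c(1.5, -0.7, 0.3, 2.0, -1.1, 0.4)
  shifted <- sweep(cq, 2L, -loading)
  cand <- rownames(cq)
  expect_equal(genorm_stability(shifted, cand)$m,
               genorm_stability(cq, cand)$m)
  expect_equal(deltacq_stability(shifted, cand), deltacq_stability(cq, cand))
  expect_equal(normfinder_stability(shifted, cand),
               normfinder_stability(cq, cand))
  # BestKeeper raw-Cq SD is deliberately not loading-invariant
  expect_false(isTRUE(all.equal(bestkeeper_stats(shifted, cand)$sd,
                                bestkeeper_stats(cq, cand)$sd)))
})

test_that("composite rank is the geometric mean of the four method ranks", {
  mk <- function(v) setNames(v, paste0("G", seq_along(v)))
  one <- function(r1, r2, r3, r4, gene = "G1") {
    ranks <- lapply(list(r1, r2, r3, r4), mk)
    composite_rank(ranks)$composite[composite_rank(ranks)$gene == gene]
  }
  # single-gene sanity via 2-gene vectors covering the printed composites
  ranks <- list(mk(c(1, 2)), mk(c(1, 2)), mk(c(2, 1)), mk(c(1, 2)))
  res <- composite_rank(ranks)
  expect_equal(res$composite[res$gene == "G1"], 2^(1 / 4))   # 1.19
  ranks <- list(mk(c(1, 2)), mk(c(2, 1)), mk(c(1, 2)), mk(c(2, 1)))
  res <- composite_rank(ranks)
  expect_equal(res$composite[res$gene == "G1"], 4^(1 / 4))   # 1.41
  ranks <- lapply(1:4, function(i) mk(c(3, 1, 2, 4)))
  res <- composite_rank(ranks)
  expect_equal(res$composite[res$gene == "G1"], 3)
  expect_equal(res$composite[res$gene == "G4"], 4)
  expect_equal(res$gene, paste0("G", c(2, 3, 1, 4)))   # ascending order

  expect_error(composite_rank(list(mk(1:2), mk(1:2), mk(1:2))),
               class = "relqpcr_argument_error")
  bad <- list(mk(1:2), mk(1:2), mk(1:2), setNames(1:2, c("G1", "GX")))
  expect_error(composite_rank(bad), class = "relqpcr_argument_error")
})

test_that("composite ordering survives monotone re-scoring of any method", {
  set.seed(41)
  cq <- toy_cq_matrix()
  tab <- rank_reference_genes(cq, rownames(cq))
  # re-score one method by any strictly increasing transform of its ranks:
  # ranks are unchanged, so the composite ordering must be identical
  ranks <- list(tab$rank_genorm, tab$rank_normfinder, tab$rank_bestkeeper,
                tab$rank_deltacq)
  names(ranks) <- c("rank_genorm", "rank_normfinder", "rank_bestkeeper",
                    "rank_deltacq")
  ranks <- lapply(ranks, function(r) setNames(r, tab$gene))
  rescored <- ranks
  rescored[[2L]] <- setNames(rank(exp(ranks[[2L]])), tab$gene)
  expect_equal(composite_rank(rescored)$gene, composite_rank(ranks)$gene)
})

test_that("a spiked-unstable candidate ranks last in seeded simulations", {
  set.seed(51)
  last <- 0L
  for (i in 1:100) {
    n <- 12L
    loading <- rnorm(n, 0, 0.8)
    cq <- t(sapply(1:3, function(j)
      23 + 1.5 * j + loading + rnorm(n, 0, 0.1)))
    cq <- rbind(cq, 26 + loading + rnorm(n, 0, 0.1) + rnorm(n, 0, 1.2))
    rownames(cq) <- c("R1", "R2", "R3", "SPIKED")
    colnames(cq) <- paste0("S", 1:n)
    tab <- rank_reference_genes(cq, rownames(cq))
    if (tab$gene[tab$composite_rank == 4] == "SPIKED") last <- last + 1L
  }
  expect_gte(last, 99L)
})

test_that("missing cells drop samples complete-case for all methods", {
  cq <- toy_cq_matrix()
  cq["G2", "S3"] <- NA
  full <- toy_cq_matrix()[, -3L]
  expect_equal(genorm_stability(cq, rownames(cq))$m,
               genorm_stability(full, rownames(full))$m)
  expect_equal(genorm_stability(cq, rownames(cq))$dropped_samples, "S3")
})
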