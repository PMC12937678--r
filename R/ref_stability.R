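# Reference-gene stability: geNorm, NormFinder, BestKeeper, comparative
# delta-Cq, and their composite geometric-mean rank.
#
# All methods operate on mean Cq values (replicate triage already applied).
# Where a method is defined on relative quantities, Cq is converted with a
# fixed amplification factor of 2 per cycle, so log2 quantity q = -Cq up to
# a gene-wise constant that cancels in every pairwise statistic.

# complete-case sample selection shared by all four methods so that ranks
# are computed on one common sample set
stability_input <- function(matrix, candidates) {
  cm <- as_cq_matrix(matrix)
  mat <- cm$mean_cq
  missing_genes <- setdiff(candidates, rownames(mat))
  if (length(missing_genes) > 0L) {
    stop_argument("candidate gene(s) not in matrix: ",
                  paste(missing_genes, collapse = ", "))
  }
  sub <- mat[candidates, , drop = FALSE]
  complete <- colSums(is.na(sub)) == 0L
  dropped <- colnames(sub)[!complete]
  sub <- sub[, complete, drop = FALSE]
  list(cq = sub, dropped_samples = dropped,
       groups = if (!is.null(cm$groups)) cm$groups[colnames(sub)] else NULL)
}

#' geNorm expression-stability measure M
#'
#' For each candidate j, M_j is the arithmetic mean over the other
#' candidates k of the standard deviation across samples of the pairwise
#' log2 expression ratio q_j - q_k. With q = -Cq (amplification factor 2)
#' this equals SD(Cq_k - Cq_j). The least stable gene (highest M) is
#' removed iteratively until two genes remain, which defines the classic
#' stepwise exclusion order.
#'
#' @param matrix a `cq_matrix` or genes x samples numeric matrix of mean Cq.
#' @param candidates character vector of candidate reference genes (>= 2).
#' @return list: `m` (named vector, M on the full candidate panel),
#'   `ranking` (rank of each gene by ascending full-panel M, average ranks
#'   on ties), `exclusion_order` (genes in removal order, least stable
#'   first; the final two are appended by ascending M), `dropped_samples`.
#' @export
genorm_stability <- function(matrix, candidates) {
  if (length(candidates) < 2L) {
    stop_argument("geNorm needs at least 2 candidate genes")
  }
  inp <- stability_input(matrix, candidates)
  if (ncol(inp$cq) < 3L) {
    stop_argument("geNorm needs at least 3 complete samples, have ",
                  ncol(inp$cq))
  }
  m_full <- genorm_m(inp$cq)

  remaining <- candidates
  excluded <- character()
  cq <- inp$cq
  while (length(remaining) > 2L) {
    m <- genorm_m(cq[remaining, , drop = FALSE])
    worst <- names(m)[which.max(m)]
    excluded <- c(excluded, worst)
    remaining <- setdiff(remaining, worst)
  }
  last_two <- remaining[order(m_full[remaining])]
  list(m = m_full, ranking = rank(m_full),
       exclusion_order = c(excluded, rev(last_two)),
       dropped_samples = inp$dropped_samples)
}

genorm_m <- function(cq) {
  genes <- rownames(cq)
  m <- stats::setNames(numeric(length(genes)), genes)
  for (j in seq_along(genes)) {
    v <- vapply(seq_along(genes)[-j], function(k) {
      stats::sd(cq[k, ] - cq[j, ])
    }, 0)
    m[j] <- mean(v)
  }
  m
}

#' geNorm pairwise variation V(n/n+1)
#'
#' Measures the effect of adding the (n+1)-th ranked reference gene to a
#' normalization factor built from the top n genes: V is the standard
#' deviation across samples of the difference between the two log2
#' normalization factors (arithmetic mean of q = -Cq over the top n vs the
#' top n+1 genes).
#'
#' @param matrix a `cq_matrix` or genes x samples numeric matrix.
#' @param ordered_candidates candidate genes ordered best-first by the
#'   geNorm ranking (>= 3).
#' @return named numeric vector of length `length(ordered_candidates) - 2`
#'   with names "V2/3", "V3/4", ...
#' @export
genorm_pairwise_variation <- function(matrix, ordered_candidates) {
  n <- length(ordered_candidates)
  if (n < 3L) {
    stop_argument("pairwise variation needs at least 3 ordered candidates")
  }
  inp <- stability_input(matrix, ordered_candidates)
  q <- -inp$cq[ordered_candidates, , drop = FALSE]
  v <- numeric(n - 2L)
  names(v) <- paste0("V", 2:(n - 1L), "/", 3:n)
  for (k in 2:(n - 1L)) {
    nf_k <- colMeans(q[seq_len(k), , drop = FALSE])
    nf_k1 <- colMeans(q[seq_len(k + 1L), , drop = FALSE])
    v[k - 1L] <- stats::sd(nf_k - nf_k1)
  }
  v
}

#' NormFinder stability value
#'
#' Ungrouped variant (default): on the log2 quantity scale q = -Cq, the
#' gene x sample table is double-centered (each gene by its mean, each
#' sample by its mean over candidates) and the stability of gene j is the
#' standard deviation of its residuals across samples — the gene's
#' non-shared variation. Grouped variant (model with intra- and inter-group
#' variation): per gene, the sample-centered values are decomposed into
#' within-group variances and a between-group variance component, and
#' stability = sqrt(inter-group variance estimate + mean intra-group
#' variance). Lower values indicate more stable expression.
#'
#' @param matrix a `cq_matrix` or genes x samples numeric matrix.
#' @param candidates candidate gene ids (>= 3).
#' @param groups optional group label per sample (named or in matrix
#'   order); when supplied, the grouped variant is used and every group
#'   must contain at least 2 complete samples.
#' @return named numeric vector of stability values (lower = more stable).
#' @export
normfinder_stability <- function(matrix, candidates, groups = NULL) {
  if (length(candidates) < 3L) {
    stop_argument("NormFinder needs at least 3 candidate genes")
  }
  inp <- stability_input(matrix, candidates)
  q <- -inp$cq
  if (is.null(groups)) {
    res <- q - rowMeans(q)
    res <- sweep(res, 2L, colMeans(res))
    return(apply(res, 1L, stats::sd))
  }
  if (!is.null(names(groups))) groups <- groups[colnames(q)]
  groups <- as.character(groups)
  if (length(groups) != ncol(q)) {
    stop_argument("groups must label every complete sample")
  }
  tab <- table(groups)
  if (any(tab < 2L)) {
    stop_argument("grouped NormFinder requires >= 2 samples per group; ",
                  "singleton group(s): ",
                  paste(names(tab)[tab < 2L], collapse = ", "))
  }
  d <- sweep(q, 2L, colMeans(q))           # sample-centered expression
  out <- stats::setNames(numeric(nrow(q)), rownames(q))
  for (j in seq_len(nrow(q))) {
    gm <- tapply(d[j, ], groups, mean)
    gv <- tapply(d[j, ], groups, stats::var)
    gn <- tapply(d[j, ], groups, length)
    # between-group variance of group means, shrunk by the sampling noise
    # the within-group variation contributes to those means
    inter <- max(0, stats::var(gm) - mean(gv / gn))
    out[j] <- sqrt(inter + mean(gv))
  }
  out
}

#' BestKeeper descriptive statistics
#'
#' Per candidate: standard deviation and coefficient of variation of the
#' raw Cq values across samples, and the Pearson correlation with the
#' BestKeeper index (the per-sample arithmetic mean Cq over all
#' candidates). Ranking is by ascending SD. Note that unlike the log-ratio
#' based methods, raw-Cq SD is not invariant to sample loading offsets.
#'
#' @param matrix a `cq_matrix` or genes x samples numeric matrix.
#' @param candidates candidate gene ids (>= 2).
#' @return data.frame with columns gene, sd, cv (percent), r (NA when the
#'   index or the gene has zero variance), plus attribute "index".
#' @export
bestkeeper_stats <- function(matrix, candidates) {
  if (length(candidates) < 2L) {
    stop_argument("BestKeeper needs at least 2 candidate genes")
  }
  inp <- stability_input(matrix, candidates)
  cq <- inp$cq
  index <- colMeans(cq)
  sds <- apply(cq, 1L, stats::sd)
  cvs <- 100 * sds / rowMeans(cq)
  rs <- vapply(seq_len(nrow(cq)), function(j) {
    if (stats::sd(index) == 0 || sds[j] == 0) return(NA_real_)
    stats::cor(cq[j, ], index)
  }, 0)
  out <- data.frame(gene = rownames(cq), sd = sds, cv = cvs, r = rs,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "index") <- index
  out
}

#' Comparative delta-Cq stability
#'
#' For gene j, the mean over the other candidates k of the standard
#' deviation across samples of the difference Cq_j - Cq_k. Numerically
#' identical to the geNorm M value when every assay amplifies with
#' efficiency 2, but computed directly on raw Cq as the classic
#' "comparative delta-Cq" method prescribes.
#'
#' @inheritParams bestkeeper_stats
#' @return named numeric vector (lower = more stable).
#' @export
deltacq_stability <- function(matrix, candidates) {
  if (length(candidates) < 2L) {
    stop_argument("delta-Cq method needs at least 2 candidate genes")
  }
  inp <- stability_input(matrix, candidates)
  cq <- inp$cq
  genes <- rownames(cq)
  out <- stats::setNames(numeric(length(genes)), genes)
  for (j in seq_along(genes)) {
    out[j] <- mean(vapply(seq_along(genes)[-j], function(k) {
      stats::sd(cq[j, ] - cq[k, ])
    }, 0))
  }
  out
}

#' Composite geometric-mean rank of the four stability methods
#'
#' Aggregates one rank vector per method (geNorm, NormFinder, BestKeeper,
#' delta-Cq) into a composite value per gene: the geometric mean of its
#' four ranks. The final ordering is ascending composite, with average
#' ranks on ties.
#'
#' @param per_method_ranks list of exactly 4 numeric rank vectors, each
#'   named by the same candidate genes.
#' @return data.frame: gene, the four ranks, composite, composite_rank,
#'   ordered by ascending composite.
#' @export
composite_rank <- function(per_method_ranks) {
  if (length(per_method_ranks) != 4L) {
    stop_argument("expected 4 per-method rank vectors, got ",
                  length(per_method_ranks))
  }
  genes <- names(per_method_ranks[[1L]])
  if (is.null(genes)) stop_argument("rank vectors must be named by gene")
  for (r in per_method_ranks) {
    if (is.null(names(r)) || !setequal(names(r), genes)) {
      stop_argument("all four rank vectors must cover the same candidates")
    }
  }
  rank_mat <- vapply(per_method_ranks, function(r) r[genes],
                     numeric(length(genes)))
  composite <- apply(rank_mat, 1L, function(r) exp(mean(log(r))))
  nm <- names(per_method_ranks)
  if (is.null(nm) || any(!nzchar(nm))) {
    nm <- c("rank_genorm", "rank_normfinder", "rank_bestkeeper",
            "rank_deltacq")
  }
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (i in 1:4) out[[nm[i]]] <- rank_mat[, i]
  out$composite <- composite
  out$composite_rank <- rank(composite)
  out[order(out$composite), , drop = FALSE]
}

#' Rank candidate reference genes by all four methods and their composite
#'
#' Convenience wrapper running [genorm_stability()],
#' [normfinder_stability()], [bestkeeper_stats()] and
#' [deltacq_stability()] on one common complete-case sample set and
#' aggregating the per-method ranks with [composite_rank()]. Candidates
#' with composite values at or below about 1.5 are conventionally
#' considered good references.
#'
#' @param matrix a `cq_matrix` or genes x samples numeric matrix of mean Cq.
#' @param candidates candidate reference genes (>= 3 for geNorm/NormFinder).
#' @param groups optional sample groups for the grouped NormFinder variant;
#'   the default (NULL) uses the ungrouped model.
#' @return data.frame, one row per candidate ordered by ascending
#'   composite: the raw per-method statistics, the four ranks, `composite`
#'   and `composite_rank`.
#' @export
rank_reference_genes <- function(matrix, candidates, groups = NULL) {
  gn <- genorm_stability(matrix, candidates)
  nf <- normfinder_stability(matrix, candidates, groups = groups)
  bk <- bestkeeper_stats(matrix, candidates)
  dc <- deltacq_stability(matrix, candidates)

  bk_sd <- stats::setNames(bk$sd, bk$gene)[candidates]
  ranks <- list(rank_genorm = rank(gn$m[candidates]),
                rank_normfinder = rank(nf[candidates]),
                rank_bestkeeper = rank(bk_sd),
                rank_deltacq = rank(dc[candidates]))
  comp <- composite_rank(ranks)
  comp$genorm_m <- gn$m[comp$gene]
  comp$normfinder_stability <- nf[comp$gene]
  comp$bestkeeper_sd <- bk_sd[comp$gene]
  comp$bestkeeper_cv <- stats::setNames(bk$cv, bk$gene)[comp$gene]
  comp$bestkeeper_r <- stats::setNames(bk$r, bk$gene)[comp$gene]
  comp$deltacq_mean_sd <- dc[comp$gene]
  rownames(comp) <- NULL
  comp
}
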