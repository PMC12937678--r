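# Nonparametric subtype statistics: medians, tie-corrected Kruskal-Wallis,
# Mann-Whitney (normal approximation or exact enumeration), BH adjustment,
# Spearman correlation.

#' Median log2 fold change per gene and subtype
#'
#' @param records an [expression_table()] (needs sample_id, group,
#'   target_id, log2fc). Excluded samples should already be absent.
#' @param groups subtype columns to report, in order; defaults to tumor
#'   subtypes plus normals.
#' @param include_normals keep the "N" row when present.
#' @return numeric matrix, groups x genes, of median log2FC (sample median;
#'   midpoint for even counts). Empty gene x group cells are NA with a
#'   warning.
#' @export
subtype_medians <- function(records,
                            groups = c("N", "A", "B1", "B2", "B3", "TC"),
                            include_normals = TRUE) {
  if (!all(c("group", "target_id", "log2fc") %in% names(records))) {
    stop_argument("records must have group, target_id and log2fc columns")
  }
  if (!include_normals) groups <- setdiff(groups, "N")
  groups <- intersect(groups, unique(records$group))
  genes <- unique(records$target_id)
  out <- matrix(NA_real_, length(groups), length(genes),
                dimnames = list(groups, genes))
  for (gr in groups) for (g in genes) {
    v <- records$log2fc[records$group == gr & records$target_id == g]
    if (length(v) == 0L) {
      warning("no values for gene ", g, " in group ", gr)
    } else {
      out[gr, g] <- stats::median(v)
    }
  }
  out
}

#' Tie-corrected Kruskal-Wallis rank test
#'
#' H is computed on average ranks of the pooled values, divided by the tie
#' correction factor 1 - sum(t^3 - t) / (N^3 - N), with the p-value from
#' the chi-square upper tail on (number of groups - 1) degrees of freedom
#' (delegated to [stats::kruskal.test()], which implements exactly this).
#' Because ranks are invariant under strictly monotone transforms, FC and
#' log2FC inputs give identical results. With all pooled values identical,
#' H is reported as 0 with p = 1.
#'
#' @param values numeric response (e.g. log2FC).
#' @param groups group label per value (>= 2 non-empty groups).
#' @return data.frame: test, statistic (H), df, p_raw.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) {
    stop_argument("values and groups must have equal length")
  }
  if (length(unique(groups)) < 2L) {
    stop_argument("Kruskal-Wallis needs >= 2 groups")
  }
  if (length(unique(values)) == 1L) {
    # zero-variance input: the statistic degenerates to 0/0; define H = 0
    return(data.frame(test = "KRUSKAL_WALLIS", statistic = 0,
                      df = length(unique(groups)) - 1L, p_raw = 1,
                      stringsAsFactors = FALSE))
  }
  kt <- stats::kruskal.test(values, factor(groups))
  data.frame(test = "KRUSKAL_WALLIS", statistic = unname(kt$statistic),
             df = unname(kt$parameter), p_raw = kt$p.value,
             stringsAsFactors = FALSE)
}

#' Mann-Whitney rank-sum test
#'
#' `NORMAL_APPROX` (default) computes the rank sum W of `group_a` over the
#' pooled average ranks and the two-sided p-value from
#' z = (W - n_a (N + 1) / 2) / sqrt(V) with the tie-corrected variance
#' V = n_a n_b / 12 * ((N + 1) - sum(t^3 - t) / (N (N - 1))), without
#' continuity correction. `EXACT` enumerates the full permutation
#' distribution of the rank sum (ties handled via doubled average ranks and
#' a subset-sum dynamic program) and reports the doubled smaller tail,
#' capped at 1; it is limited to n_a + n_b <= 25.
#'
#' @param group_a,group_b numeric samples, both non-empty.
#' @param mode "NORMAL_APPROX" or "EXACT".
#' @return data.frame: test, statistic (z for the approximation, W for the
#'   exact mode), w (rank sum of group_a), u (Mann-Whitney U of group_a),
#'   p_raw, mode.
#' @export
mann_whitney <- function(group_a, group_b,
                         mode = c("NORMAL_APPROX", "EXACT")) {
  mode <- match.arg(mode)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop_argument("both groups must be non-empty")
  }
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  w <- sum(r[seq_len(na)])
  u <- w - na * (na + 1) / 2

  if (mode == "NORMAL_APPROX") {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- na * nb / 12 * ((n + 1) - tie_term)
    if (v <= 0) {
      z <- 0; p <- 1
    } else {
      z <- (w - na * (n + 1) / 2) / sqrt(v)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    return(data.frame(test = "MANN_WHITNEY", statistic = z, w = w, u = u,
                      p_raw = p, mode = mode, stringsAsFactors = FALSE))
  }

  if (n > 25L) {
    stop_argument("EXACT mode is limited to n_a + n_b <= 25; ",
                  "use mode = \"NORMAL_APPROX\"")
  }
  dist <- ranksum_distribution(round(2 * r), na)
  w2 <- round(2 * w)
  p_le <- sum(dist$prob[dist$sum <= w2])
  p_ge <- sum(dist$prob[dist$sum >= w2])
  p <- min(1, 2 * min(p_le, p_ge))
  data.frame(test = "MANN_WHITNEY", statistic = w, w = w, u = u, p_raw = p,
             mode = mode, stringsAsFactors = FALSE)
}

# exact null distribution of the group-a rank sum over all choose(n, na)
# equally likely subsets; ranks arrive doubled so tied average ranks are
# integers. Dynamic program over (number chosen, doubled sum).
ranksum_distribution <- function(scaled_ranks, na) {
  n <- length(scaled_ranks)
  max_sum <- sum(sort(scaled_ranks, decreasing = TRUE)[seq_len(na)])
  # count[k + 1, s + 1] = number of k-subsets with doubled rank sum s
  count <- matrix(0, nrow = na + 1L, ncol = max_sum + 1L)
  count[1L, 1L] <- 1
  for (x in scaled_ranks) {
    for (k in rev(seq_len(na))) {
      nz <- which(count[k, ] > 0)
      if (length(nz) > 0L) {
        tgt <- nz + x
        ok <- tgt <= max_sum + 1L
        count[k + 1L, tgt[ok]] <- count[k + 1L, tgt[ok]] + count[k, nz[ok]]
      }
    }
  }
  sums <- which(count[na + 1L, ] > 0) - 1L
  data.frame(sum = sums,
             prob = count[na + 1L, sums + 1L] / choose(n, na))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with method "BH" (monotone
#' step-up, capped at 1).
#'
#' @param p_values raw p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_domain("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of the average ranks; the two-sided
#' p-value uses t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of
#' freedom (p = 0 when |rho| = 1). Zero variance in either vector makes
#' rho undefined (NA, with a warning).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return data.frame: test, statistic (rho), n, p_raw.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop_argument("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop_argument("Spearman correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: Spearman rho undefined")
    return(data.frame(test = "SPEARMAN", statistic = NA_real_, n = n,
                      p_raw = NA_real_, stringsAsFactors = FALSE))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  data.frame(test = "SPEARMAN", statistic = rho, n = n, p_raw = p,
             stringsAsFactors = FALSE)
}

#' Per-gene subtype statistics on an expression table
#'
#' Runs, for every target gene, (1) the tie-corrected Kruskal-Wallis test
#' across the tumor subtypes and (2) the Mann-Whitney test of one contrast
#' group against all other non-excluded samples (normals included).
#' Benjamini-Hochberg adjustment is applied within each test family (one
#' family per test type across genes); both raw and adjusted p-values are
#' reported.
#'
#' @param records an [expression_table()] with group labels; excluded
#'   samples must already be absent.
#' @param kw_groups groups entering the Kruskal-Wallis comparison
#'   (default: tumor subtypes only).
#' @param mwu_group contrast group for the Mann-Whitney test (default
#'   "TC"); compared against every other sample in `records`.
#' @param mwu_mode Mann-Whitney p-value mode, see [mann_whitney()].
#' @return data.frame: gene_id, test, statistic, df, p_raw, p_adj,
#'   group_spec.
#' @export
analyze_groups <- function(records,
                           kw_groups = c("A", "B1", "B2", "B3", "TC"),
                           mwu_group = "TC",
                           mwu_mode = "NORMAL_APPROX") {
  genes <- unique(records$target_id)
  kw <- lapply(genes, function(g) {
    sub <- records[records$target_id == g & records$group %in% kw_groups, ]
    res <- kruskal_wallis(sub$log2fc, sub$group)
    data.frame(gene_id = g, test = res$test, statistic = res$statistic,
               df = res$df, p_raw = res$p_raw,
               group_spec = paste(kw_groups, collapse = "|"),
               stringsAsFactors = FALSE)
  })
  kw <- do.call(rbind, kw)
  kw$p_adj <- bh_adjust(kw$p_raw)

  mwu <- lapply(genes, function(g) {
    sub <- records[records$target_id == g, ]
    a <- sub$log2fc[sub$group == mwu_group]
    b <- sub$log2fc[sub$group != mwu_group]
    res <- mann_whitney(a, b, mode = mwu_mode)
    data.frame(gene_id = g, test = res$test, statistic = res$statistic,
               df = NA_integer_, p_raw = res$p_raw,
               group_spec = paste0(mwu_group, " vs rest"),
               stringsAsFactors = FALSE)
  })
  mwu <- do.call(rbind, mwu)
  mwu$p_adj <- bh_adjust(mwu$p_raw)

  out <- rbind(kw, mwu)
  out <- out[, c("gene_id", "test", "statistic", "df", "p_raw", "p_adj",
                 "group_spec")]
  rownames(out) <- NULL
  out
}
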