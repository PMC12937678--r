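# Two-reference ddCq quantification against a pooled calibrator.
#
# Normalization to the geometric mean of the reference genes' expression is
# carried out as the arithmetic mean of their Cq values — the exact
# log-space equivalent when every assay amplifies with efficiency 2 (the
# geometric mean of 2^-Cq values is 2^-mean(Cq)). Implementers commonly get
# this wrong by geometric-averaging the Cq values themselves.

#' Reference-normalized Cq (delta Cq) for one sample and target
#'
#' dCq = Cq_target - mean(Cq of the reference genes), i.e. the sample's
#' normalized abundance on the -log2 scale.
#'
#' @param sample sample id (column of the matrix).
#' @param target target gene id (row of the matrix).
#' @param matrix a `cq_matrix` or genes x samples numeric matrix of mean Cq.
#' @param references one or more reference gene ids.
#' @return dCq in cycles.
#' @export
delta_cq <- function(sample, target, matrix, references) {
  cm <- as_cq_matrix(matrix)$mean_cq
  for (g in c(target, references)) {
    if (!g %in% rownames(cm)) stop_missing("gene not in matrix: ", g)
  }
  if (!sample %in% colnames(cm)) stop_missing("sample not in matrix: ", sample)
  vals <- cm[c(target, references), sample]
  if (anyNA(vals)) {
    stop_missing("missing Cq for sample ", sample, ", gene(s) ",
                 paste(c(target, references)[is.na(vals)], collapse = ", "))
  }
  unname(vals[1L] - mean(vals[-1L]))
}

#' Fold-change table by the 2^-ddCq method
#'
#' For every target gene and non-excluded sample: dCq is computed against
#' the reference genes, the calibrator dCq is the median of the calibrator
#' samples' dCq values (with two calibrators, their midpoint), and
#' ddCq = dCq_sample - dCq_calibrator, FC = 2^-ddCq, log2FC = -ddCq. Full
#' precision is carried throughout; the 2-decimal presentation applies only
#' in [write_table()].
#'
#' @param matrix a `cq_matrix` (or plain matrix plus `groups`).
#' @param targets target gene ids.
#' @param references reference gene ids averaged into the normalizer.
#' @param calibrators sample ids anchoring fold change 1 (>= 1); each must
#'   have a QC-passed Cq for every target and reference gene.
#' @param excluded sample ids to drop from the output (reported via the
#'   "excluded" attribute rather than silently).
#' @param groups optional named group vector overriding the matrix groups.
#' @return data.frame of class `expression_table`: sample_id, group,
#'   target_id, delta_cq, delta_delta_cq, fold_change, log2fc. The
#'   calibrator dCq per target is in attribute "calibrator_dcq".
#' @export
expression_table <- function(matrix, targets, references, calibrators,
                             excluded = character(), groups = NULL) {
  cm <- as_cq_matrix(matrix)
  mat <- cm$mean_cq
  if (is.null(groups)) groups <- cm$groups
  if (length(calibrators) < 1L) {
    stop_argument("at least one calibrator sample is required")
  }
  for (s in calibrators) {
    vals <- mat[c(targets, references), s]
    if (anyNA(vals)) {
      stop_missing("calibrator ", s, " is missing QC-passed Cq for gene(s) ",
                   paste(c(targets, references)[is.na(vals)], collapse = ", "))
    }
  }
  keep <- setdiff(colnames(mat), excluded)
  rows <- list()
  cal_dcq <- stats::setNames(numeric(length(targets)), targets)
  for (g in targets) {
    dcq_cal <- stats::median(vapply(calibrators, function(s)
      delta_cq(s, g, cm, references), 0))
    cal_dcq[g] <- dcq_cal
    for (s in keep) {
      vals <- mat[c(g, references), s]
      if (anyNA(vals)) next  # INVALID reaction: no record for this cell
      dcq <- unname(vals[1L] - mean(vals[-1L]))
      ddcq <- dcq - dcq_cal
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s,
        group = if (!is.null(groups)) unname(groups[s]) else NA_character_,
        target_id = g, delta_cq = dcq, delta_delta_cq = ddcq,
        fold_change = 2^(-ddcq), log2fc = -ddcq, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "calibrator_dcq") <- cal_dcq
  attr(out, "excluded") <- excluded
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Base-2 logarithm of a fold change
#'
#' @param fc fold change(s), strictly positive.
#' @return log2(fc).
#' @export
log2_of_fc <- function(fc) {
  if (any(!is.finite(fc) | fc <= 0)) {
    stop_domain("fold change must be finite and > 0")
  }
  log2(fc)
}

#' Amplification efficiency from a dilution series
#'
#' Fits the least-squares regression of Cq on log10(template amount) and
#' reports the slope, R-squared, amplification factor E = 10^(-1/slope) and
#' percent efficiency (E - 1) * 100. A standard-curve slope of -3.3219
#' corresponds to perfect doubling (E = 2). This is a reporting/validation
#' tool: downstream quantification always assumes E = 2 rather than
#' applying assay-specific correction, since dilution series from
#' fragmented templates frequently show apparent efficiencies above 100%
#' for matrix-related reasons.
#'
#' @param input_amounts template amounts per reaction (e.g. ng), >= 3
#'   distinct positive values.
#' @param cq measured Cq per dilution level.
#' @return list of class `dilution_series`: input_amounts, cq, slope,
#'   r_squared, efficiency (E, NA for a non-negative slope),
#'   percent_efficiency.
#' @export
standard_curve_efficiency <- function(input_amounts, cq) {
  if (length(input_amounts) != length(cq)) {
    stop_argument("input_amounts and cq must have equal length")
  }
  if (length(unique(input_amounts)) < 3L) {
    stop_argument("need >= 3 distinct dilution levels")
  }
  if (any(input_amounts <= 0)) stop_domain("template amounts must be > 0")
  fit <- stats::lm(cq ~ log10(input_amounts))
  slope <- unname(stats::coef(fit)[2L])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- 1 - ss_res / ss_tot
  if (slope >= 0) {
    warning("non-negative standard-curve slope; efficiency undefined")
    eff <- NA_real_
  } else {
    eff <- 10^(-1 / slope)
  }
  structure(list(input_amounts = input_amounts, cq = cq, slope = slope,
                 r_squared = r2, efficiency = eff,
                 percent_efficiency = (eff - 1) * 100),
            class = "dilution_series")
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf(
    "<dilution_series> slope %.4f, R^2 %.4f, E = %.2f (%.0f%% efficiency)\n",
    x$slope, x$r_squared, x$efficiency, x$percent_efficiency))
  invisible(x)
}

#' Pivot an expression table to the wide per-sample layout
#'
#' One row per sample with per-gene FC and log2FC columns, the layout used
#' for publication-style fold-change matrices and heatmap input.
#'
#' @param records an [expression_table()].
#' @param value one of "both", "fold_change", "log2fc".
#' @return data.frame: sample_id, group, then `<gene>_fc` and/or
#'   `<gene>_log2fc` columns.
#' @export
expression_wide <- function(records, value = c("both", "fold_change",
                                               "log2fc")) {
  value <- match.arg(value)
  samples <- unique(records$sample_id)
  genes <- unique(records$target_id)
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  if ("group" %in% names(records)) {
    out$group <- records$group[match(samples, records$sample_id)]
  }
  for (g in genes) {
    sub <- records[records$target_id == g, ]
    i <- match(samples, sub$sample_id)
    if (value %in% c("both", "fold_change")) {
      out[[paste0(g, "_fc")]] <- sub$fold_change[i]
    }
    if (value %in% c("both", "log2fc")) {
      out[[paste0(g, "_log2fc")]] <- sub$log2fc[i]
    }
  }
  out
}
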