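# Cohort simulator with known ground truth, plus the packaged worked
# example: a published thymic epithelial tumor (TET) fold-change table.

HIPPO_TARGETS <- c("MST1", "SAV1", "LATS1", "MOB1A", "YAP1", "TEAD4")
REF_CANDIDATES <- c("HPRT1_RTP", "TBP", "PPIA", "HPRT1_IDT")

# subtype-specific log2 expression shifts used as the default simulated
# effect profile: the median log2FC per target x subtype observed in the
# TET cohort the package ships as its worked example (normals 0 by
# construction)
tet_median_effects <- function() {
  eff <- rbind(
    MST1  = c(N = 0, A = -0.15, B1 = -0.68, B2 = -0.09, B3 = -0.26, TC = -1.38),
    SAV1  = c(N = 0, A =  2.25, B1 = -0.32, B2 =  0.78, B3 =  2.01, TC =  0.67),
    LATS1 = c(N = 0, A =  0.13, B1 = -0.83, B2 =  0.10, B3 = -0.03, TC = -1.34),
    MOB1A = c(N = 0, A =  0.22, B1 = -0.13, B2 =  0.15, B3 =  0.33, TC = -0.14),
    YAP1  = c(N = 0, A =  3.43, B1 =  0.18, B2 =  0.74, B3 =  2.78, TC =  1.64),
    TEAD4 = c(N = 0, A =  1.74, B1 =  0.31, B2 =  0.01, B3 =  1.55, TC =  3.49))
  eff
}

#' Simulation settings for a synthetic RT-qPCR cohort
#'
#' Defaults emulate the study design of the packaged TET example: 26 FFPE
#' samples in six groups (3 normals, 3 type A, 5 each of B1/B2/B3/TC), six
#' target genes and four candidate reference genes run in technical
#' triplicate, with sample-specific loading offsets (removed by reference
#' normalization), subtype-specific log2 expression shifts (default: the
#' example cohort's median log2FC profile), small replicate noise typical
#' of a well-behaved SYBR assay (0.15 Cq), one deliberately unstable
#' reference candidate, and sporadic outlier/invalid reactions plus
#' NTC/NRT/IC control wells.
#'
#' @param group_sizes named integer vector of samples per group; must
#'   include "N" (the calibrator group).
#' @param target_genes,reference_genes gene identifiers.
#' @param gene_baseline_cq named baseline Cq per gene, or NULL to draw
#'   each from Uniform(22, 30) at simulation time.
#' @param group_effects targets x groups matrix of log2 expression shifts
#'   (positive = higher expression = lower Cq); reference genes always 0.
#' @param loading_sd SD of the per-sample loading offset (Cq, default 1.0).
#' @param replicate_sd SD of technical replicate noise (Cq, default 0.15).
#' @param reference_instability_sd per-reference SD of gene-specific
#'   sample-level wobble; the default makes the last candidate unstable
#'   (0.8 Cq) so stability ranking has signal.
#' @param outlier_prob probability a reaction carries one shifted replicate.
#' @param outlier_shift range (min, max) of the uniform outlier shift in Cq.
#' @param invalid_prob probability a reaction is scattered beyond repair.
#' @param ntc_signal_prob probability an NTC well shows a late signal
#'   (Cq drawn from Uniform(37.5, 40) rather than no amplification).
#' @param max_cycles cycling program length.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(group_sizes = c(N = 3L, A = 3L, B1 = 5L,
                                              B2 = 5L, B3 = 5L, TC = 5L),
                              target_genes = HIPPO_TARGETS,
                              reference_genes = REF_CANDIDATES,
                              gene_baseline_cq = NULL,
                              group_effects = NULL,
                              loading_sd = 1.0,
                              replicate_sd = 0.15,
                              reference_instability_sd = NULL,
                              outlier_prob = 0.03,
                              outlier_shift = c(1.0, 3.0),
                              invalid_prob = 0.01,
                              ntc_signal_prob = 0.05,
                              max_cycles = 40L) {
  if (!"N" %in% names(group_sizes)) {
    stop_argument("group_sizes must include the calibrator group \"N\"")
  }
  if (any(group_sizes < 1L)) stop_argument("group sizes must be >= 1")
  if (is.null(group_effects)) {
    group_effects <- tet_median_effects()[target_genes, names(group_sizes),
                                          drop = FALSE]
    group_effects[is.na(group_effects)] <- 0
  }
  if (!all(is.finite(group_effects))) {
    stop_argument("group_effects must be finite")
  }
  if (is.null(reference_instability_sd)) {
    reference_instability_sd <- rep(0.05, length(reference_genes))
    reference_instability_sd[length(reference_genes)] <- 0.8
  }
  probs <- c(outlier_prob, invalid_prob, ntc_signal_prob)
  if (any(probs < 0 | probs > 1)) stop_argument("probabilities must be in [0,1]")
  if (loading_sd < 0 || replicate_sd < 0 ||
      any(reference_instability_sd < 0)) {
    stop_argument("standard deviations must be >= 0")
  }
  structure(list(group_sizes = group_sizes, target_genes = target_genes,
                 reference_genes = reference_genes,
                 gene_baseline_cq = gene_baseline_cq,
                 group_effects = group_effects, loading_sd = loading_sd,
                 replicate_sd = replicate_sd,
                 reference_instability_sd = stats::setNames(
                   reference_instability_sd, reference_genes),
                 outlier_prob = outlier_prob, outlier_shift = outlier_shift,
                 invalid_prob = invalid_prob,
                 ntc_signal_prob = ntc_signal_prob,
                 max_cycles = as.integer(max_cycles)),
            class = "simulation_config")
}

#' Simulate a cohort-shaped Cq dataset with known ground truth
#'
#' Cq(sample j of group g, gene i, replicate k) =
#' baseline_i - effect_(i,g) + loading_j + instability_(i,j) + noise, with
#' replicate noise ~ Normal(0, replicate_sd^2) and loading_j ~
#' Normal(0, loading_sd^2). Outlier reactions shift one replicate by a
#' uniform draw from `outlier_shift`; invalid reactions scatter the three
#' replicates ~2 Cq apart so no consistent pair survives triage. One plate
#' per gene is emitted with an NTC well; NRT wells per sample (negative)
#' and IC wells per sample accompany the cohort. Reference genes carry no
#' group effect, so every sample's true log2FC equals its group effect.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; identical seeds give identical datasets.
#' @return list: `dataset` (a [cq_dataset()]), `truth` (data.frame
#'   sample_id, group, target_id, true_log2fc), `config`, `seed`.
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  gs <- config$group_sizes
  sample_ids <- unlist(lapply(names(gs), function(g)
    paste0(g, seq_len(gs[[g]]))), use.names = FALSE)
  groups <- rep(names(gs), times = gs)
  n <- length(sample_ids)

  targets <- config$target_genes
  refs <- config$reference_genes
  genes <- c(targets, refs)
  baseline <- config$gene_baseline_cq
  if (is.null(baseline)) {
    baseline <- stats::setNames(stats::runif(length(genes), 22, 30), genes)
  } else {
    baseline <- baseline[genes]
  }
  effects <- matrix(0, length(genes), length(gs),
                    dimnames = list(genes, names(gs)))
  effects[targets, colnames(config$group_effects)] <-
    config$group_effects[targets, , drop = FALSE]

  loading <- stats::rnorm(n, 0, config$loading_sd)

  rows <- vector("list", length(genes) * n + length(genes) + 2L * n)
  ri <- 0L
  add <- function(df) { ri <<- ri + 1L; rows[[ri]] <<- df }

  for (gi in seq_along(genes)) {
    g <- genes[gi]
    plate <- paste0("P_", g)
    run <- if (gi <= ceiling(length(genes) / 2)) "run1" else "run2"
    inst_sd <- if (g %in% refs) config$reference_instability_sd[[g]] else 0
    for (j in seq_len(n)) {
      true_cq <- baseline[g] - effects[g, groups[j]] + loading[j] +
        if (inst_sd > 0) stats::rnorm(1L, 0, inst_sd) else 0
      cqs <- true_cq + stats::rnorm(3L, 0, config$replicate_sd)
      u <- stats::runif(1L)
      invalid <- u < config$invalid_prob
      if (invalid) {
        cqs <- cqs + c(0, 2, 4)  # no pair within 0.8 Cq survives
      } else if (u < config$invalid_prob + config$outlier_prob) {
        k <- sample.int(3L, 1L)
        cqs[k] <- cqs[k] + stats::runif(1L, config$outlier_shift[1L],
                                        config$outlier_shift[2L])
      }
      cqs <- pmin(cqs, config$max_cycles)
      add(data.frame(sample_id = sample_ids[j], target_id = g,
                     replicate_index = 1:3, cq = cqs, plate_id = plate,
                     run_id = run, well_role = "SAMPLE",
                     stringsAsFactors = FALSE))
      if (invalid && groups[j] == "N") {
        # calibrator-group reactions that fail triage are re-analyzed on an
        # additional plate, as a real study must (the calibrator anchors
        # every fold change and cannot be left missing)
        rep_cqs <- true_cq + stats::rnorm(3L, 0, config$replicate_sd)
        add(data.frame(sample_id = sample_ids[j], target_id = g,
                       replicate_index = 1:3,
                       cq = pmin(rep_cqs, config$max_cycles),
                       plate_id = paste0(plate, "_repeat"), run_id = run,
                       well_role = "SAMPLE", stringsAsFactors = FALSE))
      }
    }
    ntc_cq <- if (stats::runif(1L) < config$ntc_signal_prob) {
      stats::runif(1L, 37.5, config$max_cycles)
    } else NA_real_
    add(data.frame(sample_id = "NTC", target_id = g, replicate_index = 1L,
                   cq = ntc_cq, plate_id = plate, run_id = run,
                   well_role = "NTC", stringsAsFactors = FALSE))
  }

  # NRT (always negative here) and IC wells, one per sample
  for (j in seq_len(n)) {
    add(data.frame(sample_id = sample_ids[j], target_id = targets[1L],
                   replicate_index = 1L, cq = NA_real_,
                   plate_id = paste0("P_", targets[1L]), run_id = "run1",
                   well_role = "NRT", stringsAsFactors = FALSE))
    add(data.frame(sample_id = sample_ids[j], target_id = "IC",
                   replicate_index = 1L,
                   cq = 25 + stats::rnorm(1L, 0, 0.3),
                   plate_id = "P_IC", run_id = "run1", well_role = "IC",
                   stringsAsFactors = FALSE))
  }

  measurements <- do.call(rbind, rows[seq_len(ri)])
  samples <- data.frame(
    sample_id = sample_ids, group = groups,
    is_calibrator = groups == "N",
    is_excluded = FALSE, exclusion_reason = "",
    stringsAsFactors = FALSE)

  truth <- do.call(rbind, lapply(targets, function(g)
    data.frame(sample_id = sample_ids, group = groups, target_id = g,
               true_log2fc = effects[g, groups], stringsAsFactors = FALSE)))
  rownames(truth) <- NULL

  list(dataset = cq_dataset(measurements, samples,
                            max_cycles = config$max_cycles),
       truth = truth, config = config, seed = seed)
}

#' Packaged worked example: TET Hippo-pathway fold-change table
#'
#' Returns the per-sample fold-change / log2FC table of the packaged
#' thymic epithelial tumor cohort (26 samples x 6 Hippo-pathway genes,
#' normalized to the HPRT1/TBP geometric mean and calibrated to the median
#' of the two retained normal thymus samples), together with its sample
#' metadata: samples 1 and 3 (normal thymus) are the calibrators; sample 2
#' is excluded from group statistics because of benign cystic histology
#' with sparse thymic parenchyma.
#'
#' @return list: `records` (sample_id, group, target_id, fold_change,
#'   log2fc; class `expression_table`), `samples` (sample metadata).
#' @export
fixture_table2 <- function() {
  path <- system.file("extdata", "tet_hippo_expression.csv",
                      package = "relqpcr", mustWork = TRUE)
  rec <- utils::read.csv(path, colClasses = c(sample_id = "character"),
                         stringsAsFactors = FALSE)
  class(rec) <- c("expression_table", "data.frame")
  ids <- unique(rec$sample_id)
  samples <- data.frame(
    sample_id = ids,
    group = rec$group[match(ids, rec$sample_id)],
    is_calibrator = ids %in% c("1", "3"),
    is_excluded = ids == "2",
    exclusion_reason = ifelse(ids == "2",
      "benign cystic histology, sparse thymic parenchyma", ""),
    stringsAsFactors = FALSE)
  list(records = rec, samples = samples)
}
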