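# End-to-end orchestration: QC -> stability -> expression -> statistics,
# with all result tables written to an output directory plus a JSON
# manifest recording thresholds, counts and content hashes.

#' Pipeline configuration
#'
#' Collects every tunable threshold and analysis choice of the workflow in
#' one validated list. Defaults are the package-wide conventions: replicate
#' spread thresholds 0.5 / 0.8 Cq, outlier cutoff 0.5 Cq, NTC acceptance at
#' 37.5 cycles, IC deviation < 2 Cq, inter-run bridge tolerance 1 Cq,
#' two-reference normalization, and TC-vs-rest / tumor-subtype statistics.
#'
#' @param references reference genes averaged into the normalizer.
#' @param calibrators calibrator sample ids (fold change 1 anchor).
#' @param excluded sample ids removed before quantification/statistics.
#' @param targets target genes; NULL = every non-reference gene present.
#' @param qc named list overriding QC thresholds (gold_spread,
#'   accept_spread, outlier_delta, ntc_min_cq, ic_max_delta,
#'   bridge_tolerance).
#' @param kw_groups,mwu_group group specifications for [analyze_groups()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(references = c("HPRT1_RTP", "TBP"),
                            calibrators = c("N1", "N3"),
                            excluded = character(),
                            targets = NULL,
                            qc = list(),
                            kw_groups = c("A", "B1", "B2", "B3", "TC"),
                            mwu_group = "TC") {
  thresholds <- utils::modifyList(QC_DEFAULTS, qc)
  unknown <- setdiff(names(qc), names(QC_DEFAULTS))
  if (length(unknown) > 0L) {
    stop_argument("unknown qc config key(s): ",
                  paste(unknown, collapse = ", "),
                  " (config path: qc.<key>)")
  }
  if (any(unlist(thresholds) <= 0)) {
    stop_argument("all qc thresholds must be positive")
  }
  structure(list(references = references, calibrators = calibrators,
                 excluded = excluded, targets = targets, qc = thresholds,
                 kw_groups = kw_groups, mwu_group = mwu_group),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a Cq dataset
#'
#' Executes replicate triage and control checks, builds the mean-Cq
#' matrix, ranks the reference-gene candidates, computes the 2^-ddCq
#' fold-change table against the configured calibrator, derives subtype
#' medians (the heatmap-ready gene x subtype matrix) and the nonparametric
#' group statistics, and (optionally) writes every table to `out_dir`
#' together with a JSON manifest of thresholds, stage counts and per-file
#' MD5 hashes. Re-running on identical inputs reproduces identical files.
#'
#' @param dataset a [cq_dataset()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or NULL to skip writing.
#' @param ref_candidates candidate genes for the stability ranking;
#'   defaults to `config$references` plus any other genes that are not
#'   targets, when at least 3 such candidates exist.
#' @return invisibly, a list: triage, controls, matrix, stability (NULL if
#'   too few candidates), expression, medians, stats, manifest.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(),
                         out_dir = NULL, ref_candidates = NULL) {
  stopifnot(inherits(dataset, "cq_dataset"),
            inherits(config, "pipeline_config"))
  th <- config$qc

  triage <- triage_dataset(dataset, gold_spread = th$gold_spread,
                           accept_spread = th$accept_spread,
                           outlier_delta = th$outlier_delta)
  controls <- qc_controls(dataset, ntc_min_cq = th$ntc_min_cq,
                          ic_max_delta = th$ic_max_delta)
  mat <- build_cq_matrix(dataset, triage)

  all_genes <- rownames(mat$mean_cq)
  missing_ref <- setdiff(config$references, all_genes)
  if (length(missing_ref) > 0L) {
    stop_missing("configured reference gene(s) absent from data: ",
                 paste(missing_ref, collapse = ", "),
                 " (config path: references)")
  }
  if (is.null(ref_candidates)) {
    # default candidate panel: the configured references plus any other
    # known housekeeping candidates present in the data
    ref_candidates <- intersect(unique(c(config$references, REF_CANDIDATES)),
                                all_genes)
  }
  targets <- config$targets
  if (is.null(targets)) {
    targets <- setdiff(all_genes, c(ref_candidates, "IC"))
  }
  targets <- setdiff(targets, ref_candidates)

  stability <- if (length(ref_candidates) >= 3L) {
    rank_reference_genes(mat, ref_candidates)
  } else NULL

  expr <- expression_table(mat, targets = targets,
                           references = config$references,
                           calibrators = config$calibrators,
                           excluded = config$excluded)
  stats_in <- expr[!expr$sample_id %in% config$excluded, , drop = FALSE]
  medians <- subtype_medians(stats_in)
  stats <- analyze_groups(stats_in, kw_groups = config$kw_groups,
                          mwu_group = config$mwu_group)

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      qc_triage.tsv = triage,
      expression_long.tsv = as.data.frame(expr),
      expression_wide.tsv = expression_wide(expr),
      subtype_medians.tsv = cbind(group = rownames(medians),
                                  as.data.frame(medians)),
      stats.tsv = stats)
    if (!is.null(stability)) files$stability.tsv <- stability
    for (nm in names(files)) {
      write_table(files[[nm]], file.path(out_dir, nm), format = "TSV",
                  allow_empty = TRUE)
    }
    manifest <- list(
      package = "relqpcr",
      version = as.character(utils::packageVersion("relqpcr")),
      thresholds = th,
      references = config$references,
      calibrators = config$calibrators,
      excluded = config$excluded,
      counts = list(
        wells = nrow(dataset$measurements),
        reactions = nrow(triage),
        invalid_reactions = sum(triage$status == "INVALID"),
        expression_records = nrow(expr),
        genes = length(targets),
        samples = ncol(mat$mean_cq)),
      files = lapply(stats::setNames(names(files), names(files)),
                     function(nm) list(
                       path = nm,
                       md5 = unname(tools::md5sum(file.path(out_dir, nm)))))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(triage = triage, controls = controls, matrix = mat,
                 stability = stability, expression = expr,
                 medians = medians, stats = stats, manifest = manifest))
}
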