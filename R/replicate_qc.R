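# Replicate triage and control-well acceptance.
#
# Triage thresholds reflect FFPE practice: triplicates whose total spread is
# within 0.5 Cq are fully consistent ("gold standard"); a spread up to
# 0.8 Cq is still accepted for fragmented FFPE templates; a single replicate
# deviating by more than 0.5 Cq from the mean of the two most consistent
# replicates is a technical outlier and is dropped; reactions without two
# replicates within 0.8 Cq of each other are invalid.

QC_DEFAULTS <- list(gold_spread = 0.5, accept_spread = 0.8,
                    outlier_delta = 0.5, ntc_min_cq = 37.5,
                    ic_max_delta = 2.0, bridge_tolerance = 1.0)

#' Classify one reaction's technical replicates
#'
#' Applies the replicate-consistency rules to 1--3 Cq values from one
#' sample x target reaction. `NA` values (no amplification) are dropped
#' before classification and reported in the summary message. The decision
#' sequence is: fewer than two present values is INVALID; otherwise find the
#' two most consistent replicates (smallest absolute difference; ties broken
#' toward the pair whose mean is closest to the median of all three, then by
#' lowest replicate indices); if even that pair differs by more than
#' `accept_spread` the reaction is INVALID; a third replicate deviating by
#' more than `outlier_delta` from the pair mean is excluded
#' (OUTLIER_REMOVED); otherwise the reaction is GOLD when the total spread
#' is within `gold_spread` and FFPE_ACCEPTED when within `accept_spread`.
#' The outlier rule is checked before the total-spread acceptance because it
#' is stated unconditionally.
#'
#' @param cqs numeric vector of 1--3 Cq values; `NA` = no amplification.
#' @param gold_spread maximum total spread for GOLD (Cq, default 0.5).
#' @param accept_spread maximum accepted spread / pair difference (default 0.8).
#' @param outlier_delta deviation from the consistent-pair mean beyond which
#'   a third replicate is excluded (default 0.5).
#' @param sample_id,target_id optional identifiers carried into the summary.
#' @return A `triplicate_summary` list: `status` (GOLD, FFPE_ACCEPTED,
#'   OUTLIER_REMOVED, INVALID), `retained_cqs`, `mean_cq`, `sd_cq`, `spread`
#'   (max - min of present raw replicates), `n_absent`, `message`.
#' @export
classify_triplicate <- function(cqs, gold_spread = 0.5, accept_spread = 0.8,
                                outlier_delta = 0.5, sample_id = NA_character_,
                                target_id = NA_character_) {
  if (length(cqs) < 1L || length(cqs) > 3L) {
    stop_argument("classify_triplicate expects 1-3 Cq values, got ",
                  length(cqs))
  }
  raw <- as.numeric(cqs)
  n_absent <- sum(is.na(raw))
  present <- raw[!is.na(raw)]
  msg <- if (n_absent > 0L) {
    paste0(n_absent, " replicate(s) with no amplification dropped")
  } else ""

  mk <- function(status, retained, message = msg) {
    structure(list(sample_id = sample_id, target_id = target_id,
                   status = status,
                   retained_cqs = retained,
                   mean_cq = if (length(retained)) mean(retained) else NA_real_,
                   sd_cq = if (length(retained) > 1L) stats::sd(retained)
                           else NA_real_,
                   spread = if (length(present) > 1L)
                              max(present) - min(present) else 0,
                   n_absent = n_absent,
                   message = message),
              class = "triplicate_summary")
  }

  if (length(present) < 2L) {
    return(mk("INVALID", numeric(0),
              message = trimws(paste(msg,
                "fewer than two replicates amplified"))))
  }

  if (length(present) == 2L) {
    d <- abs(present[1L] - present[2L])
    if (d > accept_spread) return(mk("INVALID", numeric(0),
      message = trimws(paste(msg, sprintf(
        "pair difference %.3f > %.2f", d, accept_spread)))))
    status <- if (d <= gold_spread) "GOLD" else "FFPE_ACCEPTED"
    return(mk(status, present))
  }

  pair <- closest_pair(present)
  pair_vals <- present[pair]
  d <- abs(diff(pair_vals))
  if (d > accept_spread) {
    return(mk("INVALID", numeric(0),
              message = trimws(paste(msg, sprintf(
                "no two replicates within %.2f Cq (closest pair %.3f)",
                accept_spread, d)))))
  }
  third <- present[-pair]
  if (abs(third - mean(pair_vals)) > outlier_delta) {
    return(mk("OUTLIER_REMOVED", pair_vals,
              message = trimws(paste(msg, sprintf(
                "replicate %.3f deviates %.3f > %.2f from pair mean",
                third, abs(third - mean(pair_vals)), outlier_delta)))))
  }
  spread <- max(present) - min(present)
  if (spread <= gold_spread) return(mk("GOLD", present))
  if (spread <= accept_spread) return(mk("FFPE_ACCEPTED", present))
  # unreachable for valid thresholds (a spread > accept_spread with a
  # consistent pair forces the third replicate past outlier_delta), but kept
  # as a defensive terminal state
  mk("INVALID", numeric(0))
}

# index pair (i, j) of the two most consistent replicates among three;
# ties resolved toward the pair whose mean is nearest the median, then by
# lowest indices
closest_pair <- function(x) {
  stopifnot(length(x) == 3L)
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  diffs <- vapply(pairs, function(p) abs(x[p[1L]] - x[p[2L]]), 0)
  best <- which(diffs == min(diffs))
  if (length(best) > 1L) {
    med <- stats::median(x)
    dist_med <- vapply(best, function(i) abs(mean(x[pairs[[i]]]) - med), 0)
    best <- best[dist_med == min(dist_med)]
  }
  pairs[[best[1L]]]
}

#' @export
print.triplicate_summary <- function(x, ...) {
  cat("<triplicate_summary> ", x$status,
      if (!is.na(x$mean_cq)) sprintf(" mean %.3f (sd %.3f, spread %.3f)",
                                     x$mean_cq, x$sd_cq, x$spread),
      if (nzchar(x$message)) paste0(" [", x$message, "]"), "\n", sep = "")
  invisible(x)
}

#' Triage every sample reaction in a dataset
#'
#' Runs [classify_triplicate()] on each SAMPLE-role sample x target x plate
#' combination.
#'
#' @param dataset a [cq_dataset()].
#' @inheritParams classify_triplicate
#' @return data.frame with one row per reaction: sample_id, target_id,
#'   plate_id, status, n_retained, mean_cq, sd_cq, spread, message.
#' @export
triage_dataset <- function(dataset, gold_spread = 0.5, accept_spread = 0.8,
                           outlier_delta = 0.5) {
  stopifnot(inherits(dataset, "cq_dataset"))
  m <- dataset$measurements
  m <- m[m$well_role == "SAMPLE", , drop = FALSE]
  if (nrow(m) == 0L) {
    return(data.frame(sample_id = character(), target_id = character(),
                      plate_id = character(), status = character(),
                      n_retained = integer(), mean_cq = numeric(),
                      sd_cq = numeric(), spread = numeric(),
                      message = character(), stringsAsFactors = FALSE))
  }
  key <- paste(m$sample_id, m$target_id, m$plate_id, sep = "\r")
  # preserve first-appearance order so later plates (re-runs) sort last
  idx <- split(seq_len(nrow(m)), factor(key, levels = unique(key)))
  rows <- lapply(idx, function(i) {
    s <- classify_triplicate(m$cq[i], gold_spread, accept_spread,
                             outlier_delta, sample_id = m$sample_id[i[1L]],
                             target_id = m$target_id[i[1L]])
    data.frame(sample_id = m$sample_id[i[1L]], target_id = m$target_id[i[1L]],
               plate_id = m$plate_id[i[1L]], status = s$status,
               n_retained = length(s$retained_cqs), mean_cq = s$mean_cq,
               sd_cq = s$sd_cq, spread = s$spread, message = s$message,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate control wells (NTC, NRT, IC)
#'
#' No-template controls pass when they show no amplification or only a late
#' signal (`cq >= ntc_min_cq`); no-RT controls must be negative (no signal);
#' internal-control wells pass when their Cq deviates by less than
#' `ic_max_delta` from the median IC Cq of the same run. Control classes
#' absent from the dataset yield "not evaluated" messages, never failures.
#'
#' @param dataset a [cq_dataset()].
#' @param ntc_min_cq NTC late-signal acceptance cutoff (default 37.5).
#' @param ic_max_delta maximum IC deviation from the run median (default 2.0).
#' @return A `control_report` list with data.frames `ntc` (plate x target),
#'   `nrt` (sample x target), `ic` (sample), and a character vector
#'   `messages`.
#' @export
qc_controls <- function(dataset, ntc_min_cq = 37.5, ic_max_delta = 2.0) {
  stopifnot(inherits(dataset, "cq_dataset"))
  m <- dataset$measurements
  messages <- character()

  ntc <- m[m$well_role == "NTC", , drop = FALSE]
  if (nrow(ntc) == 0L) {
    messages <- c(messages, "NTC: not evaluated (no NTC wells)")
    ntc_df <- data.frame(plate_id = character(), target_id = character(),
                         cq = numeric(), pass = logical())
  } else {
    ntc_df <- data.frame(plate_id = ntc$plate_id, target_id = ntc$target_id,
                         cq = ntc$cq,
                         pass = is.na(ntc$cq) | ntc$cq >= ntc_min_cq,
                         stringsAsFactors = FALSE)
    if (any(!ntc_df$pass)) {
      messages <- c(messages, sprintf(
        "NTC failure: %d well(s) with Cq < %.1f", sum(!ntc_df$pass),
        ntc_min_cq))
    }
  }

  nrt <- m[m$well_role == "NRT", , drop = FALSE]
  if (nrow(nrt) == 0L) {
    messages <- c(messages, "NRT: not evaluated (no NRT wells)")
    nrt_df <- data.frame(sample_id = character(), target_id = character(),
                         cq = numeric(), pass = logical())
  } else {
    nrt_df <- data.frame(sample_id = nrt$sample_id, target_id = nrt$target_id,
                         cq = nrt$cq, pass = is.na(nrt$cq),
                         stringsAsFactors = FALSE)
    if (any(!nrt_df$pass)) {
      messages <- c(messages, sprintf(
        "NRT failure: %d well(s) with amplification (possible gDNA)",
        sum(!nrt_df$pass)))
    }
  }

  ic <- m[m$well_role == "IC" & !is.na(m$cq), , drop = FALSE]
  if (nrow(ic) == 0L) {
    messages <- c(messages, "IC: not evaluated (no IC wells)")
    ic_df <- data.frame(sample_id = character(), run_id = character(),
                        cq = numeric(), delta = numeric(), pass = logical())
  } else {
    run_median <- stats::ave(ic$cq, ic$run_id, FUN = stats::median)
    delta <- abs(ic$cq - run_median)
    ic_df <- data.frame(sample_id = ic$sample_id, run_id = ic$run_id,
                        cq = ic$cq, delta = delta,
                        pass = delta < ic_max_delta, stringsAsFactors = FALSE)
    if (any(!ic_df$pass)) {
      messages <- c(messages, sprintf(
        "IC failure (possible inhibition): sample(s) %s deviate >= %.1f Cq from run median",
        paste(ic_df$sample_id[!ic_df$pass], collapse = ", "), ic_max_delta))
    }
  }

  structure(list(ntc = ntc_df, nrt = nrt_df, ic = ic_df,
                 messages = messages),
            class = "control_report")
}

#' @export
print.control_report <- function(x, ...) {
  cat("<control_report> NTC ", sum(x$ntc$pass), "/", nrow(x$ntc),
      " pass; NRT ", sum(x$nrt$pass), "/", nrow(x$nrt),
      " pass; IC ", sum(x$ic$pass), "/", nrow(x$ic), " pass\n", sep = "")
  for (msg in x$messages) cat("  - ", msg, "\n", sep = "")
  invisible(x)
}

#' Inter-run bridging check
#'
#' Compares triaged mean Cq values of samples re-measured across two runs
#' (e.g. after an instrument replacement or reagent lot change) and passes
#' when every shared sample x target deviates by at most `tolerance` Cq.
#'
#' @param run_a,run_b data.frames as returned by [triage_dataset()] (need
#'   columns sample_id, target_id, mean_cq).
#' @param tolerance maximum accepted |mean Cq difference| (default 1.0, the
#'   permissive end of the usual 0.5--1 Cq inter-run band).
#' @return list with `pass` (logical, `NA` if nothing shared), per-key
#'   data.frame `detail`, `max_deviation`, and `messages`.
#' @export
bridge_check <- function(run_a, run_b, tolerance = 1.0) {
  key_a <- paste(run_a$sample_id, run_a$target_id, sep = "\r")
  key_b <- paste(run_b$sample_id, run_b$target_id, sep = "\r")
  shared <- intersect(key_a, key_b)
  if (length(shared) == 0L) {
    return(list(pass = NA, detail = NULL, max_deviation = NA_real_,
                messages = "bridge: not evaluated (no shared sample x target)"))
  }
  ia <- match(shared, key_a); ib <- match(shared, key_b)
  dev <- abs(run_a$mean_cq[ia] - run_b$mean_cq[ib])
  detail <- data.frame(sample_id = run_a$sample_id[ia],
                       target_id = run_a$target_id[ia],
                       mean_cq_a = run_a$mean_cq[ia],
                       mean_cq_b = run_b$mean_cq[ib],
                       deviation = dev, pass = dev <= tolerance,
                       stringsAsFactors = FALSE)
  list(pass = all(detail$pass, na.rm = TRUE), detail = detail,
       max_deviation = max(dev, na.rm = TRUE),
       messages = if (all(detail$pass)) character() else sprintf(
         "bridge failure: %d key(s) deviate > %.2f Cq", sum(!detail$pass),
         tolerance))
}

#' Build the genes x samples mean-Cq matrix from triaged reactions
#'
#' Aggregates triage results into the matrix consumed by the stability and
#' quantification stages. When a reaction was repeated on a further plate,
#' the valid measurement from the latest plate (in order of appearance)
#' replaces earlier ones; reactions that are INVALID on every plate leave a
#' missing cell.
#'
#' @param dataset a [cq_dataset()].
#' @param triage optional precomputed [triage_dataset()] result.
#' @return A `cq_matrix` object: list with `mean_cq` (genes x samples numeric
#'   matrix), `status` (same shape, character), `groups` (named by sample).
#' @export
build_cq_matrix <- function(dataset, triage = NULL) {
  stopifnot(inherits(dataset, "cq_dataset"))
  if (is.null(triage)) triage <- triage_dataset(dataset)
  genes <- unique(triage$target_id)
  sample_ids <- dataset$samples$sample_id
  mean_cq <- matrix(NA_real_, length(genes), length(sample_ids),
                    dimnames = list(genes, sample_ids))
  status <- matrix(NA_character_, length(genes), length(sample_ids),
                   dimnames = list(genes, sample_ids))
  for (i in seq_len(nrow(triage))) {
    g <- triage$target_id[i]; s <- triage$sample_id[i]
    if (!s %in% sample_ids) next
    valid <- triage$status[i] != "INVALID"
    # later plates overwrite earlier results when valid (re-run replaces
    # failure); an invalid re-run never erases an earlier valid result
    if (valid || is.na(status[g, s])) {
      mean_cq[g, s] <- triage$mean_cq[i]
      status[g, s] <- triage$status[i]
    }
  }
  all_missing <- colSums(!is.na(mean_cq)) == 0L
  if (any(all_missing)) {
    warning("sample(s) with no valid reaction for any target: ",
            paste(sample_ids[all_missing], collapse = ", "))
  }
  groups <- stats::setNames(dataset$samples$group, sample_ids)
  structure(list(mean_cq = mean_cq, status = status, groups = groups),
            class = "cq_matrix")
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat("<cq_matrix> ", nrow(x$mean_cq), " genes x ", ncol(x$mean_cq),
      " samples; ", sum(is.na(x$mean_cq)), " missing cell(s)\n", sep = "")
  invisible(x)
}

# coerce plain matrices for the stability functions
as_cq_matrix <- function(x) {
  if (inherits(x, "cq_matrix")) return(x)
  if (is.matrix(x)) {
    return(structure(list(mean_cq = x, status = NULL, groups = NULL),
                     class = "cq_matrix"))
  }
  stop_argument("expected a cq_matrix or a genes x samples numeric matrix")
}
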