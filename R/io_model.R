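#' relqpcr: relative RT-qPCR quantification with replicate triage and
#' reference-gene stability ranking
#'
#' Tools for the complete analysis path of a SYBR-green RT-qPCR experiment
#' on challenging templates (e.g. FFPE-derived RNA): technical-replicate
#' quality triage, control-well acceptance (NTC/NRT/IC), inter-run bridging,
#' reference-gene stability assessment (geNorm, NormFinder, BestKeeper,
#' comparative delta-Cq, and their composite geometric-mean rank),
#' two-reference 2^-ddCq fold changes against a pooled calibrator, and
#' nonparametric group statistics. A seeded cohort simulator with known
#' ground truth supports end-to-end validation.
#'
#' @keywords internal
"_PACKAGE"

WELL_ROLES <- c("SAMPLE", "NTC", "NRT", "IC")
SUBTYPE_GROUPS <- c("N", "A", "B1", "B2", "B3", "TC")

CQ_COLUMNS <- c("sample_id", "target_id", "replicate_index", "cq",
                "plate_id", "run_id", "well_role")
META_COLUMNS <- c("sample_id", "group", "is_calibrator", "is_excluded",
                  "exclusion_reason")

#' Construct a validated Cq dataset
#'
#' Bundles well-level Cq measurements with sample metadata and validates the
#' combination: column presence, Cq range, well-key uniqueness, replicate
#' counts and referential integrity. `cq` may be `NA`, which encodes a well
#' with no amplification within `max_cycles` cycles ("ABSENT") -- distinct
#' from both 0 and a late Cq.
#'
#' @param measurements data.frame with columns `sample_id`, `target_id`,
#'   `replicate_index` (1--3), `cq` (numeric, `NA` = no amplification),
#'   `plate_id`, `run_id`, `well_role` (one of SAMPLE, NTC, NRT, IC).
#' @param samples data.frame with columns `sample_id`, `group`,
#'   `is_calibrator`, `is_excluded`, `exclusion_reason`.
#' @param max_cycles cycling program length; present Cq values must lie in
#'   (0, `max_cycles`]. Default 40.
#' @return An object of class `cq_dataset`: a list with elements
#'   `measurements`, `samples`, `max_cycles`.
#' @export
cq_dataset <- function(measurements, samples, max_cycles = 40L) {
  measurements <- as.data.frame(measurements)
  samples <- as.data.frame(samples)

  miss <- setdiff(CQ_COLUMNS, names(measurements))
  if (length(miss) > 0L) {
    stop_schema("Cq table is missing required column(s): ",
                paste(miss, collapse = ", "))
  }
  miss <- setdiff(META_COLUMNS, names(samples))
  if (length(miss) > 0L) {
    stop_schema("metadata table is missing required column(s): ",
                paste(miss, collapse = ", "))
  }

  measurements$cq <- as.numeric(measurements$cq)
  measurements$replicate_index <- as.integer(measurements$replicate_index)
  for (col in c("sample_id", "target_id", "plate_id", "run_id", "well_role")) {
    measurements[[col]] <- as.character(measurements[[col]])
  }

  bad_role <- !measurements$well_role %in% WELL_ROLES
  if (any(bad_role)) {
    stop_schema("invalid well_role at row(s) ",
                paste(head(which(bad_role), 5L), collapse = ", "),
                "; must be one of ", paste(WELL_ROLES, collapse = "/"))
  }

  present <- !is.na(measurements$cq)
  out_of_range <- present &
    (measurements$cq <= 0 | measurements$cq > max_cycles |
       !is.finite(measurements$cq))
  if (any(out_of_range)) {
    stop_range("cq outside (0, ", max_cycles, "] at row(s) ",
               paste(head(which(out_of_range), 5L), collapse = ", "))
  }

  key <- paste(measurements$sample_id, measurements$target_id,
               measurements$replicate_index, measurements$plate_id,
               measurements$well_role, sep = "\r")
  if (anyDuplicated(key)) {
    stop_integrity("duplicate well key (sample, target, replicate, plate, ",
                   "role) at row(s) ",
                   paste(head(which(duplicated(key)), 5L), collapse = ", "))
  }

  if (anyDuplicated(samples$sample_id)) {
    stop_integrity("duplicate sample_id in metadata: ",
                   paste(unique(samples$sample_id[
                     duplicated(samples$sample_id)]), collapse = ", "))
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$group <- as.character(samples$group)
  samples$is_calibrator <- as_flag(samples$is_calibrator)
  samples$is_excluded <- as_flag(samples$is_excluded)
  samples$exclusion_reason <- as.character(samples$exclusion_reason)
  samples$exclusion_reason[is.na(samples$exclusion_reason)] <- ""

  bad_group <- !samples$group %in% SUBTYPE_GROUPS
  if (any(bad_group)) {
    stop_schema("unknown group label(s): ",
                paste(unique(samples$group[bad_group]), collapse = ", "))
  }
  bad_cal <- samples$is_calibrator & (samples$group != "N" | samples$is_excluded)
  if (any(bad_cal)) {
    stop_integrity("calibrator sample(s) must have group N and not be ",
                   "excluded: ",
                   paste(samples$sample_id[bad_cal], collapse = ", "))
  }

  needs_meta <- measurements$well_role %in% c("SAMPLE", "NRT", "IC")
  unknown <- setdiff(unique(measurements$sample_id[needs_meta]),
                     samples$sample_id)
  if (length(unknown) > 0L) {
    stop_integrity("measurement references sample_id(s) absent from ",
                   "metadata: ", paste(unknown, collapse = ", "))
  }

  is_sample <- measurements$well_role == "SAMPLE"
  if (any(is_sample)) {
    rk <- paste(measurements$sample_id[is_sample],
                measurements$target_id[is_sample],
                measurements$plate_id[is_sample], sep = "\r")
    n_rep <- table(rk)
    if (any(n_rep > 3L)) {
      stop_integrity("more than 3 replicates for sample x target x plate: ",
                     gsub("\r", " / ", names(n_rep)[n_rep > 3L][1L]))
    }
  }

  structure(list(measurements = measurements, samples = samples,
                 max_cycles = as.integer(max_cycles)),
            class = "cq_dataset")
}

#' @export
print.cq_dataset <- function(x, ...) {
  m <- x$measurements
  cat("<cq_dataset> ", nrow(m), " wells: ",
      sum(m$well_role == "SAMPLE"), " sample, ",
      sum(m$well_role != "SAMPLE"), " control; ",
      length(unique(m$target_id[m$well_role == "SAMPLE"])), " targets x ",
      nrow(x$samples), " samples; max_cycles = ", x$max_cycles, "\n",
      sep = "")
  invisible(x)
}

#' Read a long-format Cq table and its sample metadata
#'
#' Expects the canonical long layout, one well per row, with header
#' `sample_id,target_id,replicate_index,cq,plate_id,run_id,well_role` and a
#' metadata file `sample_id,group,is_calibrator,is_excluded,exclusion_reason`.
#' An empty `cq` field or the literal `NA` encodes no amplification. Decimal
#' separator is `.`; files are UTF-8 with a mandatory header row.
#'
#' @param path path to the Cq CSV.
#' @param metadata_path path to the sample-metadata CSV.
#' @param max_cycles cycle count used for Cq range validation.
#' @return A validated [cq_dataset()].
#' @export
read_cq_table <- function(path, metadata_path, max_cycles = 40L) {
  for (p in c(path, metadata_path)) {
    if (!file.exists(p)) stop_io("file not found: ", p)
  }
  meas <- utils::read.csv(path, colClasses = "character",
                          na.strings = character(), encoding = "UTF-8")
  meta <- utils::read.csv(metadata_path, colClasses = "character",
                          na.strings = character(), encoding = "UTF-8")
  miss <- setdiff(CQ_COLUMNS, names(meas))
  if (length(miss) > 0L) {
    stop_schema("Cq table ", path, " is missing required column(s): ",
                paste(miss, collapse = ", "))
  }
  meas$cq[meas$cq %in% c("", "NA")] <- NA_character_
  suppressWarnings(cq_num <- as.numeric(meas$cq))
  bad <- is.na(cq_num) & !is.na(meas$cq)
  if (any(bad)) {
    stop_range("non-numeric cq at row(s) ",
               paste(head(which(bad), 5L), collapse = ", "))
  }
  meas$cq <- cq_num
  cq_dataset(meas, meta, max_cycles = max_cycles)
}

#' Write a result table to CSV, TSV or JSON
#'
#' Applies the package rounding policy at write time only: fold-change and
#' log2 fold-change columns are written with 2 decimals
#' (round-half-away-from-zero, matching how instrument software and
#' spreadsheets print), p-value columns with 3 decimals alongside a
#' full-precision companion column `<col>_full`. All other numeric columns
#' are written at full precision. JSON output is a single object with a
#' `records` array.
#'
#' @param records data.frame of results (may be empty only if
#'   `allow_empty = TRUE`).
#' @param path output file path.
#' @param format one of "CSV", "TSV", "JSON".
#' @param allow_empty permit writing an empty table.
#' @return Invisibly, the formatted data.frame that was written.
#' @export
write_table <- function(records, path, format = c("CSV", "TSV", "JSON"),
                        allow_empty = FALSE) {
  format <- match.arg(toupper(format), c("CSV", "TSV", "JSON"))
  records <- as.data.frame(records)
  if (nrow(records) == 0L && !allow_empty) {
    stop_io("refusing to write empty table to ", path,
            " (set allow_empty = TRUE)")
  }
  out <- records
  fc_cols <- grep("^(fold_change|fc|log2fc|log2_fc)$", names(out),
                  ignore.case = TRUE, value = TRUE)
  p_cols <- grep("^(p|p_raw|p_adj|p_value)$", names(out),
                 ignore.case = TRUE, value = TRUE)
  for (col in fc_cols) {
    out[[col]] <- format_fixed(round_half_away(out[[col]], 2L), 2L)
  }
  for (col in p_cols) {
    out[[paste0(col, "_full")]] <- records[[col]]
    out[[col]] <- format_fixed(round_half_away(out[[col]], 3L), 3L)
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    switch(format,
      CSV = utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
      TSV = utils::write.table(out, path, sep = "\t", row.names = FALSE,
                               quote = FALSE),
      JSON = writeLines(jsonlite::toJSON(list(records = out),
                                         dataframe = "rows", digits = NA,
                                         na = "null", auto_unbox = TRUE),
                        path))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_io("cannot write ", path, ": ", conditionMessage(ok))
  invisible(out)
}

#' Write a Cq dataset back to its two canonical CSV files
#'
#' Inverse of [read_cq_table()]: values round-trip field-by-field, with
#' absent Cq written as an empty field.
#'
#' @param dataset a [cq_dataset()].
#' @param path,metadata_path output paths for the Cq and metadata CSVs.
#' @export
write_cq_table <- function(dataset, path, metadata_path) {
  stopifnot(inherits(dataset, "cq_dataset"))
  m <- dataset$measurements
  m$cq <- ifelse(is.na(m$cq), "", format(m$cq, trim = TRUE, digits = 15))
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$samples, metadata_path, row.names = FALSE,
                   quote = FALSE)
  invisible(dataset)
}

# --- typed error helpers -----------------------------------------------------

stop_typed <- function(class, ...) {
  stop(structure(class = c(class, "relqpcr_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1L))))
}
stop_schema    <- function(...) stop_typed("relqpcr_schema_error", ...)
stop_integrity <- function(...) stop_typed("relqpcr_integrity_error", ...)
stop_range     <- function(...) stop_typed("relqpcr_range_error", ...)
stop_io        <- function(...) stop_typed("relqpcr_io_error", ...)
stop_argument  <- function(...) stop_typed("relqpcr_argument_error", ...)
stop_missing   <- function(...) stop_typed("relqpcr_missing_value_error", ...)
stop_domain    <- function(...) stop_typed("relqpcr_domain_error", ...)

as_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

# round half away from zero at `digits` decimals (printed-table convention;
# base round() uses banker's rounding)
round_half_away <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

format_fixed <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}
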