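# Reading, validating and normalizing longitudinal first-diagnosis tables.

MANDATORY_COLS <- c("patient_id", "disease", "first_dx_date",
                    "age", "gender", "ethnicity")

#' Construct a validated EMR dataset from a data frame of first diagnoses
#'
#' Normalizes a table of first-diagnosis records into the canonical container
#' used by the rest of the pipeline. One row is one patient's first diagnosis
#' of one disease. Duplicate (patient, disease) rows are collapsed to the
#' earliest date; rows with unparseable dates, missing mandatory fields or
#' negative ages are dropped and counted in the validation report.
#'
#' @param records data frame with at least the columns `patient_id`,
#'   `disease`, `first_dx_date` (`Date` or string), `age`, `gender`,
#'   `ethnicity`. Any further columns are carried along as extra covariates.
#' @param date_format format string used when `first_dx_date` is character;
#'   default ISO-8601.
#' @return An object of class `emr_dataset`: a list with elements
#'   `records` (normalized data frame, sorted by patient then date, with an
#'   integer `day` column counting days since 1970-01-01), `diseases`,
#'   `patients`, `covariate_names` and a validation `report`.
#' @export
as_emr_dataset <- function(records, date_format = "%Y-%m-%d") {
  if (!is.data.frame(records)) dcn_stop("dcn_bad_input", "records must be a data frame")
  missing <- setdiff(MANDATORY_COLS, names(records))
  if (length(missing) > 0L) {
    dcn_stop("dcn_missing_column",
             sprintf("missing mandatory column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(records) == 0L) dcn_stop("dcn_empty_input", "no diagnosis records")

  covariate_names <- setdiff(names(records), MANDATORY_COLS)
  dt <- data.table::as.data.table(records)

  n_read <- nrow(dt)
  trim <- function(x) trimws(as.character(x))
  dt[, `:=`(patient_id = trim(patient_id), disease = trim(disease),
            gender = trim(gender), ethnicity = trim(ethnicity))]
  if (inherits(dt$first_dx_date, "Date")) {
    dte <- dt$first_dx_date
  } else {
    dte <- as.Date(trim(dt$first_dx_date), format = date_format)
  }
  dt[, first_dx_date := dte]
  dt[, age := suppressWarnings(as.numeric(age))]

  bad_date <- is.na(dt$first_dx_date)
  bad_field <- (is.na(dt$patient_id) | dt$patient_id == "" |
                is.na(dt$disease) | dt$disease == "" |
                is.na(dt$gender) | dt$gender == "" |
                is.na(dt$ethnicity) | dt$ethnicity == "" |
                is.na(dt$age) | dt$age < 0)
  n_bad_date <- sum(bad_date)
  n_bad_field <- sum(bad_field & !bad_date)
  dt <- dt[!(bad_date | bad_field)]
  if (nrow(dt) == 0L) dcn_stop("dcn_empty_input", "no valid diagnosis records after validation")

  dt[, day := as.integer(unclass(first_dx_date))]
  data.table::setorder(dt, patient_id, day, disease)
  dup <- duplicated(dt, by = c("patient_id", "disease"))
  n_dup <- sum(dup)
  dt <- dt[!dup]

  n_missing_cov <- if (length(covariate_names) > 0L) {
    sum(vapply(covariate_names, function(cn) sum(is.na(dt[[cn]])), 0L))
  } else 0L

  out <- list(
    records = data.table::setDF(dt[, c(MANDATORY_COLS, "day", covariate_names), with = FALSE]),
    diseases = sort(unique(dt$disease)),
    patients = sort(unique(dt$patient_id)),
    covariate_names = covariate_names,
    report = list(
      n_rows_read = n_read,
      n_dropped_bad_date = n_bad_date,
      n_dropped_missing_field = n_bad_field,
      n_duplicates_collapsed = n_dup,
      n_missing_covariate_values = n_missing_cov,
      n_records = nrow(dt)
    )
  )
  class(out) <- "emr_dataset"
  out
}

#' Read a longitudinal first-diagnosis table from CSV/TSV
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map optional named character vector mapping the canonical
#'   names `patient_id`, `disease`, `first_dx_date`, `age`, `gender`,
#'   `ethnicity` to the column names used in the file. Unmapped columns are
#'   kept as extra covariates.
#' @param date_format date format of the diagnosis-date column
#'   (default ISO-8601 `YYYY-MM-DD`).
#' @param sep field separator; by default inferred from the file extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @return An [as_emr_dataset()] object; its `report` element counts dropped
#'   and collapsed rows.
#' @export
read_emr_table <- function(path, column_map = NULL, date_format = "%Y-%m-%d",
                           sep = NULL) {
  if (!file.exists(path)) dcn_stop("dcn_missing_file", sprintf("file not found: %s", path))
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  dt <- tryCatch(
    data.table::fread(path, sep = sep, header = TRUE, data.table = TRUE,
                      colClasses = list(character = 1L)),
    error = function(e) dcn_stop("dcn_empty_input", sprintf("cannot read %s: %s", path, conditionMessage(e)))
  )
  if (nrow(dt) == 0L) dcn_stop("dcn_empty_input", sprintf("empty input file: %s", path))

  if (!is.null(column_map)) {
    unknown <- setdiff(unname(column_map), names(dt))
    if (length(unknown) > 0L) {
      dcn_stop("dcn_missing_column",
               sprintf("column_map refers to absent column(s): %s", paste(unknown, collapse = ", ")))
    }
    data.table::setnames(dt, unname(column_map), names(column_map))
  }
  as_emr_dataset(data.table::setDF(dt), date_format = date_format)
}

#' Write an EMR dataset back to CSV
#'
#' Inverse of [read_emr_table()] for the canonical column layout; dates are
#' written in ISO-8601 so a round trip reproduces the records exactly.
#'
#' @param ds an `emr_dataset`.
#' @param path output file path.
#' @export
write_emr_table <- function(ds, path) {
  stopifnot(inherits(ds, "emr_dataset"))
  out <- ds$records[, c(MANDATORY_COLS, ds$covariate_names)]
  out$first_dx_date <- format(out$first_dx_date, "%Y-%m-%d")
  data.table::fwrite(out, path)
  invisible(path)
}

#' Enumerate candidate ordered disease pairs
#'
#' All ordered pairs (X, Y), X != Y, whose exposure disease X has at least
#' `min_exposed` diagnosed patients. Both directions of a pair are candidates:
#' X -> Y and Y -> X are tested separately.
#'
#' @param ds an `emr_dataset`.
#' @param min_exposed minimum number of patients diagnosed with X for the
#'   pair X -> Y to be considered.
#' @return data frame with columns `from`, `to`, ordered lexicographically.
#' @export
enumerate_disease_pairs <- function(ds, min_exposed = 1L) {
  stopifnot(inherits(ds, "emr_dataset"))
  if (min_exposed < 1L) dcn_stop("dcn_bad_input", "min_exposed must be >= 1")
  counts <- table(ds$records$disease)
  eligible <- sort(names(counts)[counts >= min_exposed])
  all_d <- ds$diseases
  if (length(all_d) < 2L || length(eligible) == 0L) {
    return(data.frame(from = character(0), to = character(0)))
  }
  grid <- expand.grid(to = all_d, from = eligible,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, c("from", "to")]
  grid <- grid[order(grid$from, grid$to), ]
  rownames(grid) <- NULL
  grid
}

#' @export
print.emr_dataset <- function(x, ...) {
  cat(sprintf("<emr_dataset> %d first-diagnosis records, %d patients, %d diseases\n",
              nrow(x$records), length(x$patients), length(x$diseases)))
  if (length(x$covariate_names) > 0L)
    cat("  extra covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  r <- x$report
  cat(sprintf("  validation: %d rows read, %d bad dates, %d incomplete, %d duplicates collapsed\n",
              r$n_rows_read, r$n_dropped_bad_date, r$n_dropped_missing_field,
              r$n_duplicates_collapsed))
  invisible(x)
}

# --- internal patient-level views -----------------------------------------

# One row per patient: demographics from the earliest record, a birth-day
# equivalent derived from (age, date) of that record so age can be evaluated
# at any index date, the last recorded day (censoring proxy for the end of
# the patient's record), and patient-level extra covariates (first non-NA
# record value).
patient_table <- function(ds) {
  dt <- data.table::as.data.table(ds$records)
  data.table::setorder(dt, patient_id, day)
  first <- dt[, .SD[1L], by = patient_id]
  pat <- first[, .(patient_id, gender, ethnicity,
                   birth_day = day - age * DAYS_PER_YEAR)]
  pat$last_day <- dt[, max(day), by = patient_id]$V1
  for (cn in ds$covariate_names) {
    pat[[cn]] <- dt[, {
      v <- .SD[[cn]]
      v <- v[!is.na(v)]
      if (length(v) > 0L) v[1L] else .SD[[cn]][1L]
    }, by = patient_id, .SDcols = cn]$V1
  }
  data.table::setDF(pat)
}

# First-diagnosis day of `disease` for every patient, +Inf when never
# diagnosed; indexed by position in `patients`.
first_dx_days <- function(ds, patients, disease) {
  rec <- ds$records[ds$records$disease == disease, c("patient_id", "day")]
  out <- rep(Inf, length(patients))
  out[match(rec$patient_id, patients)] <- rec$day
  out
}
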