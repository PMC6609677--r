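#' Paired per-lesion measurement tables
#'
#' A paired table holds one row per lesion and session (`"test"` /
#' `"retest"`) with the tumor blood flow measures analysed by the package:
#' the one-tissue-compartment influx constant `k1`
#' (mL min^-1 (mL tissue)^-1; the printed numbers are treated as unitless by
#' all statistics, which are log-ratio based) and the static `suv_max`,
#' `suv_mean`, `suv_peak`.  Every `(patient_id, lesion_id)` must appear with
#' exactly one `test` and one `retest` row, all measurement values must be
#' positive, and `tumor_volume_cm3` / `voi_source` are optional descriptive
#' columns (`voi_source` one of `psma_suv6`, `psma_pct30`, `mri_manual`).
#'
#' @param records a data frame with columns `patient_id`, `lesion_id`,
#'   `session`, `k1`, `suv_max`, `suv_mean`, `suv_peak` and optionally
#'   `tumor_volume_cm3`, `voi_source`.
#' @return A validated data frame of class `"paired_table"`, rows ordered by
#'   `(patient_id, lesion_id, session)` with `test` before `retest`.
#' @seealso [read_measurements()], [extract_pairs()], [table1_fixture()]
#' @export
paired_table <- function(records) {
  need <- c("patient_id", "lesion_id", "session", .measures)
  miss <- setdiff(need, names(records))
  if (length(miss))
    .stop_validation("paired table lacks column(s): %s", paste(miss, collapse = ", "))
  records$patient_id <- as.character(records$patient_id)
  records$lesion_id <- as.character(records$lesion_id)
  records$session <- as.character(records$session)
  if (!"tumor_volume_cm3" %in% names(records)) records$tumor_volume_cm3 <- NA_real_
  records$tumor_volume_cm3 <- as.numeric(records$tumor_volume_cm3)
  if (any(!is.na(records$tumor_volume_cm3) & records$tumor_volume_cm3 <= 0))
    .stop_validation("non-positive tumor volume")
  if (!"voi_source" %in% names(records)) records$voi_source <- NA_character_
  bad_src <- !is.na(records$voi_source) &
    !records$voi_source %in% c("psma_suv6", "psma_pct30", "mri_manual")
  if (any(bad_src))
    .stop_validation("unknown voi_source: %s", records$voi_source[bad_src][1])
  if (nrow(records)) {
    if (!all(records$session %in% c("test", "retest")))
      .stop_validation("session must be 'test' or 'retest'")
    for (m in .measures) {
      v <- records[[m]]
      if (!is.numeric(v) || any(!is.finite(v)))
        .stop_validation("non-numeric or non-finite values in column '%s'", m)
      if (any(v <= 0))
        .stop_validation("non-positive value in column '%s'", m)
    }
    key <- paste(records$patient_id, records$lesion_id, records$session, sep = "\r")
    if (anyDuplicated(key))
      .stop_validation("duplicate (patient_id, lesion_id, session) rows")
    lk <- paste(records$patient_id, records$lesion_id, sep = "\r")
    tab <- table(lk, records$session)
    incomplete <- rownames(tab)[rowSums(tab) != 2 | apply(tab, 1, max) != 1]
    if (length(incomplete))
      .stop_validation("lesion(s) without exactly one test and one retest row: %s",
                       paste(gsub("\r", "/", incomplete), collapse = ", "))
  }
  records <- records[.row_order(records),
                     c("patient_id", "lesion_id", "session", "tumor_volume_cm3",
                       .measures, "voi_source")]
  rownames(records) <- NULL
  structure(records, class = c("paired_table", "data.frame"))
}

.measures <- c("k1", "suv_max", "suv_mean", "suv_peak")

# sort lesions numerically when every id is numeric-like, else lexically;
# test rows before retest rows within a lesion
.row_order <- function(records) {
  key <- function(x) {
    xn <- suppressWarnings(as.numeric(x))
    if (!anyNA(xn)) xn else x
  }
  order(key(records$patient_id), key(records$lesion_id),
        match(records$session, c("test", "retest")))
}

#' Number of lesions in a paired table
#' @param table a [paired_table].
#' @return Integer lesion-pair count (`nrow(table) / 2`).
#' @export
n_lesions <- function(table) {
  stopifnot(inherits(table, "paired_table"))
  nrow(table) %/% 2L
}

#' @export
print.paired_table <- function(x, ...) {
  cat(sprintf("Paired test-retest table: %d lesions (%d rows)\n", n_lesions(x), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read and write paired measurement tables
#'
#' Tables are comma-separated with a period decimal separator and one header
#' row naming at least `patient_id,lesion_id,session,k1,suv_max,suv_mean,`
#' `suv_peak`.  Reading validates pairing and positivity; writing round-trips
#' exactly (`read_measurements(write_measurements(t)) == t`).
#'
#' @param path file path.
#' @return `read_measurements()` returns a [paired_table];
#'   `write_measurements()` invisibly returns `path`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) .stop_validation("measurement file not found: %s", path)
  df <- utils::read.csv(path, colClasses = c(patient_id = "character",
                                             lesion_id = "character"))
  paired_table(df)
}

#' @param table a [paired_table].
#' @rdname read_measurements
#' @export
write_measurements <- function(table, path) {
  stopifnot(inherits(table, "paired_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' The bundled per-lesion test-retest fixture
#'
#' Per-lesion tumor blood flow values (K1 and SUV metrics) for 11 primary
#' prostate lesions in 10 patients, each scanned twice within a week; VOIs
#' from a fixed PSMA SUV 6 threshold where PSMA PET was available, manual
#' MRI contours otherwise.  This table drives the repeatability and
#' sample-size analyses.
#'
#' @return A [paired_table] with 11 lesion pairs (22 rows).
#' @export
#' @examples
#' tab <- table1_fixture()
#' n_lesions(tab)
table1_fixture <- function() {
  read_measurements(system.file("extdata", "table1.csv", package = "rbflow",
                                mustWork = TRUE))
}

#' Extract ordered (test, retest) pairs for one measure
#'
#' @param table a [paired_table].
#' @param measure one of `"k1"`, `"suv_max"`, `"suv_mean"`, `"suv_peak"`.
#' @return A data frame with one row per lesion, ordered by
#'   `(patient_id, lesion_id)`, and columns `patient_id`, `lesion_id`,
#'   `test`, `retest`.
#' @export
#' @examples
#' extract_pairs(table1_fixture(), "k1")
extract_pairs <- function(table, measure = c("k1", "suv_max", "suv_mean", "suv_peak")) {
  stopifnot(inherits(table, "paired_table"))
  measure <- match.arg(measure)
  if (nrow(table) == 0L)
    return(data.frame(patient_id = character(), lesion_id = character(),
                      test = numeric(), retest = numeric()))
  v <- table[[measure]]
  if (any(!is.finite(v)))
    .stop_validation("measure '%s' missing for some lesion", measure)
  te <- table[table$session == "test", ]
  re <- table[table$session == "retest", ]
  # constructor ordering guarantees aligned lesion order within session
  stopifnot(identical(te$patient_id, re$patient_id),
            identical(te$lesion_id, re$lesion_id))
  data.frame(patient_id = te$patient_id, lesion_id = te$lesion_id,
             test = te[[measure]], retest = re[[measure]])
}
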