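# Atomic writers: write to a temp file in the target directory, then rename.
write_json_atomic <- function(obj, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json.tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  # I(17) significant digits: doubles round-trip bit-exactly through decimal
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  file.rename(tmp, path)
  invisible(path)
}

write_table_atomic <- function(df, path, sep = ",") {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write.table(df, tmp, sep = sep, quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write an event table to CSV
#'
#' Columns: `cell_id`, `donor_id`, then the 10 panel channels in canonical
#' order.
#'
#' @param x A `bm_sample` or an event data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_event_csv <- function(x, path) {
  if (inherits(x, "bm_sample")) x <- x$events
  cols <- c("cell_id", "donor_id", BCP_MARKERS)
  missing <- setdiff(cols, names(x))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  write_table_atomic(x[, cols], path)
}

#' Read an event table from CSV
#'
#' Validates that all 10 panel channels are present and complete.
#'
#' @param path CSV path.
#' @return Event data frame.
#' @export
read_event_csv <- function(path) {
  x <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(BCP_MARKERS, names(x))
  if (length(missing))
    stop("event file ", basename(path), " is missing channel(s): ",
         paste(missing, collapse = ", "))
  if (anyNA(x[, BCP_MARKERS]))
    stop("event file ", basename(path), " contains missing intensities")
  x
}

#' Write a threshold set as JSON
#' @param thresholds A `threshold_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
thresholds_write <- function(thresholds, path) {
  write_json_atomic(list(schema_version = BCPFLOW_SCHEMA,
                         thresholds = thresholds), path)
}

#' Read a threshold set written by [thresholds_write()]
#' @param path JSON path.
#' @return A `threshold_set`.
#' @export
thresholds_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema_version, BCPFLOW_SCHEMA))
    stop("unsupported schema version: ", obj$schema_version)
  structure(obj$thresholds, class = c("threshold_set", "data.frame"))
}

#' Write a deviation report as JSON
#' @param report A `deviation_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
deviation_write <- function(report, path) {
  write_json_atomic(unclass(report), path)
}

#' Read a deviation report written by [deviation_write()]
#' @param path JSON path.
#' @return A `deviation_report`.
#' @export
deviation_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema_version, BCPFLOW_SCHEMA))
    stop("unsupported schema version: ", obj$schema_version)
  obj$inside_own_contour <- unlist(obj$inside_own_contour)
  structure(obj, class = "deviation_report")
}

#' Write repertoire statistics as JSON
#' @param stats A `repertoire_stats` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
stats_write <- function(stats, path) {
  obj <- list(schema_version = BCPFLOW_SCHEMA,
              summary = stats$summary,
              charge_proportions =
                cbind(compartment = rownames(stats$charge_proportions),
                      as.data.frame(stats$charge_proportions,
                                    check.names = FALSE)),
              cdr3_aa_lengths = stats$cdr3_aa_lengths)
  write_json_atomic(obj, path)
}

#' Read repertoire statistics written by [stats_write()]
#' @param path JSON path.
#' @return A `repertoire_stats` object.
#' @export
stats_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema_version, BCPFLOW_SCHEMA))
    stop("unsupported schema version: ", obj$schema_version)
  ch <- as.matrix(obj$charge_proportions[, -1, drop = FALSE])
  rownames(ch) <- obj$charge_proportions$compartment
  structure(list(summary = obj$summary,
                 cdr3_aa_lengths = obj$cdr3_aa_lengths,
                 charge_proportions = ch,
                 schema_version = obj$schema_version),
            class = "repertoire_stats")
}
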