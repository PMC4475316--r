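#' Read an ECG record from a delimited text file
#'
#' One column per lead, one row per time sample, values in digital (ADC
#' count) units. Non-numeric or missing cells are rejected rather than
#' imputed.
#'
#' @param path path to the file.
#' @param sampling_rate sampling frequency in Hz.
#' @param lead_names lead names in column order; required unless
#'   `header = TRUE`, in which case names are read from the first row.
#' @param header whether the first row holds lead names.
#' @param sep field delimiter.
#' @param record_id record identifier; defaults to the file base name.
#' @return An [ecg_record()].
#' @export
read_csv_record <- function(path, sampling_rate, lead_names = NULL,
                            header = FALSE, sep = ",",
                            record_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path))
    stop_input("read_csv_record: file not found: %s", path)
  df <- tryCatch(
    utils::read.table(path, header = header, sep = sep, comment.char = "#",
                      colClasses = "numeric", fill = FALSE),
    error = function(e) stop_input("read_csv_record: %s: %s", path, conditionMessage(e)))
  if (anyNA(df))
    stop_input("read_csv_record: %s contains non-numeric or missing samples", path)
  if (header) {
    lead_names <- colnames(df)
  } else if (is.null(lead_names)) {
    stop_input("read_csv_record: lead_names are required when the file has no header row")
  }
  ecg_record(as.matrix(df), sampling_rate, lead_names, record_id = record_id)
}

#' Write an ECG record as CSV
#'
#' @param record an [ecg_record()].
#' @param path output path.
#' @param header write the lead names as a header row.
#' @return Invisibly, `path`.
#' @export
write_csv_record <- function(record, path, header = TRUE) {
  stopifnot(inherits(record, "ecg_record"))
  utils::write.table(record$samples, path, sep = ",", row.names = FALSE,
                     col.names = header, quote = FALSE)
  invisible(path)
}
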