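#' Multi-lead ECG record
#'
#' Container for a digitized multi-lead ECG. Samples are stored as raw
#' digital amplitudes (ADC counts): downstream covariance analysis operates
#' on unscaled digital units, and no gain conversion to millivolts is
#' applied anywhere in the pipeline.
#'
#' @param samples numeric matrix, one column per lead, K rows of time samples
#'   (K >= 2); or a data frame coercible to such a matrix.
#' @param sampling_rate sampling frequency in Hz (> 0); conventional
#'   diagnostic ECG machines use 500 Hz.
#' @param lead_names character vector of unique lead names, one per column.
#' @param record_id identifier used in feature/label tables.
#' @return An object of class `ecg_record` with fields `record_id`,
#'   `sampling_rate`, `lead_names`, `samples` (K x L matrix) and `duration`
#'   in seconds.
#' @examples
#' x <- matrix(rnorm(1000), ncol = 2)
#' rec <- ecg_record(x, 500, c("I", "II"))
#' @export
ecg_record <- function(samples, sampling_rate, lead_names, record_id = "record") {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 2L)
    stop_input("ecg_record: need at least 2 samples per lead, got %d", nrow(samples))
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop_input("ecg_record: sampling_rate must be a single positive number")
  lead_names <- as.character(lead_names)
  if (length(lead_names) != ncol(samples))
    stop_input("ecg_record: %d lead names for %d signal columns",
               length(lead_names), ncol(samples))
  if (anyDuplicated(lead_names))
    stop_input("ecg_record: duplicated lead names: %s",
               paste(unique(lead_names[duplicated(lead_names)]), collapse = ", "))
  if (anyNA(samples))
    stop_input("ecg_record: samples contain missing values")
  colnames(samples) <- lead_names
  structure(
    list(record_id = as.character(record_id),
         sampling_rate = as.numeric(sampling_rate),
         lead_names = lead_names,
         samples = samples,
         duration = nrow(samples) / sampling_rate),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d leads x %d samples @ %g Hz (%.3g s)\n",
              x$record_id, length(x$lead_names), nrow(x$samples),
              x$sampling_rate, x$duration))
  cat("  leads:", paste(x$lead_names, collapse = " "), "\n")
  invisible(x)
}

# Canonical analysis leads: the 8 linearly independent leads of the standard
# 12-lead ECG. III, aVR, aVL and aVF are linear combinations of these and
# carry no extra information for quality analysis.
CANONICAL_LEADS <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

#' Select the 8 analysis leads as a lead matrix
#'
#' Extracts leads I, II, V1-V6 from a record (case-insensitive name match)
#' into an 8 x K matrix in that canonical row order; any additional leads
#' (III, augmented limb leads, ...) are discarded. The result is uncentered;
#' see [center_leads()].
#'
#' @param record an [ecg_record()].
#' @return An 8 x K numeric matrix of class `lead_matrix`, rows named
#'   I, II, V1...V6, with attribute `centered = FALSE`.
#' @export
select_leads <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  idx <- match(toupper(CANONICAL_LEADS), toupper(record$lead_names))
  if (anyNA(idx))
    stop_input("select_leads: record '%s' is missing required lead(s): %s",
               record$record_id, paste(CANONICAL_LEADS[is.na(idx)], collapse = ", "))
  m <- t(record$samples[, idx, drop = FALSE])
  rownames(m) <- CANONICAL_LEADS
  structure(m, class = c("lead_matrix", "matrix"), centered = FALSE)
}

#' Remove each lead's temporal mean
#'
#' Subtracts from every row its own mean, the only preprocessing applied
#' before covariance estimation (no filtering, scaling or normalization).
#'
#' @param matrix a `lead_matrix` (or any numeric matrix with leads in rows).
#' @return The matrix with zero-mean rows and attribute `centered = TRUE`.
#' @export
center_leads <- function(matrix) {
  if (ncol(matrix) < 2L)
    stop_input("center_leads: need at least 2 time samples")
  out <- matrix - rowMeans(matrix)
  structure(out, class = c("lead_matrix", "matrix"), centered = TRUE)
}
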