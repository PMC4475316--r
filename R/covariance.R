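#' Sample covariance of the lead matrix
#'
#' Computes the sample covariance `R = (1/K) X X'` of the 8 x K lead matrix.
#' The divisor is K, not K - 1 (the difference is negligible at K = 5000 but
#' the biased form is the definition used throughout). The caller is
#' expected to have centered the rows first ([center_leads()]); no centering
#' is applied here.
#'
#' @param matrix a `lead_matrix` or numeric matrix with leads in rows.
#' @return An L x L matrix of class `cov_matrix`, in squared ADC-count units.
#' @export
estimate_covariance <- function(matrix) {
  k <- ncol(matrix)
  if (is.null(k) || k < 1L)
    stop_input("estimate_covariance: empty lead matrix")
  structure(tcrossprod(unclass(matrix)) / k, class = c("cov_matrix", "matrix"))
}

#' Eigenvalue spectrum of a lead covariance matrix
#'
#' Eigenvalues of the symmetric covariance, sorted descending. Tiny negative
#' values produced by floating point (within `1e-12 * trace`) are clamped to
#' zero; a matrix that is asymmetric or indefinite beyond tolerance is
#' rejected.
#'
#' @param cov a symmetric positive semi-definite matrix.
#' @return Numeric vector `lambda_1 >= ... >= lambda_L >= 0` of class
#'   `eigen_spectrum` (linear scale, squared ADC-count units).
#' @export
eigen_spectrum <- function(cov) {
  cov <- unclass(as.matrix(cov))
  scale <- max(abs(cov))
  if (scale > 0 && max(abs(cov - t(cov))) > 1e-9 * scale)
    stop_input("eigen_spectrum: matrix is not symmetric within tolerance")
  lam <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-12 * max(sum(diag(cov)), scale)
  if (any(lam < -max(tol, 1e-9 * scale)))
    stop_input("eigen_spectrum: matrix is not positive semi-definite")
  lam[lam < 0] <- 0
  structure(sort(lam, decreasing = TRUE), class = "eigen_spectrum")
}

#' Log10 view of an eigenvalue spectrum
#'
#' Eigenvalues at or below 1e-12 (numerically zero) map to -12, so that
#' rank-deficient spectra have a finite log representation; this floor sits
#' far below the smallest thresholds used by the classifiers.
#'
#' @param spectrum an [eigen_spectrum()] or numeric vector of eigenvalues.
#' @return Numeric vector of log10 eigenvalues.
#' @export
log10_lambdas <- function(spectrum) {
  lam <- as.numeric(spectrum)
  out <- rep(-12, length(lam))
  pos <- lam > 1e-12
  out[pos] <- log10(lam[pos])
  out
}

#' Full feature extraction for one record
#'
#' Composition select leads -> center -> covariance -> eigenvalues. Neither
#' the signals nor the eigenvalues are scaled or normalized anywhere, so the
#' spectrum is on the raw digital-amplitude-squared scale the classifier
#' thresholds were learned on.
#'
#' @param record an [ecg_record()] containing leads I, II, V1-V6.
#' @return An [eigen_spectrum()] of length 8.
#' @export
extract_features <- function(record) {
  eigen_spectrum(estimate_covariance(center_leads(select_leads(record))))
}

#' Condition number of the lead covariance
#'
#' `kappa = lambda_1 / lambda_8`: large when one lead is flat or
#' disconnected (rank-deficient covariance), `Inf` when `lambda_8` is
#' exactly zero.
#'
#' @param spectrum an [eigen_spectrum()].
#' @return A single number (possibly `Inf`).
#' @export
condition_number <- function(spectrum) {
  lam <- as.numeric(spectrum)
  l1 <- lam[1L]; l8 <- lam[length(lam)]
  if (l8 == 0) return(Inf)
  l1 / l8
}

#' Feature table for a set of records
#'
#' One row per record: the eight eigenvalues (linear and log10) and the
#' condition number.
#'
#' @param records list of [ecg_record()] objects.
#' @return A data frame with columns `record_id`, `lambda1..lambda8`,
#'   `log10_lambda1..log10_lambda8`, `kappa`.
#' @export
features_table <- function(records) {
  stopifnot(length(records) >= 1L)
  rows <- lapply(records, function(rec) {
    sp <- extract_features(rec)
    out <- c(as.numeric(sp), log10_lambdas(sp), condition_number(sp))
    names(out) <- c(paste0("lambda", 1:8), paste0("log10_lambda", 1:8), "kappa")
    data.frame(record_id = rec$record_id, t(out), check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
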