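# Shared fixtures, built in code at test time.

# A random descending spectrum spanning the log range seen in practice.
random_spectrum <- function() {
  structure(sort(10^stats::runif(8, -2, 8), decreasing = TRUE),
            class = "eigen_spectrum")
}

# Spectrum from prescribed log10 eigenvalues (must be non-increasing).
spectrum_from_log10 <- function(l10) {
  stopifnot(length(l10) == 8, !is.unsorted(rev(l10)))
  structure(10^l10, class = "eigen_spectrum")
}

# A 12-lead integer-valued record (canonical 8 + the derived limb leads).
make_12lead_record <- function(k = 5000, seed = 1, fs = 500) {
  withr_seed <- function(code) { set.seed(seed); code }
  leads <- c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))
  withr_seed({
    x <- matrix(round(rnorm(k * 12, sd = 300)), nrow = k)
    ecg_record(x, fs, leads, record_id = "fix12")
  })
}

# Independent brute-force covariance: R[i,j] = sum_t x_i(t) x_j(t) / K.
brute_force_cov <- function(x) {
  l <- nrow(x); k <- ncol(x)
  out <- matrix(0, l, l)
  for (i in seq_len(l))
    for (j in seq_len(l))
      out[i, j] <- sum(x[i, ] * x[j, ]) / k
  out
}

# Independent eigenvalue oracle: characteristic polynomial coefficients by
# the Faddeev-LeVerrier recursion, roots by polyroot.
charpoly_eigenvalues <- function(a) {
  n <- nrow(a); m <- diag(n); cs <- numeric(n)
  for (k in seq_len(n)) {
    am <- a %*% m
    cs[k] <- -sum(diag(am)) / k
    m <- am + cs[k] * diag(n)
  }
  sort(Re(polyroot(c(rev(cs), 1))), decreasing = TRUE)
}

# Exhaustive depth-1 oracle: best achievable training accuracy over all
# single-threshold splits with optimally labeled leaves.
best_depth1_accuracy <- function(data) {
  x <- as.matrix(data[paste0("log10_lambda", 1:8)])
  y <- data$label
  n <- length(y)
  best <- max(sum(y == "UN"), sum(y == "AC")) / n   # no-split baseline
  for (j in 1:8) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2) next
    for (t in (v[-1] + v[-length(v)]) / 2) {
      left <- x[, j] <= t
      acc <- (max(table(factor(y[left], c("AC", "UN")))) +
              max(table(factor(y[!left], c("AC", "UN"))))) / n
      best <- max(best, acc)
    }
  }
  best
}

# Config for an Acceptable-style draw: clean model plus the equipment
# noise floor that keeps the covariance full rank.
ac_config <- function(seed, ...) {
  synthetic_config(seed = seed,
                   noise = list(noise_event("white", 1:8, power = 9)), ...)
}
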