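# Synthetic 8-lead ECG generator.
#
# Model: x(t) = A s(t) + n(t). The N cardiac sources s(t) are zero-mean,
# mutually orthogonal unit-RMS beat trains (P-, QRS- and T-like
# sum-of-Gaussian templates), A is an 8 x N full-column-rank attenuation
# matrix, and n(t) is built from labeled noise/artifact events. With an
# empty noise list the lead covariance is exactly rank N; contamination
# either collapses the spectrum (flat leads) or inflates it (high-power
# artifacts), the two failure modes the quality classifiers key on.

NOISE_KINDS <- c("white", "powerline", "baseline_wander", "flat_lead",
                 "clipping", "transient_artifact")

#' Describe one noise/artifact contamination event
#'
#' @param kind one of `"white"` (independent Gaussian noise per target
#'   lead), `"powerline"` (coherent mains-frequency sinusoid),
#'   `"baseline_wander"` (coherent low-frequency sinusoid), `"flat_lead"`
#'   (lead overwritten with a constant, as from a disconnected electrode),
#'   `"clipping"` (saturation at the ADC ceiling), `"transient_artifact"`
#'   (independent high-power Gaussian burst in a time window).
#' @param leads target lead indices (1..8).
#' @param power noise variance in squared ADC counts (white, transient).
#' @param amplitude peak amplitude in ADC counts (powerline,
#'   baseline_wander) or saturation ceiling (clipping).
#' @param freq sinusoid frequency in Hz; defaults 50 (powerline, the
#'   common mains frequency) and 0.33 (baseline wander, respiratory range).
#' @param onset,duration transient window in seconds (transient_artifact).
#' @return A `noise_event` object.
#' @export
noise_event <- function(kind, leads = 1:8, power = NULL, amplitude = NULL,
                        freq = NULL, onset = NULL, duration = NULL) {
  kind <- match.arg(kind, NOISE_KINDS)
  leads <- as.integer(leads)
  if (length(leads) < 1L || any(leads < 1L | leads > 8L))
    stop_input("noise_event: target leads must be a subset of 1..8")
  for (p in list(power, amplitude, freq, onset, duration))
    if (!is.null(p) && (!is.numeric(p) || any(p < 0)))
      stop_input("noise_event: parameters must be non-negative numbers")
  if (kind %in% c("white", "transient_artifact") && is.null(power))
    stop_input("noise_event: '%s' requires a power parameter", kind)
  if (kind %in% c("powerline", "baseline_wander") && is.null(amplitude))
    stop_input("noise_event: '%s' requires an amplitude parameter", kind)
  if (is.null(freq)) freq <- switch(kind, powerline = 50, baseline_wander = 0.33, NULL)
  structure(list(kind = kind, leads = leads, power = power,
                 amplitude = amplitude, freq = freq, onset = onset,
                 duration = duration),
            class = "noise_event")
}

#' Configuration of a synthetic 8-lead record
#'
#' Defaults emulate the conventional acquisition setup: 8 leads at 500 Hz
#' for 10 s, digital amplitudes on a 16-bit ADC-count scale. The
#' `amplitude_scale` default (50 counts per unit source, i.e. QRS peaks of
#' a few hundred counts at a nominal 200 counts/mV gain) places the clean
#' leading eigenvalue near log10(lambda_1) = 4, the middle of the
#' Acceptable regime.
#'
#' @param n_sources number N of cardiac sources (1..8; default 3, the
#'   number of dominant eigenvalues expected of a clean record).
#' @param mixing optional 8 x N attenuation matrix; random full-column-rank
#'   attenuations in \[0.2, 1\] with random signs when `NULL`.
#' @param heart_rate beats per minute.
#' @param sampling_rate Hz.
#' @param duration seconds.
#' @param amplitude_scale ADC counts per unit source amplitude.
#' @param noise list of [noise_event()] objects (empty = clean rank-N model).
#' @param adc_ceiling saturation magnitude for clipping events (default
#'   2^15 - 1, the 16-bit ADC limit).
#' @param seed integer seed; every random draw derives from it.
#' @param record_id identifier for the generated record.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_sources = 3, mixing = NULL, heart_rate = 72,
                             sampling_rate = 500, duration = 10,
                             amplitude_scale = 50, noise = list(),
                             adc_ceiling = 32767, seed = 1,
                             record_id = "synth") {
  if (!is.numeric(n_sources) || n_sources < 1 || n_sources > 8)
    stop_input("synthetic_config: n_sources must be in 1..8")
  if (duration <= 0 || sampling_rate <= 0 ||
      round(duration * sampling_rate) < 2)
    stop_input("synthetic_config: duration and sampling_rate must give at least 2 samples")
  if (amplitude_scale <= 0)
    stop_input("synthetic_config: amplitude_scale must be positive")
  if (!is.null(mixing)) {
    mixing <- as.matrix(mixing)
    if (nrow(mixing) != 8L || ncol(mixing) != n_sources)
      stop_input("synthetic_config: mixing must be 8 x %d", n_sources)
    if (qr(mixing)$rank < n_sources)
      stop_input("synthetic_config: mixing matrix must have full column rank")
  }
  for (ev in noise)
    if (!inherits(ev, "noise_event"))
      stop_input("synthetic_config: noise must be a list of noise_event objects")
  structure(list(n_sources = as.integer(n_sources), mixing = mixing,
                 heart_rate = heart_rate, sampling_rate = sampling_rate,
                 duration = duration, amplitude_scale = amplitude_scale,
                 noise = noise, adc_ceiling = adc_ceiling,
                 seed = as.integer(seed), record_id = record_id),
            class = "synthetic_config")
}

gauss_bump <- function(t, mu, sig, amp) amp * exp(-((t - mu)^2) / (2 * sig^2))

#' Generate the cardiac source series
#'
#' Builds N zero-mean, unit-RMS source series of length
#' `duration * sampling_rate`. The first three are beat trains shaped like
#' the QRS complex, the T wave and the P wave (sum-of-Gaussian templates at
#' the configured heart rate with a seeded phase offset); further sources
#' are smoothed noise trains. Sources are sequentially orthogonalized, so
#' their pairwise sample correlations vanish by construction.
#'
#' @param config a [synthetic_config()].
#' @return An N x K numeric matrix, one source per row.
#' @export
make_sources <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_sources
  k <- round(config$duration * config$sampling_rate)
  t <- (0:(k - 1)) / config$sampling_rate
  period <- 60 / config$heart_rate
  with_seed(config$seed, {
    phase <- stats::runif(1, 0, period)
    tb <- (t + phase) %% period        # position within the beat
    qc <- 0.4 * period                 # QRS center
    templates <- list(
      function() gauss_bump(tb, qc - 0.028, 0.009, -0.15) +  # Q
                 gauss_bump(tb, qc,          0.011,  1.00) + # R
                 gauss_bump(tb, qc + 0.030,  0.010, -0.25),  # S
      function() gauss_bump(tb, qc + 0.28, 0.055, 1),        # T
      function() gauss_bump(tb, qc - 0.17, 0.028, 1))        # P
    s <- matrix(0, n, k)
    for (i in seq_len(n)) {
      row <- if (i <= 3L) templates[[i]]() else
        as.numeric(stats::filter(stats::rnorm(k), rep(1 / 21, 21), circular = TRUE))
      row <- row - mean(row)
      if (i > 1L) {                    # orthogonalize against earlier sources
        for (j in seq_len(i - 1L))
          row <- row - (sum(row * s[j, ]) / sum(s[j, ]^2)) * s[j, ]
        row <- row - mean(row)
      }
      rms <- sqrt(mean(row^2))
      if (rms < 1e-12)
        stop_input("make_sources: source %d degenerated to zero", i)
      s[i, ] <- row / rms
    }
    s
  })
}

apply_noise_event <- function(x, ev, t, fs, adc_ceiling) {
  k <- length(t)
  switch(ev$kind,
    white = {
      for (l in ev$leads) x[l, ] <- x[l, ] + stats::rnorm(k, 0, sqrt(ev$power))
      x
    },
    powerline = ,
    baseline_wander = {
      ph <- stats::runif(1, 0, 2 * pi)
      wave <- ev$amplitude * sin(2 * pi * ev$freq * t + ph)
      x[ev$leads, ] <- sweep(x[ev$leads, , drop = FALSE], 2, wave, `+`)
      x
    },
    transient_artifact = {
      onset <- ev$onset %||% stats::runif(1, 0, max(t) * 0.6)
      dur <- ev$duration %||% 1
      idx <- which(t >= onset & t < onset + dur)
      if (length(idx))
        for (l in ev$leads)
          x[l, idx] <- x[l, idx] + stats::rnorm(length(idx), 0, sqrt(ev$power))
      x
    },
    flat_lead = {
      x[ev$leads, ] <- 0
      x
    },
    clipping = {
      ceil <- ev$amplitude %||% adc_ceiling
      x[ev$leads, ] <- pmin(pmax(x[ev$leads, , drop = FALSE], -ceil), ceil)
      x
    })
}

#' Generate a synthetic contaminated 8-lead record
#'
#' Mixes the cardiac sources through the attenuation matrix, scales to
#' digital amplitude units and applies the configured noise events.
#' Additive events (white, powerline, baseline wander, transients) are
#' applied first, then flat-lead overwrites, then clipping — a flat lead is
#' flat no matter what noise preceded it. Amplitudes remain continuous;
#' quantization to integers happens only when the record is written as
#' WFDB.
#'
#' @param config a [synthetic_config()].
#' @return `list(record, report)`: the [ecg_record()] (leads I, II, V1-V6)
#'   and a ground-truth contamination report listing every injected event
#'   with its resolved parameters.
#' @export
mix_and_contaminate <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  s <- make_sources(config)
  k <- ncol(s)
  t <- (0:(k - 1)) / config$sampling_rate
  seeds <- derive_seeds(config$seed, 2)
  a <- config$mixing %||% with_seed(seeds[1], {
    repeat {
      cand <- matrix(stats::runif(8 * config$n_sources, 0.2, 1) *
                       sample(c(-1, 1), 8 * config$n_sources, replace = TRUE),
                     nrow = 8)
      # well-conditioned mixing: keeps all N source eigenvalues dominant
      if (min(svd(cand)$d) >= 0.4) break
    }
    cand
  })
  x <- config$amplitude_scale * (a %*% s)
  ordered <- config$noise[order(match(
    vapply(config$noise, `[[`, "", "kind"),
    c("white", "powerline", "baseline_wander", "transient_artifact",
      "flat_lead", "clipping")))]
  report <- ordered
  x <- with_seed(seeds[2], {
    for (ev in ordered)
      x <- apply_noise_event(x, ev, t, config$sampling_rate, config$adc_ceiling)
    x
  })
  rec <- ecg_record(t(x), config$sampling_rate, CANONICAL_LEADS,
                    record_id = config$record_id)
  list(record = rec, report = report)
}

#' Generate a labeled synthetic cohort
#'
#' Acceptable records are clean-model draws plus a low-level white
#' equipment-noise floor (sd 3 ADC counts on every lead), which keeps the
#' covariance full rank as in real recordings while leaving three dominant
#' cardiac eigenvalues. Unacceptable records additionally carry one
#' contamination event drawn from a fixed mixture of the documented failure
#' modes: a flat (disconnected) lead, a high-power transient artifact on
#' two leads, strong coherent powerline interference, or broadband
#' high-power noise on all leads. Heart rate and overall amplitude vary
#' record to record.
#'
#' @param n_records number of records (>= 1).
#' @param ac_fraction fraction of Acceptable records in \[0, 1\].
#' @param template a [synthetic_config()] supplying acquisition defaults.
#' @param seed integer seed; the cohort is a pure function of it.
#' @return `list(records, labels, reports)`: records is a list of
#'   [ecg_record()], labels a character vector (`"AC"`/`"UN"`), reports the
#'   per-record contamination reports.
#' @export
generate_cohort <- function(n_records, ac_fraction = 0.5,
                            template = synthetic_config(), seed = 1) {
  if (!is.numeric(n_records) || n_records < 1)
    stop_input("generate_cohort: n_records must be >= 1")
  if (ac_fraction < 0 || ac_fraction > 1)
    stop_input("generate_cohort: ac_fraction must be in [0, 1]")
  n <- as.integer(n_records)
  n_ac <- round(ac_fraction * n)
  sensor_floor <- noise_event("white", leads = 1:8, power = 9)
  plan <- with_seed(seed, {
    labels <- sample(c(rep("AC", n_ac), rep("UN", n - n_ac)))
    list(labels = labels,
         seeds = sample.int(.Machine$integer.max - 1L, n),
         amp_mult = stats::runif(n, 0.6, 1.5),
         hr = stats::runif(n, 55, 95),
         un_kind = sample(c("flat_lead", "transient_artifact", "powerline",
                            "white_high"), n, replace = TRUE),
         un_lead = sample.int(8L, n, replace = TRUE),
         un_pow = stats::runif(n),
         un_onset = stats::runif(n, 1, 6),
         un_nlead = sample(3:6, n, replace = TRUE))
  })
  records <- vector("list", n)
  reports <- vector("list", n)
  for (i in seq_len(n)) {
    noise <- list(sensor_floor)
    if (plan$labels[i] == "UN") {
      noise <- c(noise, list(switch(plan$un_kind[i],
        flat_lead = noise_event("flat_lead", leads = plan$un_lead[i]),
        transient_artifact = noise_event(
          "transient_artifact",
          leads = unique(c(plan$un_lead[i], 1L + plan$un_lead[i] %% 8L)),
          power = 10^(6.5 + plan$un_pow[i]),
          onset = plan$un_onset[i], duration = 2),
        powerline = noise_event(
          "powerline",
          leads = ((plan$un_lead[i] + seq_len(plan$un_nlead[i]) - 1L) %% 8L) + 1L,
          amplitude = 10^(3.3 + 0.4 * plan$un_pow[i])),
        white_high = noise_event("white", leads = 1:8,
                                 power = 10^(4.9 + 0.9 * plan$un_pow[i])))))
    }
    cfg <- template
    cfg$seed <- plan$seeds[i]
    cfg$heart_rate <- plan$hr[i]
    cfg$amplitude_scale <- template$amplitude_scale * plan$amp_mult[i]
    cfg$noise <- noise
    cfg$record_id <- sprintf("synth-%04d", i)
    out <- mix_and_contaminate(cfg)
    records[[i]] <- out$record
    reports[[i]] <- out$report
  }
  list(records = records, labels = plan$labels, reports = reports)
}
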