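# Minimal WFDB (PhysioBank) format-16 reader/writer.
# Format 16: 16-bit two's-complement little-endian samples, interleaved by
# frame (s1[t], s2[t], ..., sL[t], s1[t+1], ...). Samples are exposed in
# digital (ADC count) units; the header gain is parsed but never applied.

parse_wfdb_header <- function(hea_path) {
  if (!file.exists(hea_path))
    stop_input("read_wfdb_record: header file not found: %s", hea_path)
  lines <- readLines(hea_path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L)
    stop_input("read_wfdb_record: empty header: %s", hea_path)
  rec <- strsplit(lines[[1]], "[[:space:]]+")[[1]]
  if (length(rec) < 2L)
    stop_input("read_wfdb_record: malformed record line in %s", hea_path)
  nsig <- suppressWarnings(as.integer(rec[2]))
  if (is.na(nsig) || nsig < 1L)
    stop_input("read_wfdb_record: bad signal count in %s", hea_path)
  fs <- if (length(rec) >= 3L) suppressWarnings(as.numeric(sub("/.*$", "", rec[3]))) else 250
  if (is.na(fs) || fs <= 0)
    stop_input("read_wfdb_record: bad sampling frequency in %s", hea_path)
  nsamp <- if (length(rec) >= 4L) suppressWarnings(as.integer(rec[4])) else NA_integer_
  if (length(lines) < 1L + nsig)
    stop_input("read_wfdb_record: header %s declares %d signals but lists %d",
               hea_path, nsig, length(lines) - 1L)
  sig <- lapply(lines[1L + seq_len(nsig)], function(ln) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) < 2L)
      stop_input("read_wfdb_record: malformed signal line in %s: '%s'", hea_path, ln)
    fmt <- sub("[x:+].*$", "", tok[2])
    if (fmt != "16")
      stop_input("read_wfdb_record: unsupported signal format '%s' (only 16)", tok[2])
    desc <- if (length(tok) >= 9L) paste(tok[9:length(tok)], collapse = " ") else NA_character_
    list(file = tok[1], desc = desc)
  })
  list(record = sub("/.*$", "", rec[1]), nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

#' Read a WFDB format-16 record
#'
#' Reads a PhysioBank-style header (`.hea`) plus 16-bit signal (`.dat`) pair
#' and returns the samples in raw digital (ADC count) units, without gain
#' scaling. Lead names are taken from the signal description field of the
#' header.
#'
#' @param path path to the `.hea` file, or the record base name (with the
#'   extension omitted).
#' @return An [ecg_record()].
#' @export
read_wfdb_record <- function(path) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  hdr <- parse_wfdb_header(hea_path)
  dat_files <- unique(vapply(hdr$signals, `[[`, "", "file"))
  if (length(dat_files) != 1L)
    stop_input("read_wfdb_record: multi-file records are not supported (%s)", hea_path)
  dat_path <- file.path(dirname(hea_path), dat_files)
  if (!file.exists(dat_path))
    stop_input("read_wfdb_record: signal file not found: %s", dat_path)
  n_int16 <- file.info(dat_path)$size / 2
  vals <- readBin(dat_path, "integer", n = n_int16, size = 2L,
                  signed = TRUE, endian = "little")
  if (length(vals) %% hdr$nsig != 0L)
    stop_input("read_wfdb_record: %s holds %d samples, not a multiple of %d signals",
               dat_path, length(vals), hdr$nsig)
  k <- length(vals) %/% hdr$nsig
  if (!is.na(hdr$nsamp) && k != hdr$nsamp)
    stop_input("read_wfdb_record: header %s declares %d samples/signal but %s holds %d",
               hea_path, hdr$nsamp, dat_path, k)
  samples <- t(matrix(vals, nrow = hdr$nsig, ncol = k))
  names <- vapply(seq_along(hdr$signals), function(i)
    hdr$signals[[i]]$desc %||% sprintf("S%d", i), "")
  names[is.na(names)] <- sprintf("S%d", which(is.na(names)))
  ecg_record(samples, hdr$fs, names, record_id = hdr$record)
}

#' Write a WFDB format-16 record
#'
#' Writes `<name>.hea` and `<name>.dat` for a record. Samples are rounded to
#' integers and saturated at the 16-bit range; a record produced by the
#' synthetic generator round-trips bit-exactly once digitized.
#'
#' @param record an [ecg_record()].
#' @param dir output directory (created if needed).
#' @param name record base name; defaults to the record id.
#' @param gain nominal ADC gain written to the header (counts per mV);
#'   informational only, never applied by [read_wfdb_record()].
#' @return Invisibly, the path of the header file.
#' @export
write_wfdb_record <- function(record, dir, name = record$record_id, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  x <- round(record$samples)
  x[x > 32767] <- 32767
  x[x < -32768] <- -32768
  k <- nrow(x); l <- ncol(x)
  # signed 16-bit checksum of each signal's samples
  chks <- vapply(seq_len(l), function(j) {
    s <- sum(x[, j]) %% 65536
    if (s >= 32768) s - 65536 else s
  }, 0)
  hea <- c(sprintf("%s %d %g %d", name, l, record$sampling_rate, k),
           sprintf("%s.dat 16 %g/mV 16 0 %d %d 0 %s",
                   name, gain, as.integer(x[1, ]), as.integer(chks),
                   record$lead_names))
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  writeBin(as.integer(t(x)), file.path(dir, paste0(name, ".dat")),
           size = 2L, endian = "little")
  invisible(file.path(dir, paste0(name, ".hea")))
}
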