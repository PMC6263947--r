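#' Signal file readers and cohort serialization
#'
#' Two input routes are supported: WFDB-style records (header `.hea` plus
#' binary `.dat`, formats 212 and 16 — the formats Holter-style archives
#' use), and plain delimited numeric text files with one row per sample and
#' one column per lead. Synthetic cohorts round-trip through a directory of
#' delimited per-record files plus a tab-separated manifest.
#'
#' @name io
NULL

#' Read a delimited-text signal file as an ECG record
#'
#' @param path File with one row per sample, one numeric column per lead.
#' @param fs Sampling rate in Hz.
#' @param subject_id Label; defaults to the file name without extension.
#' @return An `ecg_record` (samples in mV as stored).
#' @export
read_delimited_record <- function(path, fs, subject_id = NULL) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  df <- tryCatch(read.table(path, header = FALSE),
                 error = function(e) abort(paste0("cannot parse ", path, ": ",
                                                  conditionMessage(e))))
  mat <- as.matrix(df)
  if (!nrow(mat)) abort(paste("empty signal file:", path))
  if (!is.numeric(mat)) abort(paste("non-numeric cells in", path))
  if (is.null(subject_id))
    subject_id <- tools::file_path_sans_ext(basename(path))
  structure(list(samples = unname(mat), fs = fs, subject_id = subject_id,
                 lead_names = paste0("lead", seq_len(ncol(mat)))),
            class = "ecg_record")
}

#' Read a WFDB-style record (formats 212 and 16)
#'
#' Parses the `.hea` header for lead count, sampling rate, gain and baseline,
#' decodes the packed `.dat` samples, and converts to millivolts as
#' `(adc - baseline) / gain`. The record name doubles as the subject id.
#'
#' @param path Record base path, with or without the `.hea` extension.
#' @return An `ecg_record` in mV.
#' @export
read_wfdb_record <- function(path) {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) abort(paste("missing header file:", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) abort(paste("empty header:", hea))
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 3) abort(paste("malformed record line in", hea))
  record_name <- rec[1]
  n_sig <- as.integer(rec[2])
  fs <- as.numeric(rec[3])
  n_samp <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  if (is.na(n_sig) || n_sig < 1 || is.na(fs) || fs <= 0)
    abort(paste("inconsistent header fields in", hea))
  if (length(lines) < 1 + n_sig)
    abort(paste("header declares", n_sig, "signals but lists fewer:", hea))

  sig <- lapply(lines[1 + seq_len(n_sig)], parse_wfdb_signal_line, hea = hea)
  dat_files <- unique(vapply(sig, `[[`, "", "file"))
  if (length(dat_files) != 1)
    abort("multi-file records are not supported")
  fmts <- unique(vapply(sig, `[[`, "", "format"))
  if (length(fmts) != 1 || !fmts %in% c("212", "16"))
    abort(paste("unsupported signal format:", paste(fmts, collapse = ",")))
  dat <- file.path(dirname(hea), dat_files)
  if (!file.exists(dat)) abort(paste("missing signal file:", dat))

  raw_bytes <- readBin(dat, "raw", n = file.info(dat)$size)
  adc <- if (fmts == "212") decode_212(raw_bytes, dat) else
    decode_16(raw_bytes)
  if (length(adc) %% n_sig != 0)
    abort(paste("truncated signal file:", dat))
  n <- length(adc) %/% n_sig
  if (!is.na(n_samp) && n < n_samp)
    abort(paste("truncated signal file:", dat,
                sprintf("(expected %d samples, found %d)", n_samp, n)))
  if (!is.na(n_samp)) n <- n_samp
  mat <- matrix(adc[seq_len(n * n_sig)], ncol = n_sig, byrow = TRUE)
  for (j in seq_len(n_sig))
    mat[, j] <- (mat[, j] - sig[[j]]$baseline) / sig[[j]]$gain
  structure(list(samples = mat, fs = fs, subject_id = record_name,
                 lead_names = vapply(seq_len(n_sig), function(j) {
                   d <- sig[[j]]$description
                   if (nzchar(d)) d else paste0("lead", j)
                 }, "")),
            class = "ecg_record")
}

parse_wfdb_signal_line <- function(line, hea) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(f) < 3) abort(paste("malformed signal line in", hea))
  fmt <- sub("x.*|:.*|\\+.*", "", f[2])   # strip samples-per-frame/skew/offset
  gain_field <- f[3]
  gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_field)))
  baseline <- if (grepl("\\(", gain_field))
    as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field)) else NA_real_
  adc_zero <- if (length(f) >= 5) as.numeric(f[5]) else 0
  if (is.na(baseline)) baseline <- adc_zero
  if (is.na(gain) || gain == 0) gain <- 200   # WFDB default gain
  desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
  list(file = f[1], format = fmt, gain = gain, baseline = baseline,
       description = desc)
}

# format 212: two 12-bit two's-complement samples packed into 3 bytes
decode_212 <- function(bytes, dat) {
  nb <- length(bytes)
  if (nb %% 3 != 0) abort(paste("truncated signal file:", dat))
  b <- as.integer(bytes)
  b1 <- b[seq(1, nb, 3)]; b2 <- b[seq(2, nb, 3)]; b3 <- b[seq(3, nb, 3)]
  s1 <- b1 + 256L * (b2 %% 16L)
  s2 <- b3 + 256L * (b2 %/% 16L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  as.vector(rbind(s1, s2))
}

# format 16: little-endian 16-bit two's complement
decode_16 <- function(bytes) {
  readBin(bytes, "integer", n = length(bytes) %/% 2L, size = 2L,
          endian = "little", signed = TRUE)
}

#' Write a cohort to a directory of delimited files
#'
#' One whitespace-delimited file per record (row = sample, column = lead)
#' plus `manifest.tsv` with `record_id`, `subject_id`, `fs`, `split`, `file`.
#'
#' @param cohort An `ecg_cohort` tibble.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::pmap_dfr(
    list(cohort$record_id, cohort$subject_id, cohort$split, cohort$record),
    function(rid, sid, split, rec) {
      fn <- paste0(rid, ".txt")
      write.table(format(rec$samples, digits = 10, trim = TRUE),
                  file.path(dir, fn),
                  row.names = FALSE, col.names = FALSE, quote = FALSE)
      tibble::tibble(record_id = rid, subject_id = sid, fs = rec$fs,
                     split = split, file = fn)
    })
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.tsv` and per-record files.
#' @return An `ecg_cohort` tibble.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) abort(paste("no manifest.tsv in", dir))
  manifest <- read.table(mf, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  rows <- purrr::pmap_dfr(manifest, function(record_id, subject_id, fs,
                                             split, file) {
    rec <- read_delimited_record(file.path(dir, file), fs, subject_id)
    tibble::tibble(record_id = record_id, subject_id = subject_id,
                   split = split, record = list(rec))
  })
  class(rows) <- c("ecg_cohort", class(rows))
  rows
}
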