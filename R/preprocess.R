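#' ECG preprocessing: from raw signal to averaged-beat images
#'
#' The identification pipeline reduces each record to one fixed-length
#' averaged-beat vector: per lead, a wide moving-average estimate of the
#' baseline is subtracted, the residual is smoothed with a short moving
#' average (which also attenuates single-sample spikes), R peaks are detected
#' as thresholded local maxima with a refractory window, and fixed windows
#' around each peak are averaged. The per-lead averages are concatenated,
#' linearly resampled to the target length, and amplitude-normalized; a
#' row-major reshape yields the square beat image the filter-bank network
#' consumes.
#'
#' @name preprocessing
NULL

#' Centered moving average with truncated edge windows
#'
#' Each output sample is the mean of a `width`-sample window centered on it;
#' windows that would extend past the signal are truncated to in-range samples
#' (no zero padding), so a constant signal maps to itself everywhere. For even
#' widths the extra sample falls before the center.
#'
#' @param values Numeric vector.
#' @param width Window width in samples (>= 1).
#' @return Numeric vector of the same length.
#' @examples
#' moving_average(c(0, 3, 6), 3)   # 1.5 3 4.5
#' @export
moving_average <- function(values, width) {
  if (length(width) != 1 || is.na(width) || width < 1)
    abort("width must be a single integer >= 1")
  width <- as.integer(width)
  n <- length(values)
  if (width == 1L) return(values)
  left <- width %/% 2L
  right <- width - 1L - left
  cs <- c(0, cumsum(values))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Remove baseline wander by subtracting a wide moving average
#'
#' @inheritParams moving_average
#' @param width Baseline window in samples; the default of 500 spans about one
#'   beat at 500 Hz so slow drift is captured without flattening the QRS.
#' @return Baseline-corrected signal, same length.
#' @export
remove_baseline <- function(values, width = 500) {
  values - moving_average(values, width)
}

#' Smooth a signal with a short moving average
#'
#' @inheritParams moving_average
#' @param width Smoothing window in samples (default 10); also knocks
#'   single-sample spikes down by a factor of `width`.
#' @export
smooth_signal <- function(values, width = 10) {
  moving_average(values, width)
}

#' Detect R peaks as thresholded local maxima
#'
#' Finds all local maxima exceeding `rel_threshold` times the global maximum,
#' then greedily keeps the larger of any two candidates closer than the
#' refractory window (ties go to the earlier index). The global maximum is
#' always retained.
#'
#' @param values Preprocessed (baseline-removed, smoothed) signal.
#' @param fs Sampling rate in Hz.
#' @param refractory Minimum peak separation in seconds (default 0.3, below
#'   any physiological RR interval).
#' @param rel_threshold Fraction of the global maximum a candidate must reach.
#' @return Sorted integer vector of peak sample indices.
#' @examples
#' x <- dnorm(seq(-3, 3, length.out = 101))
#' detect_r_peaks(x, fs = 100)
#' @export
detect_r_peaks <- function(values, fs, refractory = 0.3, rel_threshold = 0.5) {
  n <- length(values)
  if (n < 3) abort("signal too short for peak detection")
  gmax <- max(values)
  if (!is.finite(gmax) || gmax <= min(values))
    abort("no peak definable: signal is constant or non-finite")
  prev <- c(-Inf, values[-n])
  nxt <- c(values[-1], -Inf)
  cand <- which(values > prev & values >= nxt & values >= rel_threshold * gmax)
  refr <- max(1L, round(refractory * fs))
  # greedy: tallest first, earlier index breaks ties
  ord <- cand[order(-values[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= refr)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Average fixed windows around detected R peaks
#'
#' Extracts a `window`-sample segment around each peak
#' (`ceiling(window/2) - 1` samples before, `floor(window/2)` after, so any
#' odd sample lands after the peak), discards peaks whose window crosses the
#' signal boundary, and returns the element-wise mean segment. Averaging n
#' beats attenuates zero-mean noise by about `sqrt(n)`.
#'
#' @param values Signal vector.
#' @param peaks Integer peak indices (e.g. from [detect_r_peaks()]).
#' @param window Segment length in samples (default 400).
#' @return Numeric vector of length `window`.
#' @export
average_beat <- function(values, peaks, window = 400) {
  window <- as.integer(window)
  if (window < 1) abort("window must be >= 1")
  n <- length(values)
  before <- as.integer(ceiling(window / 2) - 1)
  after <- window %/% 2L
  usable <- peaks[peaks - before >= 1 & peaks + after <= n]
  if (!length(usable)) abort("no usable peak: all windows cross the boundary")
  seg <- vapply(usable, function(p) values[(p - before):(p + after)],
                numeric(window))
  rowMeans(seg)
}

#' Build a fixed-length beat vector from a record
#'
#' Per lead: baseline removal, smoothing, R-peak detection, beat averaging.
#' The per-lead averaged beats are concatenated in lead order, linearly
#' resampled to exactly `target_len` samples, and normalized to zero mean and
#' unit maximum absolute amplitude.
#'
#' @param record An `ecg_record`.
#' @param target_len Output length; `m * n` of the intended beat image
#'   (e.g. 784 for 28x28 single-lead data, 1600 for 40x40 two-lead data).
#' @param baseline_width,smooth_width Moving-average widths in samples.
#' @param window Beat window in samples (default 400).
#' @param refractory,rel_threshold Passed to [detect_r_peaks()].
#' @return Numeric vector of length `target_len` with attribute `record_id`.
#' @examples
#' rec <- synthesize_record(make_subject_template(1), 10, 500,
#'                          noise_spec(0, 0, 0, 0, 0), seed = 2)
#' length(build_beat_vector(rec, 784))
#' @export
build_beat_vector <- function(record, target_len,
                              baseline_width = 500, smooth_width = 10,
                              window = 400, refractory = 0.3,
                              rel_threshold = 0.5) {
  stopifnot(inherits(record, "ecg_record"))
  per_lead <- lapply(seq_len(ncol(record$samples)), function(j) {
    y <- remove_baseline(record$samples[, j], baseline_width)
    y <- smooth_signal(y, smooth_width)
    pk <- detect_r_peaks(y, record$fs, refractory, rel_threshold)
    average_beat(y, pk, window)
  })
  v <- unlist(per_lead, use.names = FALSE)
  if (length(v) != target_len) {
    v <- approx(seq_along(v), v,
                xout = seq(1, length(v), length.out = target_len))$y
  }
  v <- v - mean(v)
  mx <- max(abs(v))
  if (mx == 0) abort("degenerate beat vector: all zero after centering")
  v <- v / mx
  attr(v, "record_id") <- record$subject_id
  v
}

#' Reshape a beat vector into a 2D beat image
#'
#' Row-major reshape: flattening the result row by row reproduces the vector
#' exactly.
#'
#' @param vec Numeric vector of length `m * n`.
#' @param m,n Image dimensions.
#' @return An `m` x `n` numeric matrix.
#' @examples
#' img <- beat_image(1:12, 3, 4)
#' all(as.vector(t(img)) == 1:12)
#' @export
beat_image <- function(vec, m, n) {
  if (length(vec) != m * n)
    abort(sprintf("length(vec) = %d but m * n = %d", length(vec), m * n))
  matrix(as.numeric(vec), nrow = m, ncol = n, byrow = TRUE)
}

#' Preprocess every record of a cohort
#'
#' Maps [build_beat_vector()] over a cohort tibble, keeping the manifest
#' columns so the result flows straight into fitting and evaluation.
#'
#' @param cohort An `ecg_cohort` tibble (or any tibble with a `record`
#'   list-column of `ecg_record`s).
#' @param target_len Beat-vector length (`m * n`).
#' @param ... Passed to [build_beat_vector()].
#' @return The input tibble plus a `beat` list-column of numeric vectors.
#' @export
preprocess_cohort <- function(cohort, target_len = 784, ...) {
  stopifnot(is.data.frame(cohort), "record" %in% names(cohort))
  dplyr::mutate(cohort,
    beat = purrr::map(.data$record, build_beat_vector,
                      target_len = target_len, ...))
}

#' Stack a preprocessed cohort's beats into images
#'
#' @param preprocessed Tibble with a `beat` list-column.
#' @param m,n Image dimensions; `m * n` must equal the beat length.
#' @return List of `m` x `n` matrices, one per row.
#' @export
cohort_images <- function(preprocessed, m, n) {
  lapply(preprocessed$beat, beat_image, m = m, n = n)
}
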