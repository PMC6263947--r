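#' Signal-fidelity and compression metrics
#'
#' Standard measures comparing an original signal `Xs` with a reconstructed
#' (e.g. compressed-then-decompressed) signal `Xr`:
#' * `CR = B0 / Bc` — compression ratio of bit counts;
#' * `PRD = 100 * sqrt(sum((Xs - Xr)^2) / sum(Xs^2))` — percent RMS
#'   difference;
#' * `PRDN` — PRD with the mean-removed energy `sum((Xs - mean(Xs))^2)` in
#'   the denominator, making it offset-independent;
#' * `RMS = 100 * sqrt(sum((Xs - Xr)^2) / (N - 1))`;
#' * `SNR = 10 * log10(sum((Xs - mean(Xs))^2) / sum((Xs - Xr)^2))` in dB.
#'
#' Degenerate denominators (zero signal energy for PRD, constant `Xs` for
#' PRDN/SNR, perfect reconstruction for SNR) raise errors rather than
#' returning infinities.
#'
#' @param xs Original signal.
#' @param xr Reconstructed signal, same length.
#' @name fidelity_metrics
NULL

check_pair <- function(xs, xr) {
  if (length(xs) != length(xr)) abort("signals must have equal length")
  if (!length(xs)) abort("signals must be non-empty")
}

#' @rdname fidelity_metrics
#' @param B0 Bits of the original representation.
#' @param Bc Bits of the compressed representation (> 0).
#' @export
compression_ratio <- function(B0, Bc) {
  if (Bc <= 0) abort("Bc must be > 0")
  B0 / Bc
}

#' @rdname fidelity_metrics
#' @export
prd <- function(xs, xr) {
  check_pair(xs, xr)
  den <- sum(xs^2)
  if (den == 0) abort("PRD undefined: original signal is all zero")
  100 * sqrt(sum((xs - xr)^2) / den)
}

#' @rdname fidelity_metrics
#' @export
prdn <- function(xs, xr) {
  check_pair(xs, xr)
  den <- sum((xs - mean(xs))^2)
  if (den == 0) abort("PRDN undefined: original signal is constant")
  100 * sqrt(sum((xs - xr)^2) / den)
}

#' @rdname fidelity_metrics
#' @export
rms_error <- function(xs, xr) {
  check_pair(xs, xr)
  if (length(xs) < 2) abort("RMS needs at least 2 samples (N - 1 > 0)")
  100 * sqrt(sum((xs - xr)^2) / (length(xs) - 1))
}

#' @rdname fidelity_metrics
#' @export
snr <- function(xs, xr) {
  check_pair(xs, xr)
  num <- sum((xs - mean(xs))^2)
  den <- sum((xs - xr)^2)
  if (num == 0) abort("SNR undefined: original signal is constant")
  if (den == 0) abort("SNR undefined: reconstruction is exact")
  10 * log10(num / den)
}
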