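#' Classical EEG band definitions
#'
#' The four conventional rhythms used throughout the package:
#' delta 0.5-4 Hz, theta 4-8 Hz, alpha 8-14 Hz, beta 14-30 Hz.
#'
#' @return A data frame with columns `name`, `low`, `high` (Hz).
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             low  = c(0.5, 4, 8, 14),
             high = c(4, 8, 14, 30),
             stringsAsFactors = FALSE)
}

butter_design <- function(low, high, sampling_rate, order = 4) {
  nyq <- sampling_rate / 2
  if (!is.finite(low) || !is.finite(high) || low <= 0 || low >= high)
    stop("bandpass: need 0 < low < high")
  if (high >= nyq)
    stop("bandpass: high edge ", high, " Hz is not below the Nyquist rate (",
         nyq, " Hz)")
  signal::butter(order, c(low, high) / nyq, type = "pass")
}

#' Band-pass filter a segment with a Butterworth design
#'
#' Applies a fourth-order Butterworth band-pass (the prototype order; the
#' digital band-pass transfer function has twice that many poles) to a
#' signal.  By default the filter is run forward and backward
#' (`signal::filtfilt`), giving zero phase shift at the cost of squaring
#' the magnitude response; `zero_phase = FALSE` selects a causal single
#' pass.  Output length always equals input length.
#'
#' @param x An [eeg_segment] or plain numeric vector.
#' @param low,high Band edges in Hz; `high` must be below Nyquist.
#' @param sampling_rate Sampling rate in Hz; taken from `x` when it is an
#'   `eeg_segment`.
#' @param order Butterworth prototype order (default 4).
#' @param zero_phase Forward-backward application (default `TRUE`).
#' @return Filtered signal of the same type and length as `x`.
#' @examples
#' fs <- 173.61
#' tone <- sin(2 * pi * 10 * (0:2047) / fs)
#' alpha <- bandpass(tone, 8, 14, sampling_rate = fs)
#' @export
bandpass <- function(x, low, high, sampling_rate = NULL, order = 4,
                     zero_phase = TRUE) {
  is_seg <- inherits(x, "eeg_segment")
  fs <- sampling_rate %||% (if (is_seg) seg_rate(x) else
    stop("bandpass: sampling_rate required for plain numeric input"))
  v <- if (is_seg) seg_samples(x) else as.numeric(x)
  if (!all(is.finite(v))) stop("bandpass: input contains non-finite samples")
  filt <- butter_design(low, high, fs, order)
  y <- if (zero_phase) signal::filtfilt(filt, v)
       else as.numeric(signal::filter(filt, v))
  stopifnot(length(y) == length(v))
  if (is_seg)
    eeg_segment(y, sampling_rate = fs, label = attr(x, "label"),
                source_id = attr(x, "source_id"))
  else y
}

#' Magnitude response of the band-pass design
#'
#' Evaluates the designed digital Butterworth band-pass transfer function
#' on the unit circle at the requested frequencies.  With
#' `zero_phase = TRUE` the squared magnitude is returned, matching the
#' effective gain of forward-backward filtering.
#'
#' @inheritParams bandpass
#' @param freq Frequencies in Hz at which to evaluate the gain.
#' @return Numeric vector of gains, one per element of `freq`.
#' @export
bandpass_gain <- function(freq, low, high, sampling_rate, order = 4,
                          zero_phase = TRUE) {
  filt <- butter_design(low, high, sampling_rate, order)
  w <- 2 * pi * freq / sampling_rate
  z <- exp(1i * w)
  h <- vapply(z, function(zz) {
    num <- sum(filt$b * zz^(-(seq_along(filt$b) - 1)))
    den <- sum(filt$a * zz^(-(seq_along(filt$a) - 1)))
    Mod(num / den)
  }, numeric(1))
  if (zero_phase) h^2 else h
}

#' Decompose a segment into its classical rhythms
#'
#' Filters a segment into each requested band, returning the original
#' signal alongside the band-limited versions.  The four band outputs do
#' not sum back to the original: 0.5-30 Hz does not cover the spectrum and
#' the pass-bands are not a partition.
#'
#' @param x An [eeg_segment] (or numeric vector with `sampling_rate`).
#' @param bands Data frame with columns `name`, `low`, `high`; defaults to
#'   [default_bands()].
#' @inheritParams bandpass
#' @return An object of class `rhythm_bank`: a named list
#'   `original`, then one element per band, all of equal length, with the
#'   segment's `sampling_rate`, `label` and `source_id` attached.
#' @examples
#' seg <- generate_fgn(0.5, 1024, seed = 1)
#' bank <- decompose(seg)
#' names(bank)
#' @export
decompose <- function(x, bands = default_bands(), sampling_rate = NULL,
                      order = 4, zero_phase = TRUE) {
  if (is.null(bands) || nrow(as.data.frame(bands)) == 0L)
    stop("decompose: band list must be nonempty")
  bands <- as.data.frame(bands)
  if (anyDuplicated(bands$name))
    stop("decompose: duplicate band names")
  is_seg <- inherits(x, "eeg_segment")
  fs <- sampling_rate %||% (if (is_seg) seg_rate(x) else
    stop("decompose: sampling_rate required for plain numeric input"))
  v <- if (is_seg) seg_samples(x) else as.numeric(x)
  out <- c(list(original = v),
           stats::setNames(lapply(seq_len(nrow(bands)), function(i)
             bandpass(v, bands$low[i], bands$high[i], sampling_rate = fs,
                      order = order, zero_phase = zero_phase)),
             bands$name))
  structure(out,
            sampling_rate = fs,
            label = if (is_seg) attr(x, "label") else NA_character_,
            source_id = if (is_seg) attr(x, "source_id") else "",
            class = "rhythm_bank")
}

#' @export
print.rhythm_bank <- function(x, ...) {
  cat(sprintf("<rhythm_bank> %d signals x %d samples @ %.2f Hz\n",
              length(x), length(x[[1]]), attr(x, "sampling_rate")))
  cat("  signals:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
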