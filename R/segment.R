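#' Single-channel EEG segment
#'
#' Lightweight container for one single-channel EEG recording: a numeric
#' sample vector (conventionally microvolts), its sampling rate, a class
#' label (Bonn-style `A`..`E` or any synthetic analogue) and a source
#' identifier (typically the originating file name).
#'
#' @param samples Numeric vector of samples; must be finite and hold at
#'   least 64 points.
#' @param sampling_rate Sampling rate in Hz (default 173.61, the Bonn
#'   corpus rate).
#' @param label Class tag, e.g. `"A"`..`"E"`; `NA` for unlabeled data.
#' @param source_id Free-form identifier of the segment's origin.
#'
#' @return An object of class `eeg_segment`: the sample vector with
#'   `sampling_rate`, `label` and `source_id` attributes.
#' @examples
#' seg <- eeg_segment(sin(2 * pi * 10 * (0:511) / 173.61))
#' seg
#' @export
eeg_segment <- function(samples, sampling_rate = 173.61,
                        label = NA_character_, source_id = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 64L)
    stop("eeg_segment: need at least 64 samples, got ", length(samples))
  if (!all(is.finite(samples)))
    stop("eeg_segment: samples must all be finite")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("eeg_segment: sampling_rate must be a single positive number")
  structure(samples,
            sampling_rate = sampling_rate,
            label = as.character(label),
            source_id = as.character(source_id),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  fs <- attr(x, "sampling_rate")
  cat(sprintf("<eeg_segment> %d samples @ %.2f Hz (%.1f s)",
              length(x), fs, length(x) / fs))
  if (!is.na(attr(x, "label"))) cat("  label:", attr(x, "label"))
  if (nzchar(attr(x, "source_id"))) cat("  [", attr(x, "source_id"), "]", sep = "")
  cat("\n")
  invisible(x)
}

# strip class/attrs -> plain numeric
seg_samples <- function(x) as.numeric(unclass(x))

seg_rate <- function(x, default = 173.61) {
  fs <- attr(x, "sampling_rate")
  if (is.null(fs)) default else fs
}
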