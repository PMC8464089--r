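#' Higuchi fractal dimension
#'
#' Estimates the fractal dimension of a sampled waveform from the scaling
#' of its average curve length.  For each interval `p = 1..p_max` and each
#' start phase `f = 1..p`, the normalized length of the subsampled series
#' `T(f), T(f+p), T(f+2p), ...` is
#' \deqn{A_f(p) = \Big[\sum_j |T(f+jp) - T(f+(j-1)p)|\Big]
#'   \frac{Y-1}{\lfloor (Y-f)/p \rfloor \, p} \Big/ p,}
#' averaged over phases to `A(p)`.  Since `A(p)` scales as `p^{-D}`, the
#' dimension is the ordinary least-squares slope of `log A(p)` against
#' `log(1/p)` over all `p = 1..p_max` (natural logs; the slope is
#' base-invariant).  A smooth curve gives values near 1, uncorrelated
#' noise near 2.
#'
#' @param x Numeric vector (or [eeg_segment]), length strictly greater
#'   than `4 * p_max`.
#' @param p_max Largest interval (saturation point) used in the fit;
#'   the package computes features at both 30 and 45 by default.
#' @return The estimated dimension (a single number, typically in (1, 2)).
#' @examples
#' higuchi_fd(seq_len(1000), p_max = 30)   # straight line -> 1
#' @export
higuchi_fd <- function(x, p_max = 30) {
  x <- if (inherits(x, "eeg_segment")) seg_samples(x) else as.numeric(x)
  p_max <- as.integer(p_max)
  if (p_max < 2L) stop("higuchi_fd: p_max must be >= 2")
  y_len <- length(x)
  if (y_len <= 4L * p_max)
    stop("higuchi_fd: signal length ", y_len,
         " too short for p_max = ", p_max, " (need > 4 * p_max)")
  if (!all(is.finite(x))) stop("higuchi_fd: non-finite samples")
  a <- numeric(p_max)
  for (p in seq_len(p_max)) {
    af <- numeric(p)
    for (f in seq_len(p)) {
      idx <- seq.int(f, y_len, by = p)
      np <- length(idx) - 1L               # floor((Y - f) / p)
      af[f] <- sum(abs(diff(x[idx]))) * (y_len - 1) / (np * p) / p
    }
    a[p] <- mean(af)
  }
  if (any(a <= 0))
    stop("higuchi_fd: flat signal (zero curve length); dimension undefined")
  ols_slope(log(1 / seq_len(p_max)), log(a))
}

#' Katz fractal dimension
#'
#' Treats the waveform as a planar curve through the points
#' `(j, T(j))` with unit sample spacing.  With total curve length
#' `U` (sum of consecutive point distances), planar extent `b` (largest
#' distance from the first point), and mean step `m = U / (Y - 1)`, the
#' dimension is
#' \deqn{K = \frac{\log_{10}(n)}{\log_{10}(b/U) + \log_{10}(n)}, \qquad
#'   n = U/m = Y - 1.}
#' A straight line gives exactly 1.  Katz's measure is not
#' amplitude-invariant: rescaling the signal changes `K`.
#'
#' @param x Numeric vector (or [eeg_segment]) of length >= 3.
#' @return The Katz dimension (>= 1; equals 1 for monotone straight lines
#'   and for constant signals, whose curve is a straight horizontal line).
#' @examples
#' katz_fd(c(0, 1, 2, 3))   # 1
#' katz_fd(c(0, 1, 0, 1))   # ~ 1.365
#' @export
katz_fd <- function(x) {
  x <- if (inherits(x, "eeg_segment")) seg_samples(x) else as.numeric(x)
  y_len <- length(x)
  if (y_len < 3L) stop("katz_fd: need at least 3 samples")
  if (!all(is.finite(x))) stop("katz_fd: non-finite samples")
  u <- sum(sqrt(1 + diff(x)^2))
  j <- seq_len(y_len) - 1          # x-offsets from the first point
  b <- max(sqrt(j^2 + (x - x[1L])^2))
  n <- y_len - 1L                  # U / m with m = U / (Y - 1)
  log10(n) / (log10(b / u) + log10(n))
}

#' Rescaled-range (R/S) Hurst exponent
#'
#' Estimates the Hurst exponent by classical rescaled-range analysis.  The
#' series of length `M` is split into non-overlapping blocks of length
#' `m = M, M/2, M/4, ...` down to `min_block`; in each block the range of
#' the cumulative sum of the mean-removed block is divided by the block's
#' population standard deviation, and the block values are averaged into
#' `R/S_ave(m)`.  The exponent is the least-squares slope of
#' `log R/S_ave(m)` on `log m`.  Values near 0.5 indicate uncorrelated
#' increments; above 0.5 persistence, below 0.5 anti-persistence.
#'
#' Blocks with zero standard deviation are excluded; when fewer than three
#' block lengths survive, estimation is refused.  When `m` does not divide
#' `M` the trailing remainder is dropped.
#'
#' @param x Numeric vector (or [eeg_segment]), length >= `4 * min_block`.
#' @param min_block Smallest block length retained (default 16; at least 8).
#' @return The estimated Hurst exponent (unclipped; the feature assembly
#'   clips to `[0, 1]`).
#' @examples
#' hurst_exponent(as.numeric(generate_fgn(0.7, 1024, seed = 1)))
#' @export
hurst_exponent <- function(x, min_block = 16) {
  x <- if (inherits(x, "eeg_segment")) seg_samples(x) else as.numeric(x)
  min_block <- as.integer(min_block)
  if (min_block < 8L) stop("hurst_exponent: min_block must be >= 8")
  m_total <- length(x)
  if (m_total < 4L * min_block)
    stop("hurst_exponent: signal length ", m_total,
         " too short (need >= 4 * min_block)")
  if (!all(is.finite(x))) stop("hurst_exponent: non-finite samples")
  ms <- c(); rs <- c()
  m <- m_total
  while (m >= min_block) {
    nb <- m_total %/% m
    vals <- numeric(0)
    for (b in seq_len(nb)) {
      seg <- x[((b - 1L) * m + 1L):(b * m)]
      a <- mean(seg)
      s <- sqrt(mean((seg - a)^2))
      if (s > 0) {
        v <- cumsum(seg - a)
        vals <- c(vals, (max(v) - min(v)) / s)
      }
    }
    if (length(vals)) {
      ms <- c(ms, m)
      rs <- c(rs, mean(vals))
    }
    m <- m %/% 2L
  }
  if (length(ms) < 3L)
    stop("hurst_exponent: fewer than 3 usable block lengths ",
         "(signal constant or nearly so)")
  ols_slope(log(ms), log(rs))
}

#' Lempel-Ziv complexity of a binarized signal
#'
#' Coarse-grains the signal into a binary string `u(j) = 1` when
#' `T(j)` exceeds the margin `L` (the signal mean or median; values equal
#' to the margin map to 0), then counts the number of components `c(m)` in
#' the LZ76 exhaustive-history parsing: scanning left to right, a new
#' component ends at the first position where the current word no longer
#' occurs in the preceding history, and a final incomplete component
#' counts as one.  The returned normalized complexity is
#' \deqn{C(m) = \frac{c(m)}{m / \log_2 m}.}
#' Random sequences concentrate near 1; regular ones fall well below.
#'
#' @param x Numeric vector (or [eeg_segment]) of length >= 2.
#' @param threshold `"mean"` or `"median"` margin.
#' @return Normalized complexity `C(m)` (single number).
#' @examples
#' lz_complexity(c(1, 2, 1, 2, 1, 2), threshold = "mean")   # ~ 1.292
#' @export
lz_complexity <- function(x, threshold = c("mean", "median")) {
  x <- if (inherits(x, "eeg_segment")) seg_samples(x) else as.numeric(x)
  threshold <- match.arg(threshold)
  if (length(x) < 2L) stop("lz_complexity: need at least 2 samples")
  if (!all(is.finite(x))) stop("lz_complexity: non-finite samples")
  margin <- if (threshold == "mean") mean(x) else stats::median(x)
  bits <- as.integer(x > margin)
  lz76_count(bits) / (length(bits) / log2(length(bits)))
}

# LZ76 exhaustive-history component count.
# For fixed start p, "s[p..q] occurs in s[1..q-1]" is monotone in q (any
# occurrence must start at or before p-1), so the end of each component is
# located by binary search with C-level substring matching.
lz76_count <- function(bits) {
  s <- paste(bits, collapse = "")
  m <- nchar(s)
  count <- 0L
  p <- 1L
  while (p <= m) {
    if (p == 1L || !grepl(substr(s, p, p), substr(s, 1L, p - 1L),
                          fixed = TRUE)) {
      count <- count + 1L            # single new symbol
      p <- p + 1L
      next
    }
    lo <- p; hi <- m                 # s[p..lo] known to occur in history
    while (lo < hi) {
      mid <- (lo + hi + 1L) %/% 2L
      if (grepl(substr(s, p, mid), substr(s, 1L, mid - 1L), fixed = TRUE))
        lo <- mid
      else hi <- mid - 1L
    }
    count <- count + 1L
    if (lo == m) break               # incomplete final component
    p <- lo + 2L                     # component = s[p..lo+1]
  }
  count
}

ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

#' Canonical names of the 30-dimensional feature vector
#'
#' Six measures (`HFD_kmax=30`, `HFD_kmax=45`, `KFD`, `Hurst`, `LZC_mean`,
#' `LZC_median`) applied to five signals (`Original Signal`, `Delta`,
#' `Theta`, `Alpha`, `Beta`), named `"MEASURE(SOURCE)"`, e.g.
#' `"KFD(Theta)"` or `"HFD_kmax=45(Beta)"`.
#'
#' @param p_max The two Higuchi saturation points (default `c(30, 45)`).
#' @return Character vector of 30 names, sources varying slowest.
#' @export
feature_names <- function(p_max = c(30, 45)) {
  measures <- c(sprintf("HFD_kmax=%d", p_max), "KFD", "Hurst",
                "LZC_mean", "LZC_median")
  sources <- c("Original Signal", "Delta", "Theta", "Alpha", "Beta")
  as.vector(t(outer(sources, measures,
                    function(s, m) sprintf("%s(%s)", m, s))))
}

#' Extract the 30-dimensional nonlinear feature vector from a rhythm bank
#'
#' Applies the six nonlinear measures (Higuchi dimension at both
#' saturation points, Katz dimension, rescaled-range Hurst exponent
#' clipped to `[0, 1]`, and Lempel-Ziv complexity under mean and median
#' margins) to the original signal and its four rhythms.  A measure that
#' is undefined for a signal (e.g. the Hurst exponent of a constant
#' segment) yields `NA` with a warning, and the whole vector is flagged
#' via the `"incomplete"` attribute.
#'
#' @param bank A [decompose()] result (`rhythm_bank`).
#' @param p_max Two Higuchi saturation points (default `c(30, 45)`).
#' @param min_block Smallest Hurst block length (default 16).
#' @return Named numeric vector of length 30 (names from
#'   [feature_names()]), with attribute `incomplete` (logical).
#' @examples
#' bank <- decompose(generate_fgn(0.5, 1024, seed = 1))
#' fv <- extract_features(bank)
#' length(fv)
#' @export
extract_features <- function(bank, p_max = c(30, 45), min_block = 16) {
  if (!inherits(bank, "rhythm_bank"))
    stop("extract_features: bank must be a rhythm_bank from decompose()")
  stopifnot(length(p_max) == 2L)
  sources <- c("Original Signal" = "original", Delta = "delta",
               Theta = "theta", Alpha = "alpha", Beta = "beta")
  if (!all(sources %in% names(bank)))
    stop("extract_features: bank must contain signals ",
         paste(sources, collapse = ", "))
  measure_fns <- c(
    stats::setNames(lapply(p_max, function(p) function(v) higuchi_fd(v, p)),
                    sprintf("HFD_kmax=%d", p_max)),
    list(KFD = katz_fd,
         Hurst = function(v)
           min(max(hurst_exponent(v, min_block), 0), 1),
         LZC_mean = function(v) lz_complexity(v, "mean"),
         LZC_median = function(v) lz_complexity(v, "median")))
  vals <- numeric(0)
  for (src in names(sources)) {
    v <- bank[[sources[[src]]]]
    for (msr in names(measure_fns)) {
      val <- tryCatch(measure_fns[[msr]](v), error = function(e) {
        warning(sprintf("%s(%s) undefined: %s", msr, src,
                        conditionMessage(e)), call. = FALSE)
        NA_real_
      })
      vals[sprintf("%s(%s)", msr, src)] <- val
    }
  }
  vals <- vals[feature_names(p_max)]
  attr(vals, "incomplete") <- anyNA(vals)
  vals
}

#' Build a feature matrix for a collection of segments
#'
#' Runs [decompose()] and [extract_features()] over a list of segments and
#' assembles the results into a data frame with one row per segment:
#' `source_id`, `label`, then the 30 feature columns.
#'
#' @param segments List of [eeg_segment]s.
#' @param bands Band definitions passed to [decompose()].
#' @param p_max,min_block Feature configuration, see [extract_features()].
#' @param order,zero_phase Filter configuration, see [bandpass()].
#' @param progress Print a progress line every 50 segments.
#' @return Data frame (`check.names = FALSE`; feature names contain
#'   parentheses) with `nrow = length(segments)`.
#' @export
extract_feature_matrix <- function(segments, bands = default_bands(),
                                   p_max = c(30, 45), min_block = 16,
                                   order = 4, zero_phase = TRUE,
                                   progress = FALSE) {
  stopifnot(length(segments) >= 1L)
  rows <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    bank <- decompose(segments[[i]], bands = bands, order = order,
                      zero_phase = zero_phase)
    rows[[i]] <- extract_features(bank, p_max = p_max, min_block = min_block)
    if (progress && i %% 50L == 0L)
      message("features: ", i, "/", length(segments), " segments")
  }
  feat <- do.call(rbind, rows)
  out <- data.frame(
    source_id = vapply(segments, function(s) attr(s, "source_id") %||% "",
                       character(1)),
    label = vapply(segments, function(s) attr(s, "label") %||% NA_character_,
                   character(1)),
    stringsAsFactors = FALSE, check.names = FALSE)
  out[colnames(feat)] <- as.data.frame(feat, check.names = FALSE)
  rownames(out) <- NULL
  out
}
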