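#' Fractional Gaussian noise by circulant embedding
#'
#' Exact synthesis (Davies-Harte) of stationary fractional Gaussian noise
#' (fGn) with Hurst index `hurst`: the autocovariance of the returned
#' series is exactly
#' \deqn{\gamma(k) = \tfrac12 (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}),}
#' so its cumulative sum is a sampled fractional Brownian motion.  The
#' first row of the fGn autocovariance is embedded in a circulant matrix of
#' order `2n`, whose eigenvalues (obtained by FFT) are non-negative for fGn;
#' a Hermitian Gaussian coefficient vector is then transformed back.  fGn
#' with known `H` is the standard oracle signal for rescaled-range Hurst
#' estimators: `H = 0.5` is white noise, `H > 0.5` persistent, `H < 0.5`
#' anti-persistent.
#'
#' @param hurst Hurst index, strictly between 0 and 1.
#' @param n Number of samples (at least 64).
#' @param seed Integer seed; the generator is a pure function of
#'   `(hurst, n, seed)`.
#' @param sampling_rate Sampling rate attached to the returned segment.
#' @return An [eeg_segment] of unit-variance fGn, label `NA`.
#' @examples
#' x <- generate_fgn(0.8, 1024, seed = 1)
#' var(as.numeric(x))   # ~ 1
#' @export
generate_fgn <- function(hurst, n, seed, sampling_rate = 173.61) {
  if (!is.numeric(hurst) || length(hurst) != 1L || hurst <= 0 || hurst >= 1)
    stop("generate_fgn: hurst must lie strictly inside (0, 1)")
  n <- as.integer(n)
  if (n < 64L) stop("generate_fgn: n must be >= 64")
  k <- 0:(n - 1L)
  gam <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                  abs(k - 1)^(2 * hurst))
  circ <- c(gam, 0, rev(gam[-1L]))
  m <- length(circ)                       # 2n
  lam <- Re(stats::fft(circ))
  if (min(lam) < -1e-8 * max(lam))
    stop("generate_fgn: circulant embedding is not non-negative definite")
  lam[lam < 0] <- 0
  half <- m %/% 2L
  coef <- complex(m)
  with_seed(seed, {
    coef[1L] <- sqrt(lam[1L] / m) * stats::rnorm(1)
    coef[half + 1L] <- sqrt(lam[half + 1L] / m) * stats::rnorm(1)
    u <- stats::rnorm(half - 1L)
    v <- stats::rnorm(half - 1L)
    idx <- 2L:half
    coef[idx] <- sqrt(lam[idx] / (2 * m)) * complex(real = u, imaginary = v)
    coef[m + 2L - idx] <- Conj(coef[idx])
  })
  x <- Re(stats::fft(coef))[1:n]
  eeg_segment(x, sampling_rate = sampling_rate,
              source_id = sprintf("fgn_H%.3f_seed%d", hurst, as.integer(seed)))
}

#' Weierstrass cosine signal of known fractal dimension
#'
#' Deterministic Weierstrass-type series
#' \deqn{W(t) = \sum_{k=0}^{K-1} \lambda^{-kH} \cos(2\pi \lambda^k t)}
#' sampled on `[0, 1)`, with roughness exponent `H = 2 - dim`; its graph has
#' box-counting (and Higuchi) dimension `dim` for `1 < dim < 2`.  Used as a
#' known-dimension oracle for fractal-dimension estimators.
#'
#' @param dim Target fractal dimension, strictly between 1 and 2.
#' @param n Number of samples on `[0, 1)` (at least 64).
#' @param n_harmonics Number of cosine terms `K`; default places the highest
#'   harmonic at the Nyquist limit, `K = floor(log(n/2) / log(lambda)) + 1`.
#'   `n_harmonics = 1` gives a pure cosine.
#' @param lambda Frequency ratio between successive harmonics (> 1).
#' @param sampling_rate Sampling rate attached to the returned segment.
#' @return An [eeg_segment], label `NA`.
#' @examples
#' w <- generate_weierstrass(1.5, 4096)
#' @export
generate_weierstrass <- function(dim, n, n_harmonics = NULL, lambda = 2,
                                 sampling_rate = 173.61) {
  if (!is.numeric(dim) || length(dim) != 1L || dim <= 1 || dim >= 2)
    stop("generate_weierstrass: dim must lie strictly inside (1, 2)")
  if (lambda <= 1) stop("generate_weierstrass: lambda must exceed 1")
  n <- as.integer(n)
  if (n < 64L) stop("generate_weierstrass: n must be >= 64")
  if (is.null(n_harmonics))
    n_harmonics <- floor(log(n / 2) / log(lambda)) + 1L
  n_harmonics <- as.integer(n_harmonics)
  if (n_harmonics < 1L) stop("generate_weierstrass: n_harmonics must be >= 1")
  h <- 2 - dim
  t <- (0:(n - 1L)) / n
  x <- numeric(n)
  for (k in 0:(n_harmonics - 1L))
    x <- x + lambda^(-k * h) * cos(2 * pi * lambda^k * t)
  eeg_segment(x, sampling_rate = sampling_rate,
              source_id = sprintf("weierstrass_d%.3f", dim))
}

#' Specification of a synthetic Bonn-style corpus
#'
#' Parameter bundle for [generate_bonn_mimic()].  Defaults mirror the
#' structure of the Bonn EEG benchmark: five classes (`A`..`E`) of 100
#' segments each, 4097 samples at 173.61 Hz (23.6 s).  Each class profile
#' sets relative spectral weight in the four classical bands, a broadband
#' roughness floor, a target RMS amplitude in microvolts, and a spike rate
#' for the seizure-like class.
#'
#' The default profiles emulate the qualitative morphology of the
#' benchmark: the normal-like classes `A`/`B` are alpha-dominant with a
#' substantial broadband component (rough, low amplitude); the
#' interictal-like classes `C`/`D` mix theta/delta with intermediate
#' roughness; the seizure-like class `E` is a large-amplitude low-frequency
#' oscillation with superimposed sharp transients and almost no broadband
#' floor, hence smoother waveforms (lower Katz dimension) at much higher
#' amplitude.  No claim of clinical realism is made.
#'
#' @param n_classes Number of classes, 1..5 (labels are taken from
#'   `A`..`E` in order).
#' @param segments_per_class Segments generated per class.
#' @param n_samples Samples per segment (>= 64).
#' @param sampling_rate Sampling rate in Hz; must exceed twice the highest
#'   band edge (30 Hz).
#' @param seed Integer seed making the corpus reproducible.
#' @param class_profiles Named list of per-class profiles as produced by
#'   the default; each holds `band_weights` (named delta/theta/alpha/beta),
#'   `broadband`, `rms_uV`, `spike_rate_hz`.
#' @return An object of class `corpus_spec`.
#' @export
synthetic_corpus_spec <- function(n_classes = 5L, segments_per_class = 100L,
                                  n_samples = 4097L, sampling_rate = 173.61,
                                  seed = 0L, class_profiles = NULL) {
  n_classes <- as.integer(n_classes)
  segments_per_class <- as.integer(segments_per_class)
  n_samples <- as.integer(n_samples)
  if (n_classes < 1L || n_classes > 5L)
    stop("synthetic_corpus_spec: n_classes must be between 1 and 5")
  if (segments_per_class < 1L)
    stop("synthetic_corpus_spec: segments_per_class must be >= 1")
  if (n_samples < 64L)
    stop("synthetic_corpus_spec: n_samples must be >= 64")
  if (sampling_rate <= 2 * 30)
    stop("synthetic_corpus_spec: sampling_rate must exceed 60 Hz (2 x 30 Hz)")
  if (is.null(class_profiles)) class_profiles <- default_class_profiles()
  labels <- c("A", "B", "C", "D", "E")[seq_len(n_classes)]
  missing <- setdiff(labels, names(class_profiles))
  if (length(missing))
    stop("synthetic_corpus_spec: no profile for class ",
         paste(missing, collapse = ", "))
  structure(list(n_classes = n_classes,
                 segments_per_class = segments_per_class,
                 n_samples = n_samples,
                 sampling_rate = sampling_rate,
                 seed = as.integer(seed),
                 labels = labels,
                 class_profiles = class_profiles[labels]),
            class = "corpus_spec")
}

default_class_profiles <- function() {
  prof <- function(delta, theta, alpha, beta, broadband, rms, spikes = 0) {
    list(band_weights = c(delta = delta, theta = theta,
                          alpha = alpha, beta = beta),
         broadband = broadband, rms_uV = rms, spike_rate_hz = spikes)
  }
  list(
    A = prof(0.5, 0.7, 2.0, 0.8, broadband = 0.35, rms = 40),
    B = prof(0.6, 0.8, 2.5, 0.6, broadband = 0.30, rms = 50),
    C = prof(1.2, 1.8, 0.8, 0.4, broadband = 0.20, rms = 60),
    D = prof(1.5, 1.6, 0.6, 0.4, broadband = 0.15, rms = 70),
    E = prof(3.5, 0.5, 0.1, 0.05, broadband = 0.01, rms = 250,
             spikes = 0.5)
  )
}

#' Generate a labeled synthetic corpus mimicking the Bonn structure
#'
#' Draws `segments_per_class` segments for each class in `spec` by spectral
#' shaping: a white Gaussian spectrum is weighted with smooth band bumps
#' plus a broadband floor according to the class profile, inverse-FFT'd,
#' scaled to the class RMS amplitude, and (for spike-bearing classes)
#' decorated with sharp biphasic transients at Poisson times.  The corpus
#' is a pure function of the spec, including its seed.
#'
#' @param spec A [synthetic_corpus_spec()].
#' @return A list of [eeg_segment]s of length
#'   `n_classes * segments_per_class`, labels balanced by construction.
#' @examples
#' spec <- synthetic_corpus_spec(segments_per_class = 2, n_samples = 512)
#' corpus <- generate_bonn_mimic(spec)
#' table(vapply(corpus, attr, "", "label"))
#' @export
generate_bonn_mimic <- function(spec) {
  if (!inherits(spec, "corpus_spec"))
    stop("generate_bonn_mimic: spec must be a synthetic_corpus_spec()")
  n <- spec$n_samples
  fs <- spec$sampling_rate
  freqs <- seq(0, fs / 2, length.out = n %/% 2L + 1L)
  bands <- list(delta = c(0.5, 4), theta = c(4, 8),
                alpha = c(8, 14), beta = c(14, 30))
  out <- vector("list", spec$n_classes * spec$segments_per_class)
  i <- 0L
  with_seed(spec$seed, {
    for (lab in spec$labels) {
      p <- spec$class_profiles[[lab]]
      env <- spectral_envelope(freqs, p$band_weights, p$broadband)
      for (s in seq_len(spec$segments_per_class)) {
        x <- shaped_noise(n, env)
        if (p$spike_rate_hz > 0)
          x <- add_spikes(x, fs, p$spike_rate_hz)
        x <- x * (p$rms_uV / stats::sd(x))
        i <- i + 1L
        out[[i]] <- eeg_segment(x, sampling_rate = fs, label = lab,
                                source_id = sprintf("%s%03d", lab, s))
      }
    }
  })
  out
}

# smooth per-band Gaussian bumps + broadband floor over the rfft grid
spectral_envelope <- function(freqs, band_weights, broadband) {
  bands <- list(delta = c(0.5, 4), theta = c(4, 8),
                alpha = c(8, 14), beta = c(14, 30))
  env <- rep(broadband, length(freqs))
  for (b in names(bands)) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    ctr <- (lo + hi) / 2
    width <- (hi - lo) / 2
    env <- env + band_weights[[b]] * exp(-((freqs - ctr) / width)^2)
  }
  env[1L] <- 0           # no DC
  env
}

# real signal with amplitude spectrum shaped by `env` (white phases)
shaped_noise <- function(n, env) {
  nf <- n %/% 2L + 1L
  re <- stats::rnorm(nf)
  im <- stats::rnorm(nf)
  spec <- complex(real = re, imaginary = im) * env
  spec[1L] <- 0
  if (n %% 2L == 0L) spec[nf] <- complex(real = re[nf] * env[nf], imaginary = 0)
  full <- c(spec, Conj(rev(spec[2:(nf - 1L + (n %% 2L))])))
  full <- full[1:n]
  Re(stats::fft(full, inverse = TRUE)) / sqrt(n)
}

# biphasic transients at Poisson times, ~150 ms wide, 2.5x running scale
add_spikes <- function(x, fs, rate_hz) {
  n <- length(x)
  n_spikes <- stats::rpois(1, rate_hz * n / fs)
  if (n_spikes == 0) return(x)
  half <- max(2L, round(0.075 * fs))
  shape <- c(seq(0, 1, length.out = half), seq(1, -0.5, length.out = half),
             seq(-0.5, 0, length.out = half))
  amp <- 2.5 * stats::sd(x)
  at <- sample.int(n - length(shape), n_spikes, replace = TRUE)
  for (t0 in at) {
    idx <- t0 + seq_along(shape) - 1L
    x[idx] <- x[idx] + amp * shape * stats::runif(1, 0.7, 1.3)
  }
  x
}
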