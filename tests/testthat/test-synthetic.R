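test_that("fGn generator reproduces the closed-form autocovariance", {
  gam <- function(k, h) 0.5 * (abs(k + 1)^(2 * h) - 2 * abs(k)^(2 * h) +
                                 abs(k - 1)^(2 * h))
  n <- 4096
  lags <- 0:5
  acvf <- matrix(0, 50, length(lags))
  for (s in 1:50) {
    x <- as.numeric(generate_fgn(0.8, n, seed = s))
    # process mean is known to be zero; no mean subtraction (the subtracted
    # estimator is biased low by Var(mean) ~ n^(2H-2) under persistence)
    acvf[s, ] <- vapply(lags, function(k)
      sum(x[1:(n - k)] * x[(k + 1):n]) / (n - k), numeric(1))
  }
  mc_se <- apply(acvf, 2, stats::sd) / sqrt(nrow(acvf))
  expect_true(all(abs(colMeans(acvf) - gam(lags, 0.8)) < 4 * mc_se + 0.01))
})

test_that("fGn at H = 0.5 is uncorrelated white noise", {
  r1 <- vapply(1:20, function(s) {
    x <- as.numeric(generate_fgn(0.5, 4096, seed = s))
    stats::cor(x[-1], x[-length(x)])
  }, numeric(1))
  expect_lt(abs(mean(r1)), 0.05)
})

test_that("fGn is deterministic in (hurst, n, seed) and validates hurst", {
  expect_identical(as.numeric(generate_fgn(0.7, 256, seed = 9)),
                   as.numeric(generate_fgn(0.7, 256, seed = 9)))
  expect_false(identical(as.numeric(generate_fgn(0.7, 256, seed = 9)),
                         as.numeric(generate_fgn(0.7, 256, seed = 10))))
  expect_error(generate_fgn(0, 256, seed = 1), "hurst")
  expect_error(generate_fgn(1.2, 256, seed = 1), "hurst")
})

test_that("aggregated-variance scaling of fGn follows m^(2H-2)", {
  ms <- 2^(0:6)
  for (h in c(0.3, 0.5, 0.8)) {
    slopes <- vapply(1:20, function(s) {
      x <- as.numeric(generate_fgn(h, 4096, seed = 200 + s))
      v <- vapply(ms, function(m) {
        agg <- colMeans(matrix(x[1:(m * (length(x) %/% m))], nrow = m))
        mean(agg^2)
      }, numeric(1))
      stats::coef(stats::lm(log(v) ~ log(ms)))[2]
    }, numeric(1))
    expect_lt(abs(mean(slopes) - (2 * h - 2)), 0.1)
  }
})

test_that("Weierstrass signal truncates to a pure cosine and obeys limits", {
  n <- 512
  w <- generate_weierstrass(1.5, n, n_harmonics = 1)
  expect_equal(as.numeric(w), cos(2 * pi * (0:(n - 1)) / n), tolerance = 1e-12)
  smooth <- generate_weierstrass(1.001, 4096)
  expect_lt(higuchi_fd(smooth, 30), 1.2)
  expect_error(generate_weierstrass(2.3, 512), "dim")
})

test_that("Bonn-mimic corpus is balanced, labeled and seed-deterministic", {
  spec <- synthetic_corpus_spec(segments_per_class = 3, n_samples = 256,
                                seed = 11)
  corpus <- generate_bonn_mimic(spec)
  expect_length(corpus, 15)
  labs <- vapply(corpus, attr, "", "label")
  expect_equal(unname(table(labs)), array(rep(3L, 5)), ignore_attr = TRUE)
  spec2 <- synthetic_corpus_spec(n_classes = 2, segments_per_class = 3,
                                 n_samples = 256, seed = 11)
  expect_length(generate_bonn_mimic(spec2), 6)
  again <- generate_bonn_mimic(spec)
  expect_identical(lapply(corpus, as.numeric), lapply(again, as.numeric))
})

test_that("seizure-like class has higher amplitude but smoother waveform", {
  spec <- synthetic_corpus_spec(segments_per_class = 15, seed = 5)
  corpus <- generate_bonn_mimic(spec)
  labs <- vapply(corpus, attr, "", "label")
  kfd <- vapply(corpus, katz_fd, numeric(1))
  rms <- vapply(corpus, function(s) stats::sd(as.numeric(s)), numeric(1))
  ka <- kfd[labs == "A"]; ke <- kfd[labs == "E"]
  pooled_z <- (mean(ka) - mean(ke)) /
    sqrt(stats::var(ka) / length(ka) + stats::var(ke) / length(ke))
  expect_gt(pooled_z, 3)                       # E smoother: lower KFD
  expect_gt(mean(rms[labs == "E"]), 3 * mean(rms[labs == "A"]))
})

test_that("corpus spec validates its invariants", {
  expect_error(synthetic_corpus_spec(n_samples = 32), "n_samples")
  expect_error(synthetic_corpus_spec(segments_per_class = 0),
               "segments_per_class")
  expect_error(synthetic_corpus_spec(sampling_rate = 50), "sampling_rate")
})
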