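test_that("Higuchi dimension matches the literal curve-length transcription", {
  set.seed(101)
  for (i in 1:50) {
    x <- rnorm(512)
    expect_equal(higuchi_fd(x, p_max = 20), higuchi_naive(x, 20),
                 tolerance = 1e-10)
  }
})

test_that("Higuchi recovers known dimensions", {
  expect_equal(higuchi_fd(as.numeric(1:1000), p_max = 30), 1,
               tolerance = 0.01)
  wfd <- higuchi_fd(generate_weierstrass(1.5, 4096), p_max = 30)
  expect_equal(wfd, 1.5, tolerance = 0.1)
})

test_that("Higuchi refuses flat and too-short signals", {
  expect_error(higuchi_fd(rep(2, 400), p_max = 30), "flat")
  expect_error(higuchi_fd(rnorm(100), p_max = 30), "too short")
})

test_that("Higuchi dimension of fBm decreases with the Hurst index", {
  fd_at <- function(h) vapply(1:20, function(s)
    higuchi_fd(cumsum(as.numeric(generate_fgn(h, 2048, seed = 300 + s))),
               p_max = 30), numeric(1))
  expect_gt(mean(fd_at(0.2)), mean(fd_at(0.8)))
})

test_that("Katz dimension matches literal evaluation and hand values", {
  expect_equal(katz_fd(c(0, 1, 2, 3)), 1, tolerance = 1e-12)
  # zig-zag: U = 3*sqrt(2), b = sqrt(10), n = 3
  k_hand <- log10(3) / (log10(sqrt(10) / (3 * sqrt(2))) + log10(3))
  expect_equal(katz_fd(c(0, 1, 0, 1)), k_hand, tolerance = 1e-12)
  expect_equal(k_hand, 1.365, tolerance = 1e-3)
  set.seed(7)
  for (i in 1:50) {
    x <- rnorm(sample(5:20, 1))
    expect_equal(katz_fd(x), katz_naive(x), tolerance = 1e-10)
  }
})

test_that("Katz dimension is amplitude dependent but defined for constants", {
  expect_false(isTRUE(all.equal(katz_fd(c(0, 1, 0, 1)),
                                katz_fd(c(0, 2, 0, 2)))))
  expect_equal(katz_fd(rep(3, 10)), 1)     # horizontal straight line
  expect_error(katz_fd(c(1, 2)), "3 samples")
})

test_that("rescaled-range estimator recovers the fGn Hurst index", {
  est <- vapply(1:20, function(s)
    hurst_exponent(generate_fgn(0.7, 4096, seed = 400 + s)), numeric(1))
  expect_equal(mean(est), 0.7, tolerance = 0.1)
  wn <- vapply(1:20, function(s) {
    set.seed(500 + s)
    hurst_exponent(rnorm(4096))
  }, numeric(1))
  expect_equal(mean(wn), 0.5, tolerance = 0.1)
})

test_that("Hurst estimation refuses constant or too-short input", {
  expect_error(hurst_exponent(rep(1, 256)), "block")
  expect_error(hurst_exponent(rnorm(32)), "too short")
  expect_error(hurst_exponent(rnorm(256), min_block = 4), "min_block")
})

test_that("LZ76 complexity reproduces hand-parsed examples", {
  # constant: "0000" parses as 0|000 -> c = 2, C = 2/(4/log2 4) = 1
  expect_equal(lz_complexity(c(5, 5, 5, 5), "mean"), 1)
  # alternating: "010101" parses as 0|1|0101 -> c = 3
  expect_equal(lz_complexity(c(1, 2, 1, 2, 1, 2), "mean"),
               3 * log2(6) / 6, tolerance = 1e-12)
})

test_that("LZ76 parser agrees with the brute-force exhaustive history", {
  set.seed(13)
  for (i in 1:100) {
    bits <- sample(0:1, 500, replace = TRUE)
    expect_identical(eegrhythms:::lz76_count(bits), lz76_naive(bits))
  }
})

test_that("normalized complexity of random sequences concentrates near 1", {
  cs <- vapply(1:20, function(s) {
    set.seed(600 + s)
    lz_complexity(sample(c(-1, 1), 4096, replace = TRUE), "mean")
  }, numeric(1))
  expect_true(all(cs >= 0.8 & cs <= 1.2))
})

test_that("mean and median margins can differ on skewed signals", {
  x <- c(12.4, 44.2, 10.5, 10.4, 18.8, 6.5, 3.4, 5.9, 23.6, 6.4, 2.9, 5.7)
  expect_false(isTRUE(all.equal(lz_complexity(x, "mean"),
                                lz_complexity(x, "median"))))
})

test_that("extract_features yields 30 named values with Table-style names", {
  bank <- decompose(generate_fgn(0.5, 512, seed = 21))
  fv <- extract_features(bank)
  expect_length(fv, 30)
  expect_true(all(c("KFD(Beta)", "HFD_kmax=45(Beta)", "KFD(Theta)",
                    "Hurst(Original Signal)", "LZC_median(Delta)")
                  %in% names(fv)))
  expect_true(all(is.finite(fv)))
  expect_false(attr(fv, "incomplete"))
  expect_true(all(fv[grep("^Hurst", names(fv))] >= 0 &
                    fv[grep("^Hurst", names(fv))] <= 1))
})

test_that("undefined measures propagate as flagged missing values", {
  const <- eeg_segment(rep(7, 512))
  bank <- decompose(const)
  # flat original: Hurst and Higuchi are undefined, KFD/LZC stay defined
  w <- capture_warnings(fv <- extract_features(bank))
  expect_true(any(grepl("Hurst", w)))
  expect_true(is.na(fv[["Hurst(Original Signal)"]]))
  expect_equal(fv[["KFD(Original Signal)"]], 1)
  expect_equal(fv[["LZC_mean(Original Signal)"]],
               2 / (512 / log2(512)))
  expect_true(attr(fv, "incomplete"))
})

test_that("feature matrix assembly keeps ids, labels and all 30 columns", {
  spec <- synthetic_corpus_spec(segments_per_class = 2, n_samples = 256,
                                seed = 2)
  fm <- extract_feature_matrix(generate_bonn_mimic(spec))
  expect_equal(dim(fm), c(10, 32))
  expect_identical(colnames(fm)[1:2], c("source_id", "label"))
  expect_identical(colnames(fm)[-(1:2)], feature_names())
})
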