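test_that("difference features match hand computations", {
  expect_equal(first_difference(rep(3, 10)), 0)
  expect_equal(first_difference(c(0, 1, 0, 1)), 1)
  expect_equal(first_difference(c(1, 3, 2)), 1.5)
  expect_equal(second_difference(c(0, 1, 0, 1)), 0)
  expect_equal(second_difference(rep(2, 5)), 0)
  set.seed(1); x <- rnorm(100)
  expect_equal(norm_first_difference(4 * x), norm_first_difference(x))
  expect_error(first_difference(1), "at least 2")
  expect_error(norm_first_difference(rep(1, 10)), "zero-variance")
})

test_that("Hjorth parameters hit their closed forms", {
  set.seed(2)
  z <- rnorm(5000)
  h <- hjorth(z / sd(z))
  expect_equal(unname(h["activity"]), 1, tolerance = 1e-6)

  s <- tone(10)
  hs <- hjorth(s)
  expect_equal(unname(hs["complexity"]), 1, tolerance = 1e-3)
  # discrete-difference mobility of a sampled sine: 2*sin(pi*f/fs)
  expect_equal(unname(hs["mobility"]), 2 * sin(pi * 10 / 500),
               tolerance = 1e-2)
  expect_error(hjorth(rep(1, 10)), "zero-variance")
})

test_that("Higuchi fractal dimension spans smooth to noisy", {
  expect_lt(abs(fractal_dimension(seq(0, 1, length.out = 500)) - 1), 0.05)
  set.seed(3)
  fd_noise <- fractal_dimension(rnorm(2000))
  expect_lt(abs(fd_noise - 2), 0.1)
  expect_lt(fractal_dimension(tone(5)), fd_noise)
  expect_error(fractal_dimension(rnorm(50)), "at least 100")
})

test_that("envelope and CVE reach their analytic limits", {
  env <- hilbert_envelope(tone(10))
  expect_lt(sd(env[200:2300]), 0.01)        # constant in the interior
  expect_lt(cve(tone(10)), 0.05)

  # AM tone: envelope 1 + 0.5 cos -> CVE = 0.5/sqrt(2) / 1
  t <- (0:2499) / 500
  am <- (1 + 0.5 * cos(2 * pi * 2 * t)) * cos(2 * pi * 30 * t)
  expect_lt(abs(cve(am) - 0.5 / sqrt(2)) / (0.5 / sqrt(2)), 0.1)

  # Rayleigh envelope of Gaussian noise: sqrt((4 - pi)/pi)
  set.seed(4)
  expect_lt(abs(cve(rnorm(20000)) - sqrt((4 - pi) / pi)) /
            sqrt((4 - pi) / pi), 0.05)
})

test_that("instantaneous frequency and RMFDIF behave on tones and chirps", {
  fi <- instantaneous_frequency(tone(10), 500)
  expect_lt(abs(mean(fi[200:2300]) - 10), 0.05)
  expect_lt(rmfdif(tone(10), 500), 0.1)     # < 1% of the tone frequency

  # linear chirp 5 -> 25 Hz over 5 s: |diff IF| = rate_chirp / fs;
  # the closed form holds in the leakage-free interior (trim 0.3)
  t <- (0:2499) / 500
  ch <- sin(2 * pi * (5 * t + 2 * t^2))
  expect_lt(abs(rmfdif(ch, 500, trim = 0.3) - 4 / 500) / (4 / 500), 0.1)

  set.seed(5)
  expect_gt(rmfdif(rnorm(2500), 500), 10 * rmfdif(tone(10), 500))
  expect_error(rmfdif(rnorm(16), 500), "at least 32")
})

test_that("Welch PSD and spectral summaries locate a tone", {
  ps <- welch_psd(tone(10), 500)
  sm <- spectral_moments(ps$frequencies, ps$psd)
  expect_lt(abs(sm["centroid"] - 10), 500 / 256)   # within one bin
  expect_equal(smpsd(c(0, 1, 0)), 2)

  # symmetric two-tone spectrum has near-zero spectral skewness
  x2 <- tone(10) + tone(30)
  ps2 <- welch_psd(x2, 500)
  sm2 <- spectral_moments(ps2$frequencies, ps2$psd)
  expect_lt(abs(sm2["skewness"]), 0.1)
  expect_error(spectral_moments(1:4, numeric(4)), "all-zero")
  expect_error(welch_psd(rnorm(32), 500), "at least 64")
})

test_that("the descriptor has 21 canonical entries in two blocks", {
  f <- extract_imf_features(tone(7), 500)
  expect_length(f, 21)
  expect_identical(names(f), feature_names())
  time_block <- feature_names()[1:14]
  freq_block <- feature_names()[15:21]
  expect_length(time_block, 14)
  expect_length(freq_block, 7)
  expect_true(all(c("hjorth_activity", "fractal_dimension") %in% time_block))
  expect_true(all(c("spectral_centroid", "cve", "rmfdif", "smpsd") %in%
                  freq_block))
  # pure function: bitwise identical on repeat
  expect_identical(f, extract_imf_features(tone(7), 500))
})

test_that("feature scale behavior: linear vs amplitude-invariant", {
  set.seed(6)
  x <- as.vector(arima.sim(list(ar = 0.9), 1000))
  a <- 3.7
  f1 <- extract_imf_features(x, 250)
  f2 <- extract_imf_features(a * x, 250)
  linear <- c("std", "max", "min", "first_difference", "second_difference")
  for (nm in linear) expect_equal(f2[[nm]], a * f1[[nm]], tolerance = 1e-9)
  expect_equal(f2[["mean"]], a * f1[["mean"]], tolerance = 1e-9)
  invariant <- c("skewness", "kurtosis", "norm_first_difference",
                 "norm_second_difference", "hjorth_mobility",
                 "hjorth_complexity", "cve")
  for (nm in invariant) expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-8)
})

test_that("all features stay finite over random inputs (property)", {
  set.seed(7)
  for (rep in 1:200) {
    x <- rnorm(256) * exp(rnorm(1))
    f <- extract_imf_features(x, 500)
    expect_true(all(is.finite(f)))
  }
})

test_that("feature maps stack electrodes and normalize columns", {
  ref <- ref512()
  set.seed(8)
  mk_sel <- function(seed) {
    x <- tone(8, n = 512, rate = 128) + 0.3 * rnorm(512)
    deemd_select(eeg_signal(x, 128), ref, ensemble_size = 10, seed = seed)
  }
  sels <- list(A = mk_sel(1), B = mk_sel(2))
  fm <- build_feature_map(sels)
  expect_s3_class(fm, "feature_map")
  expect_equal(ncol(fm$matrix), 21)
  nA <- ncol(sels$A$selected); nB <- ncol(sels$B$selected)
  expect_equal(nrow(fm$matrix), nA + nB)
  expect_equal(fm$electrode_boundaries$label, c("A", "B"))
  expect_equal(fm$electrode_boundaries$last[2], nA + nB)
  # fresh normalization gives zero-mean unit-sd columns
  live <- apply(fm$matrix, 2, sd) > 0
  expect_lt(max(abs(colMeans(fm$matrix[, live]))), 1e-8)
  # re-normalizing an already-normalized map is idempotent
  fm2_norm <- list(mean = colMeans(fm$matrix),
                   sd = pmax(apply(fm$matrix, 2, sd), 1e-12))
  again <- sweep(sweep(fm$matrix, 2, fm2_norm$mean), 2, fm2_norm$sd, "/")
  expect_equal(again[, live], fm$matrix[, live], tolerance = 1e-6)

  one <- build_feature_map(list(solo = sels$A))
  expect_equal(dim(one$matrix), c(nA, 21))
})
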