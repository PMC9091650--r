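test_that("find_extrema locates interior extrema, plateaus, and errors", {
  ex <- find_extrema(c(0, 1, 0, -1, 0, 1, 0))
  expect_equal(ex$maxima, c(2L, 6L))
  expect_equal(ex$minima, 4L)

  mono <- find_extrema(seq_len(10))
  expect_length(mono$maxima, 0)
  expect_length(mono$minima, 0)

  # plateau collapses to its middle index
  expect_equal(find_extrema(c(0, 1, 1, 0))$maxima, 2L)
  expect_equal(find_extrema(c(0, 2, 2, 2, 0, 3, 0))$maxima, c(3L, 6L))
  expect_equal(find_extrema(c(1, 0, 0, 1))$minima, 2L)

  expect_error(find_extrema(c(1, 2)), "at least 3")
})

test_that("maxima and minima interleave (property)", {
  set.seed(42)
  for (rep in 1:20) {
    x <- cumsum(rnorm(200))
    ex <- find_extrema(x)
    pos <- sort(c(ex$maxima, ex$minima))
    kinds <- ifelse(pos %in% ex$maxima, "M", "m")
    if (length(kinds) > 1)
      expect_true(all(kinds[-1] != kinds[-length(kinds)]))
  }
})

test_that("envelope_mean produces symmetric spline envelopes", {
  x <- tone(5)                                    # many cycles
  env <- envelope_mean(x)
  interior <- 100:2400
  expect_lt(max(abs(env$mean[interior])), 0.05)
  expect_true(all(env$upper >= env$lower - 1e-9))
  expect_equal(env$mean, (env$upper + env$lower) / 2)
  # upper envelope hugs the amplitude away from the ends
  expect_lt(max(abs(env$upper[interior] - 1)), 0.05)

  # shift equivariance: constant offset moves the mean envelope by it
  env2 <- envelope_mean(x + 7)
  expect_lt(max(abs(env2$mean[interior] - 7)), 0.06)

  expect_error(envelope_mean(seq_len(100)), "monotone")
})

test_that("envelope matches an independent natural-spline oracle", {
  set.seed(3)
  x <- tone(8) + 0.3 * tone(3, phase = 1)
  ex <- find_extrema(x)
  env <- envelope_mean(x)
  # oracle: stats::spline (natural) through the mirrored maxima
  idx <- ex$maxima
  n <- length(x)
  xs <- c(-(idx[1:2] - 1), idx - 1, 2 * (n - 1) - (rev(idx)[1:2] - 1))
  ys <- c(x[idx[1:2]], x[idx], x[rev(idx)[1:2]])
  keep <- !duplicated(xs)
  oracle <- stats::spline(xs[keep], ys[keep], xout = 0:(n - 1),
                          method = "natural")$y
  expect_lt(max(abs(env$upper - oracle)), 1e-8)
})

test_that("is_imf accepts tones and rejects offsets and mixtures", {
  expect_true(is_imf(tone(5)))
  expect_false(is_imf(tone(5) + 10))              # no zero crossings
  expect_false(is_imf(tone(10) + tone(1)))        # riding waves
})

test_that("emd recovers a single tone with a tiny residue", {
  x <- tone(5)
  d <- emd(eeg_signal(x, 500))
  expect_s3_class(d, "imf_decomposition")
  expect_gt(abs(cor(d$imfs[, 1], x)), 0.99)
  expect_lt(sum(d$residue^2), 0.01 * sum(x^2))
})

test_that("emd separates a 25 Hz and a 2 Hz tone", {
  x25 <- tone(25); x2 <- tone(2)
  d <- emd(eeg_signal(x25 + x2, 500))
  cors <- abs(cor(d$imfs, cbind(x25, x2)))
  expect_gt(cors[1, 1], 0.95)
  expect_gt(max(cors[-1, 2]), 0.95)
})

test_that("emd reconstruction is exact and inputs are validated", {
  set.seed(7)
  x <- rnorm(1000)
  d <- emd(eeg_signal(x, 250))
  expect_lt(max(abs(decomposition_sum(d) - x)), 1e-9 * sd(x))
  expect_error(eeg_signal(c(x[1:100], NA), 250), "finite")
  expect_error(eeg_signal(1:5, 100), "at least 16")
  expect_error(eeg_signal(x, 0), "positive")
})

test_that("eemd degenerates to emd and is seed-deterministic", {
  x <- tone(6) + 0.1 * tone(31)
  s <- eeg_signal(x, 500)
  e0 <- eemd(s, ensemble_size = 1, noise_ratio = 0, seed = 1)
  d <- emd(s)
  expect_equal(e0$imfs, d$imfs)
  expect_equal(e0$residue, d$residue)

  e1 <- eemd(s, ensemble_size = 20, noise_ratio = 0.3, seed = 9)
  e2 <- eemd(s, ensemble_size = 20, noise_ratio = 0.3, seed = 9)
  e3 <- eemd(s, ensemble_size = 20, noise_ratio = 0.3, seed = 10)
  expect_identical(e1$imfs, e2$imfs)
  expect_false(identical(e1$imfs, e3$imfs))
  expect_error(eemd(s, ensemble_size = 0), "positive")
})

test_that("eemd ensemble means reconstruct the ensemble-mean input", {
  # sum(IMFs) + residue = x + mean(added noise); the deviation from x
  # shrinks as noise_ratio/sqrt(N)
  x <- tone(6)
  s <- eeg_signal(x, 500)
  e <- eemd(s, ensemble_size = 50, noise_ratio = 0.3, seed = 2)
  resid <- decomposition_sum(e) - x
  expect_lt(sd(resid), 2 * 0.3 * sd(x) / sqrt(50))
  expect_gt(sd(resid), 0)
})

test_that("residual added noise follows the 1/sqrt(N) law", {
  x <- tone(6)
  s <- eeg_signal(x, 500)
  Ns <- c(10, 50, 100, 500)
  resid_sd <- vapply(Ns, function(N) {
    sd(decomposition_sum(eemd(s, ensemble_size = N, noise_ratio = 0.3,
                              seed = 31)) - x)
  }, numeric(1))
  slope <- coef(lm(log(resid_sd) ~ log(Ns)))[2]
  expect_lt(abs(slope + 0.5), 0.05)
  # at N = 100 the ratio eps_n * sqrt(N) / eps is 1 within 10%
  eps <- 0.3 * sd(x)
  expect_lt(abs(resid_sd[3] * sqrt(100) / eps - 1), 0.1)
})
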