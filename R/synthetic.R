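# spectrally shaped Gaussian noise: multiply the FFT of white noise by
# gain(f) and normalize the result to unit standard deviation
shaped_noise <- function(n, rate, gain) {
  z <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)                    # two-sided frequency axis
  g <- gain(f)
  g[1] <- 0                                 # no DC
  x <- Re(stats::fft(z * g, inverse = TRUE) / n)
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

#' Composite test signal with known modes
#'
#' Sum of pure sinusoids plus Gaussian white noise, returning the
#' ground-truth mode waveforms for mode-recovery tests.
#'
#' @param modes list of `c(freq_hz, amplitude)` pairs; frequencies must be
#'   distinct and below the Nyquist rate.
#' @param noise_sd standard deviation of added white noise.
#' @param length number of samples.
#' @param rate sampling rate in Hz.
#' @param seed RNG seed for the noise.
#' @return list with `signal` (an [eeg_signal]) and `modes` (samples x
#'   n_modes matrix of the clean components).
#' @export
make_composite <- function(modes, noise_sd = 0, length = 2500L, rate = 500,
                           seed = 1L) {
  freqs <- vapply(modes, `[`, numeric(1), 1)
  if (anyDuplicated(freqs)) stop("mode frequencies must be distinct",
                                 call. = FALSE)
  if (any(freqs >= rate / 2)) stop("mode frequency at or above Nyquist",
                                   call. = FALSE)
  t <- (seq_len(length) - 1) / rate
  mode_mat <- vapply(modes, function(m) m[2] * sin(2 * pi * m[1] * t),
                     numeric(length))
  if (length(modes) == 0) mode_mat <- matrix(0, length, 0)
  x <- if (ncol(mode_mat) > 0) rowSums(mode_mat) else numeric(length)
  if (noise_sd > 0)
    x <- x + withr_seed(seed, stats::rnorm(length, sd = noise_sd))
  list(signal = eeg_signal(x, rate, "composite"), modes = mode_mat)
}

#' Specification of a synthetic EEG-like trial
#'
#' Describes the generator for preprocessed-EEG-like trials: band-limited
#' oscillatory components (delta through gamma, all below the 49 Hz
#' preprocessing cut-off), a pink (1/f) broadband background, and a small
#' white-noise floor. Defaults give 5 s trials at 500 Hz (2,500 samples
#' per channel). `class_effect` multiplies the alpha-band amplitude for
#' class-1 trials, giving classifier tests a controllable effect size.
#'
#' @param n_channels electrodes per trial (default 62; test suites use 8).
#' @param duration_s trial length in seconds.
#' @param rate sampling rate in Hz.
#' @param bands data.frame with columns `center`, `bandwidth`, `amplitude`
#'   (Hz, Hz, amplitude s.d.).
#' @param pink_amplitude s.d. of the 1/f background component.
#' @param white_amplitude s.d. of the white-noise floor.
#' @param class_effect multiplicative alpha-band amplitude factor for
#'   class 1 (1.0 = no class difference).
#' @return list of class `trial_spec`.
#' @export
trial_spec <- function(n_channels = 62L, duration_s = 5, rate = 500,
                       bands = data.frame(
                         name = c("delta", "theta", "alpha", "beta", "gamma"),
                         center = c(2, 6, 10, 20, 40),
                         bandwidth = c(1.5, 2, 2, 6, 8),
                         amplitude = c(2, 1.5, 1.5, 1, 0.5)),
                       pink_amplitude = 1, white_amplitude = 0.3,
                       class_effect = 1) {
  stopifnot(all(bands$amplitude >= 0), pink_amplitude >= 0,
            white_amplitude >= 0, rate > 0, duration_s > 0)
  structure(list(n_channels = as.integer(n_channels),
                 duration_s = duration_s, rate = rate, bands = bands,
                 pink_amplitude = pink_amplitude,
                 white_amplitude = white_amplitude,
                 class_effect = class_effect,
                 n_samples = as.integer(round(rate * duration_s))),
            class = "trial_spec")
}

# one channel: sum of narrowband components + pink background + white floor
synth_channel <- function(spec, alpha_factor) {
  n <- spec$n_samples; rate <- spec$rate
  x <- numeric(n)
  for (i in seq_len(nrow(spec$bands))) {
    b <- spec$bands[i, ]
    amp <- b$amplitude * if (b$name == "alpha") alpha_factor else 1
    if (amp == 0) next
    x <- x + amp * shaped_noise(n, rate, function(f)
      exp(-(f - b$center)^2 / (2 * (b$bandwidth / 2)^2)))
  }
  if (spec$pink_amplitude > 0)
    x <- x + spec$pink_amplitude *
      shaped_noise(n, rate, function(f) ifelse(f > 0.5, 1 / sqrt(f), 0))
  if (spec$white_amplitude > 0)
    x <- x + stats::rnorm(n, sd = spec$white_amplitude)
  x
}

#' Generate one synthetic multichannel trial
#'
#' @param spec a [trial_spec()].
#' @param label class label 0 or 1 (class 1 gets the alpha-band
#'   `class_effect` factor).
#' @param seed RNG seed.
#' @return numeric matrix, samples x channels, with channel-name columns.
#' @export
make_trial <- function(spec, label = 0L, seed = 1L) {
  stopifnot(inherits(spec, "trial_spec"))
  alpha_factor <- if (label == 1L) spec$class_effect else 1
  withr_seed(seed, {
    m <- vapply(seq_len(spec$n_channels),
                function(ch) synth_channel(spec, alpha_factor),
                numeric(spec$n_samples))
    colnames(m) <- paste0("ch", seq_len(spec$n_channels))
    m
  })
}

#' Generate a labeled synthetic dataset
#'
#' Balanced (or otherwise) binary labels; per-trial seeds are derived from
#' the master seed so generation is fully reproducible and individual
#' trials can be regenerated in isolation.
#'
#' @param spec a [trial_spec()].
#' @param n_trials number of trials (>= 2).
#' @param class_balance fraction of class-1 trials, strictly in (0, 1).
#' @param seed master seed.
#' @return list of `list(data = samples x channels matrix, label = 0/1,
#'   seed = per-trial seed)`.
#' @export
make_labeled_dataset <- function(spec, n_trials, class_balance = 0.5,
                                 seed = 1L) {
  if (n_trials < 2L) stop("need at least 2 trials", call. = FALSE)
  if (class_balance <= 0 || class_balance >= 1)
    stop("class_balance must be strictly inside (0, 1)", call. = FALSE)
  n1 <- round(n_trials * class_balance)
  if (n1 == 0 || n1 == n_trials)
    stop("degenerate class balance for this n_trials", call. = FALSE)
  labels <- withr_seed(seed, sample(c(rep(1L, n1),
                                      rep(0L, n_trials - n1))))
  lapply(seq_len(n_trials), function(i) {
    trial_seed <- (seed * 10000L + i) %% .Machine$integer.max
    list(data = make_trial(spec, labels[i], trial_seed),
         label = labels[i], seed = trial_seed)
  })
}
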