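#' Mean absolute first difference
#'
#' `Dt = mean(|x(n+1) - x(n)|)`, the intensity of change of the series.
#'
#' @param imf numeric vector, length >= 2.
#' @return numeric scalar.
#' @export
first_difference <- function(imf) {
  x <- as.numeric(imf)
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  mean(abs(diff(x)))
}

#' Mean absolute second difference
#'
#' `mean(|x(n+2) - x(n)|)`.
#'
#' @param imf numeric vector, length >= 3.
#' @return numeric scalar.
#' @export
second_difference <- function(imf) {
  x <- as.numeric(imf)
  if (length(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  mean(abs(x[-(1:2)] - x[seq_len(length(x) - 2L)]))
}

#' Normalized differences
#'
#' First/second differences divided by the standard deviation of the
#' series, making them amplitude-invariant.
#'
#' @param imf numeric vector.
#' @return numeric scalar.
#' @export
norm_first_difference <- function(imf) {
  s <- stats::sd(imf)
  if (s == 0) stop("undefined for zero-variance input", call. = FALSE)
  first_difference(imf) / s
}

#' @rdname norm_first_difference
#' @export
norm_second_difference <- function(imf) {
  s <- stats::sd(imf)
  if (s == 0) stop("undefined for zero-variance input", call. = FALSE)
  second_difference(imf) / s
}

#' Hjorth parameters
#'
#' Activity is the variance; mobility is `sd(x') / sd(x)` with `x'` the
#' first-difference sequence (a root-mean-square frequency proxy);
#' complexity is `mobility(x') / mobility(x)` (a bandwidth proxy, 1 for a
#' pure sinusoid).
#'
#' @param imf numeric vector, length >= 3, nonzero variance.
#' @return named numeric vector `c(activity, mobility, complexity)`.
#' @export
hjorth <- function(imf) {
  x <- as.numeric(imf)
  if (length(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  v0 <- stats::var(x)
  if (v0 == 0) stop("undefined for zero-variance input", call. = FALSE)
  d1 <- diff(x); d2 <- diff(d1)
  v1 <- stats::var(d1); v2 <- stats::var(d2)
  mob <- sqrt(v1 / v0)
  c(activity = v0, mobility = mob, complexity = sqrt(v2 / v1) / mob)
}

#' Higuchi fractal dimension
#'
#' Curve-length based fractal dimension: for each delay `k <= k_max` the
#' mean normalized curve length `L(k)` is computed over the `k` possible
#' offsets; the dimension is the slope of `log L(k)` against `log(1/k)`.
#' Smooth curves give about 1, Gaussian white noise about 2.
#'
#' @param imf numeric vector, length >= 100.
#' @param k_max largest delay (default 8).
#' @return numeric scalar.
#' @export
fractal_dimension <- function(imf, k_max = 8L) {
  x <- as.numeric(imf)
  n <- length(x)
  if (n < 100L) stop("need at least 100 samples", call. = FALSE)
  Lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      ni <- length(idx) - 1L
      if (ni < 1L) { Lm[m] <- NA; next }
      Lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (ni * k) / k
    }
    Lk[k] <- mean(Lm, na.rm = TRUE)
  }
  ok <- Lk > 0
  if (sum(ok) < 2L) return(1)
  -unname(stats::coef(stats::lm(log(Lk[ok]) ~ log(seq_len(k_max)[ok])))[2])
}

# analytic signal via FFT: zero out negative frequencies, double positives
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert envelope
#'
#' Modulus of the analytic signal `x + i * H(x)` computed by FFT.
#'
#' @param imf numeric vector, length >= 16.
#' @return numeric vector of instantaneous amplitudes.
#' @export
hilbert_envelope <- function(imf) {
  x <- as.numeric(imf)
  if (length(x) < 16L) stop("need at least 16 samples", call. = FALSE)
  Mod(analytic_signal(x))
}

# drop `frac` of samples from each end (Hilbert edge artifacts)
trim_edges <- function(x, frac = 0.05) {
  n <- length(x)
  k <- floor(n * frac)
  if (2 * k >= n) return(x)
  x[(k + 1):(n - k)]
}

#' Coefficient of variation of the envelope
#'
#' `CVE = sd(env) / mean(env)` on the boundary-trimmed Hilbert envelope.
#' Near 0 for a pure tone (constant envelope) and about
#' `sqrt((4 - pi)/pi) = 0.523` for Gaussian noise (Rayleigh envelope).
#'
#' @param imf numeric vector, length >= 16.
#' @param trim fraction trimmed from each end before the moments
#'   (default 0.05).
#' @return numeric scalar >= 0.
#' @export
cve <- function(imf, trim = 0.05) {
  env <- trim_edges(hilbert_envelope(imf), trim)
  m <- mean(env)
  if (m == 0) stop("undefined for an all-zero signal", call. = FALSE)
  stats::sd(env) / m
}

# unwrap phase: remove 2*pi jumps
unwrap_phase <- function(p) {
  d <- diff(p)
  jumps <- round(d / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

#' Instantaneous frequency of an IMF
#'
#' Derivative of the unwrapped analytic phase: `f[n] = rate *
#' (phi[n+1] - phi[n]) / (2 * pi)` in Hz.
#'
#' @param imf numeric vector, length >= 32.
#' @param rate sampling rate in Hz.
#' @return numeric vector of length `length(imf) - 1`.
#' @export
instantaneous_frequency <- function(imf, rate) {
  x <- as.numeric(imf)
  if (length(x) < 32L) stop("need at least 32 samples", call. = FALSE)
  phase <- unwrap_phase(Arg(analytic_signal(x)))
  diff(phase) * rate / (2 * pi)
}

#' Mean absolute successive difference of instantaneous frequency
#'
#' Frequency-variability descriptor: the mean of `|diff(f_i)|` over the
#' edge-trimmed instantaneous-frequency track. Near zero for tones and
#' linear chirps, large for noise.
#'
#' @inheritParams instantaneous_frequency
#' @param trim fraction trimmed from each end of the IF track before the
#'   mean (default 0.05, suppressing Hilbert edge artifacts).
#' @return numeric scalar in Hz.
#' @export
rmfdif <- function(imf, rate, trim = 0.05) {
  fi <- trim_edges(instantaneous_frequency(imf, rate), trim)
  mean(abs(diff(fi)))
}

#' Welch power spectral density
#'
#' Mean of modified periodograms over Hann-windowed segments with 50%
#' overlap; segment length `min(256, floor(n/2))`. One-sided density.
#'
#' @param imf numeric vector, length >= 64.
#' @param rate sampling rate in Hz.
#' @param segment segment length override.
#' @return list with `frequencies` (Hz) and `psd`.
#' @export
welch_psd <- function(imf, rate, segment = NULL) {
  x <- as.numeric(imf)
  n <- length(x)
  if (n < 64L) stop("need at least 64 samples", call. = FALSE)
  if (is.null(segment)) segment <- min(256L, n %/% 2L)
  segment <- as.integer(segment)
  step <- max(1L, segment %/% 2L)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(segment) / (segment + 1))  # Hann
  starts <- seq(1L, n - segment + 1L, by = step)
  nf <- segment %/% 2L + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + segment - 1L)] * w
    P <- Mod(stats::fft(seg))^2 / (rate * sum(w^2))
    half <- P[seq_len(nf)]
    if (segment %% 2 == 0) half[2:(nf - 1L)] <- 2 * half[2:(nf - 1L)]
    else half[2:nf] <- 2 * half[2:nf]
    acc <- acc + half
  }
  list(frequencies = (seq_len(nf) - 1) * rate / segment,
       psd = acc / length(starts))
}

#' Index-weighted spectral moment of a PSD
#'
#' `SMPSD = sum(k * PSD_k)` over 1-based bin indices.
#'
#' @param psd numeric vector of PSD values.
#' @return numeric scalar.
#' @export
smpsd <- function(psd) {
  sum(seq_along(psd) * psd)
}

#' PSD-weighted spectral moments
#'
#' Treats the PSD (normalized to unit sum) as a distribution over
#' frequency and returns its mean (centroid, Hz), variance, and
#' standardized third and fourth moments.
#'
#' @param frequencies numeric vector in Hz.
#' @param psd matching PSD values, not all zero.
#' @return named vector `c(centroid, variance, skewness, kurtosis)`.
#' @export
spectral_moments <- function(frequencies, psd) {
  tot <- sum(psd)
  if (tot <= 0) stop("undefined for an all-zero PSD", call. = FALSE)
  w <- psd / tot
  c0 <- sum(w * frequencies)
  v <- sum(w * (frequencies - c0)^2)
  if (v == 0)
    return(c(centroid = c0, variance = 0, skewness = 0, kurtosis = 0))
  c(centroid = c0, variance = v,
    skewness = sum(w * (frequencies - c0)^3) / v^1.5,
    kurtosis = sum(w * (frequencies - c0)^4) / v^2)
}

#' Canonical feature names
#'
#' The frozen order of the 21 per-IMF features: 14 time-domain followed by
#' 7 frequency-domain descriptors.
#'
#' @return character vector of length 21.
#' @export
feature_names <- function() {
  c("mean", "std", "skewness", "kurtosis", "max", "min",
    "first_difference", "second_difference",
    "norm_first_difference", "norm_second_difference",
    "hjorth_activity", "hjorth_mobility", "hjorth_complexity",
    "fractal_dimension",
    "spectral_centroid", "spectral_variance", "spectral_skewness",
    "spectral_kurtosis", "cve", "rmfdif", "smpsd")
}

#' Extract the 21-dimensional feature vector of one IMF
#'
#' Computes the full descriptor in the canonical [feature_names()] order.
#' In the default lenient mode a feature whose preconditions fail (e.g.
#' zero variance) is reported as `NA`; `strict = TRUE` raises instead.
#'
#' @param imf numeric vector (one IMF).
#' @param rate sampling rate in Hz.
#' @param strict raise on per-feature errors instead of returning `NA`.
#' @param k_max Higuchi delay cap (default 8).
#' @return named numeric vector of length 21.
#' @export
extract_imf_features <- function(imf, rate, strict = FALSE, k_max = 8L) {
  x <- as.numeric(imf)
  grab <- function(expr) {
    if (strict) expr
    else tryCatch(expr, error = function(e) NA_real_)
  }
  hj <- grab(hjorth(x))
  if (length(hj) != 3L) hj <- rep(NA_real_, 3L)
  ps <- grab(welch_psd(x, rate))
  sm <- if (is.list(ps)) grab(spectral_moments(ps$frequencies, ps$psd))
        else rep(NA_real_, 4L)
  if (length(sm) != 4L) sm <- rep(NA_real_, 4L)
  out <- c(
    mean = mean(x), std = stats::sd(x),
    skewness = grab(skewness(x)), kurtosis = grab(kurtosis(x)),
    max = max(x), min = min(x),
    first_difference = grab(first_difference(x)),
    second_difference = grab(second_difference(x)),
    norm_first_difference = grab(norm_first_difference(x)),
    norm_second_difference = grab(norm_second_difference(x)),
    hjorth_activity = unname(hj[1]), hjorth_mobility = unname(hj[2]),
    hjorth_complexity = unname(hj[3]),
    fractal_dimension = grab(fractal_dimension(x, k_max)),
    spectral_centroid = unname(sm[1]), spectral_variance = unname(sm[2]),
    spectral_skewness = unname(sm[3]), spectral_kurtosis = unname(sm[4]),
    cve = grab(cve(x)), rmfdif = grab(rmfdif(x, rate)),
    smpsd = if (is.list(ps)) smpsd(ps$psd) else NA_real_)
  names(out) <- feature_names()
  out
}

#' Stack per-electrode selections into a trial feature map
#'
#' Extracts the 21 features of every selected IMF of every electrode and
#' stacks them electrode-by-electrode (in the order given) into a
#' `sum(N_i) x 21` matrix, then z-normalizes columns. Normalization
#' statistics can be supplied (training-set statistics applied to held-out
#' trials) or computed from the map itself. Electrodes with no selected
#' IMFs contribute zero rows. Non-finite feature values are zeroed after
#' normalization.
#'
#' @param selections named list of `imf_selection` objects, one per
#'   electrode; names are electrode labels.
#' @param rate sampling rate in Hz (defaults to the first selection's).
#' @param normalization optional list with `mean` and `sd` vectors of
#'   length 21; when `NULL` they are computed from this map.
#' @return object of class `feature_map`: `matrix`,
#'   `electrode_boundaries` (data.frame label/first/last row),
#'   `normalization`.
#' @export
build_feature_map <- function(selections, rate = NULL, normalization = NULL) {
  if (length(selections) == 0) stop("no selections supplied", call. = FALSE)
  if (is.null(names(selections)))
    names(selections) <- paste0("ch", seq_along(selections))
  rows <- list(); bounds <- list(); at <- 0L
  for (lab in names(selections)) {
    sel <- selections[[lab]]
    stopifnot(inherits(sel, "imf_selection"))
    r <- if (is.null(rate)) sel$decomposition$rate else rate
    sel_mat <- sel$selected
    k <- ncol(sel_mat)
    if (k > 0) {
      f <- t(vapply(seq_len(k),
                    function(j) extract_imf_features(sel_mat[, j], r),
                    numeric(21L)))
      rows[[lab]] <- f
    }
    bounds[[lab]] <- data.frame(label = lab, first = at + 1L, last = at + k)
    at <- at + k
  }
  mat <- do.call(rbind, rows)
  if (is.null(mat) || nrow(mat) == 0)
    stop("no electrode contributed a selected IMF", call. = FALSE)
  colnames(mat) <- feature_names()
  if (is.null(normalization)) {
    mu <- colMeans(mat, na.rm = TRUE)
    sdv <- apply(mat, 2, stats::sd, na.rm = TRUE)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    mu[!is.finite(mu)] <- 0
    normalization <- list(mean = mu, sd = sdv)
  }
  mat <- sweep(sweep(mat, 2, normalization$mean), 2, normalization$sd, "/")
  mat[!is.finite(mat)] <- 0
  structure(list(matrix = mat,
                 electrode_boundaries = do.call(rbind, bounds),
                 normalization = normalization),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map> %d IMFs x %d features over %d electrodes\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$electrode_boundaries)))
  invisible(x)
}
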