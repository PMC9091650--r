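#' Locate local extrema
#'
#' Finds all interior local maxima and minima. Runs of equal consecutive
#' values (plateaus) are collapsed to a single extremum at the plateau's
#' middle index; plateaus touching either end of the vector are ignored.
#'
#' @param samples numeric vector, length >= 3.
#' @return list with integer vectors `maxima` and `minima` (1-based indices).
#' @examples
#' find_extrema(c(0, 1, 0, -1, 0, 1, 0))
#' @export
find_extrema <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 3L)
    stop("need at least 3 samples to locate extrema", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("samples must be finite", call. = FALSE)
  .find_extrema_cpp(samples)
}

#' Upper/lower cubic-spline envelopes and their mean
#'
#' Interpolates the local maxima (minima) with a natural cubic spline to form
#' the upper (lower) envelope. The two extrema nearest each end are mirrored
#' across the boundary sample before fitting, which suppresses end swings.
#'
#' @param samples numeric vector.
#' @return list of class `envelope_pair` with `upper`, `lower` and `mean`
#'   vectors (same length as input), or an error when the input has fewer
#'   than two maxima or two minima (a monotone residue).
#' @export
envelope_mean <- function(samples) {
  samples <- as.numeric(samples)
  res <- .envelope_cpp(samples)
  if (!isTRUE(res$ok))
    stop("monotone residue: fewer than 2 maxima or 2 minima", call. = FALSE)
  structure(list(upper = res$upper, lower = res$lower, mean = res$mean),
            class = "envelope_pair")
}

# zero crossings: sign changes over the nonzero samples (exact zeros are
# treated as lying on the crossing they separate)
count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

#' Test the intrinsic-mode-function conditions
#'
#' A candidate is an IMF when (a) its numbers of extrema and zero-crossings
#' differ by at most one and (b) the mean of its spline envelopes is locally
#' near zero. Condition (b) cannot hold exactly for discrete data; it is
#' accepted when the mean-envelope RMS is below `tol` times the candidate
#' RMS.
#'
#' @param candidate numeric vector.
#' @param tol relative envelope tolerance (default 0.05).
#' @return logical.
#' @export
is_imf <- function(candidate, tol = 0.05) {
  candidate <- as.numeric(candidate)
  if (!all(is.finite(candidate))) return(FALSE)
  if (length(candidate) < 3L) return(FALSE)
  ex <- .find_extrema_cpp(candidate)
  n_ex <- length(ex$maxima) + length(ex$minima)
  n_zc <- count_zero_crossings(candidate)
  if (abs(n_ex - n_zc) > 1L) return(FALSE)
  env <- .envelope_cpp(candidate)
  if (!isTRUE(env$ok)) return(FALSE)
  rms_m <- sqrt(mean(env$mean^2))
  rms_x <- sqrt(mean(candidate^2))
  rms_x > 0 && rms_m < tol * rms_x
}

default_max_imfs <- function(n) max(1L, floor(log2(n)) - 1L)

new_decomposition <- function(imfs, residue, method, ensemble_size,
                              noise_ratio, seed, rate, label) {
  colnames(imfs) <- if (ncol(imfs) > 0) paste0("IMF", seq_len(ncol(imfs)))
  structure(list(imfs = imfs, residue = residue, method = method,
                 ensemble_size = as.integer(ensemble_size),
                 noise_ratio = noise_ratio,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 rate = rate, label = label),
            class = "imf_decomposition")
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition> %s: %d IMFs + residue, %d samples (%s",
              x$label, ncol(x$imfs), nrow(x$imfs), x$method))
  if (x$method == "EEMD")
    cat(sprintf(", N = %d, noise ratio = %g, seed = %d",
                x$ensemble_size, x$noise_ratio, x$seed))
  cat(")\n")
  invisible(x)
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions by sifting: at each
#' stage the mean of the cubic-spline envelopes is subtracted from the
#' running component; after `max_sift` iterations (or earlier if the
#' Cauchy criterion SD = sum((h_prev - h)^2) / sum(h_prev^2) falls below
#' `sd_tol`) the IMF is removed and sifting restarts on the remainder.
#' Extraction stops when the residue is monotone (fewer than two maxima or
#' two minima) or `max_imfs` is reached. The IMFs plus residue reconstruct
#' the input exactly (telescoping sums).
#'
#' The default is the classical fixed sifting scheme: exactly 10
#' iterations per IMF (`sd_tol = 0` disables the early stop). Fixed-10
#' sifting gives white-noise IMFs the canonical dyadic filter-bank
#' behavior (successive mean periods doubling); the Cauchy stop at 0.2
#' fires after 1-3 iterations and leaves modes too wide-band (period
#' ratio about 2.4). Pass a positive `sd_tol` to restore the Cauchy stop.
#'
#' @param signal an [eeg_signal], or a numeric vector with `rate` supplied.
#' @param max_imfs maximum number of IMFs; default `floor(log2(n)) - 1`.
#' @param sd_tol Cauchy sifting threshold (default 0: disabled).
#' @param max_sift per-IMF sifting iterations (default 10).
#' @param rate sampling rate in Hz, required for bare numeric input.
#' @return An `imf_decomposition`: matrix `imfs` (samples x IMFs,
#'   high-frequency first), vector `residue`, and provenance fields.
#' @examples
#' t <- seq(0, 1, length.out = 512)
#' d <- emd(eeg_signal(sin(2 * pi * 25 * t) + sin(2 * pi * 2 * t), 512))
#' ncol(d$imfs)
#' @export
emd <- function(signal, max_imfs = NULL, sd_tol = 0, max_sift = 10L,
                rate = NULL) {
  s <- as_signal(signal, rate)
  n <- length(s$samples)
  if (is.null(max_imfs)) max_imfs <- default_max_imfs(n)
  if (max_imfs < 1L) stop("max_imfs must be >= 1", call. = FALSE)
  res <- .emd_cpp(s$samples, as.integer(max_imfs), sd_tol,
                  as.integer(max_sift), FALSE)
  new_decomposition(res$imfs, res$residue, "EMD", 1L, 0, NULL,
                    s$rate, s$label)
}

#' Ensemble empirical mode decomposition
#'
#' Runs EMD on `ensemble_size` noise-perturbed copies of the signal
#' (independent Gaussian white noise with standard deviation
#' `noise_ratio * sd(x)`) and averages the IMFs index-wise across the
#' ensemble. Every member is forced to produce exactly `max_imfs` IMFs
#' (zero-padded after its residue turns monotone) so the averages are
#' index-aligned. The returned IMFs plus residue reconstruct the
#' ensemble-mean input, i.e. `x + rowMeans(noise)`.
#'
#' The residual noise left in the averaged IMFs shrinks as
#' `noise_ratio / sqrt(ensemble_size)`.
#'
#' @inheritParams emd
#' @param ensemble_size number of ensemble members N (>= 1).
#' @param noise_ratio ratio of added-noise standard deviation to signal
#'   standard deviation (>= 0). Default 0.3.
#' @param seed integer seed controlling the noise draw; the decomposition is
#'   deterministic given (seed, parameters).
#' @return An `imf_decomposition` with `method = "EEMD"`.
#' @export
eemd <- function(signal, ensemble_size = 100L, noise_ratio = 0.3, seed = 1L,
                 max_imfs = NULL, sd_tol = 0, max_sift = 10L, rate = NULL) {
  s <- as_signal(signal, rate)
  if (length(ensemble_size) != 1L || ensemble_size < 1L)
    stop("ensemble_size must be a positive integer", call. = FALSE)
  if (noise_ratio < 0) stop("noise_ratio must be >= 0", call. = FALSE)
  n <- length(s$samples)
  if (is.null(max_imfs)) max_imfs <- default_max_imfs(n)
  if (noise_ratio == 0 && ensemble_size == 1L) {
    d <- .emd_cpp(s$samples, as.integer(max_imfs), sd_tol,
                  as.integer(max_sift), FALSE)
    return(new_decomposition(d$imfs, d$residue, "EEMD", 1L, 0, seed,
                             s$rate, s$label))
  }
  sd_noise <- noise_ratio * stats::sd(s$samples)
  noise <- withr_seed(seed, matrix(stats::rnorm(n * ensemble_size, sd = sd_noise),
                                   nrow = n))
  res <- .eemd_cpp(s$samples, noise, as.integer(max_imfs), sd_tol,
                   as.integer(max_sift))
  new_decomposition(res$imfs, res$residue, "EEMD", ensemble_size,
                    noise_ratio, seed, s$rate, s$label)
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Reconstruct the decomposed signal
#'
#' Sums IMFs and residue of a decomposition. See [reconstruct()] for
#' selection-aware reconstruction.
#'
#' @param x an `imf_decomposition`.
#' @return numeric vector.
#' @export
decomposition_sum <- function(x) {
  stopifnot(inherits(x, "imf_decomposition"))
  if (ncol(x$imfs) == 0) return(x$residue)
  rowSums(x$imfs) + x$residue
}
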