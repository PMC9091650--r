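`%||%` <- function(a, b) if (is.null(a)) b else a

new_verdict <- function(index, energy, period, skew, kurt, is_signal, rule) {
  data.frame(index = as.integer(index), lnE = energy, lnT = period,
             skew = skew, kurt = kurt, is_signal = is_signal, rule = rule,
             stringsAsFactors = FALSE)
}

#' Shape test for the first IMF
#'
#' The first IMF of a noise-contaminated signal is often noise-dominant. If
#' both its skewness and kurtosis fall inside the white-noise reference
#' intervals, the IMF is indistinguishable from white noise and flagged as
#' noise; otherwise it is kept as signal.
#'
#' @param imf1 numeric vector, the first IMF.
#' @param reference a [build_noise_reference()] object whose `epoch_length`
#'   equals the IMF length.
#' @return one-row data.frame verdict: `index`, `lnE`, `lnT`, `skew`,
#'   `kurt`, `is_signal`, `rule`.
#' @export
test_imf1 <- function(imf1, reference) {
  stopifnot(inherits(reference, "noise_reference"))
  x <- as.numeric(imf1)
  if (length(x) != reference$epoch_length)
    stop(sprintf("reference mismatch: IMF length %d, reference epoch length %d",
                 length(x), reference$epoch_length), call. = FALSE)
  sk <- skewness(x)
  ku <- kurtosis(x)
  noise <- sk >= reference$skew_interval[1] && sk <= reference$skew_interval[2] &&
           ku >= reference$kurt_interval[1] && ku <= reference$kurt_interval[2]
  E <- energy_density(x)
  Tbar <- tryCatch(averaged_period(x), error = function(e) NA_real_)
  new_verdict(1L, log(E), log(Tbar), sk, ku, !noise, "shape_test")
}

#' Spread-line test for IMFs 2--9
#'
#' Places the IMF's (ln averaged period, ln energy density) point against
#' the white-noise percentile spread lines. Energy above the upper bound or
#' below the lower bound means the IMF carries information; energy inside
#' the band is consistent with residual noise. The IMF must be on the same
#' amplitude scale as the reference (unit-variance input).
#'
#' @param imf numeric vector.
#' @param index 1-based IMF order, between 2 and 9.
#' @param reference a `noise_reference`.
#' @param confidence percentile for the bounds (default 0.99: the 1st/99th
#'   percentile spread lines).
#' @param sides `"two"` (default): energy outside either bound counts as
#'   information; `"upper"`: only energy above the upper bound does, the
#'   one-sided convention of classical white-noise significance testing.
#'   Energy below the lower bound means the mode carries *less* energy
#'   than noise would -- an attenuated noise mode -- so the one-sided rule
#'   is what [deemd_select()] uses for denoising.
#' @return one-row verdict data.frame as in [test_imf1()].
#' @export
test_imf_spread <- function(imf, index, reference, confidence = 0.99,
                            sides = c("two", "upper")) {
  sides <- match.arg(sides)
  stopifnot(inherits(reference, "noise_reference"))
  if (index < 2L || index > 9L)
    stop("spread test applies to IMF indices 2..9", call. = FALSE)
  x <- as.numeric(imf)
  E <- energy_density(x)
  if (E <= 0) # an all-zero padded IMF carries no information
    return(new_verdict(index, -Inf, NA_real_, NA_real_, NA_real_, FALSE,
                       "spread_test"))
  lnT <- log(averaged_period(x))
  lnE <- log(E)
  b <- spread_bounds(lnT, reference$intercept, confidence,
                     reference$epoch_length)
  hit <- if (sides == "two") lnE > b$upper || lnE < b$lower
         else lnE > b$upper
  new_verdict(index, lnE, lnT, skewness(x), kurtosis(x), hit, "spread_test")
}

#' Denoised EEMD: decompose, test, and select signal-dominant IMFs
#'
#' The full selection procedure: (1) standardize the signal to unit
#' variance and decompose it by EEMD, (2) shape-test IMF1 against the
#' white-noise skewness/kurtosis intervals, (3) bring the IMFs onto the
#' reference's noise scale by matching the energy of IMF1 -- taken as the
#' noise-level estimate, the classical assumption behind white-noise
#' significance testing -- to the reference's median IMF1 energy, and
#' (4) spread-test the rescaled IMFs 2..9 against the energy--period
#' percentile lines. IMFs beyond index 9 (and the residue) are retained
#' by default: the reference characterizes only the first nine noise
#' modes. Selection is invariant to amplitude scaling of the input.
#'
#' @param signal an [eeg_signal] (or numeric vector with `rate`).
#' @param reference a [build_noise_reference()] object built at the signal
#'   length.
#' @param confidence spread-line percentile (default 0.99).
#' @param sides spread-test sidedness (see [test_imf_spread()]); the
#'   default here is `"upper"`, treating modes at or below the noise
#'   energy line as noise, which is what makes the selection denoise.
#' @param keep_beyond keep IMFs with index > 9 as signal (default TRUE).
#' @param ensemble_size,noise_ratio,seed,max_imfs,rate passed to [eemd()].
#' @return object of class `imf_selection`: the decomposition (of the
#'   standardized signal), the verdict table, the selected IMF matrix, the
#'   standardization scale, and the reference used.
#' @export
deemd_select <- function(signal, reference, confidence = 0.99,
                         sides = "upper", keep_beyond = TRUE,
                         ensemble_size = 100L, noise_ratio = 0.3,
                         seed = 1L, max_imfs = NULL, rate = NULL) {
  s <- as_signal(signal, rate)
  stopifnot(inherits(reference, "noise_reference"))
  if (length(s$samples) != reference$epoch_length)
    stop("reference epoch length does not match the signal length",
         call. = FALSE)
  scale <- stats::sd(s$samples)
  if (scale == 0) stop("constant signal cannot be decomposed", call. = FALSE)
  z <- eeg_signal(s$samples / scale, s$rate, s$label)
  dec <- eemd(z, ensemble_size = ensemble_size, noise_ratio = noise_ratio,
              seed = seed, max_imfs = max_imfs)
  m <- ncol(dec$imfs)
  # noise-scale factor: make IMF1's energy match the reference's median
  # IMF1 energy, so the spread lines are read at the white-noise scale
  E1 <- if (m >= 1L) energy_density(dec$imfs[, 1]) else 0
  noise_scale <- if (is.finite(reference$imf1_lnE %||% NA_real_) && E1 > 0)
    sqrt(exp(reference$imf1_lnE) / E1) else 1
  verdicts <- vector("list", m)
  for (i in seq_len(m)) {
    imf <- dec$imfs[, i]
    verdicts[[i]] <-
      if (i == 1L) test_imf1(imf, reference)
      else if (i <= 9L) test_imf_spread(imf * noise_scale, i, reference,
                                        confidence, sides = sides)
      else {
        E <- energy_density(imf)
        Tbar <- tryCatch(averaged_period(imf), error = function(e) NA_real_)
        new_verdict(i, log(E), log(Tbar), NA_real_, NA_real_, keep_beyond,
                    "default_keep")
      }
  }
  verdicts <- do.call(rbind, verdicts)
  structure(list(decomposition = dec, verdicts = verdicts,
                 selected = dec$imfs[, verdicts$is_signal, drop = FALSE],
                 scale = scale, noise_scale = noise_scale,
                 confidence = confidence, reference = reference),
            class = "imf_selection")
}

#' @export
print.imf_selection <- function(x, ...) {
  cat(sprintf("<imf_selection> %d/%d IMFs signal-dominant (confidence %g)\n",
              sum(x$verdicts$is_signal), nrow(x$verdicts), x$confidence))
  print(x$verdicts, row.names = FALSE)
  invisible(x)
}

#' Reconstruct from a selection
#'
#' Sums IMFs back on the original amplitude scale. With `use = "all"` the
#' result is the full reconstruction (all IMFs plus residue), equal to the
#' ensemble-mean input. With `use = "selected"` only the signal-dominant
#' IMFs contribute; the residue is included by default since it carries the
#' slow trend.
#'
#' @param selection an `imf_selection`.
#' @param use `"selected"` (default) or `"all"`.
#' @param include_residue include the residue in the selected
#'   reconstruction (default TRUE; ignored for `use = "all"`).
#' @return numeric vector on the original signal scale.
#' @export
reconstruct <- function(selection, use = c("selected", "all"),
                        include_residue = TRUE) {
  use <- match.arg(use)
  stopifnot(inherits(selection, "imf_selection"))
  dec <- selection$decomposition
  out <- if (use == "all") {
    rowSums(dec$imfs) + dec$residue
  } else {
    keep <- selection$verdicts$is_signal
    base <- if (any(keep)) rowSums(dec$imfs[, keep, drop = FALSE])
            else numeric(nrow(dec$imfs))
    if (include_residue) base + dec$residue else base
  }
  out * selection$scale
}

#' Mean square error between a signal and its reconstruction
#'
#' @param x,x_rec equal-length numeric vectors.
#' @return `MSE = mean((x - x_rec)^2)`.
#' @export
mse <- function(x, x_rec) {
  if (length(x) != length(x_rec)) stop("length mismatch", call. = FALSE)
  mean((x - x_rec)^2)
}

#' Signal-to-noise ratio of a reconstruction, in dB
#'
#' `SNR = 10 * log10(sum(x^2) / sum((x - x_rec)^2))`. A perfect
#' reconstruction returns `Inf`.
#'
#' @inheritParams mse
#' @return SNR in dB.
#' @export
snr <- function(x, x_rec) {
  if (length(x) != length(x_rec)) stop("length mismatch", call. = FALSE)
  num <- sum(x^2)
  if (num == 0) stop("SNR undefined for an all-zero reference signal",
                     call. = FALSE)
  den <- sum((x - x_rec)^2)
  if (den == 0) return(Inf)
  10 * log10(num / den)
}
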