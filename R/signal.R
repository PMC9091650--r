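#' Single-channel signal container
#'
#' Bundles one channel of a trial with its sampling rate and channel label.
#' Amplitude units are arbitrary (nominally microvolts for EEG).
#'
#' @param samples numeric vector of at least 16 finite samples.
#' @param rate sampling frequency in Hz, strictly positive.
#' @param label channel identifier string.
#' @return An object of class `eeg_signal` with fields `samples`, `rate`,
#'   `label`.
#' @examples
#' s <- eeg_signal(sin(2 * pi * 5 * seq(0, 1, by = 1/500)), rate = 500)
#' s
#' @export
eeg_signal <- function(samples, rate, label = "ch1") {
  samples <- as.numeric(samples)
  if (length(samples) < 16L)
    stop("signal must contain at least 16 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("all samples must be finite", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("rate must be a single positive number (Hz)", call. = FALSE)
  structure(list(samples = samples, rate = as.numeric(rate),
                 label = as.character(label)),
            class = "eeg_signal")
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf("<eeg_signal> %s: %d samples @ %g Hz (%.3g s)\n",
              x$label, length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' @export
length.eeg_signal <- function(x) length(x$samples)

# Coerce numeric vectors on the fly; signals pass through.
as_signal <- function(x, rate = NULL, label = "ch1") {
  if (inherits(x, "eeg_signal")) return(x)
  if (is.null(rate))
    stop("a sampling rate is required when passing a bare numeric vector",
         call. = FALSE)
  eeg_signal(x, rate, label)
}
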