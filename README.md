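# deemd

Denoised ensemble empirical mode decomposition and spatial-pyramid-pooling
classification for EEG-like biosignals.

## What problem this solves

Ensemble empirical mode decomposition (EEMD) is the workhorse for breaking a
nonstationary biosignal into intrinsic mode functions (IMFs), but the white
noise it injects never averages out completely: some of the returned IMFs
are signal, others are residual noise, and downstream feature extraction is
only as good as that distinction. This package implements, end to end:

- **EMD / EEMD** (compiled sifting core; natural cubic-spline envelopes,
  mirrored boundaries, classical fixed-10 sifting) with exact additive
  reconstruction and a `noise_ratio / sqrt(ensemble_size)` residual-noise
  law;
- **statistical IMF selection** against Monte-Carlo white-noise references:
  the first IMF is shape-tested (population skewness within ±0.09 and
  kurtosis within [2.8, 3.2] at 2,500 samples means "indistinguishable from
  noise"), deeper IMFs are tested against the white-noise energy–period
  spread lines `ln E = −ln T̄ + b ± k·sqrt(2/N)·exp(ln T̄ / 2)` at a chosen
  percentile;
- a **21-feature per-IMF descriptor** (moments, differences, Hjorth
  activity/mobility/complexity, Higuchi fractal dimension, Hilbert-envelope
  CVE, instantaneous-frequency variability, Welch spectral moments and
  SMPSD);
- an **SPP-net classifier**: two conv layers (10×4/stride 5×1 → 5×2/stride
  1×1, 10 → 200 channels), spatial pyramid pooling at levels [4, 2, 1] to a
  fixed 4,200-long vector regardless of how many IMFs survived selection,
  then fully connected 500 → 200 → 2 — trained with momentum SGD and
  evaluated by stratified k-fold cross-validation;
- a **synthetic EEG-trial generator** (band-limited oscillations + 1/f
  background, 5 s at 500 Hz, optional alpha-band class effect) that powers
  the whole test suite.

Intended users: researchers processing trial-structured electrophysiology
who need a defensible, testable IMF-selection step and a classifier that
tolerates variable-size feature maps.

## Worked example

Denoise a 6 Hz tone buried in white noise and inspect the verdicts:

```r
library(deemd)

ref <- build_noise_reference(2500, n_epochs = 2000, seed = 1)

t <- (0:2499) / 500
clean <- sin(2 * pi * 6 * t)
set.seed(42)
x <- clean + 0.3 * rnorm(2500)

sel <- deemd_select(eeg_signal(x, 500, "Cz"), ref,
                    ensemble_size = 100, seed = 7)
sel
#> <imf_selection> 4/10 IMFs signal-dominant (confidence 0.99)
#>  index         lnE      lnT         skew     kurt is_signal         rule
#>      1  -2.4702185 1.024990 -0.026943160 2.453724      TRUE   shape_test
#>      2  -1.9204998 1.748700  0.018765355 3.091975     FALSE  spread_test
#>      3  -2.5429467 2.462754 -0.013987761 3.731887     FALSE  spread_test
#>      4   0.9379321 4.160484  0.006906253 1.914642      TRUE  spread_test
#>      5   0.1305105 4.422849  0.026402788 2.067402      TRUE  spread_test
#>      6  -5.0361031 5.115996  0.292238107 2.766196     FALSE  spread_test
#>      7  -5.5117681 5.878136 -0.399045652 2.127470     FALSE  spread_test
#>      8  -5.5185441 6.725434 -0.001260997 2.529421     FALSE  spread_test
#>      9 -11.2545040 6.725434 -0.415303929 3.302745     FALSE  spread_test
#>     10        -Inf       NA           NA       NA      TRUE default_keep
```

The 6 Hz tone (averaged period e^4.16 ≈ 64 samples ≈ 7.8 Hz worth of
extrema spacing) sits far above the 99% spread line, so IMFs 4–5 are kept;
the noise cascade in IMFs 2–3 and 6–9 falls inside the band and is
discarded. Reconstruction from the kept IMFs beats the full reconstruction
against the known clean tone:

```r
cat(sprintf("SNR vs clean tone: all IMFs %.1f dB, selected IMFs %.1f dB\n",
            snr(clean, reconstruct(sel, "all")),
            snr(clean, reconstruct(sel, "selected"))))
#> SNR vs clean tone: all IMFs 7.4 dB, selected IMFs 9.3 dB
```

Features of the kept tone-carrying IMF behave as the theory says a
narrowband mode should (centroid at the tone, near-constant envelope,
curve-like fractal dimension):

```r
f <- extract_imf_features(sel$selected[, 2], rate = 500)
round(f[c("spectral_centroid", "cve", "hjorth_mobility",
          "fractal_dimension")], 3)
#> spectral_centroid               cve   hjorth_mobility fractal_dimension
#>             6.129             0.252             0.080             1.013
```

The full synthetic pipeline (simulate → reference → select → featurize →
train → evaluate) is one call:

```r
res <- pipeline_run(run_config(n_trials = 40, n_channels = 8,
                               class_effect = 1.5, seed = 1),
                    out_dir = "runs/demo")
res$metrics$accuracy
```

or from a shell via the CLI (`inst/cli/deemd`):

```sh
Rscript -e 'deemd::deemd_cli()' simulate --n-trials 40 --channels 8 --out runs/trials
Rscript -e 'deemd::deemd_cli()' build-reference --length 2500 --epochs 10000 --out ref.json
Rscript -e 'deemd::deemd_cli()' select --input runs/trials/trial_001.csv \
    --reference ref.json --rate 500 --out runs/sel
```

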