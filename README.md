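# eegtfr

Predicting depression therapy response from pre-treatment EEG is a
treatment-selection problem: roughly half of patients do not respond to the
first therapy tried (an SSRI course or repetitive transcranial magnetic
stimulation), and each failed course costs weeks. `eegtfr` implements a
complete, testable pipeline that turns five-minute, 19-channel resting-state
recordings into time-frequency images and classifies eventual responders (R)
versus non-responders (NR) with compact neural networks, under evaluation
protocols strict enough to speak to unseen patients.

The pipeline, stage by stage:

* **Preprocessing** — zero-phase 0.5–70 Hz band-pass and 50 Hz notch
  (`filtfilt`), common average reference, non-overlapping 15-s epochs, and
  multiscale PCA denoising: a level-9 periodized sym4 wavelet decomposition
  with per-scale principal-direction soft thresholding against the universal
  threshold `sigma * sqrt(2 log N)` and Kaiser-rule component retention at the
  approximation and final reconstruction stages.
* **Variational mode decomposition** — a from-scratch solver for

  `min sum_k || d/dt [ (delta(t) + j/(pi t)) * u_k(t) e^{-j w_k t} ] ||^2
  s.t. sum_k u_k = x`,

  by alternating Fourier-domain updates: Wiener-style mode update
  `u_k <- (x - sum_{i!=k} u_i + lambda/2) / (1 + 2 alpha (w - w_k)^2)`,
  centre frequencies as spectral centroids, optional dual ascent, stopping at
  summed relative change `< 1e-7` (defaults K = 20, alpha = 2000, tau = 0).
* **Time-frequency images** — analytic Morlet scalograms (12 voices/octave,
  2–60 Hz), aggregate VMD spectrograms (per-mode STFT, Hamming 256, overlap
  250, 7680-point FFT, complex sum over modes), and their pixel-wise fusion
  `I_fused = (I_cwt + I_vmd) / 2` after per-image min-max normalisation; all
  rendered through a jet lookup table as square borderless PNGs.
* **Model zoo** — ResNet-18, MobileNet-V3-Large, EfficientNet-B0, the hybrid
  TinyViT (ResNet-18 backbone to `512 x 7 x 7`, 49 tokens of dim 512,
  learnable positional embeddings, two 8-head transformer blocks with FFN
  width 2048), and a fast `tiny_cnn`; implemented in a small pure-R engine
  with exact, numerically verified gradients, trained with AdamW + cosine
  annealing + early stopping.
* **Evaluation** — stratified image-level and subject-independent 6-fold CV,
  accuracy/precision/recall/specificity/F1 from fold confusion tables,
  subject-level majority voting with t-based 95% confidence intervals,
  per-channel accuracy maps, and exact (enumerated) Wilcoxon signed-rank
  comparison of per-fold accuracies.
* **Synthetic cohorts** — labelled 19-channel recordings with 1/f background,
  band-limited rhythms, mains interference, and a class-dependent band-power
  effect at chosen electrodes, so every stage is testable without clinical
  data. A minimal EDF writer/reader exercises the file-based path.

## A worked example

Decompose a two-tone signal and read off the centre frequencies:

```r
library(eegtfr)
x <- generate_tones(tone_spec(c(5, 40), duration_s = 15, fs = 512))
res <- vmd_decompose(as.numeric(x), fs = 512, vmd_config(K = 2, alpha = 2000))
res
#> <vmd_result> K = 2 modes, 7680 samples; converged in 5 iterations (residual 0.00495)
#>   centre frequencies (Hz): 5, 40
```

The solver recovers 5 and 40 Hz essentially exactly (errors of order
`1e-4` Hz) and the two modes reconstruct the input to half a percent.

Run the full pipeline on a synthetic cohort with an occipital alpha effect
(responders have twice the alpha power at O1/O2) and score unseen subjects:

```r
cfg <- list(
  synthetic  = list(n_responders = 10, n_nonresponders = 10,
                    duration_s = 300, fs = 128, noise_sd = 2),
  preprocess = list(low = 0.5, high = 45, notch = 50),
  tfr        = list(repr = "cwt", image_size = 24, write_png = FALSE,
                    cwt = list(fmin = 2, fmax = 45)),
  model      = list(name = "tiny_cnn"),
  train      = list(lr = 1e-3, batch_size = 32, max_epochs = 8, patience = 8),
  eval       = list(strategy = "subject", n_folds = 6),
  out_dir    = tempfile(), seed = 11)
res <- run_pipeline(cfg)
mean(res$subject_votes$vote == res$subject_votes$truth)   # subject accuracy
sort(res$per_channel_accuracy, decreasing = TRUE)[1:4]    # O1/O2 lead
```

Each of the 20 subjects contributes 380 images (20 epochs x 19 channels);
subject labels are majority votes over those images, and the per-channel
table localises the effect at the electrodes that actually carry it.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/eegtfr.R simulate --responders 2 --nonresponders 3 --out data/
Rscript inst/cli/eegtfr.R vmd --input data/S01_R.edf --channel 18 --K 20 --out modes.csv
Rscript inst/cli/eegtfr.R run --config run.yaml
```

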