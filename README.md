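# datunet

Accelerated dopamine-transporter (DaT) SPECT with a compact U-Net: an
end-to-end, fully reproducible pipeline that learns to translate short
1-cycle ^123^I-ioflupane acquisitions (~5 min) into virtual long 5-cycle
images (~25 min), and evaluates the result with the full statistical
battery an imaging study would use.

Clinical DaT-SPECT series are rarely shareable, so the package includes a
synthetic phantom cohort generator that mirrors the acquisition protocol's
statistical structure — bilateral striata in one of four canonical uptake
patterns per hemisphere (burst striatum = 1, egg shape = 2, eagle wing = 3,
normal = 4), collimator blur, and per-cycle Poisson counting noise such
that the long image is the sum of five independent cycles and the short
image is cycle 1 alone. Everything downstream of the generator is the same
code a real paired dataset would flow through.

## What it implements

* **Phantom cohorts** (`phantom_spec`, `make_activity_volume`,
  `simulate_acquisition_pair`, `generate_cohort`): 128 x 128 x 15 activity
  volumes (3.29 mm pixels), Gaussian PSF blur, per-slice count scaling,
  independent Poisson cycles, per-hemisphere ground-truth pattern labels,
  deterministic per-case seed derivation.
* **Preprocessing** (`select_slices`, `crop_center`, `normalize_case`,
  `build_samples`, `split_dataset`): max-count slice selection (centre ±2
  analysis window, ±1 reader set), central 64 x 64 crop, per-case
  normalisation, 5 samples per case with 5-slice replicate-padded input
  windows, case-level train/validation/test splitting, 8-bit PNG export and
  16-bit "Cool"-colormap reader images with optional blinding.
* **Models** (`build_unet`, `train_unet`, `unet_predict`,
  `gaussian_baseline`, `bilateral_baseline`, `model_registry`): U-Nets of
  depth 1–5 with filter schedule 16·2^(level−1), trained by pixel-wise MSE
  with Adam (batch 8, learning rate 1e-3 → 1e-5 after epoch 150). The
  convolution forward/backward passes are implemented from scratch on
  im2col+GEMM primitives (RcppArmadillo) and verified against numerical
  gradients.
* **Image-quality statistics** (`psnr`, `ssim`, `summarize_metrics`,
  `friedman_test`, `dunn_holm`): per-slice PSNR (dB) and SSIM against the
  long-acquisition reference — PSNR = 10·log10(MAX²/MSE), SSIM with the
  canonical 11 x 11 Gaussian window (σ = 1.5, K1 = 0.01, K2 = 0.03) —
  mean ± SD summaries, tie-corrected Friedman omnibus test, and Dunn
  post-hoc contrasts against U-Net(L4) with Holm adjustment.
* **Reader agreement** (`simulate_reader`, `weighted_kappa`, `icc_single`,
  `kappa_report`, `intra_rater_report`, `inter_rater_report`): quadratic
  weighted Cohen's κ against the gold standard, and ICC(2,1) (two-way
  random effects, absolute agreement, single measure) for intra-rater
  (session 1 vs 2) and inter-rater (pairwise readers) reliability,
  exercised by simulated confusion-matrix readers.
* **Pipeline** (`experiment_config`, `run_experiment`, `report_tables`):
  one call runs cohort → preprocessing → training → metrics → reader
  study, writes CSV/text reports and model checkpoints, and is
  bit-reproducible from a single master seed. A thin CLI wrapper lives at
  `inst/scripts/run_experiment.R`.

## Worked example

The built-in `"fast"` profile (35 synthetic cases split by the protocol's
proportions into 20/6/9 cases = 100/30/45 slices, U-Net L4, 30 epochs)
runs in a few minutes on one CPU:

```r
library(datunet)
res <- run_experiment(experiment_config("fast", seed = 1))
res$summary
```

```
  method_id metric       mean         sd n_used
1     short   psnr 28.5834926 1.01993821     45
2  gaussian   psnr 30.2197288 2.04065400     45
3 bilateral   psnr 29.8779679 1.99858941     45
4   unet_l4   psnr 33.5703066 0.89391118     45
5     short   ssim  0.7597186 0.02263873     45
6  gaussian   ssim  0.8375303 0.01762489     45
7 bilateral   ssim  0.8347395 0.01508611     45
8   unet_l4   ssim  0.8480121 0.01844168     45
```

Reading: on held-out test slices the trained U-Net(L4) gains ~5 dB PSNR
and ~0.09 SSIM over the raw 1-cycle images and clearly beats both
classical filters; `res$friedman` confirms the omnibus difference
(p ≈ 1e-26 for PSNR) and `res$dunn` shows every baseline significantly
below the reference after Holm correction. The simulated reader study
moves in the same direction — `res$kappa$per_method` gives mean
κ = 0.746 on short images versus 0.916 on U-Net outputs, with intra-rater
ICC ≈ 0.89–0.91 (`res$icc_intra`) and inter-rater ICC ≈ 0.69–0.74
(`res$icc_inter`).

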