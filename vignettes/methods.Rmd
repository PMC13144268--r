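---
title: "Virtual long-acquisition DaT-SPECT: phantom model, network, and evaluation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual long-acquisition DaT-SPECT: phantom model, network, and evaluation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Dopamine-transporter SPECT with ^123^I-ioflupane requires long acquisitions
(typically 25--40 minutes) to accumulate enough counts for confident visual
grading of striatal uptake. A protocol that acquires in five ~5-minute
cycles, reconstructs the sum as the clinical reference, and reconstructs
cycle 1 alone as a "short" image yields naturally paired noisy/clean data.
`datunet` implements, end to end, the experiment of learning an
image-to-image mapping from the 1-cycle image to a *virtual* 5-cycle image
with a compact U-Net, and of evaluating that mapping the way an imaging
study would: per-slice PSNR/SSIM with Friedman and Dunn--Holm statistics,
plus a reader study measured by quadratic weighted kappa and intraclass
correlation coefficients.

Clinical DaT-SPECT series are rarely shareable, so the package ships a
synthetic phantom cohort generator whose statistical structure mirrors the
acquisition protocol, and a simulated-reader model so the agreement
statistics can be exercised without human readers. Everything downstream of
the generator --- preprocessing, the network family, the statistics --- is
the same code a real paired dataset would flow through.

## The phantom model

A case is a 3-D activity map on a `128 x 128 x 15` grid (3.29 mm pixels,
voxels treated as isotropic): a uniform elliptical "brain" background plus
bilateral striata composed of three sub-regions per hemisphere (caudate
head, anterior putamen, posterior putamen). Per-hemisphere uptake follows
the four-point visual scale used for grading:

* **4 (normal)** --- full comma-shaped caudate + putamen at
  `striatal_activity`;
* **3 (eagle wing)** --- posterior putamen's specific uptake halved;
* **2 (egg shape)** --- putamen at background, caudate preserved;
* **1 (burst striatum)** --- entire striatum at background.

`striatal_activity = 8` against a background of 1 reflects typical
striatum-to-background contrast of a normal scan; both are configurable.
Mild jitter (position up to 1 px, intensity up to 10%) is seeded separately
per hemisphere, so regenerating one side can never perturb the other --- a
property the tests rely on.

Counting statistics follow the acquisition protocol: the activity map is
blurred by an isotropic Gaussian point-spread function (default FWHM 10 mm,
a typical low/medium-energy general-purpose collimator resolution class),
every non-empty slice is scaled so its expected total equals
`counts_per_cycle` (default 20,000 --- enough that single-cycle images are
visibly noisy while striata remain detectable), and each pixel of each
cycle is an independent Poisson draw. The short stack is cycle 1; the long
stack is the pixel-wise sum of five independent cycles; the noiseless stack
is five times the expected single-cycle image. Because every slice is
normalised to the same expected total, the brain ellipse is extruded
uniformly across slices (no axial taper of the brain outline) while the
striatal masks occupy the central five slices with radii tapering toward
the ends; this keeps "the slice with the highest maximum count" a
well-defined, physically meaningful selection rule. The taper acts on mask
extent rather than intensity, so the mean activity inside a striatal mask
equals the pattern's nominal value exactly --- a convenient invariant for
testing.

What the generator does *not* emulate: tomographic reconstruction
(projection space, OSEM, attenuation and scatter correction and their
spatially correlated noise), anatomical variability beyond the four-pattern
taxonomy, patient motion, and septal penetration. Tests that pass on the
phantom therefore demonstrate that the pipeline's machinery is correct and
that its statistics behave as designed under count-limited Poisson noise;
they do not certify performance on clinical reconstructions.

## Seed discipline

One master seed fans out to every stochastic stage through a deterministic
integer-mixing function (`derive_seed`), with one stream per case, per
hemisphere, per cycle, per reader. Enlarging a cohort therefore never
reshuffles earlier cases, and an identical configuration reproduces every
artifact bit-identically. All results in the package are functions of
`(config, master_seed)` only.

## Preprocessing conventions

* **Slice selection.** The analysis centre is the slice with the highest
  per-slice maximum of the case-normalised long stack; ties break to the
  lowest index. The analysis window is the centre ±2 slices (5 slices), the
  reader set the centre ±1 (3 slices); windows are shifted, never
  shortened, at stack boundaries.
* **Indexing.** The package uses R's native 1-based, inclusive indexing
  throughout. The central crop of a 128-pixel image is rows/columns 33..96.
* **Multi-slice input.** Each of a case's five window slices becomes one
  sample whose input is the five short-time slices centred on the target
  index (replicate-padded at the window edge) and whose target is the
  single matching long-time slice. This per-target reading reconciles a
  5-slice input with the protocol arithmetic of 5 samples per case
  (207 cases yield 1035 samples; a 120/37/50-case split yields 600/185/250
  samples).
* **Normalisation and quantisation.** Stacks are normalised per case by
  their own global maximum (short and long stacks separately), preserving
  inter-slice ratios. PSNR and SSIM are computed on these floating
  normalised images with `max_val = 1`; 8-bit quantisation
  (`round(x * 255)`, half away from zero) is applied only on disk export,
  so quantisation noise cannot bury model differences. A config switch
  (`max_val = 255`) supports metrics on 8-bit exports instead.
* **Splitting** is by case, never by slice, so no slice of a case can leak
  across partitions. Counts follow `floor(fraction * n)` for train and
  validation with the remainder to test.

## The network family

`build_unet(depth)` constructs an encoder--decoder with `depth` resolution
levels and filter schedule `16 * 2^(level-1)` (so depth 4 uses 16, 32, 64,
128). Each block is two 3x3 convolutions with ReLU; downsampling is 2x2 max
pooling, upsampling nearest-neighbour, and each decoder level concatenates
the matching encoder features before its convolutions; a final 1x1
convolution maps to one channel. Choices the architecture description
leaves open were resolved as follows and are deliberately conventional:
"same" padding (so 64 x 64 survives all depths), ReLU activations, no batch
normalisation, He initialisation, nearest-neighbour upsampling, final-epoch
weights returned (no early stopping), and outputs clipped to [0, 1] at
prediction time only.

Training minimises pixel-wise MSE with Adam (batch size 8), learning rate
1e-3 switching to 1e-5 *strictly after* epoch 150, for 200 epochs in the
full-scale profile. The forward/backward passes are implemented on
im2col+GEMM convolution primitives (C++ via RcppArmadillo) with
analytically derived gradients; the test suite checks them against
numerical differentiation.

The classical baselines are an isotropic Gaussian filter (sigma 1 px,
reflect boundaries) and a bilateral filter (sigma_spatial 2 px, sigma_range
0.1); no reference values exist for these parameters, so they are exposed
in the registry and flagged as conventional. The method registry is keyed
by string id (`"unet_l1"`..`"unet_l5"`, `"gaussian"`, `"bilateral"`,
`"short"`) and accepts additional entries, so further architecture variants
can be plugged in without touching the pipeline.

## Evaluation statistics

* **PSNR** is `10 log10(max_val^2 / MSE)`; a zero-MSE pair returns an
  infinite sentinel that summaries exclude with a warning.
* **SSIM** uses the canonical 11 x 11 Gaussian window (sigma 1.5),
  `K1 = 0.01`, `K2 = 0.03`, `L = 1`, weighted local moments, and averages
  the map over fully interior window positions.
* **Friedman** uses within-slice ranks with average ranks and tie
  correction (delegated to `stats::friedman.test`); a fully tied table is
  reported as statistic 0, p = 1 rather than NaN.
* **Dunn--Holm** compares the reference method (U-Net L4 by default)
  against each other method only --- m = k-1 contrasts, matching the
  study design this mirrors, not all pairs --- using tie-corrected mean-rank
  z statistics, two-sided normal p-values, and Holm step-down adjustment
  capped at 1.
* **Weighted kappa** uses quadratic weights on the fixed category set 1..4
  (unobserved categories retained so kappa is comparable across methods);
  two constant, equal raters are a degenerate case defined as kappa 1 with
  a flag.
* **ICC.** The reliability coefficient is ICC(2,1): two-way random
  effects, absolute agreement, single measure. The variant is not dictated
  by the study design this package mirrors; ICC(2,1) is the strictest
  common choice (it penalises systematic rater offsets, which consistency
  forms forgive) and is used for both intra-rater (sessions as columns) and
  inter-rater (readers as columns, pairwise) analyses. Inter-rater items
  pool all methods' scores per reader; kappa is computed per method.

## The simulated reader study

Readers are confusion-matrix samplers applied to the phantom ground-truth
labels (which stand in for the consensus reading of the long images, since
a synthetic cohort has no human consensus). The default model reports the
true category with probability `accuracy` and spills the remainder onto
adjacent categories --- 0.55 on raw short images, 0.65 on filtered images,
0.85 on U-Net outputs, chosen once to encode the qualitative finding the
pipeline must reproduce (readers agree with the reference substantially
more on enhanced than on raw short images). These accuracies are
directional inputs, not calibrated estimates of human performance; the
resulting kappa magnitudes should not be read as predictions of a clinical
reader study.

## Problem sizes and profiles

The `"paper"` profile mirrors the emulated protocol: 207 cases
(120/37/50 split), all five U-Net depths plus baselines, 200 epochs. The
`"fast"` profile --- 35 cases and 30 epochs, U-Net L4 only --- is the
package's chosen desk-scale configuration: large enough that the
enhancement ordering (U-Net > bilateral/Gaussian > short on both PSNR and
SSIM, Friedman p < 0.01) reproduces reliably, small enough to run in a few
minutes on one CPU. The acceptance script and test suite use the fast
profile for the training-dependent checks and the full 207-case scale for
the count checks.

```{r}
library(datunet)
res <- run_experiment(experiment_config("fast", seed = 1,
                                        output_dir = "datunet_run"))
writeLines(report_tables(res))
```

## Numerical and degenerate-input choices

* Gaussian filtering is separable with kernels truncated at 4 sigma and
  renormalised; the phantom's PSF blur uses truncated-renormalised band
  matrices, the baseline filter uses reflect boundaries.
* An all-zero stack cannot be normalised and is rejected with an explicit
  message; zero-activity phantoms propagate as exact zeros through the
  Poisson model.
* Training aborts with a diagnostic on non-finite loss; an empty validation
  set downgrades to a warning and skips the validation curve.
* `lr_schedule` treats the switch boundary as strictly after the switch
  epoch (epoch 150 still uses 1e-3).
* Argmax ties (slice selection) break to the lowest index; rank ties use
  average ranks with the standard tie corrections.

## Known limitations

The phantom's image-domain noise model cannot reproduce the spatially
correlated noise texture of iterative reconstruction, and its four-pattern
geometry understates anatomical variability; absolute metric values on the
phantom are therefore not comparable to values on clinical data, only
orderings and test behaviours are. The simulated readers are memoryless
confusion samplers --- they cannot model reader drift, fatigue, or
case-difficulty correlations, so intra-rater ICC on the phantom reflects
the confusion model, not human test-retest behaviour. Training on one CPU
limits the practical cohort size; the implementation is deterministic but
not parallel.
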