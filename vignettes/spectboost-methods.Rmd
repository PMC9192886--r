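---
title: "Methods: fast-scan bone SPECT enhancement with a nested-U generator"
author: "spectboost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fast-scan bone SPECT enhancement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A whole-body bone SPECT acquisition at the standard protocol (20 s per
projection, 60 projections) takes around 20 minutes; cutting the dwell to
3 s per projection divides the scan time by roughly 7 but also divides the
expected photon count per voxel by the same factor, leaving images too noisy
for confident reading. spectboost implements an image-domain enhancement
method: a convolutional generator that maps a fast-scan (1/7 dwell) SPECT
volume, together with the co-registered CT, to a synthesized standard-scan
volume. Because no paired clinical data are deposited anywhere, the package
also contains a simulator that produces paired fast/standard acquisitions of
a voxelized NEMA IEC body phantom and of synthetic bone-scan subjects, so
the whole train / enhance / evaluate loop runs on one CPU.

## Simulator

The forward model is deliberately an image-domain surrogate for the scanner
plus iterative reconstruction, not a projection-domain simulation: the
artifact enhances *reconstructed* volumes, and what the network must learn
is the count-statistics relationship between the two protocols, which the
surrogate preserves exactly.

* An activity map (arbitrary concentration units) is blurred with an
  isotropic Gaussian point-spread function, default FWHM 8 mm — typical for
  a low-energy high-resolution collimator at clinical radius. The kernel is
  normalized, so blurring conserves total activity.
* Expected counts per voxel are
  `activity x sensitivity x seconds_per_projection x n_projections` plus an
  optional flat background rate. The default sensitivity (1/24 counts per
  activity unit per second) puts the standard-protocol background at about
  50 counts/voxel — a realistic bone-SPECT count level; the absolute level
  is a free parameter because only the activity *ratio* of the phantom fill
  is standardized.
* Each voxel is drawn independently from a Poisson distribution, once, in
  image space. Expected counts are therefore exactly linear in dwell time
  (3 s vs 20 s gives the 3/20 ratio), and fast and standard scans of one
  subject are independent realizations of the same blurred activity.

The NEMA IEC phantom is voxelized analytically: a 9700 ml cylinder
(interior length fixed at 180 mm, the standard's nominal body length, with
the radius solved from the fill volume), six spheres of 10–37 mm diameter
on a 50 mm ring, centred 70 mm below the top face, filled at 12:1. Sphere
membership is decided by voxel-centre inclusion, with the centre voxel
always claimed so no sphere vanishes on coarse grids; the same analytic
ROI definition is shared by the phantom builder and the SUV report, so
noiseless quantitation is exact by construction. Synthetic subjects are an
ellipsoidal soft-tissue body (uptake 1), skeletal structures — spine rod,
pelvic plate, oblique rib-like rods — at uptake 3.5, and hot focal lesions
(uptake 10) forming the lesion mask; the pseudo-CT encodes the same
geometry at CT-like contrast (air −1000, soft tissue 40, bone 700). These
are caricatures: they reproduce count statistics, multi-modal structure
and lesion contrast, but not anatomy, attenuation, scatter, or the
spatially correlated noise of iterative reconstruction — conclusions about
real scanners require real data.

## Preprocessing

Every input and target volume is divided by its own mean over all voxels
(zeros included), recorded once per volume. The pseudo-CT is shifted so its
minimum (air) is zero before the division — a mean over signed HU-like
values would be near zero and meaningless. Training samples are whole 2-D
axial slices; the fast-SPECT slice is channel 1 and the CT slice channel 2
(dropped in the no-CT ablation). At deployment only the fast scan's
statistics exist, so synthesized volumes return to the count scale through
the *fast* volume's divisor.

## The generator

The generator is a two-level nested U-structure built from residual
U-blocks (RSU). An RSU of height L applies an input convolution, then a
small U-Net of L levels (3×3 convolutions, each followed by a stateless
channel normalization and ReLU; max-pool downsampling and bilinear
upsampling), and adds the result to the input-convolution branch. In the
dilated variant (RS-L) the pooling/upsampling pair is replaced by dilated
convolutions (rates 1, 2, 4, 8), so deep stages keep their already-small
spatial maps intact.

The outer U has a 6-stage encoder — RSU-7, RSU-6, RSU-5, RSU-4, RS-4, RS-4
— and a 5-stage decoder — RS-4, RSU-4, RSU-5, RSU-6, RSU-7 — with max-pool
between encoder stages and bilinear upsampling plus encoder-skip
concatenation between decoder stages; the three dilated blocks are the two
encoder bottoms and the first decoder. Each decoder stage and the deepest
encoder stage emit a side output through a 3×3 convolution to one channel,
bilinearly upsampled to the input size. The six side outputs are
concatenated, fused by a 1×1 convolution, and a long skip connection adds
the fast-SPECT input channel to produce the final image. All outputs are
linear: intensities are unbounded, so no saturating nonlinearity is used.

Channel widths scale with `base_channels` (64 = full size, ~44 M weights;
8 = desk preset, ~0.7 M). Convolutions inside conv-norm-ReLU trios carry no
bias (the normalization shift plays that role). Initialization is Kaiming
fan-in, seed-controlled, with two deliberate exceptions for the output
heads: side taps start at one tenth of the Kaiming scale and the fusion
convolution starts at exactly zero. Zero-initializing the last layer of a
residual branch is the standard way to start a residual network at the
identity; here it means an untrained generator returns its fast-SPECT input
unchanged, and training moves away from the identity only as the supervised
side outputs become informative. With fully random heads the untrained
fusion injects random mixtures of side outputs into the final image, which
we found corrupts it badly before training can correct it.

The normalization layer computes per-channel statistics over the batch and
spatial axes afresh at every call, at training and at inference alike. This
keeps the layer stateless and the whole forward pass deterministic — there
are no running averages whose state would depend on the training history.

## Losses

For one output y against target t (normalized units):

* `L = L1(y, t) + alpha * (1 - mean SSIM(y, t))` with alpha = 0.5. SSIM is
  computed over sliding 11×11 box windows at valid positions, constants
  `c1 = (0.01 R)^2`, `c2 = (0.03 R)^2` with R the target's dynamic range
  (the conventional k1/k2 values; the window and constants are exposed).
  A degenerate constant target uses R = 1 so the constants remain
  stabilizers only.
* Lesion attention: `l = L + beta * L_masked`, beta = 100, where `L_masked`
  recomputes the composite loss over the lesion region only — masked-mean
  L1, and the SSIM map averaged over mask-positive window centres (the full
  map is computed first, avoiding window-boundary pathologies of cropping).
  An empty mask contributes zero, so lesion-free slices are well defined.
* Deep supervision: `L_total = sum_i w_side_i * l_side_i + w_final *
  l_final` over the six side outputs plus the final output, all weights 1
  by default.

The scalar losses, their masked variants and their gradients are produced
by the same reverse-mode graph used in training, so the evaluation SSIM and
the SSIM loss share one implementation, and analytic gradients can be
checked against finite differences.

## Optimization

Adam (0.9/0.999, eps 1e-8), learning rate 2e-4 divided by 10 from epoch 80
of 100 at full scale; batches of 4 axial slices, reshuffled each epoch with
a seeded single-threaded RNG, so a fixed seed reproduces the loss history
bit for bit. The desk preset keeps the optimizer and batch size and shrinks
everything else.

## Evaluation conventions

PSNR follows `10 log10(max(gt)^2 / MSE)`; SSIM is the mean windowed map,
per axial slice for volumes. Comparisons *between protocols* are made on
the count-rate scale — counts divided by total acquisition seconds — since
raw counts differ by the dwell ratio ~6.7× and a raw-count MSE would
measure that scale gap rather than noise; dwell times are always known at
deployment, so this is a legitimate correction. SUV uses
`pixel x weight_g / dose_MBq` with the phantom weight equal to its fill
volume at 1 g/ml. Sphere ROIs are the analytic spheres, numbered 1..6 from
the largest diameter down (matching the partial-volume ordering of reported
SUV tables). Detectability uses the Rose criterion: contrast-to-noise ratio
above 4 against an annular background inside the cylinder, ±25 mm around
the sphere plane, 15 mm clear of every sphere and 10 mm off the wall; a
zero-variance background falls back to absolute contrast.

## Desk-scale problem sizes

The desk preset used by the demo, the test-suite and the acceptance script:
64×64 axial slices at 7.8 mm voxels (the clinical 500 mm in-plane field of
view at quarter resolution), 32 slices per volume; a phantom plus up to
three synthetic subjects; `base_channels = 8`; 5–6 epochs of Adam at 2e-4
(about 60–120 optimization steps). The held-out set is the last synthetic
subject plus the phantom half that contains the sphere-centre plane (on the
desk grid that is the first half, so the split direction is mirrored
relative to the full-length phantom). One training run takes on the order of a
minute on one CPU; the single-sample overfitting check runs a longer
schedule (450 single-slice epochs) because the lesion-attention side losses
start four orders of magnitude above their floor.

## Known limitations

The most important one concerns the final fusion head. The final image is
`fast + conv1x1(side outputs)` while every side output is itself supervised
toward the standard image. Because a mean-normalized fast scan equals the
mean-normalized standard scan in expectation, any smooth fusion correction
initially only adds bias, and the nearby optimum of the total loss keeps
the fusion weights near zero — the trained generator stays close to the
identity mapping. Configurations that actually cancel the fast scan's noise
exist, but they live in a large-fusion-weight regime that Adam at learning
rate 2e-4 only reaches after tens of thousands of steps — the full-scale
schedule, two orders of magnitude beyond the desk preset. At desk scale the
synthesized volume therefore tracks the fast scan closely, and desk-scale
PSNR/SSIM gains over the fast scan should not be expected from this
implementation; the desk runs exercise and verify the machinery (shapes,
losses, gradients, determinism, quantitation) rather than reproduce the
full-scale image-quality gains. Other limitations: no attenuation/scatter
physics and spatially uncorrelated noise in the simulator; identity
orientation assumed for NIfTI volumes; no data augmentation; the
adversarial discriminator mentioned alongside the optimizer settings of the
original description has no corresponding loss term and is not implemented
(a configuration hook `adversarial: none` reserves the slot).
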