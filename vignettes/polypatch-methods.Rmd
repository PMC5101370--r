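---
title: "Patch-based classification of colonic polyp images: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based classification of colonic polyp images: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-magnification endoscopy reveals the pit pattern of the colonic
mucosa — the size, shape and spatial arrangement of the surface pits —
which separates non-neoplastic from neoplastic lesions well enough to be
clinically useful. `polypatch` implements a complete, testable pipeline
for the two-class problem on still images: texture-bearing patches are
extracted from each 256 x 256 image, classified individually, and the
image-level decision is taken by majority vote; alternatively a texture
descriptor or a CNN layer activation summarises the whole image and a
linear SVM decides. Because clinical endoscopy databases are small and
private, the package ships a synthetic cohort generator that reproduces
the *structure* of such a database — patients, per-patient image counts,
class imbalance, nuisance artefacts — so every stage can be exercised and
audited end to end.

## The synthetic cohort generator

Each image is a mucosa-toned background (RGB base tone with smooth
low-frequency modulation) carrying dark elliptical "pits": a Poisson
number of blobs (density per 10^4 px) with Gaussian-profiled elliptical
cross-sections. A blob of radius $r$ and elongation $e \ge 1$ has
semi-axes $r\sqrt{e}$ and $r/\sqrt{e}$, so elongation changes shape
without changing area — elongation, density and contrast are therefore
independent class cues. The defaults give the non-neoplastic class round,
denser, fainter pits (elongation 1.2, density 12, contrast 0.35) and the
neoplastic class elongated, sparser, stronger pits (elongation 3.0,
density 8, contrast 0.55), echoing the qualitative difference between
regular and irregular pit patterns.

Three endoscopy nuisances are applied after texture synthesis: a linear
illumination gradient (fractional amplitude), an edge-renormalised
Gaussian blur with per-image sigma drawn from a range, and a small number
of specular highlights. Nuisances never influence labels or metadata.

Two design parameters deserve comment:

* **`difficulty`** in $[0, 1]$ linearly shrinks both classes' texture
  parameters towards their midpoint: 0 keeps the configured (disjoint)
  supports, 1 makes the classes identical so no classifier can beat
  chance. This one knob turns the generator into a calibrated test
  instrument: recovery experiments run at 0, null experiments at 1.
* **`class_assignment`** is the per-patient probability that an image is
  abnormal. Patients may contribute images of both classes — real
  per-class patient counts sum to more than the patient total, so the
  mixing proportion is exposed rather than guessed.

Seeding is hierarchical: a master seed plus a stable string hash of
`(patient_id, image index)` gives every patient and image its own
substream, so enlarging a cohort never reshuffles previously generated
images, and metadata is bit-reproducible.

What the generator does *not* emulate: real mucosal optics, vascular
patterns, modality-specific (virtual chromoendoscopy) colour transforms,
or inter-image registration artefacts. Passing tests on synthetic cohorts
demonstrate that the pipeline's machinery — augmentation, patient-grouped
validation, training, voting, fusion, significance testing — is correct
and leak-free; they say nothing about accuracy on clinical images.

## Preprocessing

Augmentation produces exactly seven derived samples per image (horizontal
and vertical flips, both 90-degree rotations, flips of the rotations, and
the 180-degree rotation), each keeping its parent's patient id, so a
100-image cohort becomes 800 images. Patches are extracted either on a
regular grid — offsets at all multiples of the stride in
$[0, \mathrm{side} - P]$, giving $(\lfloor(\mathrm{side}-P)/s\rfloor+1)^2$
patches, i.e. 676/49/25/9 at strides 5/20/32/48 for $P = 128$ on a
256-px image — or uniformly at random with replacement. For the stride-1
case this convention gives $129^2$ positions; a sliding convention that
yields exactly $128^2$ is not reconstructable, and we keep the consistent
closed-interval rule. Balanced sampling draws a per-image patch count
that depends on the class (e.g. 75 from each healthy and 25 from each
abnormal image when abnormal images are three times as frequent),
equalising per-class patch totals. Every patch is normalised by
subtracting its mean and dividing by its population standard deviation
(all pixels and channels jointly); constant patches map to zero rather
than dividing by zero. Resizing to a network's input (256 to 224) uses
the Keys bicubic kernel ($a = -0.5$) with linear edge extrapolation, which
reproduces linear ramps exactly and is the identity at equal size.

## From-scratch CNNs

The five small architectures for 128 x 128 x 3 patches (CNN-01..CNN-05)
are specified by their filter counts/sizes and hidden FC width; CNN-05 is
conv 48@11x11, conv 72@5x5, conv 1024@6x6, FC 1024, softmax. The
remaining geometry is fixed as the smallest consistent choice: first conv
stride 3 valid, 2x2 max pooling of stride 2 after the first two stages,
later convs stride 1 valid, ReLU everywhere except the softmax head. For
CNN-05 this chains 128 -> 40 -> 20 -> 16 -> 8 -> 3, giving 12,199,434
trainable parameters. The AlexNet-style 227-px architecture (`ARCH-227`)
follows the same conventions with stride 4 and pooling after stages 1, 2
and 5.

Training minimises softmax cross-entropy. Two optimisers are provided:
momentum SGD (default: lr 0.01 decayed 10x after two thirds of the
epochs, momentum 0.9, weight decay 5e-4, batch 64, 30 epochs) and Adam.
Per-tensor gradient-norm clipping (default ceiling 5) damps the
early-epoch spikes that otherwise kill ReLU units on very small patch
sets. Convolutions run through batched im2col and single-precision BLAS;
weight updates are double precision and in place. Given a seed, weight
initialisation (He-scaled Gaussians), batch order and therefore the final
weights are bit-reproducible.

An image is classified by extracting grid or random patches of the
model's input size, normalising and classifying each, and taking the
majority patch label; a tied vote resolves to *abnormal*, favouring
sensitivity in a screening context. The two fully connected taps
(`PFCL`, the hidden FC layer; `LFCL`, the classifier layer) expose
activation vectors for SVM-on-CNN-features variants.

## Off-the-shelf extractors and classical features

Registry replicas of VGG-VD16/19, CNN-F/M/S, AlexNet and GoogleLeNet
reproduce each network's weight-layer structure (e.g. 13 conv + 3 FC for
VGG-VD16), 224 x 224 x 3 input, and tap widths (4096; 1024 for
GoogleLeNet, whose replica ends in a global average pool). Inception
modules are simplified to a sequential stack of equivalent spatial shape:
the replicas guarantee shape and data-flow contracts, and accept
externally converted weights via `load_external_weights()`; all tests run
with random weights, since ImageNet-trained weights are an optional
plug-in, not a dependency.

Two classical descriptors are implemented. **MB-LBP** computes LBP codes
on block means (integral-image accelerated): at each valid position the
means of the eight neighbouring b x b blocks are compared (>= counts
as 1, with a small tolerance so exact ties behave as >=) against the
central block mean, the 8-bit codes are histogrammed over 256 bins,
normalised, and concatenated across scales (default b = 1, 3, 5).
**GWT-Weibull** filters the luminance image with a complex Gabor bank
(wavelengths 4, 8, 16, ... px, sigma = 0.56 lambda, aspect 0.5,
orientations evenly spaced over 180 degrees; circular FFT convolution)
and fits a two-parameter Weibull to each subband's magnitude responses by
maximum likelihood — a safeguarded Newton iteration on the profile
likelihood (tolerance 1e-8) with the scale recovered in closed form. The
kernels are built so that a 90-degree image rotation exactly permutes
orientation blocks, which the tests exploit.

Feature-level fusion is concatenation with recorded block provenance.
Because concatenated blocks live on wildly different scales, SVM training
z-scores every column with training-fold statistics and replays the same
transform at prediction; the classifier is the linear-kernel C-SVM from
`e1071` (C = 1 by default).

## Evaluation

Cross-validation is patient-grouped throughout: leave-one-patient-out
(one fold per patient) or a grouped k-fold with prescribed test-set sizes
(nine folds of 6 patients plus one of 8 for a 62-patient cohort).
Augmented and cropped samples always follow their parent's patient, so no
form of a test image can reach the training side; the tests audit this
over patch provenance. Accuracy is image-level, after voting.

Classifier pairs are compared with the exact McNemar test: with
discordant counts $n_{01}$ and $n_{10}$,
$p = \min(1,\, 2 P(\mathrm{Bin}(n_{01}+n_{10}, 1/2) \le
\min(n_{01}, n_{10})))$, and $p = 1$ without discordance. The exact
binomial form is used because image counts near 100 leave discordant
counts far too small for the chi-square approximation. Pairwise flags at
a significance level are reported without multiple-testing correction,
matching the per-pair presentation convention of comparison matrices.
`run_pipeline()` drives the whole loop from a config (R list or YAML) and
writes CSV tables plus a JSON summary; reruns with the same seeds are
byte-identical.

## The validation experiments and their scale

The acceptance-level experiments are sized for a single CPU:

* **Recovery**: 20 patients, 60 images of 256 px, balanced class
  assignment, difficulty 0, CNN-05 under LOPO with 3 random patches per
  training image, Adam (lr 2e-4, batch 16, 6 epochs), 25-patch grid
  voting (stride 32). Expected image-level accuracy >= 0.95.
* **Null**: difficulty 1 must stay inside the chance band [0.35, 0.65] —
  balanced class assignment makes the band meaningful even for a
  degenerate always-abnormal classifier. The null runs with a lighter
  training budget (2 patches per image, 2 epochs): unlearnability is a
  property of the data, and no amount of training effort can create
  signal where the classes are identical, so spending the recovery
  budget here would only spend time, not change the conclusion.
* **Fusion**: a two-cue cohort (40 patients, 80 images of 128 px) whose
  classes differ in elongation and in contrast, at difficulty 0.55 so
  that each single descriptor family is imperfect; fused
  MB-LBP + GWT-Weibull must do at least as well as each constituent
  (within one point) and strictly better than at least one.

Adam rather than the SGD default is used at this scale because a
few-epoch budget on ~100 patches leaves momentum SGD on a knife edge
between divergence and under-fitting, while per-parameter step
adaptation converges reliably; the SGD defaults remain the documented
full-scale protocol. The choice of 2 patches per image, 9-vote grids and
small epoch counts is the package's declared desk-scale protocol; all
three experiments are re-run from scratch by `scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* Convolution GEMMs are single precision; reported probabilities and all
  statistics are double. Forward activations agree with a direct
  double-precision convolution oracle to ~1e-5.
* Constant patches normalise to zero; degenerate (all-zero) Gabor
  subbands raise an error naming the subband; Weibull fitting requires
  at least two positive observations.
* Majority-vote ties go to abnormal; patch-level probability ties
  likewise. Vote aggregation is invariant to permutation and
  duplication of the votes.
* Grid offsets are 0-based multiples of the stride in a closed interval;
  random offsets are uniform with replacement over the stride-1 grid.
* PNG I/O quantises to 8 bits; the round trip preserves pixels to 1/255
  and metadata exactly.

## Known limitations

* The generator is a designed stand-in, not a simulator of colon optics;
  accuracies on it do not transfer to clinical data.
* The inception-module internals of the GoogleLeNet replica are
  simplified to a sequential shape-equivalent stack.
* Off-the-shelf replicas ship without trained weights; feature quality
  with random weights is only a shape/flow contract.
* The from-scratch trainer is CPU-bound and sized for small cohorts;
  full-scale (hundreds of epochs, thousands of patches) training is out
  of scope.
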