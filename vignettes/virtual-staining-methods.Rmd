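---
title: "Methods: virtual staining of SRS images, droplet statistics and agreement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual staining of SRS images, droplet statistics and agreement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srstain)
```

This vignette is the package's own account of its models and the choices
behind them: what is simulated and why, how the networks and losses are
defined, which knobs matter, and what the tests do and do not demonstrate.

## The problem

Stimulated Raman scattering (SRS) microscopy measures the vibrational
response of tissue at chosen Raman shifts and so maps chemistry — lipids,
proteins, nucleic acids — without stains. Thick fresh-frozen (FF) sections
can be imaged this way in minutes, and optical sectioning yields several
planes per physical cut. But pathologists diagnose from H&E morphology, and
the gold standard is the FFPE section, which takes hours to days to
prepare. The pipeline here closes that gap computationally: discrete SRS
bands → virtual FF H&E (paired translation) → virtual FFPE H&E (unpaired
translation), with two quantitative side-analyses (lipid-droplet density by
band ratio; interobserver agreement of pathologist scores).

## The tissue phantom

No imaging data ships with the package; every test runs on a seeded
synthetic phantom that emulates the relevant structure of the real data:

* **Spectra.** Each tissue class (stroma, nuclei, epithelium, lipid
  droplets) gets a max-normalised spectrum built from Gaussian peaks on the
  2800–3105 cm⁻¹ axis (4 cm⁻¹ steps, 77 bands): the lipid CH₂ stretch near
  2847 cm⁻¹, the protein CH₃ stretch near 2933 cm⁻¹, and smaller peaks near
  2880, 2960, 2979 and 3062 cm⁻¹, over a small constant tissue baseline
  (0.05 before normalisation) that keeps band tails away from the
  clip-at-zero floor. By construction the 2847/2933 ratio exceeds 1 only
  for droplets — the single property the droplet statistic needs. A seeded
  jitter (±3% amplitudes, ±2 cm⁻¹ centres) emulates biological variation
  without ever flipping that ordering.
* **Morphology.** Glands are lumen + epithelial ring + nuclei dots in a
  stroma background; the clinical-concern class controls architecture (low
  = open lumens, moderate = crowded small lumens, high = fused sheets
  without lumens). The rasteriser is split from the parameter sampler so
  multi-depth stacks can morph one gland set smoothly across planes
  (per-gland drift and radius breathing, scaled by a decorrelation rate; 0
  freezes the morphology; a tumour-onset mode plants high-grade glands only
  beyond a chosen depth).
* **Forward model.** Pixel spectrum = class spectrum × smooth brightness
  field + Gaussian noise, optional blur, clipped at zero. This is an
  invented stand-in — the real study reports only class spectra, not noise
  statistics or backgrounds — chosen as the simplest model that preserves
  the band ratios the downstream methods consume. Default noise SD is 0.01
  on max-normalised spectra (visually mild speckle; SNR ≈ 100 at peak).
* **H&E renders.** A per-class colour lookup (hematoxylin blue-purple
  nuclei, eosin pinks, white lumens) modulated by a seeded multiplicative
  texture; the FFPE style is a global contrast (1.35 about per-channel
  means) + saturation (1.15) transform of the FF base, so FFPE renders are
  always higher-contrast than FF — the property the cycle translator must
  learn. The four FF artifact kinds (stain unevenness, freezing holes,
  knife-cut streak, local blur) paint only into FF renders.
* **Droplet planting.** `ld_area_fraction` is defined as droplet pixels /
  epithelium pixels in the emitted mask; the planter solves
  L = f·E₀/(1+f) for the droplet budget before converting epithelium
  pixels, so a recount of the emitted mask lands on the requested fraction
  to within disk granularity (~±10% relative).

What passing tests on this phantom show: the *computational* pipeline is
correct — losses, gradients, schedules, segmentation and statistics do what
their definitions say, and the generators can learn a mapping of this
complexity. What they cannot show: performance on real tissue, where
spectra overlap more, morphology is richer, registration is imperfect, and
staining varies between laboratories.

## Networks and losses

The generator is a compact U-Net: per level a 3×3 convolution + instance
normalisation (no learned affine) + leaky ReLU (slope 0.2) kept as the
skip, a stride-2 convolution to descend, a bottleneck, and per decoder
level nearest-neighbour upsampling, convolution, skip concatenation and a
mixing convolution; a 1×1 convolution + sigmoid maps to [0,1]³. Inputs must
be divisible by 2^depth; tiled inference pads by edge replication and
crops. The discriminators are PatchGAN-style stride-2 conv stacks emitting
a spatial score map; the multi-scale pair applies the *identical*
architecture (and, from the shared seed, identical initial weights) to the
image and its 2× average-pooled version.

The loss algebra follows the published recipe: phase I of the stainer is
pixel MSE alone (the result is correct but over-smooth); phase II continues
from those weights with

$$\mathcal{L}_{G1} = \mathcal{L}_{adv} + \alpha\,\mathrm{MSE} +
\gamma\,\mathcal{L}_{perc}, \qquad \alpha = 0.01,\ \gamma = 0.005,$$

and the unpaired FF→FFPE pair minimises both adversarial terms plus
$\lambda$ (= 10) times the two L1 cycle terms. Three choices were genuinely
open and are isolated so each is a one-line change:

* **Adversarial form.** Least-squares GAN (score maps regressed to 0/1),
  the form standard in the multi-scale-discriminator lineage this design
  descends from. Confined to `loss_adversarial()`.
* **Term assignment.** α weighs the pixel term and γ the perceptual term;
  both live in `loss_weights()` so the transposed assignment is a config
  change.
* **Perceptual extractor.** A fixed, never-trained, seeded random two-layer
  conv stack with taps after each nonlinearity. A pretrained deep feature
  network would serve the same role through the same interface
  (`feature_extractor()`), but none ships with the package; the `identity`
  provenance (a 1×1 identity convolution) makes the perceptual loss
  collapse exactly to the pixel MSE and is used to verify the plumbing.

All forward/backward passes are hand-written (compiled im2col/GEMM kernels
for the convolutions) and verified against central finite differences at
10⁻⁴ relative tolerance — for single layers, the full generator (every
parameter tensor), and every loss.

## Training

Adam (β₁ = 0.9, β₂ = 0.999, the cited defaults) with learning rate
10⁻⁴ · 0.96^⌊t/1000⌋ for generators and discriminators alike; one
discriminator update per generator update (the source is silent; 1:1 is the
simplest choice). No image-pool replay buffer for the cycle pair — a
deliberate simplification, recorded here. Per-iteration batches are drawn
with replacement from the pools under one seeded stream, so runs are
bitwise reproducible; the unpaired pools are sampled independently
(audited by `cycle_index_stream()`). Augmentation draws one crop offset
(uniform over all in-bounds positions, 500→384 by default) and one random
affine (±10° rotation, 0.9–1.1 scale, ±5° shear — the source specifies
none) shared by both patch members.

The full-scale presets mirror the published regime (50,000 + 200,000
iterations at batch 9; 100,000 at batch 6) and are not exercised by the
tests. The tested desk-scale presets are 8 phantom pairs at 64×64,
base width 16, depth 2: 300 MSE + 300 GAN iterations at batch 4 for the
stainer, 400 iterations at batch 2 for the cycle pair — sizes chosen so the
entire two-model training runs in minutes on one CPU while still showing
the qualitative behaviour (pixel MSE halves in phase I; cycle loss falls
by a third).

## Numerical choices

* Nearest-band lookup breaks ties toward the lower shift (deterministic).
* Bilinear 2× upsampling uses the corner-aligned convention: even output
  indices coincide with source pixels.
* Warps are inverse-mapped bilinear; out-of-bounds samples are filled with
  the source median to keep dark borders out of training patches.
* Tile coordinates are 0-based (row, col), origin top-left, half-open
  intervals; the last tile of an overlapping grid is clamped to the image
  edge and blend windows are normalised so per-pixel weights sum to 1
  exactly.
* Band selection evaluates candidates on held-out pixels (default 25%)
  rather than in-sample error, so noise cannot make a selection look
  trivially good; the regression is plain OLS per output band (the source
  does not state the regression form; OLS is recorded here as the choice).
  Collinear designs (e.g. low-rank noiseless cubes) take the pivoted
  least-squares solution; only duplicated bands are an error. Greedy
  selection reuses precomputed Gram matrices, which also makes the
  exhaustive small-k search cheap enough to act as its oracle. On exactly
  noiseless low-rank data the error cannot discriminate between subsets
  (every invertible subset reconstructs exactly), so candidates whose
  errors tie within numerical resolution are resolved to the
  higher-variance — in practice higher-SNR — band, then to the lower
  shift; under this rule the exhaustive reference lands on the dominant
  spectral peaks, while forward selection may legitimately keep a mixed
  between-peak band picked at an earlier step.
* The droplet ratio threshold is not a published number; the default is
  the midpoint of the phantom library's droplet and epithelium ratios
  (`ld_default_threshold()`), and `ld_report()` always records the value
  used. Droplet density is an area fraction; IQR uses linear-interpolation
  (type 7) quantiles; pairwise t tests are pooled-variance by default
  (Welch behind a flag); no multiplicity correction is applied to the
  pairwise table.
* Fleiss' κ uses the classical large-sample variance with a
  normal-approximation 95% CI (the CI method behind published tables of
  this kind is typically unstated; this one is recorded).
* Cube TIFFs store 32-bit samples; intensities are quantised to one part in
  2³² of the recorded scale (finer than single-precision float), and the
  writer hands the TIFF layer sample centres so the quantisation is
  idempotent — a write–read round trip is bit-stable.

## Study-condition sizes

The phantom cohort for the droplet statistics defaults to four classes
(stroma and low/moderate/high concern) with planted mean ROI-area
fractions 0, 0.005, 0.05 and 0.03 — the qualitative ordering reported for
tissue (moderate-concern glands highest, stroma negligible) — with ±30%
per-ROI spread; tests use 20 ROIs per class at 96×96, and the full-scale
design (96/56/61 gland patterns plus 119 stromal ROIs) is available via
`make_ld_cohort(n_per_class = NULL)`. The survey fixture template is 35
items × 5 raters per condition, matching the published design.

## Known limitations

* The phantom's noise model, H&E colour model and depth morphing are
  deliberate simplifications; none is a physical simulation.
* Desk-scale GANs produce plausible colourisation, not
  publication-quality histology; the full-scale presets exist but need
  real data and long runs.
* Control-point selection for registration is manual by design; no
  deformable registration is attempted.
* The statistics module reproduces the published *procedures* (ANOVA,
  pairwise t, IQR/mean, Fleiss' κ with banding); the published clinical
  values themselves depend on a private 75-sample dataset and are out of
  reach by construction.
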