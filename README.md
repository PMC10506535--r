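# srstain

Virtual histologic staining of stimulated Raman scattering (SRS) images.

Fresh-frozen (FF) tissue can be imaged label-free with SRS microscopy at a
handful of Raman shifts in the CH-stretching window (2800–3105 cm⁻¹), but
the resulting chemical maps are not interpretable by pathologists. This
package implements the computational workflow that turns such measurements
into familiar diagnostic images: a two-phase conditional GAN (G1) that maps
7-band SRS images to fresh-frozen H&E appearance, and an unpaired
cycle-consistent translator (G2/G3) that converts those virtual FF images
into archival-quality, FFPE-like H&E — plus the supporting analyses a study
of this kind needs: discrete-frequency band selection by regression-based
spectral reconstruction, lipid-droplet quantification from the
SRS(2847)/SRS(2933) band ratio with group-comparison statistics, and
interobserver-agreement analysis (Fleiss' κ) for pathologist surveys.
Everything is testable end-to-end on a built-in synthetic tissue-phantom
generator with ground-truth masks, so the whole pipeline runs at desk scale
on one CPU.

It is aimed at computational-pathology and label-free-imaging researchers
who want a self-contained, fully inspectable R implementation of this
workflow — every loss term, gradient and statistic is hand-auditable and
tested against brute-force oracles.

## The models

**Virtual staining (G1).** A U-Net generator `G1 : SRS bands → RGB` trained
in two phases: phase I minimises the pixel loss `MSE(G1(x), y)` alone
(50,000 iterations at full scale), then phase II continues from those
weights with the composite objective

    L_G1 = L_adv(D(G1(x)), 1) + α·MSE(G1(x), y) + γ·L_perc(G1(x), y)

with α = 0.01 and γ = 0.005, where `L_adv` is the least-squares GAN
objective over two discriminators — an identical pair scoring the full
resolution and the 2× average-pooled image — and `L_perc` is the MSE
between feature maps of a fixed convolutional feature extractor (200,000
iterations, batch 9 at full scale). Adam, initial learning rate 10⁻⁴
multiplied by 0.96 every 1,000 iterations; training patches are random
384×384 crops of 500×500 tiles with a shared random affine.

**Virtual FFPE (G2/G3).** FF-style and FFPE images are unpaired, so the
FF→FFPE translator trains as a cycle pair with

    L = L_adv(G2) + L_adv(G3) + λ·( ‖x − G3(G2(x))‖₁ + ‖y − G2(G3(y))‖₁ )

with λ = 10 (100,000 iterations, batch 6 at full scale). Desk-scale presets
(`desk_scale = TRUE`) run the same code on 64×64 phantoms in minutes.

**Lipid droplets.** Droplets are CH₂-dominated, so the per-pixel ratio
r = SRS(2847)/SRS(2933) exceeds 1 inside droplets and stays below 1 in
protein-rich tissue. Thresholding r segments droplets; density per region
of interest is the droplet-pixel fraction; groups are compared with one-way
ANOVA and pairwise pooled-variance t tests, and within-class heterogeneity
is summarised as IQR/mean.

**Agreement.** Fleiss' κ = (P̄ − P̄ₑ)/(1 − P̄ₑ) with the large-sample
variance and a normal-approximation 95% CI, plus the conventional
interpretation bands (0.41–0.60 = moderate, etc.).

## Worked example

```r
library(srstain)

# a synthetic prostate-tissue sample: SRS cube + paired FF/FFPE H&E
s <- generate_phantom_sample(seed = 21, shape = c(96, 96),
                             grade_class = "moderate",
                             ld_area_fraction = 0.05)
s
#> <phantom_sample> 96 x 96 px, grade moderate, LD fraction 0.0497, seed 21

# droplet quantification at the library-implied ratio threshold
thr <- ld_default_threshold(s$library)
r   <- ratio_map(s$bands)
m   <- segment_ld(r, thr)
roi_m <- matrix(unclass(s$mask) %in% MASK_CLASSES[c("epithelium",
                 "lipid_droplet")], 96, 96)
roi <- roi_annotation(roi_m, "moderate")
ld_density(m, roi)$density
#> [1] 0.04736211

# cohort-level statistics across the four classes
cohort <- make_ld_cohort(n_per_class = 20, seed = 3, shape = c(96, 96))
rep_ <- ld_report(cohort, threshold = ld_default_threshold(attr(cohort, "library")))
rep_
#> <ld_group_stats> 4 classes, ANOVA F = 351.34 (p = 1.93e-44), threshold 1.998
#>   stroma    n =  20  mean density 0.00000  IQR/mean NA
#>   low       n =  20  mean density 0.00491  IQR/mean 0.264
#>   moderate  n =  20  mean density 0.04675  IQR/mean 0.354
#>   high      n =  20  mean density 0.03018  IQR/mean 0.287

# interobserver agreement for a ratings table (items x raters)
k <- fleiss_kappa(ratings_table(matrix(sample(1:5, 35 * 5, TRUE), 35, 5)))
interpret_kappa(0.491)
#> [1] "moderate"
```

The moderate-concern class carries the highest droplet density, the
high-concern class an intermediate one, and stroma essentially none; the
ANOVA confirms the classes differ far beyond chance. A kappa of 0.491
for grading agreement falls in the "moderate" band.

Training at desk scale:

```r
pairs <- lapply(1:8, function(i) { ... })   # paired 64x64 SRS/H&E patches
fit <- train_g1(pairs, g1_config(desk_scale = TRUE, seed = 1))
vffpe <- virtual_sectioning(fit$generator, g2, stack)  # multi-depth output
```

A thin command-line wrapper ships at `inst/cli/srstain`
(`simulate`, `select-bands`, `tile`, `train-stain`, `train-ffpe`, `infer`,
`ldquant`, `kappa` subcommands; see `?cli`).

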