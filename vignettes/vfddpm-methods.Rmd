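---
title: "Methods: diffusion-based synthetic augmentation for vocal fold imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion-based synthetic augmentation for vocal fold imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Laryngoscopy datasets for vocal fold structural pathology (VFSP) are small
and severely imbalanced: common lesion phenotypes (nodules, cysts) may have
tens of examples while rare ones (granuloma) have a handful, and healthy
folds dominate. Classifiers trained on such collections routinely fail to
converge. `vfddpm` implements and evaluates one remedy: train a denoising
diffusion probabilistic model (DDPM) per class, sample synthetic images to
rebalance the collection, screen them for quality, and measure how
augmented training sets change binary (pathology present/absent) and
multi-class (seven lesion phenotypes) classification.

The package's reference conditions emulate a 404-image clinical collection
with per-class counts 157/71/38/35/33/29/37/4 (healthy, nodule, cyst,
polyp, sulcus vocalis, Reinke's edema, keratosis, granuloma; imbalance
ratio 39.25) and per-class synthetic targets totalling 4180 that invert the
imbalance in favour of the rare classes.

## Phantom data: what it emulates and what it does not

No public laryngoscopy images can be bundled, so every experiment runs on
procedurally generated phantoms (`render_phantom()`): a dark vignette, a
textured pink mucosa field, two pale elongated fold bands meeting
anteriorly around a dark glottal gap, and one lesion drawn per class
archetype from the standard clinical descriptions (bilateral symmetric
mid-fold bumps for nodules, a single encapsulated mid-fold mass for cysts,
a reddish irregular blob for polyps, bilateral fold widening for Reinke's
edema, a dark medial-edge groove for sulcus, a posterior mass near the
vocal process for granuloma, a whitish patch for keratosis). Nuisance
variation emulates acquisition conditions: rotation uniform in ±15°,
illumination gain ±20%, Gaussian sensor noise with sd 4 intensity units.
These amplitudes give the generative model non-trivial variation to learn
without drowning the class signal; no quantitative appearance statistics
exist for the source domain, so they are conventions, not estimates.

Phantoms are parametric, not photorealistic. Passing tests therefore show
that the pipeline's machinery is correct and that the augmentation
mechanism works when class-relevant structure is learnable; they do not
show that a diffusion model of this size captures real laryngeal
appearance. Ground-truth lesion masks are emitted for every image, which
real data would not provide.

The default phantom side is 64 px for fixture work; the benchmark runs at
24 px (below) since every property under test is scale-free.

## The diffusion model

The forward process corrupts a sample in closed form,
$x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon$, with
the squared-cosine cumulative schedule
$\bar\alpha_t = f(t)/f(0)$, $f(t) = \cos^2\!\big(\tfrac{t/T+s}{1+s}\cdot
\tfrac{\pi}{2}\big)$. The offset is $s = 0.008$, the established
convention for this schedule. Per-step quantities are derived from
consecutive ratios, $\beta_t = 1-\bar\alpha_t/\bar\alpha_{t-1}$, clipped at
0.999 to avoid a singular final step; after clipping the stored
$\bar\alpha_t$ is recomputed as $\prod_{u\le t}(1-\beta_u)$ so the product
identity holds to machine precision. The reverse process is the standard
noise-prediction parameterization
$\mu_\theta = \tfrac{1}{\sqrt{\alpha_t}}\big(x_t -
\tfrac{\beta_t}{\sqrt{1-\bar\alpha_t}}\epsilon_\theta(x_t,t)\big)$ — the
unique choice consistent with the mean-squared noise-prediction objective —
with simple variance $\sigma_t^2 = \beta_t$ and a deterministic final step
($\sigma_1 = 0$).

### The denoiser

No deep-learning framework is available to this package, so the denoiser
is a dense encoder–decoder written on base-R matrix algebra with
hand-derived gradients and Adam: sinusoidal timestep embeddings injected
into every block, residual blocks, an encoder-to-decoder skip
concatenation, and — crucially — a time-gated identity shortcut
$(E\,T_s)\odot x_t$ plus a time-modulated bias at the output. The shortcut
matters: the optimal noise prediction approaches
$x_t/\sqrt{1-\bar\alpha_t}$ at large $t$, a near-identity map that a
low-width bottleneck cannot represent (without it, training plateaus at a
loss near 1 and samples are noise). A convolutional U-Net gets the same
property natively from its image-resolution skip connections; the gate is
the dense-network equivalent.

### Profiles and numerical choices

Two profiles are exposed. The *desk* profile — used by every test and
analysis — runs $T = 200$, widths 64/32, batch 32, 1200–3000 updates, and
learning rate $2\times10^{-3}$. The *paper* profile records the published
settings of the emulated study (input 256 or 128, batch 32 or 16,
$T = 10{,}000$, learning rate $10^{-4}$; the source reports both listings,
and whether its "steps" count timesteps or optimizer updates is ambiguous,
so the profile is recorded for provenance and not exercised). The desk
learning rate deviates from the published $10^{-4}$ deliberately: shrinking
training from hours of GPU work to a few thousand CPU updates requires
proportionally larger steps, and at $10^{-4}$ the desk denoiser cannot
leave its initialization in the available updates. The classifier keeps the
published $10^{-4}$ exactly, since classifier behaviour under the study
protocol is the quantity being reproduced.

Ancestral sampling clamps the implied clean sample
$\hat x_0 = (x_t - \sqrt{1-\bar\alpha_t}\,\hat\epsilon)/\sqrt{\bar\alpha_t}$
to $[-1,1]$ at every step and uses the forward-posterior mean of the
clamped $\hat x_0$; where the clamp is inactive this equals the plain
parameterization exactly, and it prevents per-pixel error amplification
from saturating samples. One unconditional model is trained per class
(class-conditional generation is out of scope). Timesteps are drawn
uniformly from $\{1..T\}$ during training; images are rescaled to
$[-1,1]$.

The machinery is validated on a known distribution: a two-component 2-D
Gaussian mixture (means $(\pm0.6,\pm0.6)$, sd 0.15, 1024 training points —
chosen as a well-separated but non-trivial target). After 3000 desk-profile
updates, 500 samples recover both component means within 0.1 and ≥95% of
samples fall within 3 component standard deviations of a true mean.

## Curation

The emulated study had experts discard deformed, implausible, or
remarkably blurry synthetic images. The automated stand-in implements the
two stated criteria as measurable filters: a sharpness score (variance of
a 4-neighbour Laplacian of luminance) thresholded at the 5th percentile of
the original collection's scores (inverted-ECDF quantile, so a reference
image at the threshold is retained), and a fold-structure detector that
thresholds the central 60% luminance crop at its 70th percentile, labels
connected components, and counts components that are large (≥2% of the
crop), elongated (eccentricity ≥ 0.8), and genuinely brighter than the
mucosa (mean luminance ≥ 1.15× the crop median — without the contrast
test, bright texture patches in a fold-free image masquerade as bands).
Exactly two bands is plausible; zero emulates "no folds visible", three or
more a deformed render. The detector constants are conventions tuned on
pristine phantoms and recorded in every report. A rejection can name
either criterion; fold removal, for instance, also destroys most
high-frequency structure, so such images may be rejected as blurry before
the band count is consulted. At 24 px the glottal gap is 1–2 px wide and
the detector misses it on a few percent of pristine-quality images; this
acts as a slightly conservative expert, rejecting ~13% of benchmark
synthetic images.

## Augmentation scenarios and classifiers

`build_scenario()` reproduces the study designs: *synthetic-only* (train
on synthetic, test on all originals), *mix10*/*mix50* (train on synthetic
plus a per-class largest-remainder 10%/50% of originals, test on the
rest), and the *original-only baseline* (stratified 80/20
train/validation, no synthetic data). Multi-class experiments use the
seven lesion classes only; binary experiments collapse them to
pathology-present with `with_pathology` as the positive class (consistent
with the high-sensitivity / low-specificity pattern such screens show when
healthy images are the minority negative). Tests never contain synthetic
images, and granuloma's 4 originals contribute 0 images to mix10 (warned),
since 10% of 4 rounds to zero.

The desk classifier is a two-hidden-layer perceptron (64/32, SiLU) on
standardized flattened pixels, trained exactly per the study protocol:
Adam, learning rate $10^{-4}$, batch 16, integer-label cross-entropy, 20
epochs, no further tuning. The published 16- and 50-layer convolutional
backbones cannot be trained in this environment; their descriptors are
accepted for provenance. The "pre-trained" study condition maps to
warm-starting from a user-supplied trained model, never a download.

## The benchmark and what it shows

The default benchmark (tests and the acceptance script) uses the full
reference imbalanced distribution at 24 px, per-class DDPMs (1200 updates
each), synthetic targets at one quarter of the reference synthetic counts
(kept proportional; full counts would quadruple runtime without changing
the ordering), curation, and 3 repeats per cell with derived seeds. Under
these conditions the original-only multi-class baseline stays below 0.5
validation accuracy — about 400 optimizer updates on 198 heavily
imbalanced images leaves the model near its majority-class collapse,
mirroring the source study's "failed to converge" baseline — while mix50
exceeds 0.5 and is at least as accurate as synthetic-only, reproducing the
study's qualitative ordering. Binary scenarios reproduce its
high-sensitivity / low-specificity signature. These are directional
reproductions on phantom data; absolute values are not comparable to
metrics measured on clinical images with large pretrained networks.

## Distribution similarity

`fid()` implements the Fréchet distance between Gaussian approximations of
two feature sets, $\|\mu_r-\mu_s\|^2 + \mathrm{Tr}(\Sigma_r + \Sigma_s -
2(\Sigma_r\Sigma_s)^{1/2})$, with the matrix square root taken by
eigendecomposition of the symmetrized product, negative eigenvalues
clipped at zero, covariances regularized by $10^{-6}I$, and a zero floor.
The canonical feature extractor (a large pretrained image network) needs
external weights, so the package default is a PCA projection fitted on the
original collection — deterministic, which a metric should be — with a
small bottleneck autoencoder available behind the same interface. Absolute
values are on the extractor's own scale: rankings and monotonicity are
meaningful, cross-study comparisons are not.

## Reproducibility

Every stochastic stage derives its seed from one global seed by a stable
integer hash of the stage name (and class label or repeat index), so any
stage can be re-run in isolation. Identical configurations reproduce every
artifact byte for byte; datasets round-trip exactly through the PNG +
manifest disk format.

## Known limitations

* Phantoms are geometric archetypes; none of the within-class appearance
  diversity, specularity, motion blur, or anatomical variation of real
  stroboscopy is modelled.
* The dense denoiser has no spatial weight sharing; it would scale poorly
  past ~64 px and is not a substitute for a convolutional U-Net at
  clinical resolution.
* The curation detector is calibrated to the phantom appearance model and
  would need re-tuning for real images.
* The multi-class specificity is computed one-vs-rest and macro-averaged
  by default; the weighted average is also reported, as conventions differ
  across studies.
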