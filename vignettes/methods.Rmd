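---
title: "omixae: models, metrics and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{omixae: models, metrics and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the models it
trains, the metrics it reports, the knobs that matter, what the synthetic
generator does and does not emulate, and the choices we made where the design
was genuinely open.

## The model family

All architectures share one dense building block — linear → batch
normalization → dropout → ReLU — with the ReLU omitted on the output layer
and on the last layer before the latent space. Hidden widths are not free
parameters: they follow the encoding-factor recursion

$$h_i = \max\{\lfloor h_{i-1}/e\rfloor,\; L_\mathrm{dim}\},\qquad h_0 = k_\mathrm{input},$$

so a single scalar $e$ (default 4, deliberately untuned) fixes the funnel
shape, and the decoder always mirrors the encoder. The variational models
learn $\mu$ and $\log\sigma^2$ heads and sample
$z = \mu + \epsilon\, e^{\frac{1}{2}\log\sigma^2}$ with
$\epsilon \sim \mathcal N(0,1)$ (the reparameterization trick), against a
standard Gaussian prior. The similarity loss is the analytic diagonal-Gaussian
KL divergence by default,
$\tfrac12\sum_d(\mu_d^2+\sigma_d^2-1-\log\sigma_d^2)$ averaged over the
batch, or alternatively an unbiased RBF-kernel MMD estimate (median-heuristic
bandwidth, clamped at zero, bandwidth treated as a constant in the
gradient).

Posterior collapse — the failure mode where the KL term wins early and the
latent space carries no information — is mitigated by logistic annealing of
the similarity weight:

$$\beta(\mathrm{epoch}) = \frac{\beta_\mathrm{final}}
{1+e^{-B(\mathrm{epoch}-M\cdot\mathrm{total\ epochs})}}.$$

Defaults: $M = 0.5$ and $B = 15/\mathrm{total\ epochs}$, chosen so that
$\beta(0)\approx 0$ and $\beta(T)\approx\beta_\mathrm{final}$ for any epoch
budget. $\beta_\mathrm{final}$ is *not* searchable by the tuner: it trades
off two loss terms, so minimizing the same loss over it is circular. A
useful manual guideline is to keep the similarity term below ~10% of the
reconstruction term; the loss history logs both so the ratio can be read
off directly.

**Stacked VAE.** One VAE per modality with latent width
$d_m = \max(2,\ \mathrm{round}(k_m/8))$ (floor of 2 because a 1-dimensional
VAE latent is degenerate), then a top VAE over the concatenated deterministic
$\mu$ embeddings. Training is uncoupled and two-phase; phase 2 never touches
phase-1 weights, which the tests verify by parameter snapshot.

**Ontology-masked VAE.** The decoder is the knowledge layer: latent units
correspond one-to-one to top-level ontology terms, and the linear decoder
stack is masked so a weight exists only where a feature→term (or
term→super-term) edge exists. One or two ontology levels are supported;
overlapping memberships are allowed. Masking is enforced by zeroing masked
weights at initialization, zeroing their gradients, and re-zeroing after
every optimizer step — exactly equivalent to sparse kernels but much
simpler, and exact to machine zero (asserted in the acceptance suite after
200 AdamW steps, including weight decay). When `latent_dim` is below the
number of top terms, one extra *dense* layer is inserted on both the encoder
and decoder ends; it is deliberately unmasked (it exists for dimension
reduction, not interpretation). Features absent from the ontology are
dropped for these runs, otherwise the mask would be undefined. Masked layers
use plain linear+ReLU without batch-norm or dropout, keeping the
term-to-feature weights directly interpretable.

**Cross-modal VAE.** Two VAEs with a shared latent dimensionality: a dense
VAE for the numeric source and, for images, a convolutional VAE (five conv
layers, kernel 4, stride 2, padding 1, so the side halves per layer and must
be divisible by 32; mirrored transposed-conv decoder). Channel widths double
16→256; we sized them for single-CPU training — disk-style and digit-style
images need nowhere near more, and nothing else in the design depends on the
widths. Alignment uses three signals on the sampled latents:

1. adversarial: a small classifier (input, two hidden layers, output) learns
   to tell the modalities apart; the VAEs are scored against *flipped*
   labels, so easily separable latent spaces are penalized. Alternation is
   one classifier step then one VAE step per batch, with classifier
   gradients zeroed between the two roles;
2. paired loss: mean absolute deviation across latent dimensions between the
   two embeddings of the same sample (requires paired samples);
3. class-center loss: mean absolute deviation of each embedding from its
   class center, computed within the batch pooled over both modalities, with
   centers treated as constants (stop-gradient) so the loss stays
   stochastic-gradient-friendly. This is the semisupervised alternative when
   pairing is unavailable.

Translation runs the source encoder deterministically ($\epsilon = 0$, i.e.
$z=\mu$) into the target decoder; class-center decoding feeds the
per-dimension *median* embedding of a class into the decoder. Pretraining of
the image VAE (with its own annealing schedule) precedes joint training and
noticeably stabilizes alignment; we do not freeze it afterwards.

## Embedding metrics

**Reconstruction R².** Per sample,
$R^2_s = 1 - \mathrm{Var}_f(x_s-\hat x_s)/\mathrm{Var}_f(x_s)$, averaged
over samples — scale- and width-invariant where raw MSE is not.
Zero-input-variance samples are excluded with a warning.

**Latent coverage.** Each dimension is binned into
$b=\lfloor n^{1/L}\rfloor$ equal-width bins between its observed min and max
(max falls in the last bin); coverage is the fraction of occupied cells on
the resulting $b^L$ grid. This grid-cell reading is the one under which the
three anchor cases come out right: a grid-filling sample gives 1, a point
mass gives $1/b^L$, and independent standard normal samples stay at or below
0.5 (the acceptance suite checks the 2-D case at $n=10{,}000$ across five
seeds; empirically it sits near 0.32). A purely marginal per-dimension
reading would saturate near 1 for any large Gaussian sample and could not
reproduce the 0.5 bound. Degenerate dimensions (min = max) are excluded from
the grid and contribute $1/b$. Coverage is invariant to per-dimension affine
rescaling by construction.

**Total correlation.** The shared information between latent dimensions. We
use the Gaussian estimator $-\tfrac12\log\det R$ with $R$ the Pearson
correlation matrix: closed-form, deterministic, exactly 0 at empirical
decorrelation, $+\infty$ (reported as `Inf`) for collinear dimensions.
Convention: 0 means independent/disentangled, larger means more entangled —
the standard definition.

**Downstream Z-scores.** Each annotation task (classification → macro
one-vs-rest AUROC, regression → $R^2$) is trained on the train split and
scored on the test split, for the embedding and for five seeded draws of
`latent_dim` random input features — the cheapest conceivable dimension
reduction. The Z-score $z=(\theta-\mathrm{avg}(\eta))/\mathrm{s.d.}(\eta)$
(population s.d.; near-constant cohorts yield `NA` with a warning) makes
tasks of different difficulty comparable: an easy task where random features
already score 0.98 should not flatter the embedding.

**Robustness.** With retraining, latent dimensions should mean the same
thing. For index-matched dimensions (term-anchored for the masked
architecture) we report the mean absolute Pearson correlation over all
unordered pairs of reruns; sign flips are deliberately forgiven, zero-variance
dimensions contribute 0 with a warning.

**Reference embeddings.** PCA (SVD on the centered train split, applied to
all samples) and UMAP (via `uwot`, fixed seed) provide non-AE baselines.

## The ML algorithms behind the evaluation

No external ML stack is available in the offline toolchain, so the three
algorithm classes are implemented in the package with fixed, documented
hyperparameters (never tuned): closed-form ridge / one-vs-rest logistic
regression; an RBF-kernel machine — kernelized Pegasos SVM (C = 1, 20
epochs) for classification and RBF kernel ridge regression (λ = 1) for
regression; and a random forest (100 bagged CART trees, √p or p/3 feature
subsets, depth ≤ 8). These are evaluation probes operating on ≤ a few dozen
dimensions and a few hundred samples; they are not meant as general-purpose
learners.

## The synthetic world

`make_multiomics()` draws class-conditioned latent factors
$F = c_{\mathrm{class}} + \mathcal N(0, I_k)$ (class centers scaled to a
stated mean separation) and emits per-modality matrices $X_m = FW_m + \eta$
with seeded Gaussian loadings and noise s.d. 0.1 by default — the weakest
structure under which every metric above has a known ground truth:
noiseless data have exact rank $k$, PCA with $L=k$ attains $R^2=1$, class
separation 0 forces AUROC to chance. Options: block-dominant loadings (each
feature block loads mainly on one factor) paired with `make_ontology()`'s
planted feature→term map, so the masked decoder's "correct" structure is
known; an elementwise softplus on the last modality to give nonlinear models
an edge over PCA; `make_images()` renders one filled disk per sample whose
radius tracks factor 1 and whose position tracks the class (disks rather
than digits: parameterized, license-free, resolution-controlled);
`make_links()` produces paired or within-class-shuffled linkage.

What the generator does **not** emulate: count distributions, dropout and
batch effects of real omics (normalization is assumed upstream), nonlinear
factor interactions, and any biological correlation structure beyond the
planted blocks. A green test therefore establishes that the machinery is
correct on linear-Gaussian worlds — not that an architecture will win on any
particular real dataset.

## Numerical choices and degenerate inputs

* Variance/MAD filters use the population denominator $n$; ties break by
  feature id; sample order never affects filtering.
* Correlation-medoid filtering clusters features with distance
  $1-|\rho|$ via PAM (exact below 2000 features, seeded subsampled PAM in
  the CLARA spirit above); zero-variance features are excluded first with a
  warning.
* Scalers are fitted on the training split only (no leakage into the
  embedding evaluation); constant features map to 0 under every method.
* Splits use floor rounding for train and validation with the remainder to
  test — a 70/10/20 split of 260 samples gives exactly 182/26/52.
* The split/shuffle/init/baseline seeds all derive from one config seed, so
  stages are independently reproducible; training on a fixed seed is
  bit-identical on one machine.
* Optimizer: AdamW (decoupled weight decay, applied to weight matrices
  only), default learning rate 1e-4; the masked-architecture robustness
  experiments are sensitive to learning rate above all else.
* Validation losses are logged with the final (non-annealed) β and
  deterministic $z=\mu$; the best-validation checkpoint is restored after
  training. Non-finite losses abort with a diagnostic rather than continuing.
* Downstream embeddings are always $\mu$ in inference mode (batch-norm on
  running statistics, dropout off): sampling noise belongs to training, not
  to evaluation.
* log σ² is clamped to ±15 as a numerical guard; BCE probabilities to
  [1e-7, 1-1e-7]; constant images rescale to all zeros.

## Known limitations

* Single CPU, no mixed precision, no early stopping beyond best-checkpoint
  selection; the conv stack is sized accordingly.
* Ontology depth is limited to two levels by design.
* The tuner is seeded random search over learning rate, weight decay,
  dropout and depth; no TPE surrogate.
* Image I/O covers PNG and plain-text matrices; TIFF stacks must be
  converted upstream (the in-memory `image_preprocess()` handles z-stacks).
* The h5ad reader densifies under a size guard; very large single-cell
  matrices should be pre-filtered first.
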