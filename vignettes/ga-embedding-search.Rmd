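---
title: "Evolutionary hyperparameter search for embedding-based classifiers on small radiographic datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary hyperparameter search for embedding-based classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaclassify)
```

## The problem

Rare-disease imaging studies typically hold a few hundred labelled images
from a few dozen patients. Training a convolutional network from scratch on
such data overfits; the standard remedy is transfer learning: a network
pretrained on a large natural-image corpus is frozen and used only to map
each image to a fixed-length feature embedding ("image signature"), and a
small classifier is trained on those embeddings. This package implements
that recipe for a two-class problem (positive class `ACP`, a
sellar/suprasellar pediatric brain tumor, versus `NOTACP`, any other lesion
in its radiographic differential) together with the machinery that makes it
work at small scale: stochastic data augmentation, a genetic algorithm that
searches the discrete hyperparameter space, patient-level cross-validation,
and a synthetic phantom generator for end-to-end validation.

## The model

The classification head is a single fully-connected layer,

$$\hat{y} = g(wx + b),$$

where $x$ is the embedding vector, $w$ and $b$ are the trained parameters
(two output units, one per class), and $g$ is the activation. Training
minimizes the mean categorical cross-entropy, which in the two-class case
is the Bernoulli form

$$L(y, \hat{y}) = -\frac{1}{N}\sum_{n=1}^{N}
  \bigl(y_n \log \hat{y}_n + (1 - y_n)\log(1 - \hat{y}_n)\bigr),$$

optionally plus $\ell_1$ and/or $\ell_2$ weight penalties. Before the
layer, features pass through inverted dropout with a configurable keep
probability. Since the head is a single layer with zero initialization, the
softmax training problem is convex, so training is reproducible and
insensitive to initialization; a seeded Gaussian init is available but not
the default.

For non-normalizing activations (ReLU, leaky ReLU, softplus, softsign,
identity) the training loss is computed on a softmax over the activated
scores, with the chain-rule factor $g'(z)$ applied analytically; the raw
activated score of the positive class is used for ranking at evaluation
time. Log-softmax scores are exponentiated before the loss so the loss
contract is uniform across activations. Predicted probabilities are clipped
to $[10^{-12}, 1-10^{-12}]$ before the logarithm.

### Optimizer catalogue

The search space names nine optimizer families: gradient descent, momentum
(0.9), Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\varepsilon = 10^{-8}$),
Adagrad (initial accumulator 0.1), Adadelta ($\rho = 0.95$), RMSProp
(decay 0.9), FTRL ($\beta = 1$, learning-rate power $-1/2$), and proximal
Adagrad / proximal Adadelta. The two proximal families each come in four
variants (none / $\ell_1$ / $\ell_2$ / $\ell_1+\ell_2$), implemented as the
base adaptive step followed by per-coordinate soft-thresholding and/or
shrinkage with default strength 0.001, which is how nine families expand to
fifteen optimizer variants. The source publications give the update rules
but the study protocol does not state hyperparameters, so the canonical
defaults above are fixed package-wide.

## The search space and the genetic algorithm

`build_phase1_space()` constructs the ten-axis categorical space: 12
pretrained networks, 7 learning rates
($10^{-5}$–$10^{-1}$), 3 batch sizes, 5 epoch counts, 15 optimizers, 7
activations, 4 dropout keep probabilities, 4 regularization modes, 3
training-dataset variants (original, augmented to 100 or 1000 per class)
and 3 test-dataset variants (original, 10 or 100 stochastic replicates) —
19,051,200 configurations in total.

Three axes are underdetermined in the protocol and were fixed once as
package defaults, all overridable: batch sizes $\{5, 20, 120\}$ (three
values spanning the explored 2–120 range), epochs
$\{10, 25, 50, 100, 125\}$ (100 is the baseline duration), and identity as
the seventh activation next to the six named ones (the most conservative
choice: it adds the linear classifier as a variant rather than a second
nonlinearity).

The genetic algorithm (`evolve()`) runs, by default, 10 generations of 100
individuals with a generational retention rate of 40%, a negative rejection
probability of 10% (the chance that an individual below the retention cut
survives anyway, preserving diversity), and a mutation frequency of 20%
(one uniformly chosen axis of a bred child is resampled from the full
axis). Fitness is the AUC of the classifier trained per the genome,
evaluated on the genome's test-dataset variant. Two engineering contracts
matter:

* **Purity.** Each genome's evaluation seed is derived from the master seed
  plus a content hash of the genome, never from execution order, so serial
  and parallel schedules produce bit-identical histories and fitness can be
  cached by genome key (duplicates cost one evaluation).
* **Determinism in selection.** Fitness ties are broken by accuracy, then
  by genome hash. With a continuous AUC fitness ties are rare and the
  tie-break is inert; on coarse synthetic fitness landscapes it is not (see
  Limitations).

## Augmentation and obfuscation

The stochastic pipeline applies, in order: a random grid distortion
(probability 0.75, 4×4 cell lattice, control points jittered up to 8 px,
borders fixed, bilinear resampling), a random 90/180/270° rotation
(probability 0.75), a random zoom (probability 0.5, crop of 80% area,
position-jittered, rescaled), and a left-right flip (probability 0.5).
Magnitude-0 distortion is the bit-exact identity, every operator maps
299×299 → 299×299 with values clamped to $[0, 255]$, and a fixed seed makes
a whole augmentation run byte-reproducible. Training sets are oversampled
class-balanced: originals are kept, and synthetic images (drawn from
uniformly resampled parents, with provenance recorded in
`parent_image_id`) top each class–modality cell up to an exact target. Test
variants replicate each test image through the same pipeline with all
probabilities forced to 1.

Region-of-interest obfuscation (`obfuscate()`) replaces every pixel inside
a rectangle or ellipse mask with a constant fill (default: centered
ellipse, black fill). Retraining on obfuscated images asks whether the
class signal is localized in the masked region: if AUC collapses, it was;
if some signal survives, discriminative information exists outside the
region.

## Evaluation designs

`roc_auc()` computes a threshold-swept ROC with tied scores grouped into
single steps, making the trapezoidal area equal to the tie-corrected
Mann–Whitney pairwise probability (the test suite checks this identity to
$10^{-12}$ against a brute-force oracle). Three five-fold cross-validation
designs are provided: scenario 1 pools augmented and original images and
splits at the image level — deliberately leakage-prone, kept as the
comparison arm; scenario 2 splits patients over originals, then augments
only each fold's training portion; scenario 3 is patient-level folds on
originals only. Patients are dealt to folds round-robin after a seeded
shuffle, stratified by class, with the round-robin pointer continuing
across classes so fold sizes stay within one patient. Leakage scanners
(`scan_leakage()`, `scan_patient_leakage()`) verify scenario 2/3 plans are
clean by construction. Because the published summary metrics do not say
whether they are fold means or pooled predictions, `run_cv()` reports both.

## The synthetic phantom world

Because the clinical images are private, `generate_phantom_dataset()`
emulates their structure: by default 23 + 30 training patients (3 images
per patient per modality, 318 images) and 16 + 17 test patients (1 image
per patient per modality, 66 images), all 299×299. The positive class adds
speckled bright blobs and a rim inside a central elliptical "sellar" ROI —
a cartoon of calcification and cyst boundary — while the negative class
adds one smooth disc; both are scaled by `signal_amplitude` (default 40 on
the 0–255 intensity scale, chosen to give a clearly separable but noisy
problem at the default noise level of 10). A patient-level intensity and
geometry jitter correlates a patient's images; CT and MRI backgrounds
differ in brightness and shading so modality concatenation is informative;
and an optional `confound_amplitude` adds an extra-ROI corner gradient
whose sign tracks class, giving the obfuscation experiment a latent
extra-regional signal to find.

What a green test on phantoms establishes: the plumbing (manifests,
augmentation provenance, fold hygiene), the statistics (chance-level AUC at
zero amplitude, near-perfect AUC at high amplitude, AUC collapse under
obfuscation without a confound, persistence with one), and the end-to-end
determinism. What it does not establish: anything about real tissue
contrast, scanner physics, or the accuracy attainable on clinical data —
the phantom's texture families are cartoons, and the mock feature extractor
(per-cell mean/sd on an 8×8 grid followed by a fixed random projection) is
a locality-preserving stand-in, not a pretrained network. Real embeddings
enter through `external_extractor()` tables.

## Numerical and design choices

* Probability clipping at $10^{-12}$; softmax computed with max
  subtraction; softplus switched to its linear asymptote beyond 30 to
  avoid overflow.
* Zero initialization by default (convex single-layer problem); gradient
  checks against central finite differences pass at $10^{-5}$ relative
  tolerance across activations and penalty modes.
* Embeddings are standardized feature-wise by training statistics in the
  data bundle and in `run_cv()` (constant features pass through); raw
  grid-statistic embeddings span hundreds of intensity units and would
  otherwise stall fixed-step optimizers.
* "Negative rejection probability" is read as the probability of retaining
  a below-cut individual (the convention of the public simple-GA lineage
  this design follows); the opposite reading is available as
  `rejection_mode = "drop_elites"`.
* Parents are drawn uniformly without replacement per child (no
  self-pairing when two or more survivors exist); mutation touches exactly
  one axis of a triggering child.
* On-disk images are ASCII PGM (P2): the toolchain targets plain-text
  artifacts, PGM decodes losslessly, and no JPEG codec is assumed. The
  loader enforces the 299×299 contract and all manifest invariants.
* CT–MRI pairing uses the single representative test image per modality
  per patient; training images are paired positionally after sorting by
  image id within patient, since multi-image training pairing is otherwise
  underdetermined.

## Known limitations

* The GA at small population sizes converges prematurely on coarse,
  heavily-tied fitness landscapes (such as the hidden-optimum
  match-fraction landscape used in testing): once survivors are nearly
  identical, one-axis mutation at 20% per child explores too slowly to
  reliably repair a missing axis within 10 generations, and the
  deterministic hash tie-break compounds this by preferring the same
  genomes across generations when ties abound. The acceptance suite
  measures this recovery rate honestly; at population 20 it falls short of
  high-reliability recovery. With a continuous AUC fitness (the intended
  use) ties are rare and the tie-break is inert.
* Pretrained networks are not bundled; offline work uses the mock backend
  or precomputed embedding tables.
* The classifier is intentionally a single layer; deeper heads, early
  stopping and class weighting are out of scope.
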