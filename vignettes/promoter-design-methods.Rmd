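---
title: "Designing E. coli promoters with generative and supervised sequence models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing E. coli promoters with generative and supervised sequence models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promoforge)
```

## The problem

Bacterial sigma70 promoters are short DNA regions upstream of a
transcription start site (TSS). Their activity is driven largely by two
hexamer elements — the −35 motif (consensus `TTGACA`) and the −10 motif
(consensus `TATAAT`) — separated by a spacer of 16–18 bp, with a short
discriminator between the −10 element and the TSS. promoforge provides
two complementary design routes over fixed-length 50-bp promoters:

* **A diffusion-based route**: an unconditional denoising diffusion
  model (`train_promodiff()`, `sample_promoters()`) learns the
  distribution of natural promoters from one-hot encoded sequence
  matrices and generates novel candidates, which a screening cascade
  (`drsa_screen()`) filters by a real-vs-fake classifier, a strong/weak
  classifier (score > 0.9), and a predicted-activity ranking (top 50).
* **A constraint-based route**: `generate_constrained()` fixes the two
  hexamers and the spacer-length set and randomizes everything else; a
  small CNN (`net_config(arch = "simple_cnn", task = "regression")`)
  trained on measured activities of such sequences ranks new candidates.

Supporting modules cover dataset handling (FASTA and FI/OD600 activity
tables, 81→50 bp windowing, random negative windows, genomic
extension), feature encodings (one-hot and pseudo-dinucleotide
composition), evaluation metrics (Sn/Sp/Acc/MCC/AUROC/PCC), sequence
logos, 6-mer motif scans, and a synthetic-data generator with known
ground truth.

## Activity and the active/inactive call

Promoter activity is fluorescence intensity normalized by culture
density, `activity = FI / OD600` (arbitrary units,
`normalize_activity()`). A promoter is called **active** when its
activity exceeds the negative control by more than 20%
(`call_active()`; the boundary case of exactly 1.2× the control is
called inactive — the definition of "less than a 20% increase" leaves
equality undefined, and we resolve it conservatively).

## Feature encodings

`one_hot_encode()` maps each position to an indicator 4-vector in fixed
A, C, G, T order; a 50-mer becomes a 50 × 4 matrix, flattened row-major.
`one_hot_decode()` inverts it by per-position argmax with alphabetical
tie-breaking — this convention matters because diffusion samples are
continuous relaxations.

`psednc()` implements pseudo-dinucleotide composition: the 16
normalized dinucleotide frequencies `f_u`, down-weighted as
`d_u = f_u / (1 + w * sum(theta))`, followed by `lambda`
sequence-order terms `d_(16+j) = w * theta_j / (1 + w * sum(theta))`,
where `theta_j` averages the correlation
`Theta(d1, d2) = mean_p (P_p(d1) - P_p(d2))^2` over all dinucleotide
pairs `j` steps apart. The property table `P` packaged with promoforge
(`inst/extdata/dinucleotide_properties.csv`) holds six average B-DNA
base-pair step parameters — twist, tilt, roll (degrees), shift, slide,
rise (Å) — with reverse-complement symmetry; each column is
standardized to mean 0, unit (population) variance before use, and the
table can be swapped via `psednc_params(property_table = ...)`. The
defaults `lambda = 3`, `w = 0.05` are the common pseDNC conventions;
the method's originators leave them free and so do we. All components
of a pseDNC vector are non-negative and sum to 1.

## Supervised networks

Two architectures are exposed through `net_config()`:

* `resnet_attention` — a convolution+ReLU block, `n_resblocks = 20`
  residual blocks (`Y = F(x; Wi) + Ws x`, with `F` two
  convolution+ReLU layers and `Ws` a 1×1 projection only when channel
  counts change), a single-head scaled dot-product self-attention block
  (`softmax(Q K' / sqrt(d_k)) V`, `d_k =` channel count, with a
  residual connection), max-pooling, and a dense head. Binary tasks end
  in a sigmoid; regression in a linear unit.
* `simple_cnn` — two convolution+ReLU stages with one max-pool, then a
  dense head; the architecture used for small designed training sets.

Both are trained by minibatch Adam on mean squared error — including
the binary tasks, which regress {0,1} labels on the sigmoid output;
class calls threshold at 0.5. Regression targets are standardized
internally and predictions mapped back, which stabilizes optimization
without changing the reported correlation. Defaults: 16 channels,
dropout 0.3 before the head, learning rate 1e-3, batch size 32; the
conventional tuning ranges (learning rate 1e-4 to 1, batch 4 to 64) are
searchable exhaustively with `hyperparameter_search()`, whose
tie-breaks (smaller learning rate, then smaller batch) make results
reproducible. Heavy-tailed activities can be log-transformed
(`activity_transform = "log1p"`, the default for natural-promoter
activity data); the constraint-based route's synthetic targets are
fit on the raw scale.

Two readout heads are available: a position-preserving flatten head
(default) and a per-channel global max-pool head. Promoter layouts put
the −10 element at a fixed offset while the −35 element shifts with
the spacer, so position information carries real signal and the flatten
head is the right default; the max-pool head is offered for strictly
translation-invariant problems.

Residual branches initialize their second convolution at zero, so a
freshly built deep stack is the identity map; without normalization
layers a 20-block stack would otherwise double its activation variance
per block and saturate the sigmoid before training begins.

There is no deep-learning framework dependency: convolutions are
im2col-reshaped matrix products over R's BLAS, gradients are exact
analytic backpropagation (verified against central finite differences),
and all randomness — initialization, shuffling, dropout — flows from
one seed, making every training run bit-reproducible.

### Evaluation

`cross_validate()` builds disjoint folds covering all samples
(stratified for binary tasks), trains each fold's model from scratch
and reports per-fold and mean Sn/Sp/Acc/MCC/AUROC (binary) or PCC/MSE
(regression), plus *pooled* metrics computed on the out-of-fold
predictions of all samples. The pooled PCC is the package's headline
cross-validation statistic: per-fold correlations on 40-sample folds
are noisy, and pooling matches the usual "k-fold cross-validated PCC"
protocol. `n_ensemble` trains several differently seeded models per
fold and averages their predictions; optimization variance dominates
small-sample regression, and a 3-seed ensemble is the protocol used in
the package's own validation. Metrics with zero denominators are
reported `NA`, never 0. AUROC is the Mann–Whitney rank statistic, so it
is invariant under monotone score transforms. `baseline_ml()` wraps
elastic-net (glmnet, alpha grid with internal lambda selection) and
gradient-boosted-tree (xgboost, small depth/rounds grid on an internal
split) regressors as classical reference points.

## The diffusion generator

`make_schedule()` defines the forward noising chain: `T = 1000` steps
by default with betas linear from 1e-4 to 0.02 — standard choices, not
derived quantities. One-hot matrices are rescaled to [−1, 1] and
noised by the closed-form marginal
`x_t = sqrt(alpha_bar_t) x_0 + sqrt(1 - alpha_bar_t) eps`
(`forward_diffuse()`).

The denoiser is a small UNet (`unet_config()`): encoder = convolution,
residual block (skip-connected to the decoder), max-pool downsampling
(50 → 25), residual block and self-attention at the bottleneck;
decoder = residual block, nearest-neighbor upsampling (25 → 50), skip
concatenation and two convolutions. A sinusoidal embedding of the step
index enters as a learned per-channel bias at the input and bottleneck
stages. Four fixed sinusoidal positional-encoding channels are
concatenated to the input: convolutions and un-positioned attention are
translation-equivariant, and without an absolute position signal the
model can learn motif *composition* but provably cannot pin a motif to
an absolute offset — which is precisely what promoter layouts require.

Training (`train_promodiff()`) draws random `(sample, t)` pairs and
minimizes squared reconstruction error. The default target is the
clean signal `x_0` rather than the injected noise. The two
parameterizations are affinely equivalent
(`eps = (x_t - sqrt(alpha_bar) x_0) / sqrt(1 - alpha_bar)`), but on
near-deterministic one-hot data signal reconstruction trains much
faster: at high noise its target is the simple clean pattern, whereas
noise prediction must reproduce a precise affine function of the noisy
input before the sampler benefits. At the validation scale used in the
test suite (2,000 training sequences, 200 steps, 200 epochs) the
noise-prediction objective leaves planted-motif recovery at the
percent level while signal reconstruction reaches it in essentially
every sample; `objective = "epsilon"` remains available.

Sampling (`sample_promoters()`) is ancestral: starting from Gaussian
noise, each reverse step forms the posterior mean through the *clipped*
`x_0` estimate (clamped to [−1, 1], the valid range of the relaxation)
with the standard posterior variance, and the final state is decoded by
argmax. Sampling uses an exponential moving average of the training
parameters (decay 0.999 with warmup) — the standard variance-reduction
practice for diffusion sampling. The sampler itself was verified
exactly: substituting the analytic posterior denoiser for the network
reproduces the training distribution.

One checkpoint is stored per epoch by default (`checkpoint_every`
thins this), and `checkpoint_rpp_curve()` scores each checkpoint's
samples with a real/fake classifier to pick the generation epoch — the
"real promoter portion" (RPP) criterion. `novelty_report()` counts
exact duplicates within a batch and against the training set.

## Constraint-based design and 6-mer scans

`design_constraints()` fixes the sequence layout: upstream pad, −35
hexamer, spacer (16–18 bp, uniform), −10 hexamer, 6-nt downstream pad,
50 bp total. With this convention the −10 element always occupies
positions 39–44. The original experiments place the motifs only
implicitly; the 6-nt discriminator mimics a −12…−7 placement and is
configurable. `generate_constrained()` fills all free positions i.i.d.
uniformly; `check_constraints()` re-validates any sequence against the
layout.

`scan_kmers()` asks which of the 4^6 = 4096 hexamers can serve as a
functional motif: for each 6-mer it generates `n_contexts` constrained
sequences (default 100, spacer 17) with the variable 6-mer at one role
and the conserved hexamer at the other, and records the fraction of
contexts the classifiers call real and strong (both at score 0.5; the
screening cascade keeps its stricter 0.9 strength filter).
`kmer_summary()` and `binding_table_comparison()` aggregate the scan,
the latter against a user-supplied ranking of motifs by RNAP/sigma70
binding strength — that table is an input, not something the package
derives.

## Sequence logos

`build_pfm()` counts bases per position; `information_content()`
converts frequencies to logo bar heights, `R = 2 − H` bits per position
(`H` the Shannon entropy), optionally minus the small-sample correction
`e_n = 3 / (2 ln(2) n)` (off by default), floored at zero and split
per base as `frequency × R`. A fully conserved position carries 2 bits;
a uniform one carries 0.

## The synthetic-data generator

`synthetic_spec()` defines the ground truth every learning component is
validated against. Sequences follow the sigma70 layout above, with the
hexamers drawn from consensus-biased PWMs (consensus probability 0.7 by
default — conserved but not degenerate, as in natural sigma70
elements), spacers uniform on {16, 17, 18}, and uniform background.
Activity is linear in motif quality:

```
activity = beta0 + beta35 * score35 + beta10 * score10 + gamma_spacer + eps
```

with each score the PWM log-likelihood ratio of the sampled hexamer
against background, `eps ~ N(0, sigma^2)` (`sigma = 1` by default,
roughly a third of the signal's standard deviation under the default
PWMs), and truncation at zero to keep activities physical. The spacer
effects default to `(16: 0, 17: 0, 18: −0.5)`, encoding the observation
that 18-bp spacers disfavor strong promoters. Because the model is
explicit, the best achievable prediction is known:
`activity_ceiling_pcc()` returns
`PCC* = sqrt(Var(signal) / (Var(signal) + sigma^2))`, computed exactly
from the PWMs, coefficients and spacer distribution. The truncation at
zero slightly biases the variance decomposition, which the validation
tolerances accommodate.

Two things this ceiling deliberately ignores: finite-sample estimation
error (a learner trained on 160 sequences cannot reach the
infinite-data ceiling; even the generative model's own linear family,
fit by cross-validated elastic net, falls short at that size) and the
truncation bias. Recovery checks against `PCC*` at small `n` therefore
probe the *combination* of generator and learner, and the package's
validation treats the 3-seed-ensemble pooled CV PCC as the honest
estimate of what the study size supports.

`simulate_real_fake()` produces balanced real-vs-fake contrasts (fakes
are pure background or position-shuffled reals, which preserve base
composition exactly); `simulate_ndb_like()` emulates a genome-wide
TSS-map activity table: a sigma70-like fraction with planted motifs and
log-normal activities whose default tail (`sdlog = 2`) puts the 97.7th
percentile at 10,000 activity units, mirroring the shape of natural
promoter activity distributions. What the generator does **not**
emulate: real genomic base composition, motif–background correlations,
promoter subtypes beyond sigma70, or measurement error structure —
passing recovery tests on synthetic data demonstrates the machinery is
correct and calibrated, not that real-data accuracies will match.

## Numerical choices and degenerate inputs

* Alphabet is strict A/C/G/T; ambiguity codes are rejected at ingest
  (both encodings are undefined on them).
* All coordinates are 1-based closed intervals on the forward strand.
* Argmax ties (decoding, consensus) resolve alphabetically.
* Zero-denominator metrics are `NA`; constant vectors make `pearson_cc()`
  an error rather than a silent 0.
* The 81→50 bp windowing default (`start_offset = 11`) takes the 50 nt
  ending just upstream of the TSS position conventionally at 61 in
  81-mers; it is a convention, exposed as a parameter.
* Every stochastic routine takes an explicit seed; identical seeds give
  bit-identical results, including full training runs.

## Validation scales

The test suite trains real models at reduced but non-trivial sizes,
chosen to finish on a single CPU while leaving the tested effects far
from chance level: diffusion motif recovery on 2,000 sequences with a
200-step schedule for 200 epochs (recovery is asserted at ≥50% of 200
samples versus <5% untrained); activity-regression recovery at n = 200
with 5-fold, 3-seed-ensemble cross-validation against the analytic
ceiling; real/fake classification at n = 400; 12,000 constraint-based
sequences for the layout and uniformity checks; 10,000 Monte-Carlo
draws for the forward-marginal identities. `scripts/acceptance.R`
re-runs the same computations from scratch with a caller-supplied seed
and writes the resulting numbers as JSON.

## Known limitations

* The networks are compact CPU implementations; they reproduce the
  architectures' structure (residual stacks, single-head attention,
  UNet encoder/decoder) at widths suited to thousands, not millions, of
  sequences.
* Strength prediction from small designed training sets is
  estimation-limited; expect cross-validated PCCs well below the
  noise ceiling at n in the low hundreds, whatever the model class.
* The diffusion generator is unconditional: it imitates its training
  corpus and offers no knob for steering activity beyond the
  downstream screening cascade.
* No reverse-complement handling: inputs are assumed pre-oriented.
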