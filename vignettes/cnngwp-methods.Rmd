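---
title: "CNNGWP: model, tuning, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNNGWP: model, tuning, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnngwp)
```

## The prediction model

Genome-wide prediction (GWP) regresses a quantitative phenotype $y$
($n \times 1$) on a dense panel of SNP genotypes $X$ ($n \times p$, additive
0/1/2 coding, standardized per SNP). CNNGWP replaces the linear map of
GBLUP-style models with a sparse one-dimensional convolutional network:

$$\hat y = \mathrm{flatten}\big(\mathrm{pool}(X * K)\big)^\top W + b,$$

with four stages:

1. **1-D convolution** — $q$ filters of width $k$ slide along the SNP axis
   (cross-correlation, no kernel flip) with stride 2 and *equal zero
   padding*: the total padding $\max((\lceil p/2\rceil - 1)\,2 + k - p,\, 0)$
   is split evenly with the odd zero placed on the right, so the output
   length is exactly $\lceil p/2 \rceil$. The activation is linear: with
   0/1/2 coding there is little non-linearity to capture beyond dominance,
   and the pooling stage already supplies a piecewise-linear response.
   Parameters: $kq$ kernel weights plus $q$ biases.
2. **Max pooling** of non-overlapping windows of 2 (trailing remainder
   dropped), halving the positional resolution again.
3. **Flatten**, position-major with filters fastest, giving
   $\lfloor \lceil p/2\rceil / 2\rfloor \cdot q$ features. This ordering is
   what makes output-weight indices proportional to SNP indices (below).
4. **Dense linear output** with a single unit, one bias, and an
   $\ell_1$ penalty $\lambda \lVert W\rVert_1$ on the output weights only —
   neither the conv kernels nor any bias is penalized. The training loss is
   $J = \mathrm{MSE} + \lambda\lVert W\rVert_1$; reported validation MSEs
   never include the penalty.

The convolution therefore first *expands* the parameter space locally
(exploiting linkage disequilibrium, the correlation between neighbouring
markers) and then *regularizes* it through pooling and the LASSO-like
$\ell_1$ constraint — the combination that makes the model sparse.

### Shape arithmetic

`infer_shapes()` is the single source of truth for layer shapes and
parameter counts. For the 9,723-SNP architecture with 64 filters of width
27: conv output $(4862, 64)$ with $27\cdot 64 + 64 = 1792$ parameters,
pooled $(2431, 64)$, flatten $155{,}584$, dense $155{,}585$, total
$157{,}377$. One published layer table quotes a conv output length of
23,657 for a 47,299-SNP input; that is inconsistent with
$\lceil 47299/2 \rceil = 23650$, which the other two published tables obey,
so shape inference follows the $\lceil p/s \rceil$ convention throughout.

### Training

Mini-batch ADAM ($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-7}$ —
standard framework defaults; the reference learning rate for the full-scale
simulated data is 0.00025) with the batch size defaulting to
$\lfloor\sqrt{n_\mathrm{train}}\rfloor$. One epoch is a full seeded-shuffled
pass over the training rows; the last, smaller batch is kept. The $\ell_1$
term is handled by subgradient ($\mathrm{sign}(0) = 0$), the canonical
reading of an "$\ell_1$-regularized layer" in deep-learning frameworks;
pooling routes gradients to the recorded argmax only, ties broken by the
first position. After every epoch the validation MSE is computed and the
best-epoch parameters are checkpointed; predictions always use the
checkpoint. (Whether the original analysis restored the best epoch or used
final weights is not documented; restoring the checkpoint is the only
reading under which the reported *minimum* test MSEs are usable for
prediction, so that is the contract here.) Weight initialization is
Glorot-uniform with zero biases, seed-controlled; all computation is double
precision, with the heavy loops compiled (RcppArmadillo) and verified
against the op-level R path to machine precision.

## Hyperparameter tuning

Three hyperparameters $\gamma$ = (filters, kernel width, $\lambda$) are
tuned by Gaussian-process Bayesian optimization, maximizing the score
$-\mathrm{MSE}_{val}$. The surrogate is a zero-mean GP on centered scores
over the unit-hypercube-scaled inputs; the kernel is squared-exponential
with per-dimension length-scales (Matérn 5/2 available), fitted by
multi-start maximum marginal likelihood with jitter escalation
($10^{-10} \to 10^{-6}$) for Cholesky stability. Acquisition is the upper
confidence bound $\mu(\gamma) + \beta\sigma(\gamma)$ with $\beta = 2.576$
(the convention of the R Bayesian-optimization package the original
analysis used; the kernel, $\beta$ and initialization count of that package
are not published, so these are declared substitutes and the exact
published $\gamma_{MA} = (64, 27, 0.571)$ is not a reproduction target).
Proposals maximize UCB over a seeded Latin-hypercube pool plus local
refinements around the incumbent; integer dimensions are rounded afterwards
and already-evaluated points are stepped to the nearest unevaluated lattice
neighbour. The initial design is a seeded Latin hypercube of 7 points
(configurable).

## Ensembling

Stochastic gradient training makes single runs noisy, so predictions are
model-averaged: $S$ independent BO replicates each contribute their
best-scoring $\gamma$; these are averaged componentwise into $\gamma_{MA}$
(integer components rounded half away from zero, the literal reading of
"extracted from the model with lowest test MSE, then averaged" applied to
each replicate's single best point); the network is then retrained $S$
times at the fixed $\gamma_{MA}$ and the test predictions averaged,
$\hat y_{MA} = S^{-1}\sum_s \hat y_s$. Conv-layer weights are never
averaged across runs — different runs may allocate filters to different
QTLs — so the result keeps all $S$ weight sets; only the output-layer
weights are additionally averaged for localization plots. By convexity of
squared error, $\mathrm{MSE}_{MA} \le S^{-1}\sum_s \mathrm{MSE}_s$ on every
run; the pipeline asserts this identity.

**Validation protocol.** The reference analysis scores BO on the same
generation-5 block it reports test MSE on. The default
(`validation = "test"`) reproduces that protocol — a form of selection
leakage that should be kept in mind when reading absolute MSEs — and
`validation = "holdout"` carves a clean validation block out of the
training data instead.

## QTL localization

Because the flatten step is position-major, the output-weight index of a
SNP at index $s$ is approximately $s \cdot F$ with
$F = (\text{number of output weights})/p$ — e.g. $155{,}584/9{,}723 =
16.002$. The factor is conventionally quoted, and used in the index
arithmetic, at three decimals; all published positions (931 → 14,898;
4,354 → 69,673; 5,327 → 85,243; 9,212 → 147,410; 9,404 → 150,483;
9,602 → 153,651) are reproduced by rounding $s \times 16.002$ half away
from zero. One published back-mapping (weight 25,000 at factor 10.2 →
SNP 2,450) is reproduced only by truncation; both behaviours are available
with rounding as the default. Peaks are extracted from $|w|$ (top-$k$ with
a $3\times$ median-absolute-weight floor by default — the original work
reads peaks off a plot and states no rule, so the rule here is explicit and
configurable).

## Baselines

*GBLUP*: mixed-model ridge on the genomic relationship matrix
$G = X_s X_s^\top/p$ (unit-variance standardization makes allele-frequency
weighting a constant); the variance ratio is estimated by REML profiled
over the eigendecomposition of the training block, maximized by
golden-section search on $\log\lambda_r \in [\log 10^{-4}, \log 10^4]$,
with GLS intercept and train-block mixed-model predictions. *LASSO*: cyclic
coordinate descent with soft-thresholding, warm starts along a log-spaced
path from $\lambda_{max} = \max|X_s^\top y_s|/n$, and k-fold CV on the
training rows. The original comparison used a Bayesian LASSO Gibbs
sampler; its own discussion equates the CNNGWP regularizer with the LASSO,
and the deterministic CV-tuned LASSO plays that comparison role here (the
MCMC sampler is deliberately out of scope).

## The synthetic-data generator

The generator emulates the QTLMAS2010-derived evaluation data so that every
stage is testable without external downloads: 3,226 individuals, 9,768
biallelic SNPs on five chromosomes, and 37 QTLs — two major additive genes
of effects $-3$ and $+3$ at SNP indices 4,354 and 5,327; an epistatic locus
at SNP 931 carried as a dominant additive component (effect 2) plus a pure
product-interaction pair $2(g_i-1)(g_j-1)$ with zero marginal means;
dominance, over-dominance and under-dominance loci at SNPs 9,212 / 9,404 /
9,602 with per-genotype triplets $(0, 5.00, 5.01)$, $(-0.01, 5.00, 0.01)$
and $(-0.01, -5.00, 0.01)$; and 28 random small additive QTLs with effects
from a standard normal truncated to $|a| < 2$ (the truncation bound is
published, the scale is not; a unit scale is the natural choice). About
2.5% of columns are forced monomorphic so the MAF-filter path is exercised
(the original panel had 263 monomorphic markers of 10,031).

Haplotypes are first-order Markov chains along each chromosome: a locus
copies its left neighbour's allele with probability `ld_decay` (default
0.95) or draws fresh at its sampled frequency, and the genotype is the sum
of two independent haplotypes. This preserves exactly the two features the
method exploits — Hardy-Weinberg genotype proportions per locus and strong
local LD — while replacing the original neutral-coalescent simulation,
which is out of scope. What it does *not* reproduce: pedigree/family
structure (the real data are half-sib families over five generations),
long-range LD, allele-frequency spectra from drift, or maternally imprinted
QTLs (omitted; no parent-of-origin bookkeeping). Passing tests therefore
demonstrate correct mechanics and qualitative behaviour on LD-structured
data, not performance on pedigreed populations.

The residual variance of the reference trait is unpublished, so the
generator targets a heritability instead (default $h^2 = 0.5$, a documented
guess, not a reproduction): the residual SD is set from the realized
genetic variance via $h^2 = V_g/(V_g + V_e)$, and phenotypes are
mean-centered, matching the reference preprocessing. Standardization uses
population (divide-by-$n$) SDs and, by default, statistics over *all*
individuals — the reference workflow standardizes before splitting — with
`stat_rows` available for leakage-free variants.

## Numerical and scale choices

- Indices are 1-based everywhere a user sees them (SNPs, individuals,
  weights), matching how positions are quoted in the field.
- "Round half away from zero" is used wherever continuous values become
  integers (averaged hyperparameters, index mapping): base R's
  round-half-even would break the published index arithmetic.
- MAF filtering removes SNPs with $\mathrm{MAF} < $ threshold strictly;
  ties at the threshold are retained.
- Missing genotypes default to column-mean imputation rounded to the
  nearest code (the original pipeline imputed with pedigree software,
  which is out of scope); refusing or keeping `NA` are selectable.
- The test suite exercises the full pipeline at a reduced scale chosen to
  keep the whole suite desk-sized: $n = 1200$, $p = 2000$ (causal positions
  scaled proportionally), $h^2 = 0.6$, $S = 3$ BO replicates with $T = 8$
  iterations and a 3-point initial design, 10 tuning epochs and 20
  final-training epochs at learning rate 0.003, and search bounds
  filters $[4, 16]$, kernel $[8, 24]$, $\lambda \in [0.5, 4]$ — the
  $\lambda$ range sits higher than the full-scale bounds because the toy
  phenotype variance and flatten size differ from the full-scale setting.
  At this scale the tuned ensemble reliably beats GBLUP (the direction, not
  the magnitude, of the published comparison) and the top weight peaks
  localize the planted major loci.

## Known limitations

- Single conv layer, linear activation, max pooling only: ReLU/maxout
  variants, dropout and deeper stacks were evaluated and rejected in the
  original work and are deliberately not implemented.
- BO is sequential; no batch/parallel acquisition.
- The GP surrogate assumes a stationary kernel on the scaled box; heavily
  multimodal objectives may need a larger candidate pool.
- `validation = "test"` reproduces the reference protocol including its
  leakage; use `"holdout"` for honest error estimates on new data.
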