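---
title: "Genome-wide prediction with Monte-Carlo-dropout neural networks"
author: "abnn package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide prediction with Monte-Carlo-dropout neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abnn)
```

## The problem

Genome-wide prediction (GWP) estimates phenotypes of individuals from
thousands of SNP dosages scored in hundreds to a few thousand individuals,
and genome-wide association scanning (GWAS) asks which of those markers
carry signal.  With far more markers than individuals, any flexible model
over-fits unless heavily regularized.  This package implements a shallow
neural network whose two regularizers — decoupled weight decay and
Bernoulli dropout — double as an approximate Bayesian inference scheme:
repeating the dropout sampling at every training iteration yields a chain
of thinned models that can be treated as draws from an approximate
posterior, giving model-averaged predictions, per-parameter posterior
moments, and interpretable SNP effects.

## Model

For an $n \times p$ input matrix $X$ and trait vector $y$, a network with
layer widths $k_1, \dots, k_L$ ($k_L = 1$) computes

$$\hat y = \sigma(\cdots \sigma(X W_1 + b_1) \cdots W_L + b_L),$$

with activation $\sigma$ one of linear, $\tanh(x) = 2/(1+e^{-2x}) - 1$, or
$\mathrm{relu}(x) = \max(0, x)$.  The data loss is the Euclidean loss
$\mathcal L = \frac{1}{2n}\sum_i (y_i - \hat y_i)^2$, optionally penalized
by $\lambda_1 \lVert W_1\rVert^2 + \lambda_2 \lVert W_{>1}\rVert^2 +
\lambda_3 \lVert b\rVert^2$.

**Layer convention.**  Formulations of shallow networks differ in whether
the last layer is activated and carries a bias.  We adopt one uniform
rule — every layer has weights and a bias, and the activation is applied at
every layer — because it makes the one-layer one-unit case exactly
$\hat y = \sigma(X W_1 + b)$ (a multiple regression model when $\sigma$ is
linear), keeps deeper architectures recursive without special cases, and,
for the linear activation used by the interpretable model, coincides with
the classical single-hidden-layer form up to an extra (harmless) output
intercept.  The gradient checks in the test suite cover every
width/activation combination under this convention.

**Input encoding.**  Dosages 0/1/2 can be used directly (`"dosage"`
encoding; a linear net then models additive gene action only), or expanded
into three indicators per marker in the fixed order (Hom0, Het1, Hom2)
(`"onehot"`).  One-hot encoding lets even a linear one-unit network express
a separate effect per genotype class, i.e. additive *and* dominance action.
Internally the package stores one-hot designs as the index of the single 1
per marker triple and evaluates the input layer by table lookup; this is an
exact reformulation, not an approximation.

## Training

Three optimizers are provided: full-batch gradient descent, stochastic
gradient descent (single samples), and the default mini-batch ADAM
(moment decay $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$).
Gradients are exact reverse-mode derivatives of the data loss; they are
verified against central finite differences to a relative error of
$10^{-5}$ in the test suite.

Weight decay is applied in its *decoupled* form inside the ADAM update,

$$\theta_t = \left(1 - \tfrac{\eta \lambda}{b}\right)\theta_{t-1}
  - \eta\, \hat m_t / (\sqrt{\hat v_t} + \epsilon),$$

with the group coefficient ($\lambda_1$ input weights, $\lambda_2$ deeper
weights, $\lambda_3$ biases) taken from the penalty configuration.
Decoupled decay and the coupled $\ell_2$-in-the-gradient form are *not*
equivalent under ADAM; the coupled form is retained for plain gradient
descent, where it provably converges to the closed-form ridge solution
$(X'X + 2n\lambda_1 I)^{-1}X'y$ — the $2n$ factor follows from the
$\frac{1}{2n}$ loss normalization, and the test suite checks this
equivalence to $10^{-6}$.

Defaults: learning rate $\eta = 10^{-3}$ (the conventional ADAM choice;
ADAM adapts per-coordinate step sizes so this rarely needs tuning), batch
size 128 (mini-batches of 50–250 are the practical range for a few
thousand training samples), $\lambda_2 = \lambda_1$, $\lambda_3 = 0$
(biases unpenalized, which keeps predictions equivariant to phenotype
shifts).

## The MC-dropout chain

Dropout masks are Bernoulli: retention $p_1$ on the input dimension (rows
of $W_1$) and $p_2$ on each hidden-layer output, both 0.5 by default.
Masked weights are rescaled by $1/p$ (inverted scaling), so each masked
network is the thinned model actually used for prediction; biases are
never masked.  With one-hot input, indicator columns are masked
independently by default — a SNP can lose one genotype column and keep the
others; `jointTriples = TRUE` drops whole triples instead for users who
prefer locus-level dropout.  We default to independent masking because the
masks act on weight-vector entries, not on loci, and independent masking
is what makes the variational reading of dropout exact at the level of
individual parameters.

One chain iteration $t$: sample fresh masks, run **one optimization pass
over the training data** (mini-batched) continuing from the current
parameters, then record the thinned model
$\omega^t = \{z \odot W / p,\ b\}$, its test predictions $\hat y^{*t}$ and

$$\mathrm{MSE}_t = \tfrac{1}{n_{test}}\textstyle\sum (\hat y^{*t} - y_{test})^2 .$$

Defining an iteration as a full pass (rather than a single mini-batch
step) matches the notion of one gradient-descent optimization per mask
draw; `stepsPerIter` exposes the alternative.  The chain warm-starts each
iteration from the previous parameters — a single continuing optimization
under changing masks, which converges quickly and mixes around the
stationary region — rather than running independent restarts.

After discarding a burn-in $t_s$ (a configuration parameter; inspect the
trace plot, with `detectPlateau()` as an advisory helper), posterior
summaries are

$$\mathbb E[\omega] \approx \tfrac{1}{T - t_s}\sum_{t > t_s} \omega^t,
\qquad
\mathrm{VAR}[\omega] \approx \tfrac{1}{T - t_s}\sum_{t > t_s}
  (\omega^t - \mathbb E[\omega])^2,$$

(note the $1/(T - t_s)$ normalization, i.e. the biased sample variance)
and the model-averaged error $\mathrm{MSE}_{\mathcal M}$ is the arithmetic
mean of the retained $\mathrm{MSE}_t$ — by Jensen's inequality it is never
smaller than the MSE of the averaged prediction, and both are reported.
At full data scale (thousands of samples, tens of thousands of markers) a
practical protocol is 6000 iterations with the first 1000 discarded; the
desk-scale experiments in this package use 2000 iterations with 500
discarded, which the trace plots show is well past convergence for these
problem sizes.

## SNP effects and what their scale means

For the one-layer, one-unit, **linear**, one-hot model the posterior-mean
input weights are genotype-class regression coefficients, and

$$a_j = -\mathbb E[W_{1,\mathrm{Hom0}_j}] + \mathbb E[W_{1,\mathrm{Hom2}_j}],
\qquad
d_j = \mathbb E[W_{1,\mathrm{Het1}_j}].$$

Effects are refused for deeper or nonlinear models, whose weights are not
interpretable this way.

These are *regularized* estimates, and the dropout shrinkage has a known,
exact form for the linear model: marginalizing the masks adds a penalty
$\frac{1-p_1}{2 p_1} \sum_j f_j w_j^2$ (with $f_j$ the frequency of
indicator column $j$), so at the stationary point each weight is
approximately $p_1$ times the (intercept-centred) genotype-class contrast.
At the default $p_1 = 0.5$ the weights are *halved*.  Two consequences
matter for interpretation:

* the additive contrast $a_j$ contrasts the two homozygote weights, whose
  halving cancels against the two-unit dosage difference, so $a_j$
  estimates the conventional additive effect (half the homozygote
  difference) essentially unshrunk — the recovery experiments find a
  controlled QTL simulated at $a = 3$ at a median $\approx 2.5$–$2.8$,
  the remaining attenuation coming from LD sharing with flanking markers;
* the dominance weight $d_j$ is a *single* weight, so it reports roughly
  half of the heterozygote's deviation from the locus mean contribution —
  for a simulated heterozygote effect of 5 at a locus of intermediate
  frequency the estimate stabilizes near $(5 - \bar t)/2 \approx 1$–$2$,
  where $\bar t$ is the locus' mean contribution.  The dominance column
  therefore ranks loci reliably (the simulated dominance locus is the top
  $|d|$ hit in the recovery experiments) but understates large
  heterozygote deviations; no un-shrinking is applied because the ranking,
  not the absolute size, is the intended use.

## The simulator

`simConfig()`/`simulateDataset()` emulate a livestock-style trait with
known ground truth so every pipeline stage is testable without external
data:

* **Genotypes** — two haplotypes per individual; along each chromosome a
  haplotype thresholds a latent Gaussian AR(1) at $\Phi^{-1}(q_j)$, so
  allele frequencies ($q_j \sim U(0.05, 0.5)$ by default) are matched
  exactly, genotypes are Hardy–Weinberg consistent by construction, and
  adjacent markers are correlated.  The latent correlation default
  $\rho = 0.53$ was calibrated once (`calibrateRho()`) so the mean
  adjacent-marker $r^2$ at MAF > 0.05 is $\approx 0.10$, a typical value
  for medium-density livestock panels.
* **Trait architecture** — controlled additive QTL with fixed effect $+3$
  placed at highly polymorphic markers (MAF $\ge 0.35$); random additive
  QTL with effects from $N(0, 10)$ accepted when $|a| < 2$; two epistatic
  pairs among the controlled QTL adding $+4$ when both members are lower
  homozygotes; and one locus each of full dominance (genotype values
  $0, 5, 5.01$), over-dominance ($-0.01, 5, 0.01$) and under-dominance
  ($-0.01, -5, 0.01$).  Additive contributions are coded $a\,(g-1)$, which
  fixes them up to an intercept and makes $a$ exactly half the homozygote
  difference.  Defaults: $n = 2000$, $p = 500$ on 5 chromosomes, 9
  controlled + 28 random QTL, target $h^2 = 0.4$; the residual SD is set
  from the realized genetic variance and the achieved $h^2$ is reported.
* **Splits** — samples are labelled into five sequential pseudo-
  generations and the last is held out, mirroring forward prediction in
  breeding programs.  No pedigree is simulated: the generator reproduces
  the LD summary and trait architecture, not family structure, so results
  on real pedigreed data may differ where close kinship dominates.
  The MAF filter (default 0.01) runs after trait construction; causal
  loci are restricted to MAF $\ge 0.05$ and always survive it.

What passing tests on these simulations shows: the estimator recovers the
architecture it targets under realistic LD, heritability and sample size.
What it does not show: robustness to genotyping error, strong population
structure, pre-imputed missingness, or pedigree confounding — none of
which the generator emulates.

## Numerical choices and degenerate inputs

* All randomness (masks, shuffles, initialization, simulation) flows
  through R's RNG, so a seed makes chains bit-reproducible; the ADAM
  moment state is returned with the chain, and a resumed chain reproduces
  an unbroken one exactly.
* Weight initialization: biases zero, weights uniform on
  $\pm 1/\sqrt{\text{fan-in}}$.
* The decay factor $(1 - \eta\lambda/b)$ must stay positive; a
  configuration that flips its sign is an error, not a warning.
* Ranking ties break by original marker order, deterministically.
* Divergence (nonfinite parameters or predictions) aborts the chain and
  keeps the trace collected so far.
* The posterior variance uses a one-pass accumulator clamped at zero to
  absorb rounding; the test suite cross-checks it against a two-pass
  oracle at $10^{-12}$.

## The GBLUP baseline

For comparison workflows the package ships a deterministic genomic-BLUP
baseline: the VanRaden relationship matrix
$K = ZZ'/(2\sum_j p_j(1-p_j))$ and closed-form kernel ridge predictions
$\hat y_{test} = K_{test,train}(K_{train,train} + \delta I)^{-1}
(y - \bar y) + \bar y$, with $\delta$ chosen by inner 5-fold
cross-validation.  This is the same family of shrinkage predictors that
MCMC-based Bayesian GBLUP averages over, computed in closed form; it is
labelled approximate wherever it stands in for a sampled Bayesian
baseline.  Its algebraic identity with marker ridge regression (kinship
kernel $\Leftrightarrow$ per-marker shrinkage $\delta \cdot c$) is
verified numerically in the tests.

## Problem sizes used by the shipped experiments

The recovery experiments run 20 replicates per scenario at $n = 2000$,
$p = 500$, $T = 2000$ with burn-in 500 — the scale at which the effect
estimator's behaviour stabilizes while a full replicate stays in the
tens-of-seconds range on one CPU.  Unit tests use smaller instances
($n \le 2000$, $p \le 400$, $T \le 600$) chosen so each property is
exercised well away from trivial sizes.

## Known limitations

* Dominance effect sizes are shrunk by design (see above); users needing
  unbiased $d$ should fit an unregularized genotype-class regression at
  candidate loci after ranking.
* Input-side dropout treats indicator columns independently; locus-level
  dropout is available but untested against real data.
* The simulator's LD is first-order (adjacent-marker); long-range LD and
  population structure are out of scope.
* Effect extraction is deliberately limited to the interpretable model;
  there is no saliency-style importance measure for deeper networks.
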