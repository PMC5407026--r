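---
title: "Methods: allele-specific bursting kinetics with technical-noise correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific bursting kinetics with technical-noise correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alleleburst)
```

# The model and its assumptions

`alleleburst` analyses allele-specific expression (ASE) at single-cell
resolution. Its object of inference is the two-state promoter model: each
allele of a gene switches ON at rate $k_{on}$ and OFF at rate $k_{off}$, and
transcribes at rate $s$ while ON. With the mRNA decay rate normalised to 1
(only the stationary distribution is observed, so rates are identifiable
only per mRNA lifetime), the steady-state transcript count is Poisson-Beta:

$$Y \sim \mathrm{Poisson}(\phi_c\, s\, p), \qquad p \sim \mathrm{Beta}(k_{on}, k_{off}),$$

where $p$ is the fraction of time the allele spends ON and $\phi_c$ is a
per-cell size factor that modulates burst size (cell size affects how much
is made per burst, not how often bursts occur, so $\phi_c$ multiplies the
Poisson mean rather than the Beta parameters). The two alleles of a gene get
separate kinetic parameters but share $\phi_c$. The quantities reported to
users are the burst frequency $k_{on}$ and the burst size $s/k_{off}$;
because estimation biases in $s$ and $k_{off}$ tend to cancel in their
ratio, burst size is more stable than either factor alone, and the package's
tests exploit exactly this ratio.

Assumptions worth keeping in mind: cells are of one type and ergodically
sample the stationary distribution; one heterozygous locus represents each
gene; decay rates are equal between alleles (an allelic decay difference
would masquerade as a burst-frequency difference); and cell-cycle phase is
not modelled (total burst frequency is roughly conserved across the cycle,
so no adjustment is attempted).

## The observation model

Observed counts are distorted by capture loss, amplification bias and
dropout. Conditional on true expression $Y > 0$:

$$Q \sim Z \cdot \mathrm{Poisson}(\alpha Y^{\beta}), \qquad
Z \sim \mathrm{Bernoulli}\big(\mathrm{expit}(\kappa + \tau \log Y)\big),$$

and $Y = 0$ yields $Q = 0$ deterministically — the dropout logistic is a
function of $\log Y$ and is only meaningful for expressed transcripts. The
four noise parameters are shared by all cells of a sequencing batch and are
estimated from spike-ins, which are present at known fixed amounts and do
not burst: $(\alpha, \beta)$ by a log-linear Poisson regression on the
strictly positive observations pooled across cells, then $(\kappa, \tau)$ by
maximising the zero-decomposition likelihood (a zero is either a dropout or
a Poisson zero) with multi-start Nelder–Mead. Pooling across cells is a
deliberate reading of "batch-shared" parameters; per-cell noise parameters
are out of scope.

# Pipeline stages and the choices inside them

## Normalisation

Library-size factors $\eta_c$ use median-of-ratios on the total
(A + B) counts, excluding genes whose total is zero in any cell (their
geometric mean is undefined). Cell sizes are proxied by the ratio of total
endogenous to total spike-in reads and median-normalised to 1; the model
only identifies $\phi_c \cdot s$ jointly, so fixing $\mathrm{median}(\phi) = 1$
keeps kinetic estimates on a per-typical-cell scale. This proxy needs a
genome-scale panel to be stable — with only a handful of genes the
endogenous total is dominated by bursting noise and user-supplied sizes are
preferable. Spike-in reads convert to molecule equivalents as
$\mathrm{reads} \times \mathrm{read\ length} / \mathrm{molecule\ length} / \eta_c$;
the three adjustments are named by the input convention, and this
arrangement (reads to transcript equivalents, then depth normalisation) is
the one defensible composition of them. True molecule counts come from the
concentration via Avogadro's number over the dilution factor.

## Classification

Per gene, each cell is in one of four states — neither allele expressed
($\varnothing$), A only, B only, both (AB) — with relative likelihoods
driven by the per-base error rate $\epsilon$ (default 0.001):
$f_1 \propto \epsilon^{n_A+n_B}$,
$f_2 \propto (1-\epsilon)^{n_A}\epsilon^{n_B}$,
$f_3 \propto \epsilon^{n_A}(1-\epsilon)^{n_B}$, and $f_4$ integrating a
latent allelic ratio $\theta \sim \mathrm{Beta}(a, b)$ over the biallelic
state. All four share one omitted combinatorial constant, so ratios are
exact. Numerical choices:

* $f_4$ has no closed form and is evaluated by order-64 Gauss–Legendre
  quadrature on $(0,1)$ in log space; the test suite validates it against
  adaptive quadrature across counts up to depth ~200, the regime the
  classifier operates in.
* $a = b \ge 3$ keeps the AB state distinguishable from the monoallelic
  ones; $a$ is selected from the grid $\{3, 4, 6, 10, 20\}$ by maximised
  log-likelihood rather than by a continuous update, keeping each EM run
  monotone and the selection reproducible.
* EM starts from uniform mixing weights, stops at $|\Delta \ell| < 10^{-6}$
  or 500 iterations, and ties in the posterior are broken deterministically
  toward $\varnothing$, then A, B, AB.
* Cells are kept for counting only if their maximum posterior exceeds 0.8.
  One consequence of the shared-constant densities deserves emphasis: at
  zero depth all four densities are equal, so the posterior for a zero-count
  cell is just the mixing weights and can never clear a 0.8 threshold in a
  mixed gene. Since a zero-depth cell is exactly what the $\varnothing$
  state predicts, such cells are assigned to $\varnothing$ directly. Without
  this, $N_\varnothing$ would be systematically zero and the downstream
  independence test would flag essentially every gene as coordinated.

Gene categories follow from the kept-cell state counts: silent if only
$\varnothing$; monoallelic if exactly one allele's states occur; otherwise
biallelic, and biallelic *bursty* when each allele is expressed in 5–95% of
assignable cells. Kinetics are only estimated for biallelic bursty genes —
outside that band the moment system is ill-conditioned (constitutive
expression is indistinguishable from large-$k_{on}$, large-$k_{off}$
bursting, and nearly-silent alleles provide too few expressing cells).

## Kinetic estimation

The estimator never models the observed counts directly; it first recovers
the distribution of true expression ("histogram repiling"). Each distinct
observed value $Q > 0$ (after $\eta_c$ normalisation) maps back through the
amplification model to $Y = (Q/\alpha)^{1/\beta}$, and its cell multiplicity
$c(Q)$ — binomially thinned by dropout — is inflated to
$\hat n(Y) = c(Q) / \mathrm{expit}(\hat\kappa + (\hat\tau/\hat\beta)\log(Q/\hat\alpha))$.
The remaining weight piles at $Y = 0$. Degenerate-input handling: if the
inflated weights alone exceed the number of cells, the zero pile is floored
at 0 and the weights rescaled so total weight always equals the cell count —
weight conservation is what lets the moments read as per-cell averages.

From the repiled histogram the factorial moments are computed with
cell-size powers in the denominators
($m_k = \sum Y(Y-1)\cdots(Y-k+1) / \sum_c \phi_c^k$), and the closed-form
inversion of the Poisson-Beta moment equations returns
$(\hat k_{on}, \hat k_{off}, \hat s)$. Two further choices:

* Repiled support values are generally non-integer when $\beta \ne 1$; the
  factorial products are evaluated on the continuous values. Rounding would
  destroy the algebraic moment identities the inversion relies on.
* $\phi_c$ enters only the moment denominators, not the repiling map,
  matching the model in which size scales the Poisson mean of each cell
  rather than the noise process.
* Sample moments can fall outside the image of the forward map; the
  inversion then returns non-positive or non-finite parameters and the gene
  (allele) is flagged *non-estimable*. Estimates are never truncated to a
  positivity boundary — truncation would bias the bootstrap null
  distributions built from re-estimated replicates. Denominators below
  $10^{-12}$ in absolute value are treated as vanishing.

Standard errors and percentile 95% CIs come from resampling cells with
replacement (both alleles and $\phi_c$ travel together, preserving
cross-allele dependence); an allele with more than half its replicates
non-estimable is flagged unstable.

## Hypothesis testing

*Differential kinetics.* The null is that both alleles share burst frequency
and burst size. Each of the $N$ bootstrap replicates pools the $2n$ observed
counts, redraws $2n$ with replacement, assigns the first $n$ to allele A and
the rest to allele B, and re-estimates both alleles; the p-value is the
fraction of valid replicates (both alleles estimable) whose absolute allelic
difference reaches the observed one. The resampled values are assigned to
the fixed cell-slot order so each slot keeps its own $\eta_c$ and $\phi_c$ —
the pooled values are exchangeable under the null, the slots are not. One
replicate stream serves both the frequency and the size statistic. P-values
are floored at $1/n_{valid}$ (never exactly zero), and fewer than 100 valid
replicates raises a low-confidence flag. The default $N$ is 1000.

*Allelic imbalance.* An exact two-sided binomial test of the total A count
among all allelic reads at probability 0.5 — the single-cell analogue of
bulk allelic-imbalance testing. Note its assumptions: read-level
independence, which bursting violates; on bursty genes it is anti-
conservative relative to the bootstrap tests and the two deliberately answer
different questions (mean shift vs kinetic shift).

*Independence.* From the classification counts
$(N_\varnothing, N_A, N_B, N_{AB})$, a Pearson chi-square (1 df, no
continuity correction) compares the 2x2 table of allele-A-expressed by
allele-B-expressed against independence of the marginals. Direction is
*coordinated* when $N_{AB}$ exceeds its expectation, *repulsed* when below;
it is reported only where the test is FDR-significant. Guards: fewer than 20
assigned cells, or a marginal of 0 or 1, skip the test (such genes are not
bursty anyway).

All four families are BH-adjusted separately across genes at a default FDR
of 0.05.

# The simulator

`simulate_allelic_dataset()` generates data from exactly the hierarchy
above: Beta active fractions, Poisson transcription scaled by log-normal
cell sizes, Bernoulli dropout, Poisson amplification, plus a matched
spike-in experiment passed through the same noise model. Defaults encode the
reference study conditions used throughout the verification suite:
$k_{on} = k_{off} = 0.2$, $s = 100$ per allele (a strongly bursty, bimodal
regime), 100 cells, and log-scale cell sizes with mean 0 and SD 0.1. The
cell-size distribution is read on the log scale — $\phi = e^g$,
$g \sim N(0, \sigma^2)$ — since $\phi$ multiplies a Poisson mean and must
stay positive. Default technical noise is $\alpha = 2$, $\beta = 0.9$,
$\kappa = -1$, $\tau = 0.8$: moderate amplification with 50% dropout near
3–4 molecules and under 10% above ~40, a plausible Smart-seq-scale spike-in
fit.

Two simulator-specific design choices: alleles can be coupled through a
Gaussian copula on their Beta quantiles with a user-set correlation, giving
a tunable alternative for power analysis of the independence test (the
generative model itself is silent on dependent bursting); and all draws flow
from a single root seed, with per-gene streams split deterministically via
`sample.int`, so datasets are bit-reproducible and gene draws don't depend
on panel order.

What the simulator does *not* emulate — and hence what passing tests do not
establish about real data: cell-type mixtures and cell-cycle structure
(both can masquerade as coordinated bursting), UMI collapsing, gene-specific
or cell-specific noise parameters, mapping artefacts at heterozygous sites,
and any upstream read-processing effects. Conclusions about those require
real datasets with their own controls.

# Verification scale

The bundled verification suite (and `scripts/acceptance.R`) uses problem
sizes chosen to make each property measurable with comfortable margins:
100 random triples for the algebraic inversion round trip; 200 replicates of
400 cells for the adjustment-ablation study; 200 null genes with 500
bootstrap replicates each for test calibration; five genes of 200 cells per
category for classification accuracy; and $10^5$ draws for the simulator
moment checks. The ablation study compares the full estimator against
cell-size adjustment disabled, noise adjustment disabled, and total-count
(non-allelic) input; the expected ordering is that the full estimator has
the smallest median relative error for both burst frequency and burst size.

# Known limitations

* The moment estimator is noisy for $k_{on} \gg k_{off}$ (constitutive-like)
  and for small $s$ with $k_{on} \ll k_{off}$ (mostly-silent); such genes
  are filtered by the bursty gate or flagged non-estimable/unstable rather
  than reported with false precision.
* The pooled-resampling bootstrap is mildly conservative, most visibly for
  the burst-size statistic, whose third-moment-based estimator has heavy
  bootstrap tails; its realised type-I error at the 0.05 level sits at or
  slightly below the nominal rate under the reference null conditions.
* The binomial imbalance test inherits read-level independence assumptions
  and should be interpreted as a mean-expression comparison, not a kinetic
  one.
* Noise parameters are batch-shared; datasets with strong per-cell
  efficiency differences beyond what $\eta_c$ captures violate this.
* Allelic decay-rate differences are unidentifiable from stationary counts
  and load onto burst frequency.
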