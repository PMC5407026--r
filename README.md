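# alleleburst

Allele-specific transcriptional bursting kinetics from single-cell RNA-seq.

In diploid cells, transcription of each allele occurs in episodic bursts as
its promoter toggles between an ON and an OFF state. `alleleburst` takes
allele-specific read counts at one heterozygous locus per gene across single
cells, plus exogenous spike-in controls, and asks whether the two alleles of
a gene differ in how they burst — not just in mean expression.

## The model

Each allele of gene *g* follows the two-state (telegraph) model with
activation rate *k*<sub>on</sub>, deactivation rate *k*<sub>off</sub> and
transcription rate *s*, all normalised by the mRNA decay rate (fixed at 1).
At steady state the true transcript count is Poisson-Beta:

    Y^A_cg ~ Poisson(phi_c * s^A_g * p^A_cg),   p^A_cg ~ Beta(k^A_on,g, k^A_off,g)

with an independent copy for allele B sharing the per-cell size factor
*phi*<sub>c</sub>. **Burst frequency** is *k*<sub>on</sub> (bursts per mRNA
lifetime) and **burst size** is *s*/*k*<sub>off</sub> (mean transcripts per
burst). Observed counts are distorted by scRNA-seq technical noise:

    Q_cg ~ Z_cg * Poisson(alpha * Y_cg^beta),   Z_cg ~ Bernoulli(expit(kappa + tau*log Y_cg))

where `alpha` (efficiency), `beta` (amplification bias) and `(kappa, tau)`
(expression-dependent dropout) are estimated from spike-in molecules of known
concentration.

The pipeline has three stages:

1. **Classification** — an empirical-Bayes EM assigns each cell to one of the
   states {neither, A only, B only, both} and each gene to
   silent / monoallelic / biallelic (bursty or non-bursty). Kinetics are only
   estimable for *biallelic bursty* genes (each allele expressed in 5–95% of
   assignable cells).
2. **Kinetic estimation** — the observed count histogram is deconvolved to a
   true-expression histogram ("histogram repiling": each observed value is
   mapped back through the amplification model and reweighted by the inverse
   non-dropout probability), cell-size-adjusted factorial moments
   m<sub>1</sub>–m<sub>3</sub> are computed, and closed-form inversion of the
   Poisson-Beta moment equations yields (k̂<sub>on</sub>, k̂<sub>off</sub>, ŝ)
   per allele, with bootstrap SEs and CIs.
3. **Testing** — pooled-resampling bootstrap tests for differential allelic
   burst frequency and burst size; an exact binomial test for allelic
   imbalance in mean expression; a chi-square test of independence of the two
   alleles' ON states with a coordinated/repulsed direction call; each family
   corrected by Benjamini–Hochberg FDR.

A full generative simulator (`simulate_allelic_dataset()`) reproduces this
entire hierarchy with known ground truth, so every estimator and test in the
package can be validated without external data.

## Worked example

Simulate three bursty genes — one with identical allelic kinetics, one whose
B allele bursts ~3.5x more often, one whose B allele has 5x smaller bursts —
and run the pipeline:

```r
library(alleleburst)

truth <- tibble::tibble(
  gene    = c("g_null", "g_freq", "g_size"),
  k_on_a  = c(0.2, 0.2, 0.2), k_off_a = c(0.2, 0.2, 0.2), s_a = c(100, 100, 100),
  k_on_b  = c(0.2, 0.7, 0.2), k_off_b = c(0.2, 0.2, 1.0), s_b = c(100, 100, 100))

sim <- simulate_allelic_dataset(truth, n_cells = 200, seed = 11)
fit <- allelic_bursting(
  sim$counts, spike_ins = sim$spike_ins,
  cell_sizes = tibble::tibble(cell = unique(sim$counts$cell), phi = sim$phi),
  n_boot = 1000, seed = 11)

dplyr::select(tidy(fit), gene, category, burst_frequency_a, burst_frequency_b,
              burst_size_a, burst_size_b, q_freq, q_size)
```

```
    gene         category burst_frequency_a burst_frequency_b burst_size_a burst_size_b q_freq q_size
1 g_null biallelic_bursty             0.240             0.256          338          400  0.762  0.504
2 g_freq biallelic_bursty             0.328             0.718          356          510  0.042  0.470
3 g_size biallelic_bursty             0.209             0.144          365          109  0.115  0.003
```

All three genes are classified biallelic bursty. The null gene shows no
significant allelic difference. The frequency-shifted gene recovers allelic
burst frequencies of 0.33 vs 0.72 (truth 0.2 vs 0.7) and is significant for
differential burst frequency (q = 0.042) but not burst size. The
size-shifted gene recovers burst sizes of 365 vs 109 (truth 500 vs 100) and
is significant for differential burst size (q = 0.003). `glance(fit)` gives
the one-row run summary and `autoplot(fit)` the allele-A vs allele-B kinetic
scatter.

A command-line front end over the same pipeline lives at
`inst/scripts/alleleburst.R` (TSV matrices in, result/noise/size-factor TSVs
out; see its header for flags).

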