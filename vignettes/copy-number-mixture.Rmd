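---
title: "A Bayesian spatial mixture model for SNP-array copy number"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian spatial mixture model for SNP-array copy number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvmix)
```

## The model

Let $y_i$ be the preprocessed (normalized, GC-adjusted) log2-ratio of SNP $i$,
ordered along one chromosome. cnvmix models the $y_i$ as a normal mixture with
an unknown number $k$ of components,

$$p(y_i \mid k, \omega, \mu, \sigma^2) = \sum_{j=1}^{k} \omega_{ij}\,
  N(y_i \mid \mu_j, \sigma_j^2),$$

where each component corresponds to an integer copy-number class
(0, 1, 2, 3, 4, 5, or more than 5). Latent allocations $z_i$ assign each SNP
to a component with $P(z_i = j) = \omega_{ij}$.

Copy-number aberrations occupy contiguous stretches, so the mixture weights
must vary smoothly along the chromosome. For each class $j$ the package keeps
a Gaussian Markov random field $x_{\cdot j}$ over SNP positions with density

$$p(x_{\cdot j} \mid h) = c(h) \exp\Big\{-\tfrac12\Big(
  h \sum_{i \sim i'} (x_{ij} - x_{i'j})^2 + \sum_i x_{ij}^2\Big)\Big\},$$

where $i \sim i'$ ranges over unordered pairs of window neighbors
($|i - i'| \le nb$; SNPs at the chromosome ends simply have fewer
neighbors). Expanding the exponent shows the precision matrix is $I + hQ$
with $Q$ the graph Laplacian of the window graph, so
$c(h) = (2\pi)^{-n/2} \prod_i (1 + h g_i)^{1/2}$ with $g_i$ the Laplacian
eigenvalues — the interpretation under which $c(h)$ actually normalizes the
density, verified in the tests against dense multivariate-normal oracles.
The eigenvalues are computed once per chromosome and cached. Weights are a
tempered softmax of the fields,
$\omega_{ij} = \exp(x_{ij}/\phi) / \sum_l \exp(x_{il}/\phi)$: large $h$ makes
neighboring fields (hence weights) similar, and small $\phi$ sharpens the
weights toward hard segment boundaries.

### The signal model and class intervals

Each component mean has a uniform prior on a class-specific interval. The
seven default intervals (`cn_classes()`) are $(-2, -0.8)$, $(-0.6, -0.25)$,
$(-0.05, 0.05)$, $(0.15, 0.4)$, $(0.45, 0.66)$, $(0.75, 0.9)$, $(0.95, 1.3)$
for CN 0, 1, 2, 3, 4, 5, >5. The diploid interval is symmetric about 0; the
non-diploid intervals for CN 1–5 sit slightly closer to zero than the
uncontaminated class means, anticipating the shrinkage that normal-cell
contamination produces in real tumor samples. Because every mean owns a
disjoint interval, components are permanently identified by their interval and
the label-switching problem of exchangeable mixtures does not arise.

A locus with $j$ tumor copies diluted by a fraction $p$ of normal (diploid)
cells and measured with additive background $b$ has expected log2-ratio

$$m_j = \log_2\frac{j(1-p) + 2p + b}{2 + b}.$$

The background $b$ is not observable directly; `calibrate_background()`
recovers it by least squares from published uncontaminated component means
(CN 1, 3, 4, 5), giving $b \approx 1.47$, under which the implied CN 0 mean is
$-1.24$ and the ">5" class evaluated at $j = 6$ gives $1.106$ — both matching
the published values. This calibrated $b = 1.47$ is the package default
everywhere. Estimating $p$ from data is out of scope: when the pathologist
knows the contamination fraction, `cn_classes_contaminated(p)` centers the
intervals on the shrunk means.

### Priors

* $k \sim$ truncated Poisson on $\{1, \dots, k_{max}\}$ with mean 2
  ($k_{max} = 7$ by default).
* $\mu_j \sim U(a_j, b_j)$, the class interval.
* $\sigma_j^2 \sim$ Inverse-Gamma$(2.1, 0.22)$. Only the center (0.2) and a
  vague spread are fixed by the model's design; the pair $(2.1, 0.22)$ gives
  mean $0.22/1.1 = 0.2$ with essentially undefined variance.
* $h \sim U(0, 10^6)$, wide enough that the data decide the smoothing.
* $\phi = 0.01$ and $nb = 4$ (eight neighbors for interior SNPs), the
  defaults that sensitivity analysis of the original study singled out.

## The sampler

`cnv_fit()` runs a reversible-jump MCMC whose iteration is, in order:

1. **Birth/death of a component.** A birth is proposed with probability
   $b_k$ ($b_1 = 1$, $b_{k_{max}} = 0$, else $1/2$). A birth draws an
   inactive class uniformly, then $\mu_*, \sigma_*^2, x_*$ from their priors
   ($x_*$ from the field prior at the current $h$, which keeps the reverse
   death move well defined); the acceptance ratio multiplies the prior/move
   factor by the marginal-likelihood ratio, the proposal densities of the new
   block cancelling against its priors (identity augmentation, Jacobian 1).
   A death removes a uniformly chosen component; allocations pointing at it
   are refreshed at the next Gibbs sweep, the acceptance ratio being a
   function of the allocation-free mixture likelihood only.
2. **Field sweep.** For $i = 1, \dots, n$ sequentially, the whole row
   $(x_{i1}, \dots, x_{ik})$ is proposed jointly from the exact Gaussian full
   conditionals, mean $h \sum_{i' \sim i} x_{i'j} / (1 + h n_i)$ and variance
   $1/(1 + h n_i)$. Because the proposal is the full conditional of the field
   prior, the prior cancels and the move accepts with the ratio of mixture
   densities at $y_i$ under the new and old weights.
3. **Smoothing parameter.** A random-walk update of $h$ with a
   truncated-normal proposal on $[0, h_{max}]$; the acceptance ratio carries
   $c(h')^k/c(h)^k$, the pairwise-difference exponent, and the truncation
   correction. The proposal scale adapts multiplicatively during burn-in
   (×1.25 above 70% acceptance, ×0.8 below 40%, window of 50 iterations) and
   is frozen afterwards so the sampling phase is a fixed-kernel chain.
4. **Allocations.** Gibbs draws
   $P(z_i = j) \propto \omega_{ij} N(y_i \mid \mu_j, \sigma_j^2)$.
5. **Means and variances.** For each component the unconstrained normal full
   conditional $N(\bar y_j, \sigma_j^2/N_j)$ is evaluated on all $k_{max}$
   intervals; the interval with the largest mass is selected (ties to the
   lowest index; if every mass underflows, the interval nearest the
   conditional mean) and $\mu_j$ is drawn truncated to it. A component may
   therefore migrate to the class its data supports. If two components land
   in one interval they are merged: $\mu$, $\sigma$ (on the SD scale) and the
   field column are averaged with allocation-count weights (equal weights if
   all counts are zero), allocations are redirected, and $k$ drops. Then each
   $\sigma_j^2$ is drawn from Inverse-Gamma$(N_j/2 + \alpha,\,
   \tfrac12\sum_{z_i=j}(y_i - \mu_j)^2 + \beta)$; empty components draw from
   their priors.

All acceptance probabilities are computed in log space, weights by
max-subtracted softmax, so no reachable state produces NaN or infinities.
After burn-in the per-iteration weights over all $k_{max}$ classes (zero for
inactive classes) are averaged into $\bar\omega$; each SNP is called as the
class with the largest averaged weight, ties resolved toward diploid.

### Numerical and design choices

* **Initialization.** All $k_{max}$ classes start active, means at interval
  midpoints, $\sigma_j^2 = 0.04$, $x = 0$, $h = 10$, allocations from one
  Gibbs sweep. Starting saturated is deliberate: burn-in then only has to
  *prune* unneeded components through death moves, which mix well (a
  component with no weight anywhere is cheap to remove), instead of having to
  *discover* a rare component through a birth move whose prior-drawn field
  column seldom lines up with the short segment that needs it. In desk-scale
  experiments a three-component start lost a genuine 10-SNP single-copy loss
  in roughly twice as many replicates as the saturated start.
* **Trans-dimensional warm-up.** With $x = 0$ the weights are uniform, and a
  component supported by only a handful of SNPs can be culled in the very
  first iterations because removing it raises every other SNP's uniform
  weight. The first `k_warmup` burn-in iterations (200 by default) therefore
  run only the within-model moves, letting the fields sharpen around the
  initial components before births and deaths begin. This is purely an
  initialization policy: warm-up iterations are discarded with the rest of
  burn-in and the post-burn-in kernel is unchanged.
* **Proposal variance of the field move.** The exact full-conditional
  variance $1/(1 + h n_i)$ is used. (A variance of $1/(h n_i)$ would diverge
  at $h = 0$ and would require an explicit proposal correction; the
  full-conditional form makes the prior cancel exactly.)
* **One global $h$ update per iteration.** $h$ is a chromosome-level scalar;
  its update is a single Metropolis step per iteration.
* **The implied prior over $k$.** The printed birth/death acceptance ratios
  weight every active-class subset by the truncated-Poisson mass of its size,
  so the chain's exact invariant marginal over $k$ (with the likelihood
  removed) is $p(k)\binom{k_{max}}{k}$, renormalized — not $p(k)$ itself.
  The likelihood-free validation run in the test suite checks the chain
  against this exact closed form, together with uniform $\mu$ and uniform
  $h$ marginals.
* **Averaging $\bar\omega$** uses every post-burn-in draw, unthinned, and
  averages the softmax weights rather than allocation indicators.
* **Degenerate inputs.** Constant tracks are called entirely diploid;
  non-finite log2-ratios are rejected before sampling; truncated-normal
  draws falling numerically outside their interval are clamped.

## The simulator and error metrics

`simulate_track()` draws $y_i \sim N(m_{j(i)}, sd^2)$ independently over a
true segment profile, the same SD for every class — the data-generating
process of the package's validation study. Two fixed 245-SNP patterns are
built in (`cn_pattern()`): pattern A with CN 3(5), 1(10), 3(20), 3(40)
aberrations between diploid runs, pattern B with CN 4(5), 3(10), 0(20),
3(40). The scenario grid (`scenario_grid()`) crosses the patterns with SD
0.05/0.15/0.2 at no contamination and SD 0.2 at 20% contamination; the
derived signal-to-noise ratios (three-copy mean over SD) are 7.3, 2.4, 1.8
and 1.5.

Error rates follow the segment-level definitions: misclassification
$P(\mathrm{call} \ne j \mid \mathrm{true}\ j \ne 2)$, false negatives
$P(\mathrm{call} = 2 \mid \mathrm{true} \ne 2)$, false positives
$P(\mathrm{call} \ne 2 \mid \mathrm{true} = 2)$, the last pooled across the
two patterns' diploid segments by width (`reproduce_tables()`).

What the simulator deliberately does not emulate: genome-wave autocorrelation
and GC effects (inputs are assumed already adjusted), heteroscedastic or
heavy-tailed probe noise, inter-probe distance variation, allele-specific
signal. Passing the simulation study therefore demonstrates correctness of
the model and sampler under its own assumptions, not robustness to raw-array
artifacts.

## Problem sizes used for validation

The package's test suite and `scripts/acceptance.R` run a desk-scale version
of the study: 10 replicates with 5,000 burn-in + 5,000 sampling iterations
(the original used 50 replicates of 50,000 + 50,000). At this scale the
high-SNR scenario reproduces 0% misclassification on every aberrant segment,
and the SNR 2.4 scenario stays well inside the published 5% bound for
segments of at least 10 SNPs. The hardest cell — the 10-SNP single-copy loss
at SNR 1.8 — is marginal at desk scale: the posterior for that segment is
genuinely bimodal (loss present vs. diploid), the chain switches between the
modes on a timescale of a few thousand iterations, and a 5,000-draw averaging
window is short relative to that, so whole replicates flip to the wrong call
more often than at full scale. The averaged weights themselves are unbiased;
it is their argmax that is noisy. Re-running flipped replicates at the full
50,000 + 50,000 scale recovers the correct call in the majority of them, with
averaged loss-class probabilities around 0.5–0.75. Expect the desk-scale
misclassification estimate for that one cell to fluctuate around 10–30%
across seed batches (its replicate-level failure indicator is Bernoulli with
p roughly 0.2), against roughly 11% at full scale. Five-SNP aberrations at
SNR below 2 are frequently missed at every scale, which is the published
behavior as well. The likelihood-free prior-recovery run uses 20,000 draws on
a 12-SNP track with $h_{max}$ scaled to 100 so a short chain can traverse the
support.

## Worked example

```{r example, eval = FALSE}
trk <- simulate_track("A", sd = 0.05, seed = 1)
fit <- cnv_fit(trk, burnin = 5000, samples = 5000, seed = 2)
glance(fit)
segment_calls(tidy(fit))
autoplot(fit)
```

## Known limitations

* Run time grows linearly in SNPs × iterations; whole high-density
  chromosomes need longer runs than the desk-scale defaults.
* The contamination fraction $p$ is an input, not an estimate.
* Aberrations spanning fewer than ~5 probes are unreliable below SNR 2, as
  in the original study.
* Only total copy number is modeled; B-allele frequencies and copy-neutral
  LOH are out of scope.
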