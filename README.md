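# cnvmix

Bayesian inference of integer genomic copy number from ordered SNP-array
log2-ratios, for cancer genomics workflows where tumor samples carry an
unknown mixture of aberrant and normal cells.

## The model

A chromosome's preprocessed log2-ratios y<sub>1</sub>, ..., y<sub>n</sub> are
modeled as a normal mixture with an unknown number *k* of components, each
tied to an integer copy-number class (0, 1, 2, 3, 4, 5, >5):

    p(y_i | k, ω, μ, σ²) = Σ_j ω_ij N(y_i | μ_j, σ_j²)

Aberrations are contiguous, so the per-SNP mixture weights ω<sub>ij</sub> are
made spatially smooth: each class carries a Gaussian Markov random field
x<sub>·j</sub> over SNP positions with precision I + hQ (Q the Laplacian of a
window neighbor graph), and ω<sub>ij</sub> = exp(x<sub>ij</sub>/φ) / Σ_l
exp(x<sub>il</sub>/φ). Each component mean has a uniform prior on a disjoint
class interval, which identifies components permanently and sidesteps label
switching. Normal-cell contamination enters through the signal model

    E[log2-ratio | CN = j] = log2( (j(1−p) + 2p + b) / (2 + b) )

with contamination fraction *p* and background *b* (calibrated to 1.47 from
published component means): contamination shrinks every aberrant mean toward
0, and the class intervals can be re-centered accordingly when *p* is known.

Posterior inference is by reversible-jump MCMC: birth/death moves on the
number of components, Metropolis–Hastings sweeps of the fields using their
exact full conditionals as proposals, an adaptive random-walk update of the
smoothing parameter *h*, Gibbs allocation draws, and truncated-normal mean
updates in which components may migrate between class intervals and merge.
Averaged per-SNP class probabilities give the final integer calls.

See `vignette("copy-number-mixture")` for the full model, priors, sampler
and design choices.

## Worked example

```r
library(cnvmix)

trk <- simulate_track("A", sd = 0.05, seed = 1)   # 245-SNP benchmark pattern
fit <- cnv_fit(trk, burnin = 5000, samples = 5000, seed = 2)
fit
#> Bayesian spatial mixture copy-number fit
#>   SNPs: 245  classes: 7  burn-in: 5000  samples: 5000
#>   posterior k mode: 3  median h: 123.5
#>   segments called: 9 ( 2(10), 3(5), 2(50), 1(10), 2(50), 3(20), 2(50), 3(40), 2(10) )

segment_calls(tidy(fit))
#> # A tibble: 9 × 8
#>   chrom start   end cn_call cn_label n_snps pos_start pos_end
#>   <chr> <int> <int>   <int> <chr>     <int>     <int>   <int>
#> 1 chr1      0    10       2 2            10   1000000 1022500
#> 2 chr1     10    15       3 3             5   1025000 1035000
#> 3 chr1     15    65       2 2            50   1037500 1160000
#> 4 chr1     65    75       1 1            10   1162500 1185000
#> ...
```

The simulated truth is the segment pattern 2(10), 3(5), 2(50), 1(10), 2(50),
3(20), 2(50), 3(40), 2(10); at this signal-to-noise ratio (7.3) every
segment, including the 5-SNP gain, is recovered exactly. `tidy(fit)` returns
the per-SNP table with the seven averaged class probabilities and the call;
`glance(fit)` gives chain diagnostics (posterior mode of *k*, acceptance
rates, final proposal scale); `autoplot(fit)` plots the track colored by
call.

A small command line ships in `inst/cli/`:

```sh
inst/cli/cnvmix simulate --pattern A --sd 0.05 --seed 7 --out sim
inst/cli/cnvmix call --in sim.track.tsv --out called --seed 3
inst/cli/cnvmix evaluate --calls called.calls.tsv --truth sim.truth.tsv --out rates.tsv
```

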