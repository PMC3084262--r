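# corecruit

Genome-wide inference of how a non-DNA-binding transcriptional co-repressor
is targeted to its sites. The motivating system is yeast Tup1-Ssn6: a
conserved co-repressor complex that silences hundreds of genes yet binds no
DNA itself, relying instead on sequence-specific "recruiter" transcription
factors (Sut1, Nrg1, Rox1, Sko1, Cup9, ...) to tether it to promoters.
`corecruit` is for computational biologists who have genome-wide occupancy
profiles (ChIP-chip log2 IP/input ratios over intergenic regions, with
binding p-values) and want to answer: where does the co-repressor bind,
which factors recruit it, and how well does recruiter occupancy predict
co-repressor occupancy?

## What it implements

* **Peak calling** — replicate standardization (per-replicate Z-transform,
  per-element median), a Gaussian background null fitted by reflecting the
  sub-median half of the data, 1 kb sliding windows every 0.25 kb scored by
  mean element value with p-value `P(N(mu, sigma/sqrt(n)) >= mean)`,
  Benjamini–Hochberg FDR (q < 0.001), an element-wise mock-IP filter
  (signal Z − mock Z > 1 and mock Z < 2), and collapsing of windows within
  1 kb with the highest element as each peak's representative.
* **Co-occupancy analysis** — classification of targets by cofactor binding
  (p < 0.001), binning and regression of occupancy on the number of bound
  recruiters, IP-efficiency scaling and paired comparison of wild-type vs
  recruiter-deletion profiles, Welch tests of derepression for bound vs
  unbound targets, and decile binning of genes by derepression.
* **Recruiter screen** — five tests per factor (motif over-representation
  by exact-p PWM scanning and a binomial test; sensitivity; specificity;
  top-quartile binding correlation; top-quartile expression correlation),
  each converted to a percentile rank over the factor panel and averaged
  over the tests available to each factor. The core statistic per factor
  is the composite rank; the model ranks true recruiters above
  binding-rate-matched decoys.
* **Occupancy regression** — the linear recruitment model
  `y = b0 + sum_r b_r x_r + e`, fitted with Gaussian imputation of missing
  entries (10 draws), a positive-and-significant univariate screen, five
  random half-genome splits with held-out R² (repeated random-subsampling
  cross-validation), pruning of non-significant recruiters (p > 0.01), and
  a partial F-test for nested model comparison.
* **Synthetic data** — a generator with stored ground truth: mixture
  occupancies with binding p-values, a planted linear co-repressor model
  whose noise is calibrated analytically to a genome-wide R² of 0.43,
  missing entries, replicates, deletion strains with tunable redundancy,
  derepression-linked expression, and sequences with planted PWM sites.

## Worked example

```r
library(corecruit)

cfg <- sim_config(n_regions = 6000, decoys = c("DEC01", "DEC02", "DEC03"))
d   <- generate_dataset(cfg, seed = 1)
d
#> occupancy_dataset: 6000 regions x 12 factors (+ TUP1), noise_sd = 1.062, seed = 1

fit <- fit_occupancy_model(d, seed = 2)   # impute -> screen -> CV fit -> prune
fit$model
#> occupancy_model: 9 recruiters, R2 train 0.407 / held-out 0.415 (5 splits x 10 imputations)
#>             weight   p_value
#> (Intercept)  0.131        NA
#> SUT1         0.441  2.81e-63
#> NRG1         0.330  2.12e-36
#> ROX1         0.190  1.35e-13
#> SKO1         0.164  3.69e-10
#> CUP9         0.503  1.63e-82
#> YAP6         0.687 2.37e-149
#> CIN5         0.401  7.89e-54
#> PHD1         0.141  2.08e-08
#> SKN7         0.165  8.85e-11
```

The pipeline rejected the three decoy candidates and recovered all nine
planted recruiters with weights close to the planted values
(`default_recruiter_weights()`); the held-out R² of 0.41 approaches the
generative model's calibrated 0.43. The composite screen tells the same
story from the co-occupancy side — all nine planted recruiters outrank
fifty binding-rate-matched decoys:

```r
st <- screen_study(1, n_regions = 6000, n_decoys = 50, include_motif = FALSE)
head(st$scorecard[, c("factor", "average_rank", "n_tests_used")], 10)
#>    factor average_rank n_tests_used
#> 1    YAP6       100.00            4
#> 2    CUP9        98.31            4
#> 3    CIN5        95.76            4
#> 4    SUT1        95.76            4
#> 5    NRG1        93.22            4
#> 6    SKO1        90.89            4
#> 7    PHD1        88.77            4
#> 8    ROX1        86.65            4
#> 9    SKN7        84.96            4
#> 10  DEC15        80.51            4
```

A thin command-line wrapper over the same functions is in
`inst/scripts/corecruit-cli.R` (`simulate`, `callpeaks`, `regress`).

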