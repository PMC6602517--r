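# mktools

Estimation of the rate of adaptive molecular evolution from polymorphism and
divergence data with the McDonald–Kreitman (MK) framework, for population
geneticists analyzing coding sequences from a population sample plus an
outgroup orthologue.

## The statistics

The MK test contrasts two site classes — putatively selected (typically
nonsynonymous, N) and putatively neutral (typically synonymous, S) — in a
2×2 table of segregating polymorphisms (P) versus fixed differences to an
outgroup (D):

|          | polymorphic | divergent |
|----------|-------------|-----------|
| selected | P_N         | D_N       |
| neutral  | P_S         | D_S       |

Under neutrality the two ratios agree; an excess of selected divergence
signals recurrent positive selection. The fraction of adaptive
nonsynonymous substitutions is

    alpha = 1 − (D_S · P_N) / (D_N · P_S)

Because weakly deleterious variants segregate at low frequency but rarely
fix, raw alpha estimates are biased downward. The package implements four
estimators that deal with this differently:

1. **Standard MKT** — the plain 2×2 table with Fisher's exact test.
2. **FWW correction** — discards all variants below a frequency cutoff
   (default 0.05) from both classes.
3. **Extended MKT (eMKT)** — partitions low-frequency nonsynonymous
   polymorphism into neutral and weakly deleterious fractions using the
   synonymous spectrum, and, given site totals m_N and m_S, estimates the
   fractions of nonsynonymous sites under each selection regime: f
   (neutral), b (weakly deleterious), d (strongly deleterious).
4. **Asymptotic MKT (aMKT)** — computes alpha(x) per derived-allele-frequency
   bin, fits alpha(x) = a + b·exp(−c·x), and reports the fitted value at
   x = 1 with a parametric-bootstrap 95% CI.

Upstream of the tests, the package builds the derived allele frequency (DAF)
spectrum and divergence counts directly from an aligned multi-FASTA of
coding sequences (site classification against the standard genetic code,
subsampling to uniform depth, outgroup polarization, Nei–Gojobori site
counting). Downstream, gene sets can be concatenated, tested for
heterogeneity of selection (Cochran–Mantel–Haenszel and Breslow–Day–Tarone
statistics) and compared by bootstrap resampling of genes.

## Worked example

```r
library(mktools)

# Two gene sets: one evolving with true alpha = 0.6 (e.g. genes in high
# recombination regions), one with 0.44 (genome-wide background)
high   <- simulate_cohort(475,  regime_preset("figure2_high"),   seed = 7,
                          rec_range = c(7, 15))
genome <- simulate_cohort(1500, regime_preset("figure2_genome"), seed = 8)

# Extended MKT on the pooled high-recombination set
pool <- concatenate_genes(high)
mkt(pool, method = "emkt", cutoff = 0.05)
#> Extended MKT
#>   table: Pn = 40577, Ps = 13616, Dn = 142431, Ds = 18908
#>   cutoff: 0.05
#>   alpha = 0.6044   p = 0
#>   regimes: f (neutral) = 0.9934, b (weakly del.) = 0, d (strongly del.) = 0.006634

# Bootstrap comparison of the two sets (100 replicates of 400 genes)
compare_groups(high, genome, labels = c("high-rec", "genome"),
               method = "emkt", cutoff = 0.05, n_reps = 100,
               sample_size = 400, seed = 9)
#> Bootstrap comparison (emkt, 100 replicates)
#>   high-rec: alpha mean = 0.605 +/- SD 0.00606, 95% CI [0.5935, 0.6171]
#>   genome: alpha mean = 0.4435 +/- SD 0.007615, 95% CI [0.4275, 0.4575]
#>   difference (high-rec - genome): 0.1615, 95% CI [0.1436, 0.1787]
```

The bootstrap means recover the planted adaptation rates (0.6 and 0.44)
and the non-overlapping CIs separate the two sets, the signature of a
higher adaptation rate in the first group.

A thin command-line front end over the same functions is installed at
`inst/exec/mktools` with subcommands `spectrum`, `test`, `cohort`,
`simulate` and `report` (JSON canonical output, optional static HTML).

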