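---
title: "The MK framework in mktools: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MK framework in mktools: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mktools)
```

## The model

The McDonald–Kreitman framework compares, for a coding region, the ratio of
selected-class (nonsynonymous) to neutral-class (synonymous) variation
within a species against the same ratio between species. Polymorphism
counts `Pn`, `Ps` come from a sample of `n` chromosomes; divergence counts
`Dn`, `Ds` come from comparison with a single outgroup orthologue, which
also supplies the ancestral state of each segregating site (so spectra are
*unfolded*, binned by derived allele frequency `x = i/n`). Under strict
neutrality of segregating sites, the expected fraction of adaptive
nonsynonymous fixations is

$$\alpha = 1 - \frac{D_S\,P_N}{D_N\,P_S}.$$

The assumption that fails in practice is strict neutrality: weakly
deleterious nonsynonymous variants inflate `Pn` (mostly at low frequency)
without contributing to `Dn`, biasing $\alpha$ downward. Each estimator in
`mkt()` handles this differently, and comparing them on the same data is
itself informative:

* **standard** uses the raw table;
* **fww** removes every bin with `x < cutoff` from *both* classes;
* **emkt** estimates how much of the low-frequency `Pn` is neutral by
  assuming the neutral fraction of nonsynonymous variants has the same
  spectrum shape as the synonymous class: with `L`/`H` the bins below/at or
  above the cutoff, the expected neutral part of `Pn(L)` is
  `Pn(H) * Ps(L) / Ps(H)`, the excess is the weakly deleterious load, and
  $\alpha$ uses only the neutral part. Given site totals `m_n`, `m_s` it
  also reports the regime fractions
  `f = m_s * Pn_neutral / (m_n * Ps)` (effectively neutral),
  `b = m_s * wd / (m_n * Ps)` (weakly deleterious) and `d = 1 - f - b`
  (strongly deleterious, contributing neither polymorphism nor divergence);
* **asymptotic** computes $\alpha(x)$ per frequency bin and extrapolates
  $\alpha(x) = a + b e^{-cx}$ to `x = 1`. Deleterious load depresses only
  the low-`x` points, so the asymptote recovers $\alpha$ without a hard
  cutoff, at the price of a nonlinear fit.

## Tunable parameters

* `cutoff` (frequency, default **0.05**): the low-frequency threshold for
  `fww` and `emkt`. Variants below 5% frequency are where slightly
  deleterious alleles concentrate; the default matches common practice for
  population samples of tens of chromosomes. Note that with `n = 20`
  chromosomes the lowest bin is exactly 0.05 and a *strict* `< 0.05`
  cutoff excludes nothing; choose the cutoff relative to `1/n`.
* `x_low`, `x_high` (default **[0, 0.9]**): the trajectory interval for the
  asymptotic fit. The top bins are removed because ancestral-state
  (polarization) errors convert high-frequency ancestral alleles into
  spurious high-frequency derived variants.
* `n_boot` (default **1000**): parametric-bootstrap replicates for the
  asymptotic CI.
* `depth` in `build_tables()` (default: largest `n` retaining ≥ 90% of
  columns): the uniform number of chromosomes subsampled per site. Higher
  depth refines the spectrum but discards more columns with missing data.
* `n_reps` / `sample_size` in `bootstrap_alpha()` (defaults **100** and the
  group size): gene-level bootstrap settings for cohort comparisons.

## From alignments to tables

`build_tables()` processes one codon at a time, after per-column
subsampling without replacement to the target depth (columns with fewer
valid bases are excluded as `insufficient_depth`; gaps count as missing,
like `N`). The outgroup codon serves as the ancestral codon. A codon is
excluded entirely, and logged, when its outgroup codon is incomplete
(`unpolarizable`), any site carries more than two alleles
(`multiallelic`), more than one position is segregating or divergent
(`multihit` — the order of multiple hits within a codon is not
identifiable, so exclusion is the conservative choice), the ancestral
codon is a stop (`stop`), or a segregating site's outgroup base matches
neither allele (`unpolarizable`). Sites that are simultaneously
polymorphic and divergent fall into that last rule: with no identifiable
ancestral allele they are excluded altogether rather than guessed at.

Site totals use Nei–Gojobori fractional counting on the ancestral codon:
each position contributes (number of its three possible mutations that are
synonymous)/3 to `m_s`, the rest to `m_n`, so `m_n + m_s` equals three
times the number of retained codons; mutations to stop codons count as
nonsynonymous. When overlapping transcript frames assign different classes
to one site, the most selectively constrained class (nonsynonymous) wins
(`resolve_site_class()`).

Subsampling randomness is controlled by a single integer seed from which
per-column streams are derived in counter mode, so results are independent
of column processing order, and deterministic at full depth on complete
data.

## Numerical choices

* **Fisher's exact test** is computed from hypergeometric point
  probabilities, two-sided by summing all outcomes no more probable than
  the observed one (with the conventional `1e-7` relative slack), no
  continuity correction. Tables with a zero margin are uninformative:
  `p = 1` with note `degenerate_margin`. $\alpha$ is reported as undefined
  (`NA` + note), never as `±Inf`, when `Dn = 0` or `Ps = 0`; cohort
  aggregation drops and counts such replicates.
* **eMKT guards**: sampling noise can make the expected neutral
  low-frequency count exceed the observed `Pn(L)`; the neutral part is
  capped at `Pn(L)` so the weakly deleterious load is never negative.
  Regime fractions are clamped to `[0, 1]` (noted when it happens) and
  `d` absorbs the remainder. The Fisher table rounds the non-integer
  `Pn_neutral` to the nearest count (noted); $\alpha$ itself uses the
  unrounded value.
* **Exponential fit**: for fixed decay rate `c` the model is linear in
  `(a, b)`, so the fitter scans the profiled SSE over a log-spaced grid of
  `c` in `[1e-4, 100]`, refines the best bracket by 1-D optimization, and
  polishes with Levenberg–Marquardt restarts from
  `c ∈ {0.1, 0.5, 1, 2, 5, 10}` plus the profiled optimum (`c` bounded in
  `(0, 100]`). This handles the multimodality of exponential regression
  without user-supplied starting values. If every restart fails (possible
  only for degenerate abscissae) an ordinary linear fit is used and
  flagged. Bins are equally weighted by default — the per-bin variance is
  dominated by counts, and a `weights = "count"` switch is exposed — and
  the asymptote is capped at 1 (noted) since $\alpha \le 1$ by
  construction.
* **Asymptotic CI**: the 95% interval is a parametric bootstrap — per-bin
  Poisson resampling of `Pn(x)`, `Ps(x)` around the observed counts with a
  full refit per replicate, percentile 2.5/97.5 — constructed and labeled
  as this package's own choice. Failed replicates are dropped and counted;
  more than half failing flags the interval.
* **Stratified tests**: `cmh_test(variant = "common")` is the classic
  Cochran–Mantel–Haenszel chi-square of common association (df = 1, no
  continuity correction). Because a *heterogeneity* question is often what
  is actually asked of a multi-gene table, the Breslow–Day statistic with
  Tarone's correction (df = K−1) is exposed as
  `variant = "heterogeneity"`; reports show whichever the user selects,
  and the CLI cohort report includes both, since the two address different
  nulls.
* **Concatenation across depths**: genes sampled at different depths are
  rebinned onto a fixed 20-bin grid (width 0.05, midpoints) before
  summation, making mixed-population inputs legal at the cost of
  within-bin resolution.
* **Bootstrap determinism**: replicate streams are derived from the seed
  by replicate index and genes are sorted by id before resampling, so
  bootstrap results are invariant to input order and bit-reproducible.
  Group comparisons use independent derived streams per group and the
  percentile CI of the replicate-wise difference (percentile rather than
  BCa, matching the simple resampling CI this kind of analysis reports).

## The simulator: what it emulates and what it does not

`simulate_gene()` draws Poisson counts around closed-form expectations:
the neutral spectrum `E[Ps_i] = theta_s * m_s / i`, a selected-class
mixture of a neutral fraction `f` (same shape, scaled by `m_n/m_s`) and a
weakly deleterious fraction `b` with spectrum `∝ 1/i^(1+weak_skew)`
(normalized to the same total mass as the neutral shape, so `b` and `f`
are comparable; `weak_skew = 1` by default), and divergence
`E[Ds] = ds_mean`, `E[Dn] = ds_mean * (m_n/m_s) * f / (1 - alpha_true)`.
The strongly deleterious fraction `d` contributes nothing. This yields
*calibrated truth*: pooled expectations imply
$\alpha \to \alpha_{true}$ for the standard test when `b = 0`, and a known
downward bias when `b > 0` — exactly the properties the estimators are
tested against. Defaults (`n_sample = 20`, `m_n = 1200`, `m_s = 400`,
`theta_s = 0.02`, `ds_mean = 40`) are Drosophila-like single-gene scales.

What the simulator does **not** emulate: genealogical noise and linkage
(counts are independent Poisson, not coalescent-correlated), demography
(no skews from growth or structure beyond the planted `weak_skew`),
polarization error, and base-composition or mutation-rate heterogeneity.
Passing recovery tests on these fixtures therefore demonstrates estimator
correctness under the MK generative assumptions, not robustness to the
full messiness of real data.

The `figure2_high` / `figure2_genome` presets (true $\alpha$ 0.6 and 0.44,
no deleterious load) emulate the textbook contrast of a high-recombination
gene set against the genome-wide background; the load is omitted there so
the comparison isolates the adaptation-rate difference itself. The
end-to-end comparison uses 475 and 1500 simulated genes with 100 bootstrap
replicates of 400 genes, a desk-scale rendering of that analysis.

## Worked cohort example

```{r example}
high   <- simulate_cohort(80, regime_preset("figure2_high"),   seed = 61,
                          rec_range = c(7, 15))
genome <- simulate_cohort(240, regime_preset("figure2_genome"), seed = 62)

# strict > 7 cM/Mb, mirroring a "min recombination rate: 7" gene filter
high_rec <- filter_genes(c(high, genome), min_rec = 7)
length(high_rec)

cmp <- compare_groups(high, genome, labels = c("high-rec", "genome"),
                      method = "emkt", cutoff = 0.05, n_reps = 100,
                      sample_size = 80, seed = 9)
cmp
```

## Known limitations

* One outgroup only: no multi-outgroup ancestral inference, hence no
  correction for polarization error beyond the aMKT high-frequency trim.
* Divergence counts are raw (no multiple-hit correction such as
  Jukes–Cantor); for close outgroups this is standard, for distant ones
  `Dn`, `Ds` will be underestimated.
* Multi-hit codons are excluded rather than path-averaged, slightly
  undercounting divergence in fast-evolving codons.
* The eMKT regime fractions require site totals `m_n`, `m_s`; without them
  only $\alpha$ is reported.
* The asymptotic CI is a parametric bootstrap, not an analytic interval;
  with very sparse spectra it can be flagged unreliable.
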