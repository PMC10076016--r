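---
title: "Methods: selection scans and genotype-environment association"
author: "adaptscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection scans and genotype-environment association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptscan)
```

`adaptscan` characterises rapid protein evolution and its link to
ecological variation through four stages: codon-level dN/dS, the
McDonald–Kreitman (MK) test, per-population allele frequencies from variant
calls, and a gene-level environment-association test. This vignette sets
out the models and conventions behind each stage, the choices made where
the methodology is genuinely open, and what the synthetic-data generators
do and do not establish.

## Pairwise dN/dS by codon counting

`pairwiseDnDs()` implements a counting estimator in the Nei–Gojobori
tradition under the standard genetic code:

* **Expected sites.** For each codon position, the synonymous site fraction
  is the proportion of the up to three single-nucleotide neighbours that
  encode the same amino acid; neighbours creating stop codons are excluded
  from both numerator and denominator at that position. Site counts sum to
  exactly 3 per codon and are averaged between the two sequences.
* **Observed differences.** For a codon pair differing at $k$ positions,
  all $k!$ minimal single-step pathways are enumerated; the synonymous and
  nonsynonymous step counts are averaged with equal weights. Pathways that
  pass through a stop codon are excluded; in the rare case that every
  pathway does, all are retained (a step into or out of a stop counts as
  nonsynonymous, since the product changes). `Sd + Nd` always equals the
  codon Hamming distance.
* **Correction and ratio.** $p_S = S_d/S$ and $p_N = N_d/N$ are corrected
  for multiple hits by Jukes–Cantor, $d = -\tfrac{3}{4}\ln(1-\tfrac{4}{3}p)$,
  and $\omega = d_N/d_S$.

A maximum-likelihood codon model (e.g. the Yang–Nielsen family) would
additionally estimate transition/transversion and codon-frequency
parameters; the counting estimator was chosen as the primary method because
it is deterministic, desk-checkable against exhaustive enumeration (the
test suite verifies every one of the $61 \times 61$ codon pairs against an
independently written brute-force enumerator), and adequate at the modest
divergences where the ratio is interpretable. Outputs carry a `status`
field so a model-based backend could be added without changing the
interface.

Degenerate cases are reported, never silently dropped: $d_S = 0$ yields an
undefined $\omega$ with status `"dS_zero"` (not infinity), and
$p \ge 3/4$ yields a saturation status. Codons containing a gap, `N`, or a
stop in either sequence are excluded pairwise.

### Sliding windows

`slidingWindowDnDs()` defaults to 34-codon (102-nt) windows advanced by 31
codons, i.e. consecutive windows overlap by 3 codons. When the last regular
window stops short of the sequence end, an extra window anchored at the end
is appended, so the windows always tile the alignment; the trailing window
may overlap its predecessor by more than 3 codons, which we prefer to
discarding terminal codons. Windows with undefined $\omega$ (for instance
fully conserved ones) are reported as missing rather than removed, so
window tracks from different genes stay positionally comparable.

### Percentile ranks

All ranking in the package uses one percentile definition, the midpoint
tie rule: $100 \cdot (\#\{x < v\} + 0.5\,\#\{x = v\}) / N$. It is stable
under duplicated values (a population of identical scores all sit at the
50th percentile) and symmetric, at the price that a strict maximum ranks at
$100(N-0.5)/N$ rather than 100. Genes with undefined $\omega$ are excluded
from the ranked population and reported separately.

## McDonald–Kreitman test

`classifySites()` walks the ingroup-plus-outgroup alignment codon by codon
(codons with a gap, `N`, or stop in any row are skipped) and classifies
every variable nucleotide position independently against the ingroup
major-allele codon context:

* a position segregating in the ingroup contributes one polymorphism per
  non-major allele, typed synonymous/nonsynonymous by substituting that
  allele into the major-allele codon;
* a position monomorphic in the ingroup but differing from the outgroup
  contributes one fixed difference, typed by substituting the outgroup
  base;
* a position that is both polymorphic and divergent counts as polymorphism
  only — the ingroup major allele defines the lineage state, the standard
  conservative convention.

Classifying segregating positions independently (rather than
pathway-averaging within a codon) keeps the counts integral and matches
how per-SNP effect classification works when alternative coding sequences
are built from individual genotypes. Majority ties are broken toward the
outgroup allele when it is among the tied alleles (parsimony-flavoured,
avoids manufacturing divergence), otherwise alphabetically. A substitution
creating a stop codon is counted as nonsynonymous. No frequency cutoff is
applied inside this module; whether low-frequency polymorphisms were
removed upstream is the caller's decision via `filterVariants()`.

`mkAlpha()` is the Smith–Eyre-Walker point estimate
$\alpha = 1 - (D_s P_n)/(D_n P_s)$, an error when $D_n = 0$ or $P_s = 0$
(`mkTest()` maps that to `NA`). `fisherExact2x2()` enumerates the full
hypergeometric distribution at the observed margins and sums the
probabilities of all tables no more probable than the observed one
(two-sided probability-mass rule, with a $1+10^{-7}$ relative tolerance on
the comparison, matching the convention of `stats::fisher.test`, which the
tests use as an independent cross-check). Tables with a zero row or column
margin get $p = 1$ by convention, flagged with a warning.

One property worth knowing when interpreting calibration results: because
the null distribution is discrete, the exact test is conservative — in the
package's neutral calibration (below) its realised rejection rate at the
5% level is about 3–4%, not 5%. That is a property of exact tests on
finite tables, not a miscalibration of the implementation.

## Population variants and filters

Genotypes are read from VCF 4.x through `VariantAnnotation`; only diploid
calls are supported (haploid calls are an explicit error), and half-calls
keep their one called allele. `splitMultiallelic()` produces one biallelic
record per alternate allele, with alleles belonging to other alternates
recoded as missing — the genotype-level analogue of `bcftools norm -m -`.
Frequencies are $AF = AC/AN$ per population, missing when no allele was
called.

`filterVariants()` applies three rules, with the quoted boundaries strict:

1. missingness: dropped if the fraction of individuals with a *fully*
   missing genotype exceeds 0.9 **in any single population** (exactly 0.9
   is kept). The per-population reading follows the stated screening
   wording; a site-wide `F_MISSING` expression would be weaker.
2. quality: dropped if `QUAL < 30` (exactly 30 is kept; missing QUAL
   fails);
3. frequency: dropped if `AF < 0.05` in every population with a defined
   frequency (exactly 0.05 anywhere rescues the record).

Each dropped record is tallied under the first rule that removes it, in
that order, and the filter is idempotent. Gene assignment uses 1-based
inclusive intervals, converted internally at the boundary.

## Environment association

For each (variant, variable) pair, `pearsonWithP()` computes the sample
Pearson $r$ of the per-population allele frequency against the variable
after pairwise deletion of missing populations, with the two-tailed p-value
from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. Pairs with
fewer than 3 complete populations or a constant vector are skipped and
counted, not errors: with realistic missingness such variants always
exist.

Per gene and variable, the variant p-values are combined by the harmonic
mean p-value, $\mathrm{HMP} = 1/\sum_i w_i/p_i$ with equal weights by
default. The HMP is robust to the strong linkage-driven dependence among a
gene's variants. The gene score is $-\log_{10}(\mathrm{HMP})$ of the *raw*
harmonic mean — the quantity the score formula is defined on — while the
asymptotically exact multiplicity-adjusted p-value is computed alongside
(`combined_p_adjusted`): for $L \ge 2$ the reciprocal of the raw HMP is
referred to the upper tail of a Landau distribution with location
$\log L + 0.8743670\ldots$ and scale $\pi/2$. Because the adjustment is a
monotone function of the raw HMP at fixed $L$, percentile ranks of
count-matched comparisons are unaffected by which of the two is ranked.
Input p-values of exactly zero (possible at tiny population counts where
$|r| = 1$) are clamped to the smallest positive double with a warning.

The Landau tail has no closed form; it is evaluated by direct numerical
integration of the classic density representation
$f(x) = \pi^{-1}\int_0^\infty e^{-t\log t - xt}\sin(\pi t)\,dt$, with the
far tail (beyond $100\times$ the evaluation point) closed by the $x^{-2}$
density asymptote. The unit tests pin this evaluation against reference
values computed with an independent stable-distribution implementation to
four significant digits, well inside any use the adjusted p-value is put
to here.

### Percentiles and the permutation null

Genes are percentile-ranked per variable (same midpoint rule), with a
top-decile flag at the 90th percentile. Because the combined p-value of a
gene depends strongly on its variant count $L$, significance for a focal
gene uses a permutation null *matched on variant count*: `permutationTest()`
draws, independently in each of $B$ replicates, $L$ variants without
replacement from the genome-wide pool of variant correlations and
recomputes the gene statistic. The statistic is the mean $|r|$ over the
gene's variants — direction-agnostic, since alternate-allele polarity is
arbitrary with respect to any environmental axis; a mean $-\log_{10} p$
variant would weight extreme variants more heavily and is an easy drop-in
replacement. The p-value uses the add-one rule
$(1 + \#\{T_{\mathrm{null}} \ge T_{\mathrm{obs}}\})/(1 + B)$, so it is
never zero, and significance is $p < 0.05$. Every stochastic operation
requires an explicit integer seed — there is deliberately no default — and
is bit-reproducible given (seed, $B$, pool order).

## Synthetic data: what it emulates, and what it does not

The generators plant the statistical structure each stage assumes, directly
and transparently; they are not population-genetic simulators.

* `simulateCodingPair()` evolves one copy of a random stop-free CDS by
  uniform single-nucleotide proposals, accepting synonymous proposals with
  probability $\min(1, 1/\omega)$ and nonsynonymous ones with
  $\min(1, \omega)$, until 5% of sites differ. This yields an expected
  estimated $\omega$ near the target across the whole range (including
  $\omega > 1$, where synonymous acceptance is down-weighted instead).
  Default divergence of 5% keeps the Jukes–Cantor correction mild.
* `simulatePopulationCds()` plants fixed differences and segregating sites
  (derived counts uniform on $1..n-1$) at distinct codons, each
  independently nonsynonymous with a configured proportion. Defaults —
  600 codons, 20 haplotypes, 160 polymorphisms and 160 divergences — were
  chosen to emulate a rapidly evolving gene of the size and variant count
  scale reported for the focal genes this analysis style targets (hundreds
  of variants per gene against a deeply diverged outgroup). Because events
  never share a codon, `classifySites()` recovers the planted table
  exactly, which separates classification correctness from statistical
  behaviour of $\alpha$ and the exact test.
* `simulateEnvDataset()` draws standard-normal ecological variables per
  population (optionally sharing a latent factor to mimic correlated
  bioclimatic summaries) and, for planted signal genes, sets each
  variant's true frequency by $\mathrm{logit}(AF_p) = a + \beta z_p$ with
  $a \sim N(-1, 0.5)$ and $z$ the first variable; null genes have
  $\beta = 0$. Observed counts are $AC \sim \mathrm{Binomial}(AN, AF_p)$
  with $AN = 40$ called alleles per population, the order of a
  20-individual diploid population sample. Defaults: 200 genes, 20
  variants per gene, 25 populations, effect $\beta = 1.5$ on the logit
  scale. Per-gene random substreams keep earlier genes byte-identical when
  genes are added.

What passing tests on these data show: the counting estimator, the MK
classification and test, the filters, the HMP machinery, and the
permutation test are algorithmically correct and statistically calibrated
under their own assumptions. What they do not show: robustness to
population structure and kinship (allele frequencies here are independent
across populations given the covariate; real populations share drift and
admixture), to linkage between variants within and between genes, to
ascertainment of variants, or to non-equilibrium demography. Conclusions
about real cohorts need those caveats; a latent-factor or
kinship-corrected association method is out of scope here.

## Test and calibration problem sizes

The shipped suite exercises, among others: exhaustive codon-pair oracle
agreement ($61 \times 61$); 1000 random 2×2 tables against an independent
Fisher implementation at $10^{-12}$; $\omega$ recovery at targets
$\{0.2, 1, 5\}$ with 2000-codon pairs over 50 seeds (mean within 15%, and
within $\pm 0.1$ at $\omega = 1$); 500 neutral MK replicates (mean $\alpha$
within $\pm 0.05$ of 0 — the ratio estimator carries a small-sample bias of
roughly $-4/n$ for $n$ events per row, visible at these sizes); permutation
size over 1000 null replicates at $B = 1000$ and power over 20 planted
replicates (the planted gene must clear the 90th percentile and
$p < 0.05$ in at least 80%). These sizes were picked so the whole suite
runs in a few minutes on one CPU while leaving the Monte-Carlo error well
below each tolerance.

## Known limitations

* Standard genetic code only; no alternative translation tables.
* No transition/transversion or codon-frequency weighting in the counting
  estimator; $\omega$ from very short windows is noisy and often undefined.
* The exact MK test is conservative on small tables (see above);
  polarised MK with two outgroups and asymptotic-MK extensions are not
  implemented.
* Ploidy is fixed at two in the variant stage.
* The association stage assumes populations are exchangeable given the
  ecological covariate; it applies no spatial or kinship correction.
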