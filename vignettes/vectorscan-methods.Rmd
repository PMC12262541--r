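---
title: "Methods: spatial population genomics of Anopheles vectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial population genomics of Anopheles vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vectorscan)
```

`vectorscan` implements the statistical core of a spatially explicit
population-genomics study of *Anopheles gambiae s.l.* sampled at village
scale: relatedness estimation that is robust to chromosomal inversions,
pedigree identity-by-descent (IBD) simulation, isolation-by-distance
inference, haplotype-homozygosity selection scans, diplotype clustering
and coverage-based copy-number inference. This vignette describes each
model, its assumptions, the tunable parameters, and the design choices
made where the methodology was genuinely open. Every number quoted here
is computed by the package's test suite or acceptance script; nothing is
asserted that the code does not reproduce.

## Kinship: the KING-robust estimator and inversion masking

For a pair of diploid individuals genotyped at biallelic SNPs, the
KING-robust kinship coefficient is

$$\hat\phi = \frac{N_{Aa,Aa} - 2\,N_{AA,aa}}{N_{Aa}^{(i)} + N_{Aa}^{(j)}},$$

where $N_{Aa,Aa}$ counts sites at which both individuals are
heterozygous, $N_{AA,aa}$ counts opposing homozygotes and the
denominator sums the individual heterozygote counts. Its expectation is
0.5 for identical genomes, 0.25 for full siblings, and roughly
$2^{-k-1}$ for $k$-th degree relatives; `classify_degree()` uses the
standard powers-of-two midpoints $2^{-k-3/2}$ as category boundaries.
The estimator consumes hard genotypes (`{0,1,2}` alternate-allele
counts); at the 30X coverage typical of modern WGS panels the difference
from a genotype-likelihood formulation is negligible, and the formula is
identical. Missing genotypes are removed pairwise-complete: every pair
uses exactly the sites called in both of its members. A pair with no
heterozygous site in either member has an undefined (not zero)
coefficient.

Ancient polymorphic inversions such as 2La violate the estimator's
exchangeability assumption: the two karyotype classes are more diverged
from each other than sibling species, so unrelated pairs of opposite
karyotype accumulate opposing homozygotes and receive strongly negative
$\hat\phi$, while same-karyotype pairs drift upward. Genome-wide KING
distributions then become multi-modal. `king_matrix()` therefore accepts
a `region_mask` (BED input, converted from 0-based half-open to the
package's 1-based inclusive convention) and the synthetic generator's
`plant_inversion()` reproduces the mechanism: two frequency pools with
divergence `d`, karyotype dosage drawn Binomial(2, `q`). The tests
verify that an unmasked planted inversion (q = 0.4, d = 0.95) produces
at least two kernel-density modes among unrelated pairs and that masking
the region restores a single mode. The divergence `d` of real inversions
is not quantified by the study; the values used by the tests are stated
in the tests themselves.

Between two individuals, windowed Hudson $F_{st}$ (each individual
treated as a population of two chromosomes) exposes IBD state along the
genome. The ratio-of-averages estimator gives exactly $-1$ where the
pair shares both homologs (IBD2). Where exactly one homolog is shared
(IBD1), enumerating the eight equally likely haplotype configurations
gives per-site expectations $E[\hat N] = -0.5\,pq$ and
$E[\hat D] = 1.5\,pq$, hence a genome mean of $-1/3$ — the package
asserts this derived value (the study's reading of its figure, "about
$-0.25$", is an eyeball approximation of the same level). Unshared
regions (IBD0) centre on 0.

## Pedigree IBD simulation

`propagate_ibd()` transmits founder-labelled chromosome segments through
an arbitrary pedigree. Each meiosis draws a crossover count per
chromosome from a Poisson distribution with mean equal to the map length
in Morgans, places the crossovers uniformly on the map-distance scale,
and converts to physical coordinates by inverse interpolation of the
genetic map. There is no crossover interference — deliberately, to match
the stated Poisson model — and no obligate chiasma by default (an
`obligate` flag exists). Maps are sex-averaged. Realized relatedness of
a pair is $r = L_1/2 + L_2$ over its IBD1/IBD2 genome fractions.

Two constant-rate maps ship with the package: a 3-chromosome
*An. gambiae* map (chromosome 2: 111.0 Mb, chromosome 3: 95.2 Mb, X:
24.4 Mb at $10^{-8}$ per bp, 2.31 Morgans in total; the chromosome-2
length is AgamP4 2R + 2L = 110,909,430 bp) and a 22-autosome human-like
comparison map with lengths proportional to a standard autosome table,
scaled to 35 Morgans (`inst/extdata/human_like_map.tsv`). Under the
binomial model for chromosome 2, crossovers per meiosis have mean 1.11,
a 33% chance of zero events, and central 95% interval 0–4 (evaluated in
log space so $L \sim 10^8$ is exact). Full siblings have expected
$r = 0.5$ under any map, but the standard deviation under the mosquito
map (about 0.14 over 1000 simulated pairs) is several times that under
the human-like map (about 0.04): with only 2.3 Morgans of genome, sib
pairs can resemble cousins or near-twins, which is the study's central
caveat for kinship-based dispersal inference in this species.

The default 4-generation pedigree prints 4 + 8 + 24 + 24 = 60
individuals and 28 within-branch full-sibling pairs per replicate (280
pairs over the default 10 replicates). Unprinted "connector" children
link each branch to its own parent couple so that printed full-sib pairs
occur only within branches.

## Isolation by distance

Between-site differentiation uses Hudson's estimator with per-site terms
$\hat N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}$
and $\hat D = p_1(1-p_2) + p_2(1-p_1)$, combined across sites as a ratio
of sums (ratio of averages) — never averaged per site, a distinction the
test suite demonstrates on heterogeneous windows. Sites with fewer than
10 samples are excluded before the site-pair matrix is built, mirroring
the study's filter. Rousset's regression fits linearised
$F_{st}/(1-F_{st})$ against $\ln$ great-circle distance (haversine, km;
the study does not state its metric) by OLS over unordered site pairs,
with the caveat — inherited from the method itself — that site pairs are
not independent. The same caveat applies to the pair-level doubleton
regression; the study's exact regression design there is unstated, so
the package provides pair-level OLS and this label. A doubleton is
shared only when each member of the pair carries exactly one copy; a
homozygous single carrier shares with nobody.

Mantel and partial Mantel tests are implemented directly so the
permutation contract is explicit: the statistic is the Pearson
correlation over off-diagonal entries, significance comes from
simultaneous row/column permutations of the first matrix, and p-values
follow the $(1 + \#\{r^* \ge r\})/(1 + n_{perm})$ convention (never
exactly zero). The partial test uses the matrix-regression residual
method: both matrices are regressed on the control matrix and the
residual matrices enter the permutation test. `vegan::mantel` serves as
an independent cross-check in the test suite, not as the implementation.
Ecological distance z-scores the site variables after greedily dropping
one of every pair with $|r| \ge 0.8$ (first-in-column-order wins) and
takes Euclidean distances.

## The synthetic spatial model

Real sampling in the study placed 70% of sites on a grid and 30% as
close pairs within a short radius of grid sites;
`simulate_sampling_design()` reproduces this with largest-remainder
apportionment across strata (counts within one site of exact
proportionality). The close-pair radius defaults to 2 km on a
degree-approximate plane — the study does not state it, so it is a
parameter.

Genotypes come from a spatially autocorrelated logit-normal frequency
field rather than a coalescent: per locus, site deviations from an
ancestral frequency are a Gaussian process with correlation
$e^{-d/\text{range}}$ (range 20 km by default) and standard deviation
$1/\sqrt{2m}$, where $m$ is a migration-like parameter. This is a
deliberate desk-scale choice: it gives direct control of the
isolation-by-distance signal the pipeline must detect, at the cost of
realism in linkage structure (loci are exchangeable and unlinked) and
site-frequency spectra. Consequently, passing tests demonstrate that the
estimators detect spatial frequency autocorrelation of the planted
magnitude — not that they would have the same power against
coalescent-realistic backgrounds. The strong-structure condition used in
testing is $m = 0.5$ (between-site $F_{st}$ up to a few percent, weak
IBD of the kind the study reports); the null condition is $m = \infty$.
With 13 sites, 10 samples per site and 5000 loci, the Rousset slope is
detected in effectively all replicates under strong structure, with a
type-I rate at the nominal level under panmixia.

## Selection scans

`garud_h()` computes H1 $=\sum p_i^2$, H12 $=(p_1+p_2)^2+\sum_{i\ge3}p_i^2$,
H123 and H2/H1 from exact-match haplotype frequencies in 1500-SNP
windows; `h1x()` computes the between-cohort sharing statistic
$\sum_h f_h g_h$. "Stepping windows" is interpreted as non-overlapping
(step = window size); a `step` argument allows overlap. The trailing
remainder window is dropped. Phased input must be complete; a cohort
with fewer than two haplotypes is skipped with a warning. Sweeps are
planted by copying a core haplotype into a chosen fraction of cohort
haplotypes; recovery tests require the top H12 window to coincide with a
private planted sweep and the top H1X window to exceed the 99th
percentile of background windows for a shared sweep.

## Diplotype clustering

Diplotypes (multi-locus unphased genotypes, one allele-count per
alternate allele per site so multiallelic sites are representable) are
compared with Manhattan distance and clustered with complete linkage.
Sites with any missing call are dropped by default (`max_missing = 0`)
because the city-block metric has no natural missing-data contract.
The cut height is a user parameter — the study does not state one — with
a default of 0.05 × the number of sites, and the dendrogram is always
returned so any cut can be re-derived. Agglomeration uses
`stats::hclust`, whose merge heights the tests verify against a
brute-force implementation on small inputs. Per-sample heterozygosity
(mean per-variant heterozygote status over the block) annotates the leaf
ordering: a cluster with pairwise distance 0 and heterozygosity 0 is the
signature of samples homozygous for one swept haplotype.

## Copy-number inference

Window counts (300 bp windows) are first normalized for nucleotide
composition: windows are binned by GC fraction in 2% bins, divided by
the bin median and scaled to a diploid baseline of 2; bins with fewer
than 10 windows (or zero median) fall back to the global median. The
13-state HMM assigns copy numbers 0–12 (up to 10 extra copies; higher
true copy numbers are capped at state 12) by Viterbi decoding with
Gaussian emissions centred on the state copy number. The shared emission
standard deviation is estimated as the scaled MAD of normalized coverage
around 2 — robust to the amplified minority of windows — and the stay
probability defaults to 0.99995 (about one spurious transition per 6 Mb
of windows), chosen because segments of interest span kilobases; neither
constant is stated by the study's source method. Gene-level calls take
the modal state over overlapping windows, with an `amplified` flag when
states above 2 cover at least half the gene's windows (ties amplify).
Normalization assumes most of a chromosome is diploid: amplification
recovery degrades by construction if a large fraction of windows is
amplified, because bin medians then drift off the diploid baseline.

## Numerical and testing choices

All randomised operations accept an explicit integer seed and are
deterministic given it. Problem sizes in the default test run are chosen
for a laptop-scale run: 10,000 loci for kinship expectations (500 sib
pairs), 2000 sib pairs for realized relatedness, 100 replicate seeds for
the isolation-by-distance operating characteristics, 3 seeds for the
sweep/inversion recovery properties, and 10 for CNV recovery. Null-effect
criteria (the un-planted ecological Mantel effect) are asserted as
majority behaviour across replicates rather than on a single seed,
since a single draw is non-significant only with probability
$1-\alpha$. Known limitations: no coalescent linkage structure in the
spatial generator, no crossover interference, hard-genotype (not
likelihood-based) kinship, and no breakpoint-level CNV detection
(discordant/split reads are out of scope).
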