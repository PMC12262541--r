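# vectorscan

Spatially explicit population genomics for densely sampled *Anopheles
gambiae s.l.* collections — the malaria vectors in which village-scale
("micro-spatial") sampling has recently made it possible to detect kin
pairs, weak isolation by distance and insecticide-resistance sweeps
within a few tens of kilometres. The package is aimed at vector-genomics
analysts who have called genotypes (VCF), sample coordinates and
windowed coverage, and want the downstream statistics with explicit,
tested contracts.

## What it implements

* **Kinship robust to inversions** — the KING-robust estimator
  φ̂ = (N_Aa,Aa − 2·N_AA,aa)/(N_Aa⁽ⁱ⁾ + N_Aa⁽ʲ⁾) over all sample pairs,
  with BED region masking. Ancient polymorphic inversions (2La, 2Rb)
  hold haplotype classes more diverged than sibling species; unmasked,
  they make the within-species kinship distribution tri-modal, and
  `king_matrix()` + `region_mask()` reproduce and remove that artefact.
  Windowed two-individual Hudson F_ST (`pairwise_fst_scan()`) exposes
  IBD state along the genome: ≈ 0 (no sharing), −1/3 (one shared
  homolog), exactly −1 (both).
* **Pedigree IBD simulation** — Poisson crossovers on a genetic map,
  founder-labelled segment propagation, realized relatedness
  r = L₁/2 + L₂. With only three chromosomes (≈ 2.3 Morgans),
  *An. gambiae* sib pairs spread far around the 0.5 expectation compared
  with a 35-Morgan human-like genome. Closed-form crossover statistics:
  Binomial(110,909,430, 10⁻⁸) for chromosome 2 gives mean 1.11, 33%
  zero-crossover meioses, 95% interval 0–4.
* **Isolation by distance** — Hudson F_ST between sites (ratio of
  averages, ≥10-sample site filter), Rousset regression of
  F_ST/(1−F_ST) on ln distance, doubleton (f₂) sharing, ecological
  distance, Mantel and partial Mantel tests, PCA and neighbour-joining
  trees.
* **Selection scans** — Garud H1/H12/H123/H2H1 in 1500-SNP windows per
  cohort and the between-cohort H1X sharing statistic.
* **Diplotype clustering** — Manhattan distance over multi-locus
  allele-count vectors, complete-linkage dendrograms, per-sample
  heterozygosity and amino-acid/CNV annotation tracks.
* **CNV calling** — GC-bin median normalization of 300 bp window
  coverage and a 13-state (copy 0–12) Gaussian-emission Viterbi HMM with
  gene-level modal calls and amplification frequencies.
* **Synthetic data** — grid + close-pair sampling designs (70/30),
  spatially autocorrelated allele-frequency fields, planted inversions,
  nuclear families, planted sweeps and coverage amplifications, all with
  stored truth so every stage has recovery tests.

## Worked example

```r
library(vectorscan)

# closed-form crossover statistics for An. gambiae chromosome 2
st <- recombination_count_stats(110909430, 1e-8)
cat("mean:", round(st$mean, 2), " P0:", round(st$p_zero, 3), " ci:", st$ci95, "\n")
#> mean: 1.11  P0: 0.33  ci: 0 4

# one simulated family, KING between the siblings
fam <- simulate_family(runif(10000, 0.05, 0.95), n_offspring = 2, seed = 1)
k <- king_robust(fam$G[, "off1"], fam$G[, "off2"])
cat("sib phi:", round(k$phi, 4), " degree:", classify_degree(k$phi), "\n")
#> sib phi: 0.2532  degree: 1st-degree

# realized relatedness under the 3-chromosome mosquito map
r <- simulate_sib_relatedness(500, gambiae_map(), seed = 1)
cat("mean r:", round(mean(r), 3), " sd:", round(sd(r), 3), "\n")
#> mean r: 0.495  sd: 0.132
```

The sib kinship sits at the full-sibling expectation of 0.25, and the
realized-relatedness spread (sd ≈ 0.13) is the low-chromosome-number
effect: some mosquito sib pairs share cousin-like fractions of their
genome, others near-twin fractions.

`run_demo(seed, out_dir)` generates a full synthetic study (13 sites,
inversion, sweeps, CNVs) and writes every stage's results as CSV:

```r
res <- run_demo(seed = 1, out_dir = "demo_out")
res$summary
#>                metric        value
#> 1 king_modes_unmasked 3.000000e+00
#> 2   king_modes_masked 1.000000e+00
#> 3           ibd_slope 8.567181e-03
#> 4         ibd_p_value 2.787702e-29
#> 5             max_h1x 3.600000e-01
#> 6       cnv_gene_copy 4.000000e+00
```

The unmasked kinship distribution is tri-modal (the inversion artefact);
masking restores one mode. The isolation-by-distance slope is positive
and significant, the shared sweep produces an H1X peak of 0.36 (= 0.6²
at the planted sweep frequency), and the planted 4-copy amplification is
called at copy 4.

## Documentation

`vignettes/vectorscan-methods.Rmd` describes the models, their
assumptions, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, and known
limitations.
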