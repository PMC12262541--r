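test_that("sampling design splits grid and close-pair sites 70/30", {
  d30 <- simulate_sampling_design(30, seed = 1)
  expect_equal(sum(d30$type == "grid"), 21L)
  expect_equal(sum(d30$type == "close_pair"), 9L)
  d10 <- simulate_sampling_design(10, seed = 1)
  expect_equal(as.vector(table(d10$type)[c("grid", "close_pair")]), c(7L, 3L))
  expect_error(simulate_sampling_design(30, close_pair_radius_km = 0),
               "positive")
  # determinism
  expect_equal(simulate_sampling_design(12, seed = 9),
               simulate_sampling_design(12, seed = 9))
})

test_that("close pairs lie within the stated radius of a grid site", {
  d <- simulate_sampling_design(40, close_pair_radius_km = 2, seed = 5)
  dm <- site_distance_matrix(d)
  cp <- which(d$type == "close_pair")
  gr <- which(d$type == "grid")
  nearest <- apply(dm[cp, gr, drop = FALSE], 1, min)
  expect_true(all(nearest <= 2.01))
})

test_that("strata apportionment follows largest remainder within one site", {
  d <- simulate_sampling_design(30, strata_weights = c(0.8, 0.2), seed = 2)
  expect_equal(as.vector(table(d$stratum)), c(24L, 6L))
  for (w in list(c(1, 1, 1), c(5, 3, 2), c(0.55, 0.25, 0.2))) {
    n <- 17
    counts <- apportion(n, w)
    expect_equal(sum(counts), n)
    expect_true(all(abs(counts - n * w / sum(w)) < 1))
  }
  expect_error(apportion(10, c(1, -1)), "positive")
})

test_that("spatial genotypes are deterministic and panmictic at m = Inf", {
  design <- simulate_sampling_design(13, seed = 3)
  a <- simulate_spatial_genotypes(design, n_loci = 400, n_per_site = 10,
                                  seed = 3)
  b <- simulate_spatial_genotypes(design, n_loci = 400, n_per_site = 10,
                                  seed = 3)
  expect_equal(a$genotypes$G, b$genotypes$G)
  expect_true(all(a$site_freqs >= 0 & a$site_freqs <= 1))
  expect_equal(nrow(a$metadata), 130L)
  # panmixia: Rousset slope indistinguishable from zero
  pan <- simulate_spatial_genotypes(design, n_loci = 4000, n_per_site = 10,
                                    m = Inf, seed = 7)
  res <- site_fst_matrix(pan$genotypes, pan$metadata, min_per_site = 10)
  coords <- unique(pan$metadata[, c("site_id", "lat", "lon")])
  dmat <- site_distance_matrix(coords[match(res$sites, coords$site_id), ])
  fit <- rousset_regression(res$linear_fst, dmat)
  se <- coef(summary(fit$model))[2, 2]
  expect_lt(abs(fit$slope), 2 * se)
})

test_that("planted inversions leave d = 0 data unchanged in distribution", {
  design <- simulate_sampling_design(4, seed = 8)
  sim <- simulate_spatial_genotypes(design, n_loci = 3000, n_per_site = 10,
                                    m = Inf, seed = 8)
  reg <- list("3R", 1, 2.5e7)
  g0 <- plant_inversion(sim$genotypes, reg, q = 0.4, d = 0, seed = 1)
  vi <- sim$genotypes$chrom == "3R" & sim$genotypes$pos <= 2.5e7
  p_in <- rowMeans(sim$genotypes$G[vi, ]) / 2
  p_out <- rowMeans(g0$G[vi, ]) / 2
  expect_lt(abs(mean(p_in) - mean(p_out)), 0.02)
  expect_lt(abs(sd(p_in) - sd(p_out)), 0.02)
  expect_error(plant_inversion(sim$genotypes, list("X", 1, 100)),
               "no variants")
})

test_that("inversion pools are far more diverged than the background", {
  design <- simulate_sampling_design(4, seed = 10)
  sim <- simulate_spatial_genotypes(design, n_loci = 4000, n_per_site = 15,
                                    m = Inf, seed = 10)
  reg <- list("3R", 1, 2.5e7)
  gmi <- plant_inversion(sim$genotypes, reg, q = 0.5, d = 0.9, seed = 10)
  kar <- attr(gmi, "karyotype")
  vi <- which(gmi$chrom == "3R" & gmi$pos <= 2.5e7)
  vo <- which(gmi$pos > 2.5e7)
  inv_hom <- gmi$samples[kar == 2]; std_hom <- gmi$samples[kar == 0]
  gm_in <- subset_genotypes(gmi, vi)
  gm_out <- subset_genotypes(gmi, vo)
  fst_in <- hudson_fst(site_allele_counts(gm_in, inv_hom),
                       site_allele_counts(gm_in, std_hom))$fst
  fst_out <- hudson_fst(site_allele_counts(gm_out, inv_hom),
                        site_allele_counts(gm_out, std_hom))$fst
  expect_gt(fst_in, 10 * max(fst_out, 0.001))
})

test_that("families are Mendelian-consistent", {
  set.seed(2)
  fam <- simulate_family(runif(2000, 0.05, 0.95), n_offspring = 3)
  f <- fam$G[, "father"]; m <- fam$G[, "mother"]
  for (k in 1:3) {
    o <- fam$G[, paste0("off", k)]
    # opposing homozygous parents always give heterozygous offspring
    expect_true(all(o[f == 0 & m == 2] == 1))
    expect_true(all(o[f == 2 & m == 0] == 1))
    # offspring alleles are inherited: count bounded by parental dosage
    expect_true(all(o <= ceiling(f / 2) + ceiling(m / 2)))
    expect_true(all(o >= floor(f / 2) + floor(m / 2)))
  }
})

test_that("map-linked families correlate sibling sharing along the chromosome", {
  map <- constant_rate_map(c(c1 = 1e8), 1e-8)
  fam <- simulate_family(runif(4000, 0.2, 0.8), n_offspring = 2, map = map,
                         seed = 6)
  expect_equal(unique(fam$chrom), "c1")
  # IBD status changes only at crossovers, so neighbouring windows of the
  # sib-pair Fst track are positively autocorrelated
  trk <- pairwise_fst_scan(fam, "off1", "off2", window_size_bp = 5e6)
  fst <- trk$fst[!is.na(trk$fst)]
  expect_gt(cor(fst[-1], fst[-length(fst)]), 0)
})

test_that("sweep planting records carriers and truth", {
  hm <- simulate_haplotypes(c(A = 10, B = 10), n_loci = 2000, seed = 4)
  swept <- plant_sweep(hm, c(501L, 1500L), 0.6, cohorts = c("A", "B"),
                       shared = TRUE, seed = 4)
  tr <- attr(swept, "sweep")
  expect_equal(tr$variants, 501:1500)
  expect_equal(lengths(tr$carriers), c(A = 12L, B = 12L))
  core <- swept$H[tr$variants, tr$carriers$A[1]]
  for (col in c(tr$carriers$A, tr$carriers$B))
    expect_equal(swept$H[tr$variants, col], core)
})
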