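test_that("hudson_fst matches closed-form single-site values", {
  # fixed difference
  expect_equal(hudson_fst(cbind(0, 10), cbind(8, 0))$fst, 1)
  # p1 = p2 = 0.5 with 4 chromosomes each
  expect_equal(hudson_fst(cbind(2, 2), cbind(2, 2))$fst, -1 / 3)
  # identical diploids with a heterozygous site
  expect_equal(hudson_fst(cbind(1, 1), cbind(1, 1))$fst, -1)
  # all-monomorphic input is undefined
  expect_true(is.na(hudson_fst(cbind(4, 0), cbind(6, 0))$fst))
})

test_that("ratio of averages differs from average of ratios on heterogeneous sites", {
  ac1 <- rbind(c(0, 10), c(2, 2))
  ac2 <- rbind(c(8, 0), c(2, 2))
  roa <- hudson_fst(ac1, ac2)$fst
  per_site <- c(hudson_fst(ac1[1, , drop = FALSE], ac2[1, , drop = FALSE])$fst,
                hudson_fst(ac1[2, , drop = FALSE], ac2[2, , drop = FALSE])$fst)
  expect_false(isTRUE(all.equal(roa, mean(per_site))))
})

test_that("site Fst matrix applies the minimum-sample filter and linearises", {
  design <- simulate_sampling_design(15, seed = 4)
  sim <- simulate_spatial_genotypes(design, n_loci = 800, n_per_site = 12,
                                    m = 3, seed = 4)
  # push 2 sites below the threshold of 10
  within_site_rank <- ave(seq_len(nrow(sim$metadata)), sim$metadata$site_id,
                          FUN = seq_along)
  drop <- sim$metadata$site_id %in% c("site01", "site02") & within_site_rank > 5
  md <- sim$metadata[!drop, ]
  gm <- subset_genotypes(sim$genotypes, samples = md$sample_id)
  res <- site_fst_matrix(gm, md, min_per_site = 10)
  expect_length(res$sites, 13L)
  expect_false(any(c("site01", "site02") %in% res$sites))
  expect_equal(res$linear_fst, res$fst / (1 - res$fst))
  expect_error(site_fst_matrix(gm, md, min_per_site = 1000), "fewer than 2")
})

test_that("duplicate sites have near-zero Fst; linearisation is algebraic", {
  set.seed(9)
  p <- runif(2000, 0.1, 0.9)
  G <- matrix(rbinom(2000 * 24, 2, p), 2000, 24)
  gm <- genotype_matrix(G, rep("2L", 2000), 1:2000)
  md <- data.frame(sample_id = gm$samples,
                   site_id = rep(c("x", "y"), each = 12))
  res <- site_fst_matrix(gm, md, min_per_site = 10)
  expect_lt(abs(res$fst["x", "y"]), 0.01)
  expect_equal(0.2 / (1 - 0.2), 0.25)
})

test_that("Rousset regression recovers exact synthetic slopes", {
  k <- 6
  d <- matrix(0, k, k)
  d[upper.tri(d)] <- seq(2, 2 + sum(upper.tri(d)) - 1)
  d <- d + t(d)
  y <- 0.01 * log(d); diag(y) <- 0
  fit <- suppressWarnings(rousset_regression(y, d))   # exact fit warns
  expect_equal(fit$slope, 0.01, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-6)
  # constant Fst: slope 0
  y0 <- matrix(0.05, k, k); diag(y0) <- 0
  expect_equal(suppressWarnings(rousset_regression(y0, d))$slope, 0,
               tolerance = 1e-12)
  # zero-distance pairs dropped with a warning
  d2 <- d; d2[1, 2] <- d2[2, 1] <- 0
  w <- testthat::capture_warnings(rousset_regression(y, d2))
  expect_true(any(grepl("zero-distance", w)))
})

test_that("doubleton sharing follows the one-copy-each convention", {
  G <- rbind(c(1L, 1L, 0L),   # shared by samples 1,2
             c(2L, 0L, 0L),   # homozygous single carrier: shared by nobody
             c(1L, 0L, 1L),   # shared by samples 1,3
             c(1L, 1L, 1L))   # tripleton: not a doubleton
  gm <- genotype_matrix(G, rep("2L", 4), 1:4)
  sh <- doubleton_sharing(gm)
  expect_equal(sh[1, 2], 1L)
  expect_equal(sh[1, 3], 1L)
  expect_equal(sh[2, 3], 0L)
  expect_equal(sum(sh) / 2, 2L)
  expect_equal(sh, t(sh))
})

test_that("full siblings share more doubletons than unrelated pairs", {
  set.seed(14)
  sib_counts <- c(); unrel_counts <- c()
  for (i in 1:20) {
    # rare variants so that doubletons are plentiful
    fam <- simulate_family(runif(3000, 0.001, 0.05), n_offspring = 2)
    strangers <- matrix(rbinom(3000 * 4, 2, runif(3000, 0.001, 0.05)), 3000, 4)
    G <- cbind(fam$G[, c("off1", "off2")], strangers)
    gm <- genotype_matrix(G, fam$chrom, fam$pos,
                          samples = c("off1", "off2", paste0("u", 1:4)))
    sh <- doubleton_sharing(gm)
    sib_counts <- c(sib_counts, sh["off1", "off2"])
    unrel_counts <- c(unrel_counts, sh[cbind(3:6, c(4:6, 3))])
  }
  expect_lt(wilcox.test(sib_counts, unrel_counts,
                        alternative = "greater")$p.value, 1e-4)
})

test_that("ecological distance decorrelates, z-scores and is Euclidean", {
  env <- data.frame(site_id = paste0("s", 1:6),
                    a = c(1, 2, 3, 4, 5, 6),
                    b = c(2, 4, 6, 8, 10, 12),      # duplicate of a (r = 1)
                    c = c(5, 1, 4, 2, 6, 3))
  res <- ecological_distance(env)
  expect_equal(res$kept, c("a", "c"))
  # oracle: manual z-score + euclidean over kept variables
  Z <- scale(as.matrix(env[, c("a", "c")]))
  expect_equal(unname(res$dist), unname(as.matrix(dist(Z))))
  # identical sites at distance zero
  env2 <- data.frame(site_id = c("x", "y", "z"), a = c(1, 1, 3), b = c(2, 2, 9))
  expect_equal(ecological_distance(env2)$dist["x", "y"], 0)
  # zero-variance variables dropped with warning
  env3 <- data.frame(site_id = paste0("s", 1:4), a = 1:4, flat = rep(2, 4))
  expect_warning(ecological_distance(env3), "zero-variance")
})

test_that("Mantel statistics and p-value conventions behave", {
  set.seed(30)
  X <- matrix(runif(100), 10); A <- as.matrix(dist(X))
  m <- mantel(A, A, n_perm = 99, seed = 1)
  expect_equal(m$statistic, 1)
  expect_equal(m$p_value, 1 / 100)
  # p-values never zero, honour (1+count)/(1+n_perm)
  B <- as.matrix(dist(matrix(runif(100), 10)))
  m2 <- mantel(A, B, n_perm = 99, seed = 1)
  expect_gte(m2$p_value, 1 / 100)
  expect_error(mantel(A[1:3, 1:3], B[1:3, 1:3]), "at least 4")
  # controlling for B removes B
  pm <- partial_mantel(A, B, B, n_perm = 99, seed = 2)
  expect_lt(abs(pm$statistic), 0.05)
})

test_that("Mantel agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(41)
  A <- as.matrix(dist(matrix(runif(80), 8)))
  B <- as.matrix(dist(matrix(runif(80), 8)))
  ours <- mantel(A, B, n_perm = 999, seed = 5)
  ref <- vegan::mantel(as.dist(A), as.dist(B), permutations = 999)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_lt(abs(ours$p_value - ref$signif), 0.05)
})

test_that("Mantel type-I error is calibrated", {
  set.seed(50)
  rej <- replicate(200, {
    A <- as.matrix(dist(matrix(runif(30), 10)))
    B <- as.matrix(dist(matrix(runif(30), 10)))
    mantel(A, B, n_perm = 99)$p_value <= 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.04)
})

test_that("PCA separates diverged populations and is deterministic", {
  set.seed(17)
  p1 <- runif(1500, 0.05, 0.95)
  p2 <- plogis(qlogis(p1) + rnorm(1500, 0, 1.5))
  G <- cbind(matrix(rbinom(1500 * 10, 2, p1), 1500, 10),
             matrix(rbinom(1500 * 10, 2, p2), 1500, 10))
  G <- cbind(G, G[, 1])          # duplicate of sample 1
  gm <- genotype_matrix(G, rep("2L", 1500), 1:1500)
  pc <- pca_genotypes(gm)
  s <- pc$scores[, 1]
  expect_true(max(s[1:10]) < min(s[11:20]) || min(s[1:10]) > max(s[11:20]))
  expect_equal(pc$scores[21, ], pc$scores[1, ], ignore_attr = TRUE)
  expect_true(all(diff(pc$explained) <= 1e-12))
})

test_that("neighbour joining recovers closed-form and additive trees", {
  # 3 taxa: v_A = (d_AB + d_AC - d_BC)/2
  d3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- nj_tree(d3)
  bl <- setNames(tr3$edge.length[tr3$edge[, 2] <= 3],
                 tr3$tip.label[tr3$edge[tr3$edge[, 2] <= 3, 2]])
  expect_equal(bl[["A"]], (3 + 5 - 6) / 2)
  expect_equal(bl[["B"]], (3 + 6 - 5) / 2)
  expect_equal(bl[["C"]], (5 + 6 - 3) / 2)
  # 4-taxon additive matrix from a known tree is recovered exactly
  true <- ape::read.tree(text = "((A:1,B:2):1.5,(C:3,D:4):0);")
  dm <- ape::cophenetic.phylo(true)
  rec <- nj_tree(dm)
  expect_equal(ape::cophenetic.phylo(rec)[rownames(dm), colnames(dm)], dm)
  expect_equal(ape::dist.topo(ape::unroot(true), rec), structure(0, Size = 2),
               ignore_attr = TRUE)
  # 2 taxa split the distance evenly
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- nj_tree(d2)
  expect_equal(sort(tr2$edge.length), c(0.15, 0.15))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("stepping-stone simulations show a monotone distance-Fst trend", {
  design <- simulate_sampling_design(13, seed = 6)
  sim <- simulate_spatial_genotypes(design, n_loci = 5000, n_per_site = 10,
                                    m = 0.5, seed = 6)
  res <- site_fst_matrix(sim$genotypes, sim$metadata, min_per_site = 10)
  coords <- unique(sim$metadata[, c("site_id", "lat", "lon")])
  d <- site_distance_matrix(coords[match(res$sites, coords$site_id), ])
  ut <- upper.tri(d)
  expect_gt(cor(d[ut], res$fst[ut], method = "spearman"), 0)
})
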