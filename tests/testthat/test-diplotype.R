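test_that("diplotype extraction keeps allele counts and drops missing sites", {
  G <- rbind(c(0L, 1L, 2L), c(2L, 1L, 0L), c(1L, NA, 0L))
  gm <- genotype_matrix(G, rep("2L", 3), c(100L, 200L, 300L))
  blk <- extract_diplotypes(gm, "2L:1-1000")
  expect_equal(ncol(blk$counts), 2L)            # site with missing call dropped
  expect_equal(unname(blk$counts[1, ]), c(0L, 2L))
  expect_error(extract_diplotypes(gm, "2L:5000-6000"), "no variants")
  blk2 <- extract_diplotypes(gm, "2L:1-1000", max_missing = 1)
  expect_equal(ncol(blk2$counts), 3L)
})

test_that("multiallelic sites contribute one count per alternate allele", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(f, vcf_record("2L", 100, "A", "C,T", c("1/2", "0/1")))
  gm <- read_vcf_genotypes(f, biallelic_only = FALSE)
  blk <- extract_diplotypes(gm, "2L:1-1000")
  expect_equal(unname(blk$counts["A", ]), c(1L, 1L))
  expect_equal(unname(blk$counts["B", ]), c(1L, 0L))
})

test_that("Manhattan distance matches hand sums and is a metric", {
  blk <- structure(list(counts = rbind(a = c(0L, 2L, 1L), b = c(2L, 0L, 1L),
                                       c = c(0L, 2L, 1L)),
                        sites = data.frame(chrom = "2L", pos = 1:3,
                                           ref = "A", alt = "T")),
                   class = "diplotype_block")
  d <- diplotype_distance(blk)
  expect_equal(d["a", "b"], 4)
  expect_equal(d["a", "c"], 0)
  set.seed(33)
  counts <- matrix(sample(0:2, 10 * 8, replace = TRUE), 10)
  d2 <- as.matrix(dist(counts, method = "manhattan"))
  for (i in 1:10) for (j in 1:10) for (k in 1:10)
    expect_lte(d2[i, j], d2[i, k] + d2[k, j])
})

test_that("distance is invariant to site order and consistent ref/alt swap", {
  set.seed(8)
  counts <- matrix(sample(0:2, 6 * 10, replace = TRUE), 6)
  blk <- structure(list(counts = counts), class = "diplotype_block")
  d <- diplotype_distance(blk)
  perm <- sample(ncol(counts))
  blk_p <- structure(list(counts = counts[, perm]), class = "diplotype_block")
  expect_equal(diplotype_distance(blk_p), d)
  swap <- counts; swap[, 3] <- 2L - swap[, 3]
  blk_s <- structure(list(counts = swap), class = "diplotype_block")
  expect_equal(diplotype_distance(blk_s), d)
})

test_that("complete linkage recovers planted groups and matches brute force", {
  set.seed(19)
  base1 <- sample(0:2, 30, replace = TRUE)
  base2 <- (base1 + sample(1:2, 30, replace = TRUE)) %% 3L  # >=20 differences
  grp1 <- t(vapply(1:5, function(i) {
    x <- base1; k <- sample(30, 1); x[k] <- (x[k] + 1L) %% 3L; x
  }, integer(30)))
  grp2 <- t(vapply(1:5, function(i) {
    x <- base2; k <- sample(30, 1); x[k] <- (x[k] + 1L) %% 3L; x
  }, integer(30)))
  counts <- rbind(grp1, grp2)
  rownames(counts) <- paste0("s", 1:10)
  blk <- structure(list(counts = counts), class = "diplotype_block")
  d <- diplotype_distance(blk)
  cl <- cluster_complete_linkage(d, cut_height = 10)
  expect_equal(length(unique(cl$labels)), 2L)
  expect_equal(length(unique(cl$labels[1:5])), 1L)
  expect_equal(length(unique(cl$labels[6:10])), 1L)
  # merge heights equal brute-force agglomeration (<=8 samples)
  d8 <- d[1:8, 1:8]
  hc <- cluster_complete_linkage(d8, cut_height = 1)$hclust
  expect_equal(sort(hc$height), sort(complete_linkage_bruteforce(d8)))
  # final merge height is the maximum pairwise distance
  expect_equal(max(cl$hclust$height), max(d))
})

test_that("degenerate clustering inputs behave", {
  one <- matrix(0, 1, 1, dimnames = list("only", "only"))
  cl <- cluster_complete_linkage(one, cut_height = 5)
  expect_equal(unname(cl$labels), 1L)
  expect_error(cluster_complete_linkage(matrix(0, 2, 2), cut_height = -1),
               "non-negative")
})

test_that("sample heterozygosity averages per-variant het status", {
  counts <- rbind(all_hom = c(0L, 2L, 0L, 2L),
                  all_het = c(1L, 1L, 1L, 1L),
                  half = c(1L, 0L, 1L, 2L))
  blk <- structure(list(counts = counts,
                        sites = data.frame(chrom = "2L", pos = 1:4,
                                           ref = "A", alt = "T")),
                   class = "diplotype_block")
  h <- sample_heterozygosity(blk)
  expect_equal(unname(h), c(0, 1, 0.5))
})

test_that("annotation encodes genotypes in stable leaf order; swept clusters have zero heterozygosity", {
  set.seed(44)
  swept <- matrix(rep(sample(c(0L, 2L), 12, replace = TRUE), 4), 4,
                  byrow = TRUE)
  other <- matrix(sample(0:2, 4 * 12, replace = TRUE), 4)
  counts <- rbind(swept, other)
  rownames(counts) <- paste0("s", 1:8)
  blk <- structure(list(counts = counts,
                        sites = data.frame(chrom = "2L", pos = 1:12,
                                           ref = "A", alt = "T")),
                   class = "diplotype_block")
  cl <- cluster_complete_linkage(diplotype_distance(blk), cut_height = 2)
  aa <- data.frame(sample_id = c("s1", "s5", "ghost"),
                   variant = "L995F", genotype = c(2L, 1L, 2L))
  expect_warning(ann <- annotate_clusters(cl, blk, aa_table = aa), "ghost")
  a <- ann$annotation
  expect_equal(a$aa_L995F[a$sample_id == "s1"], "homozygous")
  expect_equal(a$aa_L995F[a$sample_id == "s5"], "heterozygous")
  expect_equal(a$aa_L995F[a$sample_id == "s2"], "absent")
  # swept cluster: all-identical homozygous diplotypes, heterozygosity 0
  expect_equal(a$heterozygosity[a$sample_id %in% paste0("s", 1:4)],
               rep(0, 4))
  # leaf order is deterministic across reruns
  cl2 <- cluster_complete_linkage(diplotype_distance(blk), cut_height = 2)
  expect_equal(cl2$leaf_order, cl$leaf_order)
})
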