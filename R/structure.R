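#' Per-site Hudson Fst terms
#'
#' For allele frequencies \eqn{p_1, p_2} estimated from \eqn{n_1, n_2}
#' chromosomes, the per-site numerator and denominator of the Hudson
#' estimator are
#' \deqn{\hat N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1},
#'       \quad \hat D = p_1(1-p_2) + p_2(1-p_1).}
#' Multi-site Fst is always combined as a ratio of sums (ratio of
#' averages), never an average of per-site ratios.
#'
#' @param p1,p2 per-site alternate-allele frequencies in each population.
#' @param n1,n2 chromosome counts per site (scalar or vector), >= 2.
#' @return List of vectors `num`, `den`.
#' @keywords internal
hudson_site_terms <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

#' Hudson Fst between two populations from allele counts
#'
#' @param ac1,ac2 two-column matrices (ref count, alt count) per variant,
#'   or lists with `p` (frequencies) and `n` (chromosome counts).
#' @return List with `fst` (ratio of sums; NA when the denominator sum is
#'   0, e.g. all-monomorphic input), `num_sum`, `den_sum`.
#' @export
hudson_fst <- function(ac1, ac2) {
  as_pn <- function(ac) {
    if (is.list(ac) && !is.null(ac$p)) return(list(p = ac$p, n = ac$n))
    ac <- as.matrix(ac)
    n <- rowSums(ac)
    list(p = ifelse(n > 0, ac[, 2] / n, NA_real_), n = n)
  }
  a <- as_pn(ac1); b <- as_pn(ac2)
  use <- !is.na(a$p) & !is.na(b$p) & a$n >= 2 & b$n >= 2
  t_ <- hudson_site_terms(a$p[use], b$p[use], a$n[use], b$n[use])
  num_sum <- sum(t_$num); den_sum <- sum(t_$den)
  list(fst = if (den_sum > 0) num_sum / den_sum else NA_real_,
       num_sum = num_sum, den_sum = den_sum)
}

#' Per-variant allele counts for a set of samples
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample ids forming the population.
#' @return Two-column matrix (`ref`, `alt`) of allele counts per variant;
#'   missing genotypes reduce the chromosome count.
#' @export
site_allele_counts <- function(gm, samples) {
  g <- gm$G[, samples, drop = FALSE]
  alt <- rowSums(g, na.rm = TRUE)
  n <- 2 * rowSums(!is.na(g))
  cbind(ref = n - alt, alt = alt)
}

#' Pairwise Hudson Fst between sampling sites
#'
#' All samples of a site form one population (2n chromosomes). Sites with
#' fewer than `min_per_site` samples are dropped before computing pairwise
#' Fst; linearised values Fst/(1-Fst) are returned alongside.
#'
#' @param gm a [genotype_matrix()].
#' @param metadata data frame with `sample_id` and `site_id` covering all
#'   samples.
#' @param min_per_site minimum samples per retained site (default 10, the
#'   study's site filter).
#' @return List with `fst` and `linear_fst` matrices (site x site),
#'   `sites` (retained ids) and `site_n` (sample counts).
#' @export
site_fst_matrix <- function(gm, metadata, min_per_site = 10) {
  md <- metadata[match(gm$samples, metadata$sample_id), ]
  if (any(is.na(md$site_id))) stop("metadata must cover every sample")
  tab <- table(md$site_id)
  sites <- names(tab)[tab >= min_per_site]
  if (length(sites) < 2L) stop("fewer than 2 sites pass the size filter")
  ac <- lapply(sites, function(s)
    site_allele_counts(gm, gm$samples[md$site_id == s]))
  names(ac) <- sites
  k <- length(sites)
  fst <- matrix(0, k, k, dimnames = list(sites, sites))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    f <- hudson_fst(ac[[i]], ac[[j]])$fst
    fst[i, j] <- fst[j, i] <- f
  }
  list(fst = fst, linear_fst = fst / (1 - fst), sites = sites,
       site_n = as.integer(tab[sites]))
}

#' Great-circle distance matrix between sites (km)
#'
#' @param coords data frame with `site_id`, `lat`, `lon` (decimal degrees).
#' @return Symmetric matrix of haversine distances in km.
#' @export
site_distance_matrix <- function(coords) {
  k <- nrow(coords)
  d <- matrix(0, k, k, dimnames = list(coords$site_id, coords$site_id))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d[i, j] <- d[j, i] <- geosphere::distHaversine(
      c(coords$lon[i], coords$lat[i]), c(coords$lon[j], coords$lat[j])) / 1000
  }
  d
}

#' Rousset isolation-by-distance regression
#'
#' Ordinary least squares of linearised Fst, Fst/(1-Fst), on the natural
#' logarithm of geographic distance over unordered site pairs. A positive,
#' significant slope indicates isolation by distance in a two-dimensional
#' habitat.
#'
#' @param linear_fst_matrix symmetric matrix of Fst/(1-Fst).
#' @param dist_km symmetric matrix of great-circle distances in km.
#' @return List with `slope`, `intercept`, `p_value` (two-sided slope
#'   test), `n_pairs` and the fitted `model`.
#' @export
rousset_regression <- function(linear_fst_matrix, dist_km) {
  stopifnot(all(dim(linear_fst_matrix) == dim(dist_km)))
  ut <- upper.tri(dist_km)
  y <- linear_fst_matrix[ut]; d <- dist_km[ut]
  drop <- d <= 0 | !is.finite(y)
  if (any(d <= 0)) warning("dropping ", sum(d <= 0), " zero-distance pair(s)")
  y <- y[!drop]; d <- d[!drop]
  if (length(y) < 3L) stop("need at least 3 usable site pairs")
  fit <- stats::lm(y ~ log(d))
  co <- summary(fit)$coefficients
  list(slope = unname(co[2, 1]), intercept = unname(co[1, 1]),
       p_value = unname(co[2, 4]), n_pairs = length(y), model = fit)
}

#' Shared doubleton (f2) counts per sample pair
#'
#' A doubleton is a variant whose alternate allele is observed exactly
#' twice in the whole dataset. It is shared by a pair when each member
#' carries exactly one copy; a single homozygous carrier shares it with
#' nobody. Because doubletons mark very recent mutations, sharing traces
#' fine-scale coancestry: close kin share many, distant pairs few.
#'
#' @param gm a [genotype_matrix()].
#' @return Symmetric integer matrix of shared-doubleton counts (zero
#'   diagonal).
#' @export
doubleton_sharing <- function(gm) {
  G <- gm$G
  total <- rowSums(G, na.rm = TRUE)
  f2 <- which(total == 2L)
  n <- ncol(G)
  out <- matrix(0L, n, n, dimnames = list(gm$samples, gm$samples))
  for (v in f2) {
    carriers <- which(!is.na(G[v, ]) & G[v, ] == 1L)
    if (length(carriers) == 2L) {
      out[carriers[1], carriers[2]] <- out[carriers[1], carriers[2]] + 1L
      out[carriers[2], carriers[1]] <- out[carriers[2], carriers[1]] + 1L
    }
  }
  out
}

#' Ecological distance between sites
#'
#' Removes one variable from every pair with absolute Pearson correlation
#' at or above `corr_threshold` (keeping the first in column order),
#' z-scores the remainder, and returns pairwise Euclidean distances.
#'
#' @param env_table data frame of numeric ecological variables, one row
#'   per site; row names or a `site_id` column label the sites.
#' @param corr_threshold decorrelation cutoff (default 0.8).
#' @return List with the `dist` matrix and `kept` variable names.
#' @export
ecological_distance <- function(env_table, corr_threshold = 0.8) {
  ids <- if ("site_id" %in% names(env_table)) env_table$site_id
         else rownames(env_table)
  X <- as.matrix(env_table[, setdiff(names(env_table), "site_id"), drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance variable(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  keep <- rep(TRUE, ncol(X))
  if (ncol(X) > 1L) {
    cm <- abs(stats::cor(X))
    for (j in seq_len(ncol(X))) {
      if (!keep[j]) next
      later <- which(keep & seq_len(ncol(X)) > j & cm[j, ] >= corr_threshold)
      keep[later] <- FALSE
    }
  }
  X <- scale(X[, keep, drop = FALSE])
  d <- as.matrix(stats::dist(X))
  dimnames(d) <- list(ids, ids)
  list(dist = d, kept = colnames(X))
}

mantel_stat <- function(A, B) {
  ut <- upper.tri(A)
  stats::cor(A[ut], B[ut])
}

#' Mantel test
#'
#' Pearson correlation between the off-diagonal entries of two symmetric
#' distance matrices, with significance from simultaneous row/column
#' permutations of `A`. The one-sided p-value uses the
#' (1 + count)/(1 + n_perm) convention and is never exactly zero.
#'
#' @param A,B conformable symmetric matrices.
#' @param n_perm number of permutations (default 9999).
#' @param seed optional RNG seed.
#' @return List with `statistic`, `p_value`, `n_perm`.
#' @export
mantel <- function(A, B, n_perm = 9999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(A)
  if (n < 4L) stop("Mantel test needs at least 4 sites")
  stopifnot(all(dim(A) == c(n, n)), all(dim(B) == c(n, n)))
  obs <- mantel_stat(A, B)
  perm <- replicate(n_perm, {
    p <- sample.int(n)
    mantel_stat(A[p, p], B)
  })
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
       n_perm = n_perm)
}

#' Partial Mantel test
#'
#' Correlates two distance matrices while controlling for a third, by the
#' matrix-regression residual method: the off-diagonal entries of `A` and
#' `B` are each regressed on those of `C`, residuals are folded back into
#' matrix form, and a Mantel permutation test is run on the residual
#' matrices.
#'
#' @inheritParams mantel
#' @param C the matrix controlled for.
#' @return List with `statistic`, `p_value`, `n_perm`.
#' @export
partial_mantel <- function(A, B, C, n_perm = 9999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(A)
  if (n < 4L) stop("Mantel test needs at least 4 sites")
  resid_matrix <- function(M) {
    ut <- upper.tri(M)
    r <- stats::resid(stats::lm(M[ut] ~ C[ut]))
    R <- matrix(0, n, n)
    R[ut] <- r
    R + t(R)
  }
  RA <- resid_matrix(A); RB <- resid_matrix(B)
  obs <- mantel_stat(RA, RB)
  perm <- replicate(n_perm, {
    p <- sample.int(n)
    mantel_stat(RA[p, p], RB)
  })
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
       n_perm = n_perm)
}

#' Principal components analysis of genotypes
#'
#' Mean-centres each variant and scales by \eqn{\sqrt{p(1-p)}} (allele
#' frequency scaling); missing entries contribute zero after centring;
#' monomorphic variants are dropped. Decomposition is by SVD and is
#' deterministic up to the sign of each component.
#'
#' @param gm a [genotype_matrix()].
#' @param region optional `"chrom:start-end"` restriction.
#' @param n_components number of PCs to return.
#' @return List with `scores` (samples x PCs), `explained` (variance
#'   fractions) and `n_variants`.
#' @export
pca_genotypes <- function(gm, region = NULL, n_components = 10) {
  if (!is.null(region)) {
    r <- parse_region(region)
    gm <- subset_genotypes(gm, gm$chrom == r$chrom & gm$pos >= r$start &
                                gm$pos <= r$end)
  }
  G <- gm$G
  p <- rowMeans(G, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  G <- G[poly, , drop = FALSE]; p <- p[poly]
  X <- (G - 2 * p) / sqrt(p * (1 - p))
  X[is.na(X)] <- 0
  sv <- svd(t(X))
  k <- min(n_components, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- gm$samples
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, explained = sv$d^2 / sum(sv$d^2),
       n_variants = sum(poly))
}

#' Neighbour-joining tree from a distance matrix
#'
#' Canonical neighbour-joining agglomeration (via [ape::nj()]); negative
#' branch lengths are clamped to zero with a warning.
#'
#' @param distance_matrix symmetric non-negative matrix.
#' @param labels optional taxon labels (defaults to matrix dimnames).
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(distance_matrix, labels = NULL) {
  d <- as.matrix(distance_matrix)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  if (is.null(rownames(d)))
    dimnames(d) <- list(paste0("t", seq_len(nrow(d))),
                        paste0("t", seq_len(nrow(d))))
  if (nrow(d) == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);", rownames(d)[1],
                                        d[1, 2] / 2, rownames(d)[2],
                                        d[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("clamping ", sum(tr$edge.length < 0), " negative branch length(s) to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}
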