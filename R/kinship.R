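#' KING-robust kinship for one pair
#'
#' Computes the KING-robust kinship coefficient from hard diploid
#' genotypes,
#' \deqn{\hat\phi = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{N_{Aa}^{(i)} + N_{Aa}^{(j)}},}
#' where \eqn{N_{Aa,Aa}} counts sites at which both individuals are
#' heterozygous, \eqn{N_{AA,aa}} counts opposing homozygotes, and the
#' denominator sums the two individual heterozygote counts. Only
#' pairwise-complete sites (non-missing in both individuals) are used.
#' The estimator is robust to population structure; its expectation is 0.5
#' for identical genomes and 0.25 for full siblings.
#'
#' @param g_i,g_j equal-length vectors of alternate-allele counts
#'   (0/1/2/NA).
#' @return A list with `phi` (NA when the denominator is zero),
#'   `n_both_het`, `n_opposing_hom`, `n_het_i`, `n_het_j`, `n_sites_used`.
#' @export
king_robust <- function(g_i, g_j) {
  stopifnot(length(g_i) == length(g_j))
  use <- !is.na(g_i) & !is.na(g_j)
  gi <- g_i[use]; gj <- g_j[use]
  n_both_het <- sum(gi == 1L & gj == 1L)
  n_opp <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
  n_het_i <- sum(gi == 1L)
  n_het_j <- sum(gj == 1L)
  denom <- n_het_i + n_het_j
  phi <- if (denom == 0L) NA_real_ else (n_both_het - 2 * n_opp) / denom
  list(phi = phi, n_both_het = n_both_het, n_opposing_hom = n_opp,
       n_het_i = n_het_i, n_het_j = n_het_j, n_sites_used = sum(use))
}

#' KING-robust kinship matrix
#'
#' All-pairs KING-robust coefficients over a genotype matrix, optionally
#' after removing variants inside a mask (e.g. the 2La and 2Rb inversion
#' regions, whose deeply diverged karyotypes otherwise bias kinship and
#' make the within-species KING distribution multi-modal). Missing data is
#' handled pairwise-complete. The diagonal is self-kinship (0.5 whenever
#' the individual has at least one heterozygous site).
#'
#' @param gm a [genotype_matrix()].
#' @param mask optional [region_mask()] applied before counting.
#' @return A list with symmetric matrices `phi`, `n_both_het`,
#'   `n_opposing_hom`, `n_sites_used`; pairs with zero denominator have
#'   `phi = NA`.
#' @export
king_matrix <- function(gm, mask = NULL) {
  gm <- mask_genotypes(gm, mask)
  G <- gm$G
  if (ncol(G) < 2L) stop("need at least 2 samples")
  M <- !is.na(G); storage.mode(M) <- "double"
  Het <- (!is.na(G) & G == 1L); storage.mode(Het) <- "double"
  A0 <- (!is.na(G) & G == 0L); storage.mode(A0) <- "double"
  A2 <- (!is.na(G) & G == 2L); storage.mode(A2) <- "double"
  n_hh <- crossprod(Het)
  n_opp <- crossprod(A0, A2) + crossprod(A2, A0)
  het_ij <- crossprod(Het, M)            # het in i over sites non-missing in j
  denom <- het_ij + t(het_ij)
  phi <- (n_hh - 2 * n_opp) / denom
  phi[denom == 0] <- NA_real_
  dimnames(phi) <- list(gm$samples, gm$samples)
  list(phi = phi, n_both_het = n_hh, n_opposing_hom = n_opp,
       n_sites_used = crossprod(M))
}

#' Pairs table from a KING matrix
#'
#' @param km result of [king_matrix()].
#' @return Data frame with one row per unordered sample pair: ids, `phi`,
#'   audit counts, and the kin degree from [classify_degree()].
#' @export
king_pairs <- function(km) {
  n <- ncol(km$phi)
  idx <- which(upper.tri(km$phi), arr.ind = TRUE)
  data.frame(
    id1 = rownames(km$phi)[idx[, 1]], id2 = colnames(km$phi)[idx[, 2]],
    phi = km$phi[idx],
    n_both_het = km$n_both_het[idx], n_opposing_hom = km$n_opposing_hom[idx],
    n_sites_used = km$n_sites_used[idx],
    degree = classify_degree(km$phi[idx]),
    stringsAsFactors = FALSE)
}

#' Classify kin degree from a kinship coefficient
#'
#' Uses the standard powers-of-two midpoint thresholds
#' \eqn{2^{-k-3/2}}: phi above 0.3536 is a duplicate/monozygotic pair,
#' (0.1768, 0.3536] first degree (parent-offspring or full siblings),
#' (0.0884, 0.1768] second degree, (0.0442, 0.0884] third degree, and at
#' or below 0.0442 unrelated.
#'
#' @param phi kinship coefficient(s); NA propagates.
#' @return Character vector of categories.
#' @export
classify_degree <- function(phi) {
  cuts <- 2^(-(1:4) - 0.5)   # 0.3536 0.1768 0.0884 0.0442
  out <- ifelse(phi > cuts[1], "duplicate",
         ifelse(phi > cuts[2], "1st-degree",
         ifelse(phi > cuts[3], "2nd-degree",
         ifelse(phi > cuts[4], "3rd-degree", "unrelated"))))
  out[is.na(phi)] <- NA_character_
  out
}

#' Windowed Hudson Fst between two individuals
#'
#' Treats each diploid individual as a population of two chromosomes and
#' computes the ratio-of-averages Hudson Fst in windows along the genome.
#' Between relatives the track exposes identity-by-descent: windows where
#' the pair shares both homologs sit near -1 (IBD2), one shared homolog
#' gives about -1/3 (IBD1), and no sharing gives about 0.
#'
#' @param gm a [genotype_matrix()].
#' @param id_i,id_j sample ids of the pair.
#' @param window_size_bp window width in bp (default 100 kb); mutually
#'   exclusive with `n_snps`.
#' @param n_snps optional SNP-count windowing instead of bp windows.
#' @return Data frame per window: `chrom`, `start`, `end`, `n_sites`,
#'   `num` (sum of per-site numerators), `den`, and `fst` (NA where the
#'   denominator sum is zero).
#' @export
pairwise_fst_scan <- function(gm, id_i, id_j, window_size_bp = 1e5,
                              n_snps = NULL) {
  gi <- gm$G[, id_i]; gj <- gm$G[, id_j]
  use <- !is.na(gi) & !is.na(gj)
  gi <- gi[use]; gj <- gj[use]
  chrom <- gm$chrom[use]; pos <- gm$pos[use]
  p1 <- gi / 2; p2 <- gj / 2
  terms <- hudson_site_terms(p1, p2, n1 = 2, n2 = 2)
  out <- list()
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (!is.null(n_snps)) {
      w <- (seq_along(i) - 1L) %/% n_snps
    } else {
      w <- (pos[i] - 1L) %/% as.integer(window_size_bp)
    }
    for (k in unique(w)) {
      j <- i[w == k]
      num <- sum(terms$num[j]); den <- sum(terms$den[j])
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(pos[j]), end = max(pos[j]),
        n_sites = length(j), num = num, den = den,
        fst = if (den > 0) num / den else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Genome-wide Hudson Fst between two individuals
#'
#' Single ratio-of-averages value over all pairwise-complete sites.
#'
#' @inheritParams pairwise_fst_scan
#' @return A single Fst value (NA if the denominator sum is zero).
#' @export
pairwise_fst <- function(gm, id_i, id_j) {
  gi <- gm$G[, id_i]; gj <- gm$G[, id_j]
  use <- !is.na(gi) & !is.na(gj)
  terms <- hudson_site_terms(gi[use] / 2, gj[use] / 2, n1 = 2, n2 = 2)
  den <- sum(terms$den)
  if (den > 0) sum(terms$num) / den else NA_real_
}
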