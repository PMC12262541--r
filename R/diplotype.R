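#' Extract a diplotype block
#'
#' Diplotypes (multi-locus genotypes) are stretches of unphased diploid
#' genotypes over a window, used instead of haplotypes where multiallelic
#' SNPs and copy-number variants make phasing unreliable. Each sample's
#' diplotype is its vector of per-alternate-allele counts at every site in
#' the region; multiallelic sites contribute one count per alternate
#' allele. Sites with more missing calls than `max_missing` are dropped
#' (default: any missingness drops the site, since Manhattan distance has
#' no missing-value contract).
#'
#' @param gm a [genotype_matrix()], typically read with
#'   `biallelic_only = FALSE` so multiallelic rows are expanded.
#' @param region `"chrom:start-end"` string.
#' @param max_missing maximum missing calls tolerated per site (default 0).
#' @return A list of class `diplotype_block`: `counts` (samples x
#'   site-alleles), `sites` (chrom/pos/ref/alt per column), `region`.
#' @export
extract_diplotypes <- function(gm, region, max_missing = 0) {
  r <- parse_region(region)
  vi <- which(gm$chrom == r$chrom & gm$pos >= r$start & gm$pos <= r$end)
  if (length(vi) == 0L) stop("no variants in region ", region)
  miss <- rowSums(is.na(gm$G[vi, , drop = FALSE]))
  vi <- vi[miss <= max_missing]
  if (length(vi) == 0L) stop("all sites in region fail the missingness filter")
  counts <- t(gm$G[vi, , drop = FALSE])
  counts[is.na(counts)] <- 0L
  structure(list(counts = counts,
                 sites = data.frame(chrom = gm$chrom[vi], pos = gm$pos[vi],
                                    ref = gm$ref[vi], alt = gm$alt[vi]),
                 region = region),
            class = "diplotype_block")
}

#' Manhattan distance between diplotypes
#'
#' \eqn{d(a,b) = \sum_{\mathrm{sites}} \sum_{\mathrm{alleles}}
#' |c_a - c_b|} over allele counts: the city-block metric on the
#' diplotype vectors.
#'
#' @param block a [extract_diplotypes()] result (>= 2 samples).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
diplotype_distance <- function(block) {
  if (nrow(block$counts) < 2L) stop("need at least 2 samples")
  as.matrix(stats::dist(block$counts, method = "manhattan"))
}

#' Complete-linkage clustering of diplotypes
#'
#' Agglomerative clustering where the distance between clusters is the
#' maximum pairwise member distance; flat clusters are cut at
#' `cut_height`. Merge heights are non-decreasing and the final merge
#' height equals the maximum pairwise distance.
#'
#' @param distance_matrix symmetric matrix from [diplotype_distance()].
#' @param cut_height non-negative height at which to cut the dendrogram;
#'   default 0.05 x the number of diplotype sites is a reasonable start,
#'   but the dendrogram is returned so any cut can be re-derived.
#' @return List of class `diplotype_clusters`: `hclust` (the dendrogram),
#'   `labels` (flat cluster id per sample), `cut_height`, `leaf_order`.
#' @export
cluster_complete_linkage <- function(distance_matrix, cut_height) {
  if (cut_height < 0) stop("cut_height must be non-negative")
  distance_matrix <- as.matrix(distance_matrix)
  if (nrow(distance_matrix) == 1L) {
    lab <- rownames(distance_matrix) %||% "1"
    return(structure(list(hclust = NULL, labels = stats::setNames(1L, lab),
                          cut_height = cut_height, leaf_order = lab),
                     class = "diplotype_clusters"))
  }
  if (is.null(rownames(distance_matrix)))
    dimnames(distance_matrix) <- list(seq_len(nrow(distance_matrix)),
                                      seq_len(nrow(distance_matrix)))
  hc <- stats::hclust(stats::as.dist(distance_matrix), method = "complete")
  labels <- stats::cutree(hc, h = cut_height)
  structure(list(hclust = hc, labels = labels, cut_height = cut_height,
                 leaf_order = hc$labels[hc$order]),
            class = "diplotype_clusters")
}

#' Per-sample heterozygosity over a diplotype block
#'
#' Observed heterozygosity per variant, averaged over the block's
#' variants, giving one value per sample in [0, 1]. Clusters of samples
#' homozygous for one swept haplotype show heterozygosity near 0 — the
#' selective-sweep signature read off diplotype plots.
#'
#' @param block a [extract_diplotypes()] result.
#' @return Named numeric vector, one value per sample.
#' @export
sample_heterozygosity <- function(block) {
  cnt <- block$counts
  site_key <- paste(block$sites$chrom, block$sites$pos)
  # a sample is heterozygous at a site if any single allele count is 1
  # (for biallelic rows count 1 means ref/alt het; for expanded
  # multiallelic sites any allele present in one copy implies two
  # different alleles at the site)
  het_site <- vapply(unique(site_key), function(k) {
    cols <- which(site_key == k)
    rowSums(cnt[, cols, drop = FALSE] == 1L) > 0
  }, logical(nrow(cnt)))
  if (is.null(dim(het_site))) het_site <- matrix(het_site, nrow = nrow(cnt))
  out <- rowMeans(het_site)
  names(out) <- rownames(cnt)
  out
}

#' Annotate diplotype clusters
#'
#' Attaches per-sample tracks in dendrogram leaf order: block
#' heterozygosity, amino-acid variant genotypes (absent / heterozygous /
#' homozygous) and gene copy numbers, for plotting under the dendrogram.
#'
#' @param result a [cluster_complete_linkage()] result.
#' @param block the [extract_diplotypes()] block that was clustered.
#' @param aa_table optional data frame with `sample_id`, `variant`,
#'   `genotype` (0/1/2 alternate copies).
#' @param cnv_calls optional data frame with `sample_id`, `gene`, `copy`.
#' @return The result with `annotation`: a data frame in leaf order with
#'   heterozygosity plus one column per amino-acid variant and per gene.
#' @export
annotate_clusters <- function(result, block, aa_table = NULL,
                              cnv_calls = NULL) {
  leaves <- result$leaf_order
  ann <- data.frame(sample_id = leaves,
                    cluster = result$labels[leaves],
                    heterozygosity = sample_heterozygosity(block)[leaves],
                    row.names = NULL)
  code <- c("0" = "absent", "1" = "heterozygous", "2" = "homozygous")
  if (!is.null(aa_table)) {
    unknown <- setdiff(unique(aa_table$sample_id), leaves)
    if (length(unknown))
      warning("skipping annotation for unknown sample(s): ",
              paste(unknown, collapse = ", "))
    for (v in unique(aa_table$variant)) {
      sub <- aa_table[aa_table$variant == v, ]
      g <- code[as.character(sub$genotype[match(leaves, sub$sample_id)])]
      g[is.na(g)] <- "absent"
      ann[[paste0("aa_", v)]] <- unname(g)
    }
  }
  if (!is.null(cnv_calls)) {
    for (g in unique(cnv_calls$gene)) {
      sub <- cnv_calls[cnv_calls$gene == g, ]
      ann[[paste0("copy_", g)]] <- sub$copy[match(leaves, sub$sample_id)]
    }
  }
  result$annotation <- ann
  result
}
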