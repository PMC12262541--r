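#' Genotype matrix container
#'
#' A `genotype_matrix` holds diploid alternate-allele counts (0, 1, 2 or
#' `NA` for missing) for a set of variants and samples, together with
#' per-variant chromosome labels, 1-based positions and allele strings.
#' All coordinates in the package are 1-based inclusive.
#'
#' @param G integer matrix, variants in rows and samples in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param chrom character vector of chromosome labels, one per variant.
#' @param pos integer vector of 1-based positions, strictly increasing
#'   within each chromosome.
#' @param ref,alt allele strings per variant. `alt` may be a single allele
#'   or, for expanded multiallelic records, the allele the row counts.
#' @param samples sample identifiers; must be unique.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(G, chrom, pos, ref = NULL, alt = NULL,
                            samples = colnames(G)) {
  G <- as.matrix(G)
  storage.mode(G) <- "integer"
  n_var <- nrow(G)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(G)))
  stopifnot(length(chrom) == n_var, length(pos) == n_var)
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  bad <- !is.na(G) & (G < 0L | G > 2L)
  if (any(bad)) stop("genotype counts must be in {0,1,2} or NA")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  colnames(G) <- samples
  structure(
    list(G = G, chrom = as.character(chrom), pos = as.integer(pos),
         ref = ref %||% rep("A", n_var), alt = alt %||% rep("T", n_var),
         samples = samples),
    class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$G), "variants x", ncol(x$G), "samples;",
      length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$G)

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param variants logical or integer index over variants.
#' @param samples logical, integer or character index over samples.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(gm, variants = NULL, samples = NULL) {
  vi <- variants %||% seq_len(nrow(gm$G))
  si <- samples %||% gm$samples
  genotype_matrix(gm$G[vi, si, drop = FALSE], gm$chrom[vi], gm$pos[vi],
                  gm$ref[vi], gm$alt[vi])
}

#' Drop variants falling in masked regions
#'
#' Removes every variant whose position lies inside a [region_mask()]
#' interval (1-based inclusive). Used to exclude inversion regions such as
#' 2La and 2Rb from relatedness statistics.
#'
#' @param gm a [genotype_matrix()].
#' @param mask a `region_mask` or NULL (returned unchanged).
#' @return The masked `genotype_matrix`.
#' @export
mask_genotypes <- function(gm, mask) {
  if (is.null(mask) || nrow(mask$intervals) == 0L) return(gm)
  keep <- !variant_in_mask(gm$chrom, gm$pos, mask)
  subset_genotypes(gm, variants = keep)
}

variant_in_mask <- function(chrom, pos, mask) {
  hit <- logical(length(pos))
  iv <- mask$intervals
  for (k in seq_len(nrow(iv))) {
    hit <- hit | (chrom == iv$chrom[k] & pos >= iv$start[k] & pos <= iv$end[k])
  }
  hit
}

#' Phased haplotype container
#'
#' Holds 0/1 allele codes for phased haplotypes (two per sample) at a set
#' of variants, with optional cohort labels per haplotype used by the
#' haplotype-homozygosity scan statistics.
#'
#' @param H integer matrix, variants x haplotypes, entries 0/1.
#' @param chrom,pos per-variant chromosome and 1-based position.
#' @param samples sample id per haplotype (each id appears twice).
#' @param cohort optional cohort label per haplotype.
#' @return An object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(H, chrom, pos, samples = NULL, cohort = NULL) {
  H <- as.matrix(H)
  storage.mode(H) <- "integer"
  if (any(!is.na(H) & !(H %in% c(0L, 1L)))) stop("haplotype codes must be 0/1")
  if (ncol(H) %% 2L != 0L && is.null(samples))
    stop("haplotype count must be even (two per sample)")
  if (is.null(samples))
    samples <- rep(paste0("S", seq_len(ncol(H) / 2L)), each = 2L)
  structure(
    list(H = H, chrom = as.character(chrom), pos = as.integer(pos),
         samples = samples, cohort = cohort),
    class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("haplotype_matrix:", nrow(x$H), "variants x", ncol(x$H), "haplotypes\n")
  invisible(x)
}

#' Collapse phased haplotypes to diploid genotypes
#'
#' @param hm a [haplotype_matrix()].
#' @return A [genotype_matrix()] with one column per sample.
#' @export
haplotypes_to_genotypes <- function(hm) {
  ids <- unique(hm$samples)
  G <- vapply(ids, function(s) {
    cols <- which(hm$samples == s)
    as.integer(rowSums(hm$H[, cols, drop = FALSE]))
  }, integer(nrow(hm$H)))
  genotype_matrix(G, hm$chrom, hm$pos, samples = ids)
}
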