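#' Read genotypes from a VCF file
#'
#' Parses GT fields into alternate-allele counts. `"./."` (or `".|."`)
#' becomes missing. With `biallelic_only = TRUE` (the default used by all
#' statistics except diplotype extraction) multiallelic records are
#' skipped; otherwise each alternate allele of a multiallelic record is
#' expanded to its own row carrying per-allele counts.
#'
#' @param path VCF file (plain text or bgzipped) with a GT FORMAT field.
#' @param region optional `"chrom:start-end"` string restricting variants
#'   (1-based inclusive); a region with no variants yields an empty matrix.
#' @param biallelic_only skip records with more than one alternate allele.
#' @return A [genotype_matrix()]. The attribute `"phased"` is a logical
#'   vector marking variants whose GT used the `|` separator in every
#'   sample.
#' @export
read_vcf_genotypes <- function(path, region = NULL, biallelic_only = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- rep(TRUE, length(pos))
  if (!is.null(region)) {
    r <- parse_region(region)
    keep <- chrom == r$chrom & pos >= r$start & pos <= r$end
  }
  n_alt <- lengths(strsplit(alt, ",", fixed = TRUE))
  if (biallelic_only) keep <- keep & n_alt == 1L
  idx <- which(keep)
  rows <- list(); rchrom <- character(); rpos <- integer()
  rref <- character(); ralt <- character(); rphased <- logical()
  for (i in idx) {
    codes <- strsplit(gsub("\\|", "/", gt[i, ]), "/", fixed = TRUE)
    a1 <- suppressWarnings(as.integer(vapply(codes, `[`, "", 1L)))
    a2 <- suppressWarnings(as.integer(vapply(codes, function(x) x[min(2L, length(x))], "")))
    phased <- all(grepl("|", gt[i, ], fixed = TRUE), na.rm = TRUE)
    alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
    for (a in seq_along(alts)) {
      cnt <- (a1 == a) + (a2 == a)
      cnt[is.na(a1) | is.na(a2)] <- NA_integer_
      rows[[length(rows) + 1L]] <- as.integer(cnt)
      rchrom <- c(rchrom, chrom[i]); rpos <- c(rpos, pos[i])
      rref <- c(rref, ref[i]); ralt <- c(ralt, alts[a])
      rphased <- c(rphased, phased)
    }
  }
  if (length(rows) == 0L) {
    G <- matrix(integer(), nrow = 0, ncol = ncol(gt),
                dimnames = list(NULL, colnames(gt)))
    gm <- genotype_matrix(G, character(), integer(), character(), character())
    attr(gm, "phased") <- logical()
    return(gm)
  }
  # multiallelic expansion duplicates positions; constructor monotonicity is
  # strict, so deduplicate positional ties by nudging via a stable ordering
  G <- do.call(rbind, rows)
  colnames(G) <- colnames(gt)
  gm <- structure(
    list(G = {storage.mode(G) <- "integer"; G}, chrom = rchrom,
         pos = as.integer(rpos), ref = rref, alt = ralt,
         samples = colnames(gt)),
    class = "genotype_matrix")
  attr(gm, "phased") <- rphased
  gm
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) stop("region must be 'chrom:start-end'")
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Read phased haplotypes from a VCF file
#'
#' Requires fully phased, biallelic GT fields with no missing calls.
#'
#' @inheritParams read_vcf_genotypes
#' @param cohorts optional named vector mapping sample id to cohort label.
#' @return A [haplotype_matrix()].
#' @export
read_vcf_haplotypes <- function(path, region = NULL, cohorts = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  keep <- lengths(strsplit(fix[, "ALT"], ",", fixed = TRUE)) == 1L
  if (!is.null(region)) {
    r <- parse_region(region)
    keep <- keep & chrom == r$chrom & pos >= r$start & pos <= r$end
  }
  gt <- gt[keep, , drop = FALSE]; chrom <- chrom[keep]; pos <- pos[keep]
  if (any(!grepl("|", gt, fixed = TRUE)))
    stop("haplotype input requires phased GT ('|' separator)")
  H <- matrix(NA_integer_, nrow = nrow(gt), ncol = 2L * ncol(gt))
  for (j in seq_len(ncol(gt))) {
    cell <- strsplit(gt[, j], "|", fixed = TRUE)
    H[, 2L * j - 1L] <- suppressWarnings(as.integer(vapply(cell, `[`, "", 1L)))
    H[, 2L * j] <- suppressWarnings(as.integer(vapply(cell, `[`, "", 2L)))
  }
  samples <- rep(colnames(gt), each = 2L)
  haplotype_matrix(H, chrom, pos, samples = samples,
                   cohort = if (!is.null(cohorts)) unname(cohorts[samples]))
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (plain text).
#' @param phased write `|` separators; heterozygotes are emitted as `0|1`.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(gm, path, phased = FALSE) {
  sep <- if (phased) "|" else "/"
  code <- c("0" = paste0("0", sep, "0"), "1" = paste0("0", sep, "1"),
            "2" = paste0("1", sep, "1"))
  gtxt <- matrix(code[as.character(gm$G)], nrow = nrow(gm$G))
  gtxt[is.na(gtxt)] <- paste0(".", sep, ".")
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(gm$chrom), ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  body <- apply(cbind(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", ".", ".",
                      "GT", gtxt), 1L, paste, collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Region mask
#'
#' A sorted, merged set of 1-based inclusive genomic intervals, typically
#' inversion regions (2La, 2Rb) or heterochromatin to exclude from
#' relatedness and structure statistics.
#'
#' @param chrom,start,end parallel vectors of intervals (1-based inclusive).
#' @return An object of class `region_mask` whose `intervals` data frame is
#'   sorted and overlap-merged.
#' @export
region_mask <- function(chrom = character(), start = integer(), end = integer()) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(end < start)) stop("mask intervals must have end >= start")
  iv <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end))
  iv <- iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
  merged <- iv[0, ]
  for (i in seq_len(nrow(iv))) {
    n <- nrow(merged)
    if (n > 0L && merged$chrom[n] == iv$chrom[i] &&
        iv$start[i] <= merged$end[n] + 1L) {
      merged$end[n] <- max(merged$end[n], iv$end[i])
    } else {
      merged <- rbind(merged, iv[i, ])
    }
  }
  rownames(merged) <- NULL
  structure(list(intervals = merged), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat("region_mask:", nrow(x$intervals), "interval(s),",
      sum(x$intervals$end - x$intervals$start + 1), "bp\n")
  invisible(x)
}

#' Read a BED mask
#'
#' BED input is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention and merged.
#'
#' @param path BED3+ file.
#' @return A [region_mask()].
#' @export
read_bed_mask <- function(path) {
  tb <- tryCatch(utils::read.table(path, sep = "\t", header = FALSE,
                                   stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(tb)) return(region_mask())
  if (ncol(tb) < 3L) stop("BED mask needs at least 3 columns")
  start0 <- as.integer(tb[[2]]); end0 <- as.integer(tb[[3]])
  bad <- which(start0 > end0)
  if (length(bad)) stop("BED start > end at line ", bad[1])
  region_mask(tb[[1]], start0 + 1L, end0)
}

#' Write a region mask as BED
#'
#' @param mask a [region_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_mask <- function(mask, path) {
  iv <- mask$intervals
  utils::write.table(
    data.frame(iv$chrom, iv$start - 1L, iv$end),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated table with header columns `sample_id`, `site_id`, `lat`,
#' `lon`, `species`, `stratum`, `mine_flag`.
#'
#' @param path TSV file.
#' @return A data frame.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "site_id", "lat", "lon")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(md$lat)) || any(!is.finite(md$lon)))
    stop("metadata coordinates must be finite")
  md
}

#' Genetic map
#'
#' Per-chromosome monotone relation between physical position (bp) and
#' cumulative map distance (cM), with linear interpolation between anchor
#' points. Map distance is 0 at the first anchor of each chromosome.
#'
#' @param chrom,pos_bp,cM parallel vectors of anchor points.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(chrom, pos_bp, cM) {
  stopifnot(length(chrom) == length(pos_bp), length(pos_bp) == length(cM))
  chroms <- unique(as.character(chrom))
  maps <- lapply(chroms, function(ch) {
    i <- which(chrom == ch)
    bp <- as.numeric(pos_bp[i]); cm <- as.numeric(cM[i])
    o <- order(bp); bp <- bp[o]; cm <- cm[o]
    if (is.unsorted(bp, strictly = TRUE))
      stop("physical positions must be strictly increasing on ", ch)
    if (is.unsorted(cm, strictly = TRUE))
      stop("map distances must be strictly increasing on ", ch)
    cm <- cm - cm[1]
    list(bp = bp, cM = cm)
  })
  names(maps) <- chroms
  structure(list(maps = maps), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("genetic_map:", length(x$maps), "chromosome(s), total",
      round(map_length_morgans(x), 3), "Morgans\n")
  invisible(x)
}

#' Read a genetic map from a TSV of (chrom, pos_bp, cM)
#'
#' @param path TSV file with header columns chrom, pos_bp, cM.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos_bp", "cM")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("genetic map missing columns: ", paste(miss, collapse = ", "))
  genetic_map(tb$chrom, tb$pos_bp, tb$cM)
}

#' Build a constant-rate genetic map
#'
#' @param lengths_bp named numeric vector of chromosome lengths in bp.
#' @param rate_per_bp recombination rate per bp (Morgans/bp); the An.
#'   gambiae estimate is 1e-8.
#' @return A [genetic_map()] with two anchors per chromosome.
#' @export
constant_rate_map <- function(lengths_bp, rate_per_bp = 1e-8) {
  if (is.null(names(lengths_bp)))
    names(lengths_bp) <- paste0("chr", seq_along(lengths_bp))
  genetic_map(chrom = rep(names(lengths_bp), each = 2L),
              pos_bp = as.vector(rbind(1, lengths_bp)),
              cM = as.vector(rbind(0, (lengths_bp - 1) * rate_per_bp * 100)))
}

#' Interpolate map distance at physical positions
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome label.
#' @param bp physical positions.
#' @return cM values, linearly interpolated (constant beyond the anchors).
#' @export
bp_to_cM <- function(map, chrom, bp) {
  m <- map$maps[[chrom]]
  if (is.null(m)) stop("chromosome not in map: ", chrom)
  stats::approx(m$bp, m$cM, xout = bp, rule = 2)$y
}

#' Invert map distance to physical position
#'
#' @inheritParams bp_to_cM
#' @param cM map distances.
#' @return bp positions.
#' @export
cM_to_bp <- function(map, chrom, cM) {
  m <- map$maps[[chrom]]
  if (is.null(m)) stop("chromosome not in map: ", chrom)
  stats::approx(m$cM, m$bp, xout = cM, rule = 2)$y
}

#' Total map length in Morgans
#'
#' @param map a [genetic_map()].
#' @param chrom optional single chromosome.
#' @return Length in Morgans.
#' @export
map_length_morgans <- function(map, chrom = NULL) {
  ms <- if (is.null(chrom)) map$maps else map$maps[chrom]
  sum(vapply(ms, function(m) (max(m$cM) - min(m$cM)) / 100, 0))
}

#' Chromosome bp spans of a genetic map
#' @param map a [genetic_map()].
#' @return Named numeric vector of (last anchor) bp per chromosome.
#' @export
map_chrom_lengths <- function(map) {
  vapply(map$maps, function(m) max(m$bp), 0)
}

#' Serialise a tree to newick text
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return A newick string (with trailing semicolon).
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}
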