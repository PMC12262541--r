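# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# A 2-sample, 3-record biallelic VCF plus helpers for variants on demand.
write_toy_vcf <- function(path, records, samples = c("A", "B")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=2L>", "##contig=<ID=3R>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# independent per-site tally of the KING-robust coefficient (oracle)
king_bruteforce <- function(gi, gj) {
  num <- 0; den <- 0
  for (k in seq_along(gi)) {
    if (is.na(gi[k]) || is.na(gj[k])) next
    if (gi[k] == 1 && gj[k] == 1) num <- num + 1
    if (abs(gi[k] - gj[k]) == 2) num <- num - 2
    den <- den + (gi[k] == 1) + (gj[k] == 1)
  }
  if (den == 0) NA_real_ else num / den
}

# brute-force complete-linkage agglomeration: returns sorted merge heights
complete_linkage_bruteforce <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# brute-force best HMM state path by exhaustive enumeration (small tracks)
viterbi_bruteforce <- function(x, states, sd, stay) {
  k <- length(states); n <- length(x)
  move <- (1 - stay) / (k - 1)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(grid))) {
    s <- grid[r, ]
    lp <- -log(k) + sum(dnorm(x, states[s], sd, log = TRUE))
    if (n > 1) lp <- lp + sum(ifelse(diff(s) == 0, log(stay), log(move)))
    if (lp > best) { best <- lp; best_path <- s }
  }
  states[best_path]
}

# haplotype matrix with exact haplotype frequencies over one window
haps_with_freqs <- function(counts, n_var = 6, seed = 42) {
  set.seed(seed)
  pool <- matrix(rbinom(n_var * length(counts), 1, 0.5), n_var)
  while (anyDuplicated(t(pool)) > 0)
    pool <- matrix(rbinom(n_var * length(counts), 1, 0.5), n_var)
  pool[, rep(seq_along(counts), counts), drop = FALSE]
}
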