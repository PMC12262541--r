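#' Run the full synthetic-study demonstration
#'
#' Generates a synthetic micro-spatial study (grid-plus-close-pair site
#' layout, spatially structured genotypes, a planted inversion, nuclear
#' families, shared and private selective sweeps, and coverage with a
#' planted amplification) and runs every analysis stage over it: KING
#' kinship before and after inversion masking, isolation-by-distance
#' regression, Mantel and partial Mantel tests, the H12/H1X scan,
#' diplotype clustering and CNV calling. Results are written as CSV (and
#' newick for the NJ tree) under `out_dir`.
#'
#' @param seed integer seed controlling every stage.
#' @param out_dir output directory (created if needed).
#' @param n_sites,n_per_site,n_loci study size knobs (defaults mirror the
#'   13-site, 10-per-site design used throughout the package).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_demo <- function(seed = 1, out_dir = tempfile("vectorscan_demo_"),
                     n_sites = 13, n_per_site = 10, n_loci = 4000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  design <- simulate_sampling_design(n_sites)
  sim <- simulate_spatial_genotypes(design, n_loci = n_loci,
                                    n_per_site = n_per_site, m = 2)
  inv_region <- list("3R", 1, 1.5e7)
  gm_inv <- plant_inversion(sim$genotypes, inv_region, q = 0.4, d = 0.9)
  mask <- region_mask("3R", 1, 1.5e7)

  km_raw <- king_matrix(gm_inv)
  km_masked <- king_matrix(gm_inv, mask)
  pairs <- king_pairs(km_masked)
  utils::write.csv(pairs, file.path(out_dir, "king_pairs.csv"),
                   row.names = FALSE)
  modes_raw <- count_density_modes(km_raw$phi[upper.tri(km_raw$phi)])
  modes_masked <- count_density_modes(km_masked$phi[upper.tri(km_masked$phi)])

  gm_clean <- mask_genotypes(sim$genotypes, NULL)
  fstm <- site_fst_matrix(gm_clean, sim$metadata, min_per_site = min(10, n_per_site))
  coords <- unique(sim$metadata[, c("site_id", "lat", "lon")])
  coords <- coords[match(fstm$sites, coords$site_id), ]
  dmat <- site_distance_matrix(coords)
  ibd <- rousset_regression(fstm$linear_fst, dmat)
  utils::write.csv(fstm$fst, file.path(out_dir, "fst_matrix.csv"))

  env <- data.frame(site_id = coords$site_id,
                    elevation = stats::rnorm(nrow(coords), 200, 30),
                    precip = stats::rnorm(nrow(coords), 1500, 100),
                    ndvi = stats::rnorm(nrow(coords), 0.6, 0.1))
  eco <- ecological_distance(env)
  mt <- data.frame(
    test = c("fst~geo | eco", "fst~eco | geo"),
    statistic = c(partial_mantel(fstm$linear_fst, log(dmat + diag(nrow(dmat))), eco$dist, 999)$statistic,
                  partial_mantel(fstm$linear_fst, eco$dist, log(dmat + diag(nrow(dmat))), 999)$statistic),
    p_value = c(partial_mantel(fstm$linear_fst, log(dmat + diag(nrow(dmat))), eco$dist, 999, seed = seed)$p_value,
                partial_mantel(fstm$linear_fst, eco$dist, log(dmat + diag(nrow(dmat))), 999, seed = seed)$p_value))
  utils::write.csv(mt, file.path(out_dir, "mantel.csv"), row.names = FALSE)

  tree <- nj_tree(fstm$fst)
  writeLines(write_newick(tree), file.path(out_dir, "tree.nwk"))

  hm <- simulate_haplotypes(c(gambiae = 25, coluzzii = 25), n_loci = 6000)
  # sweep aligned with the second 1500-SNP window: haplotype identity is
  # exact match over a window, so partial overlap dilutes the signal
  hm <- plant_sweep(hm, c(1501, 3000), 0.6, shared = TRUE)
  scan <- scan_genome(hm, window_size = 1500)
  utils::write.csv(scan, file.path(out_dir, "scan.csv"), row.names = FALSE)

  block <- extract_diplotypes(sim$genotypes, "3R:20000000-25000000")
  dd <- diplotype_distance(block)
  cl <- cluster_complete_linkage(dd, cut_height = 0.05 * ncol(block$counts))
  cl <- annotate_clusters(cl, block)
  utils::write.csv(cl$annotation, file.path(out_dir, "diplotype_clusters.csv"),
                   row.names = FALSE)

  profile <- rep(2L, 200); profile[80:109] <- 4L
  trk <- normalize_coverage(simulate_coverage(profile, depth = 30))
  path <- cnv_hmm(trk)
  genes <- data.frame(gene = "cyp_like", chrom = "2R",
                      start = 80 * 300 - 299, end = 109 * 300)
  calls <- gene_cnv_calls(path, trk, genes)
  utils::write.csv(calls, file.path(out_dir, "cnv_calls.csv"),
                   row.names = FALSE)

  summary <- data.frame(
    metric = c("king_modes_unmasked", "king_modes_masked", "ibd_slope",
               "ibd_p_value", "max_h1x", "cnv_gene_copy"),
    value = c(modes_raw, modes_masked, ibd$slope, ibd$p_value,
              max(scan$h1x_coluzzii_gambiae %||% scan[[grep("^h1x", names(scan))[1]]]),
              calls$copy[1]))
  utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  invisible(list(design = design, king_raw = km_raw, king_masked = km_masked,
                 ibd = ibd, mantel = mt, scan = scan, clusters = cl,
                 cnv = calls, out_dir = out_dir, summary = summary))
}

#' Count modes of a kernel density estimate
#'
#' Local maxima of a Gaussian kernel density, filtered for relative
#' height and prominence: a peak only counts as a separate mode when it
#' exceeds `min_height` times the global maximum and is separated from
#' its taller neighbours by a valley dropping below `valley_ratio` times
#' the smaller peak's height. Used to flag inversion-confounded kinship
#' distributions as multi-modal.
#'
#' @param x numeric values (NAs dropped).
#' @param min_height relative height threshold for a peak (default 0.05).
#' @param valley_ratio maximum valley/peak ratio for two peaks to count
#'   separately (default 0.8).
#' @param adjust bandwidth adjustment passed to [stats::density()].
#' @return Integer mode count.
#' @export
count_density_modes <- function(x, min_height = 0.05, valley_ratio = 0.8,
                                adjust = 1) {
  x <- x[is.finite(x)]
  d <- stats::density(x, adjust = adjust)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  peaks <- peaks[y[peaks] >= min_height * max(y)]
  if (length(peaks) <= 1L) return(length(peaks))
  # merge adjacent peaks whose intervening valley is shallow
  merged <- peaks[1]
  for (p in peaks[-1]) {
    last <- merged[length(merged)]
    valley <- min(y[last:p])
    if (valley < valley_ratio * min(y[last], y[p])) {
      merged <- c(merged, p)
    } else if (y[p] > y[last]) {
      merged[length(merged)] <- p   # keep the taller of the merged pair
    }
  }
  length(merged)
}
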