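#' Largest-remainder apportionment
#'
#' Splits `n` units over categories proportionally to `weights`, rounding
#' by the largest-remainder rule so every count differs from exact
#' proportionality by less than one unit.
#'
#' @param n total units.
#' @param weights positive weights.
#' @return Integer vector summing to `n`.
#' @export
apportion <- function(n, weights) {
  if (any(weights <= 0)) stop("weights must be positive")
  exact <- n * weights / sum(weights)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a grid-plus-close-pair sampling design
#'
#' Emulates the micro-spatial sampling framework: 70% of sites sit on a
#' regular lattice and the remaining 30% are "close pairs" placed within
#' `close_pair_radius` of a randomly chosen grid site, capturing
#' short-range spatial autocorrelation. Sites are apportioned to strata
#' proportionally to `strata_weights` by largest remainder. Coordinates
#' are decimal degrees on a degree-approximate plane around the origin.
#'
#' @param n_sites total number of sites (>= 2).
#' @param strata_weights positive stratum weights (default one stratum).
#' @param grid_fraction fraction of sites on the lattice (default 0.7).
#' @param close_pair_radius_km radius for close-pair placement (default 2).
#' @param grid_spacing_km lattice spacing (default 5).
#' @param origin c(lat, lon) of the lattice corner (default Obuasi-like).
#' @param seed optional RNG seed.
#' @return Data frame: `site_id`, `lat`, `lon`, `type` (grid/close_pair),
#'   `stratum`.
#' @export
simulate_sampling_design <- function(n_sites, strata_weights = 1,
                                     grid_fraction = 0.7,
                                     close_pair_radius_km = 2,
                                     grid_spacing_km = 5,
                                     origin = c(6.2, -1.67), seed = NULL) {
  if (n_sites < 2) stop("need at least 2 sites")
  if (close_pair_radius_km <= 0) stop("close_pair_radius_km must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_grid <- round(grid_fraction * n_sites)
  n_close <- n_sites - n_grid
  nx <- ceiling(sqrt(n_grid))
  km_per_deg <- 111.32
  gx <- ((seq_len(n_grid) - 1L) %% nx) * grid_spacing_km
  gy <- ((seq_len(n_grid) - 1L) %/% nx) * grid_spacing_km
  anchors <- sample.int(n_grid, n_close, replace = TRUE)
  theta <- stats::runif(n_close, 0, 2 * pi)
  rad <- close_pair_radius_km * sqrt(stats::runif(n_close))
  cx <- gx[anchors] + rad * cos(theta)
  cy <- gy[anchors] + rad * sin(theta)
  x <- c(gx, cx); y <- c(gy, cy)
  strat_counts <- apportion(n_sites, strata_weights)
  stratum <- rep(seq_along(strata_weights), strat_counts)
  data.frame(site_id = sprintf("site%02d", seq_len(n_sites)),
             lat = origin[1] + y / km_per_deg,
             lon = origin[2] + x / (km_per_deg * cos(origin[1] * pi / 180)),
             type = rep(c("grid", "close_pair"), c(n_grid, n_close)),
             stratum = stratum,
             stringsAsFactors = FALSE)
}

#' Simulate spatially structured genotypes
#'
#' Site allele frequencies follow a spatially autocorrelated logit-normal
#' field: per locus an ancestral frequency is drawn, and site-level
#' logit deviations are a zero-mean Gaussian process with exponential
#' spatial correlation `exp(-d/range_km)` and standard deviation
#' `1/sqrt(2 m)`. Large migration `m` shrinks the deviations towards
#' panmixia; small `m` produces between-site Fst that grows with
#' distance — the isolation-by-distance signal the pipeline must detect.
#' Genotypes are binomial draws from the site frequencies.
#'
#' @param design a [simulate_sampling_design()] data frame.
#' @param n_loci number of biallelic loci (default 5000).
#' @param n_per_site samples per site (default 10).
#' @param m migration parameter (default 5; `Inf` gives panmixia).
#' @param range_km correlation range of the spatial field (default 20).
#' @param chrom,chrom_length_bp chromosome label and span over which loci
#'   are evenly placed.
#' @param seed optional RNG seed.
#' @return List with `genotypes` (a [genotype_matrix()]), `metadata`
#'   (sample_id, site_id, lat, lon, species, stratum, mine_flag) and
#'   `site_freqs` (loci x sites truth matrix).
#' @export
simulate_spatial_genotypes <- function(design, n_loci = 5000, n_per_site = 10,
                                       m = 5, range_km = 20,
                                       chrom = "3R",
                                       chrom_length_bp = 5e7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(design)
  d_km <- site_distance_matrix(design)
  s <- if (is.infinite(m)) 0 else 1 / sqrt(2 * m)
  R <- exp(-d_km / range_km)
  Lchol <- chol(R + diag(1e-8, k))
  p0 <- stats::runif(n_loci, 0.1, 0.9)
  eps <- matrix(stats::rnorm(n_loci * k), n_loci, k) %*% Lchol * s
  pf <- stats::plogis(stats::qlogis(p0) + eps)   # loci x sites
  G <- matrix(0L, n_loci, k * n_per_site)
  meta <- list()
  for (i in seq_len(k)) {
    cols <- (i - 1L) * n_per_site + seq_len(n_per_site)
    G[, cols] <- stats::rbinom(n_loci * n_per_site, 2L,
                               rep(pf[, i], n_per_site))
    meta[[i]] <- data.frame(
      sample_id = sprintf("%s_s%02d", design$site_id[i], seq_len(n_per_site)),
      site_id = design$site_id[i], lat = design$lat[i], lon = design$lon[i],
      species = "coluzzii", stratum = design$stratum[i],
      mine_flag = FALSE, stringsAsFactors = FALSE)
  }
  md <- do.call(rbind, meta)
  pos <- round(seq(1, chrom_length_bp, length.out = n_loci))
  gm <- genotype_matrix(G, rep(chrom, n_loci), pos, samples = md$sample_id)
  list(genotypes = gm, metadata = md, site_freqs = pf)
}

#' Plant an ancient inversion polymorphism
#'
#' Replaces genotypes inside `region` with draws from two deeply diverged
#' karyotype-specific frequency pools, emulating a polymorphic
#' chromosomal inversion such as 2La: each sample receives an inverted
#' karyotype dosage Binomial(2, `q`), and each of its two chromosome
#' copies draws alleles from the pool of its karyotype. Divergence `d`
#' in [0, 1] mixes pool frequencies between the background values (d = 0:
#' no effect on the genotype distribution) and independent uniform draws
#' per pool (d = 1: differentiation far above background, as between
#' opposing inversion karyotypes). Unmasked, such a region makes the
#' KING kinship distribution among unrelated samples multi-modal.
#'
#' @param gm a [genotype_matrix()].
#' @param region list or vector `(chrom, start, end)`.
#' @param q inverted-karyotype frequency.
#' @param d divergence parameter in [0, 1].
#' @param seed optional RNG seed.
#' @return The modified `genotype_matrix`, with attributes `karyotype`
#'   (inverted-copy count per sample) and `inversion_region`.
#' @export
plant_inversion <- function(gm, region, q = 0.4, d = 0.9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  region <- as.list(region)
  ch <- region[[1]]; a <- as.numeric(region[[2]]); b <- as.numeric(region[[3]])
  vi <- which(gm$chrom == ch & gm$pos >= a & gm$pos <= b)
  if (length(vi) == 0L) stop("inversion region contains no variants")
  p_bg <- rowMeans(gm$G[vi, , drop = FALSE], na.rm = TRUE) / 2
  nv <- length(vi)
  p_std <- (1 - d) * p_bg + d * stats::runif(nv, 0.02, 0.98)
  p_inv <- (1 - d) * p_bg + d * stats::runif(nv, 0.02, 0.98)
  n_samp <- ncol(gm$G)
  kar <- stats::rbinom(n_samp, 2L, q)
  for (j in seq_len(n_samp)) {
    gm$G[vi, j] <- stats::rbinom(nv, kar[j], p_inv) +
                   stats::rbinom(nv, 2L - kar[j], p_std)
  }
  attr(gm, "karyotype") <- stats::setNames(kar, gm$samples)
  attr(gm, "inversion_region") <- list(chrom = ch, start = a, end = b)
  gm
}

#' Simulate a nuclear family
#'
#' Draws founder haplotypes from per-locus allele frequencies and
#' produces offspring by Mendelian transmission. With `map = NULL` loci
#' are unlinked (an independent coin per locus picks which parental
#' allele is transmitted); with a genetic map, gametes are crossover
#' mosaics from the Poisson meiosis model, so sibling sharing is
#' correlated along chromosomes.
#'
#' @param founder_freqs per-locus alternate-allele frequencies.
#' @param n_offspring number of full siblings (default 2).
#' @param map optional [genetic_map()] with a single chromosome spanning
#'   the loci; loci are placed evenly along it.
#' @param seed optional RNG seed.
#' @return A [genotype_matrix()] with samples `father`, `mother`,
#'   `off1..k`; attribute `haplotypes` holds the founder haplotypes.
#' @export
simulate_family <- function(founder_freqs, n_offspring = 2, map = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- founder_freqs
  L <- length(p)
  hap <- function() stats::rbinom(L, 1L, p)
  fh <- list(hap(), hap()); mh <- list(hap(), hap())
  if (is.null(map)) {
    gam <- function(h) {
      pick <- stats::rbinom(L, 1L, 0.5) + 1L
      ifelse(pick == 1L, h[[1]], h[[2]])
    }
    pos <- seq_len(L)
    chrom <- rep("chr1", L)
  } else {
    ch <- names(map$maps)[1]
    Lbp <- map_chrom_lengths(map)[[ch]]
    pos <- round(seq(1, Lbp, length.out = L))
    chrom <- rep(ch, L)
    gam <- function(h) {
      xo <- simulate_meiosis(map)[[ch]]
      src <- (sample.int(2L, 1L) + findInterval(pos, xo)) %% 2L + 1L
      ifelse(src == 1L, h[[1]], h[[2]])
    }
  }
  G <- cbind(father = fh[[1]] + fh[[2]], mother = mh[[1]] + mh[[2]])
  for (k in seq_len(n_offspring)) G <- cbind(G, gam(fh) + gam(mh))
  colnames(G) <- c("father", "mother", paste0("off", seq_len(n_offspring)))
  gm <- genotype_matrix(G, chrom, pos)
  attr(gm, "haplotypes") <- list(father = fh, mother = mh)
  gm
}

#' Simulate neutral phased haplotypes
#'
#' Independent per-locus Bernoulli draws from shared allele frequencies:
#' the neutral background for sweep-scan experiments.
#'
#' @param n_samples_per_cohort named integer vector, e.g.
#'   `c(gambiae = 25, coluzzii = 25)`.
#' @param n_loci number of variants.
#' @param freqs optional per-locus frequencies (default Uniform(0.05,
#'   0.95)).
#' @param chrom,chrom_length_bp variant placement.
#' @param seed optional RNG seed.
#' @return A [haplotype_matrix()] with cohort labels.
#' @export
simulate_haplotypes <- function(n_samples_per_cohort, n_loci = 10000,
                                freqs = NULL, chrom = "2R",
                                chrom_length_bp = 6e7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(n_samples_per_cohort)))
    names(n_samples_per_cohort) <- paste0("cohort", seq_along(n_samples_per_cohort))
  p <- freqs %||% stats::runif(n_loci, 0.05, 0.95)
  n_hap <- 2L * sum(n_samples_per_cohort)
  H <- matrix(stats::rbinom(n_loci * n_hap, 1L, p), n_loci, n_hap)
  cohort <- rep(names(n_samples_per_cohort), 2L * n_samples_per_cohort)
  samples <- paste0(cohort, "_s", rep(sequence(n_samples_per_cohort), each = 2L))
  pos <- round(seq(1, chrom_length_bp, length.out = n_loci))
  haplotype_matrix(H, rep(chrom, n_loci), pos, samples = samples,
                   cohort = cohort)
}

#' Plant a selective sweep into phased haplotypes
#'
#' Copies a single core haplotype over the region into a fraction
#' `sweep_freq` of the target cohorts' haplotypes, emulating the loss of
#' haplotype diversity around a selected allele. With `shared = TRUE`
#' the same core haplotype is used in every target cohort (a shared
#' sweep, which the H1X statistic is designed to detect); otherwise each
#' cohort receives its own core.
#'
#' @param hm a [haplotype_matrix()].
#' @param region variant-index range `c(from, to)` or bp range as
#'   `list(chrom, start, end)`.
#' @param sweep_freq fraction of cohort haplotypes carrying the core, in
#'   (0, 1].
#' @param cohorts cohort label(s) receiving the sweep (default all).
#' @param shared use one core haplotype across cohorts (default TRUE).
#' @param seed optional RNG seed.
#' @return The modified `haplotype_matrix` with attribute `sweep` (region
#'   indices and carrier haplotype columns per cohort).
#' @export
plant_sweep <- function(hm, region, sweep_freq, cohorts = NULL,
                        shared = TRUE, seed = NULL) {
  if (sweep_freq <= 0 || sweep_freq > 1) stop("sweep_freq must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (is.list(region)) {
    vi <- which(hm$chrom == region[[1]] & hm$pos >= region[[2]] &
                hm$pos <= region[[3]])
  } else {
    vi <- region[1]:region[2]
  }
  labels <- hm$cohort %||% rep("all", ncol(hm$H))
  cohorts <- cohorts %||% unique(labels)
  core <- stats::rbinom(length(vi), 1L, 0.5)
  carriers <- list()
  for (co in cohorts) {
    if (!shared) core <- stats::rbinom(length(vi), 1L, 0.5)
    cols <- which(labels == co)
    pick <- sample(cols, max(1L, round(sweep_freq * length(cols))))
    hm$H[vi, pick] <- core
    carriers[[co]] <- pick
  }
  attr(hm, "sweep") <- list(variants = vi, carriers = carriers,
                            shared = shared, freq = sweep_freq)
  hm
}

#' Simulate windowed sequencing coverage
#'
#' Per-window read counts are Poisson with mean
#' `depth * copy/2 * gc_bias(gc)`: diploid windows average `depth`
#' reads, a deletion gives zero, and a c-copy amplification scales the
#' mean by c/2. The true copy profile is stored for recovery tests.
#'
#' @param copy_profile integer vector of true copy numbers per window
#'   (values above 12 test the HMM's state cap).
#' @param depth mean diploid read count per window (> 0).
#' @param gc optional per-window GC fraction (default Uniform(0.35,
#'   0.65)).
#' @param gc_bias optional function of GC fraction giving a multiplicative
#'   bias (default none).
#' @param chrom chromosome label.
#' @param seed optional RNG seed.
#' @return A raw [coverage_track()] with attribute `truth` (the copy
#'   profile).
#' @export
simulate_coverage <- function(copy_profile, depth = 20, gc = NULL,
                              gc_bias = NULL, chrom = "2R", seed = NULL) {
  if (depth <= 0) stop("depth must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- length(copy_profile)
  gc <- gc %||% stats::runif(n, 0.35, 0.65)
  bias <- if (is.null(gc_bias)) rep(1, n) else gc_bias(gc)
  counts <- stats::rpois(n, depth * copy_profile / 2 * bias)
  tr <- coverage_track(rep(chrom, n), seq(1L, by = 300L, length.out = n),
                       counts, gc)
  attr(tr, "truth") <- as.integer(copy_profile)
  tr
}
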