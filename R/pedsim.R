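#' Simulate crossover positions for one meiosis
#'
#' Recombination breakpoints are a Poisson process on the genetic-map
#' scale with no crossover interference: per chromosome the crossover
#' count is Poisson with mean equal to the chromosome's map length in
#' Morgans, positions are uniform on the cM scale and converted to bp by
#' inverse interpolation of the map.
#'
#' @param map a [genetic_map()].
#' @param seed optional RNG seed.
#' @param obligate if TRUE, chromosomes with zero drawn crossovers receive
#'   one (obligate-chiasma option; off by default to match the plain
#'   Poisson model).
#' @return Named list per chromosome of sorted crossover bp positions
#'   (possibly empty).
#' @export
simulate_meiosis <- function(map, seed = NULL, obligate = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  lapply(map$maps, function(m) {
    morgans <- (max(m$cM) - min(m$cM)) / 100
    k <- stats::rpois(1, morgans)
    if (obligate && k == 0L && morgans > 0) k <- 1L
    if (k == 0L) return(numeric())
    cm <- sort(stats::runif(k, min(m$cM), max(m$cM)))
    sort(stats::approx(m$cM, m$bp, xout = cm, rule = 2)$y)
  })
}

# founder homolog: one segment spanning the chromosome
founder_homologs <- function(id, map) {
  lens <- map_chrom_lengths(map)
  lapply(names(lens), function(ch) {
    list(h1 = data.frame(start = 1, end = lens[[ch]],
                         label = paste0(id, "_1")),
         h2 = data.frame(start = 1, end = lens[[ch]],
                         label = paste0(id, "_2")))
  }) |> stats::setNames(names(lens))
}

clip_segments <- function(segs, a, b) {
  keep <- segs$end >= a & segs$start <= b
  s <- segs[keep, , drop = FALSE]
  s$start <- pmax(s$start, a)
  s$end <- pmin(s$end, b)
  s
}

# one gamete: mosaic of the parent's two homologs switching at crossovers
gamete_segments <- function(parent_chrom, crossovers, L) {
  bounds <- c(1, floor(crossovers) + 1, L + 1)
  src <- (sample.int(2L, 1L) + seq_len(length(bounds) - 1L)) %% 2L + 1L
  out <- vector("list", length(bounds) - 1L)
  for (i in seq_along(out)) {
    a <- bounds[i]; b <- bounds[i + 1] - 1
    if (b < a) next
    out[[i]] <- clip_segments(parent_chrom[[src[i]]], a, b)
  }
  seg <- do.call(rbind, out)
  # merge adjacent same-label runs
  if (nrow(seg) > 1L) {
    same <- c(FALSE, seg$label[-1] == seg$label[-nrow(seg)] &
                     seg$start[-1] == seg$end[-nrow(seg)] + 1)
    grp <- cumsum(!same)
    seg <- data.frame(start = tapply(seg$start, grp, min),
                      end = tapply(seg$end, grp, max),
                      label = seg$label[!same])
  }
  rownames(seg) <- NULL
  seg
}

make_gamete <- function(parent, map) {
  xo <- simulate_meiosis(map)
  lens <- map_chrom_lengths(map)
  out <- lapply(names(lens), function(ch)
    gamete_segments(parent[[ch]], xo[[ch]], lens[[ch]]))
  stats::setNames(out, names(lens))
}

#' Build a pedigree table
#'
#' @param id,father,mother,generation,printed parallel vectors; founders
#'   have NA parents. Validates acyclicity (parents in earlier
#'   generations) and two distinct parents per non-founder.
#' @return A `pedigree` data frame.
#' @export
pedigree <- function(id, father, mother, generation, printed) {
  ped <- data.frame(id = as.character(id), father = as.character(father),
                    mother = as.character(mother),
                    generation = as.integer(generation),
                    printed = as.logical(printed), stringsAsFactors = FALSE)
  if (anyDuplicated(ped$id)) stop("duplicate individual ids")
  founders <- is.na(ped$father) & is.na(ped$mother)
  half <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(half)) stop("individuals must have two parents or none")
  if (any(!founders & ped$father == ped$mother))
    stop("parents must be distinct")
  gen <- stats::setNames(ped$generation, ped$id)
  for (i in which(!founders)) {
    for (p in c(ped$father[i], ped$mother[i])) {
      if (!p %in% ped$id) stop("unknown parent: ", p)
      if (gen[p] >= ped$generation[i])
        stop("parent must be in an earlier generation (cycle?): ", p)
    }
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Read a pedigree file
#'
#' Whitespace-separated columns: id father mother generation printed;
#' founders use "0" or "NA" for both parents.
#'
#' @param path file path.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  tb <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("id", "father", "mother",
                                        "generation", "printed"))
  tb$father[tb$father %in% c("0", "NA")] <- NA
  tb$mother[tb$mother %in% c("0", "NA")] <- NA
  pedigree(tb$id, tb$father, tb$mother, tb$generation,
           as.logical(as.integer(tb$printed)))
}

#' Default 4-generation study pedigree
#'
#' Builds the replicated 4-generation pedigree used for the realized
#' relatedness experiment: generation 1 has 4 branches with 1 printed
#' individual each; generation 2 has 4 branches with 2 printed full
#' siblings each; generations 3 and 4 each have 12 branches with 2
#' printed full siblings each. Unprinted connector individuals link each
#' branch to a distinct parent couple so that full-sibling pairs among
#' printed individuals occur only within branches: per replicate 60
#' printed individuals and 28 printed full-sib pairs.
#'
#' @param replicates number of independent replicate pedigrees (default 10).
#' @return A [pedigree()] covering all replicates.
#' @export
default_pedigree <- function(replicates = 10) {
  rows <- list()
  add <- function(id, fa, mo, gen, pr)
    rows[[length(rows) + 1L]] <<- data.frame(id = id, father = fa, mother = mo,
                                             generation = gen, printed = pr)
  for (r in seq_len(replicates)) {
    pre <- paste0("r", r, "_")
    # generation 1: 4 founder couples, branch individual printed
    for (b in 1:4) {
      add(paste0(pre, "g1b", b, "_i"), NA, NA, 1L, TRUE)
      add(paste0(pre, "g1b", b, "_s"), NA, NA, 1L, FALSE)
    }
    # generation 2: 4 branches, 2 printed sibs from the gen-1 couple
    for (b in 1:4) {
      fa <- paste0(pre, "g1b", b, "_i"); mo <- paste0(pre, "g1b", b, "_s")
      for (k in 1:2) add(paste0(pre, "g2b", b, "_c", k), fa, mo, 2L, TRUE)
    }
    # generations 3 and 4: 12 branches each; every branch descends from its
    # own connector child of the parent branch couple plus a new founder
    gen_branches <- function(gen, n_branch, parent_of) {
      for (b in seq_len(n_branch)) {
        pb <- parent_of(b)
        conn <- paste0(pre, "g", gen, "b", b, "_p")
        add(conn, pb$fa, pb$mo, gen - 1L, FALSE)
        sp <- paste0(pre, "g", gen, "b", b, "_s")
        add(sp, NA, NA, gen - 1L, FALSE)
        for (k in 1:2)
          add(paste0(pre, "g", gen, "b", b, "_c", k), conn, sp, gen, TRUE)
      }
    }
    gen_branches(3L, 12L, function(b) {
      pb <- ((b - 1L) %% 4L) + 1L
      list(fa = paste0(pre, "g1b", pb, "_i"), mo = paste0(pre, "g1b", pb, "_s"))
    })
    gen_branches(4L, 12L, function(b) {
      list(fa = paste0(pre, "g3b", b, "_p"), mo = paste0(pre, "g3b", b, "_s"))
    })
  }
  tb <- do.call(rbind, rows)
  pedigree(tb$id, tb$father, tb$mother, tb$generation, tb$printed)
}

#' Printed full-sibling pairs of a pedigree
#'
#' @param ped a [pedigree()].
#' @return Data frame with columns `id1`, `id2` over printed pairs sharing
#'   both parents.
#' @export
full_sib_pairs <- function(ped) {
  pr <- ped[ped$printed & !is.na(ped$father), ]
  key <- paste(pr$father, pr$mother)
  out <- list()
  for (k in unique(key)) {
    ids <- pr$id[key == k]
    if (length(ids) > 1L) {
      cmb <- utils::combn(ids, 2L)
      out[[length(out) + 1L]] <- data.frame(id1 = cmb[1, ], id2 = cmb[2, ])
    }
  }
  do.call(rbind, out)
}

#' Propagate IBD segments through a pedigree
#'
#' Assigns every founder two uniquely labelled homologs per chromosome and
#' builds each non-founder's homologs as crossover mosaics of its parents'
#' homologs (one gamete per parent, Poisson crossovers on the map scale).
#' Founder labels propagate unchanged, so identity by descent between any
#' two individuals can be read off by comparing labels.
#'
#' @param ped a [pedigree()].
#' @param map a [genetic_map()].
#' @param seed optional RNG seed.
#' @return Named list: per individual, per chromosome, `h1`/`h2` segment
#'   data frames (start, end, label) tiling the chromosome.
#' @export
propagate_ibd <- function(ped, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  segs <- list()
  for (i in order(ped$generation)) {
    id <- ped$id[i]
    if (is.na(ped$father[i])) {
      segs[[id]] <- founder_homologs(id, map)
    } else {
      pat <- make_gamete(segs[[ped$father[i]]], map)
      mat <- make_gamete(segs[[ped$mother[i]]], map)
      segs[[id]] <- stats::setNames(lapply(names(pat), function(ch)
        list(h1 = pat[[ch]], h2 = mat[[ch]])), names(pat))
    }
  }
  segs
}

label_at <- function(segs, x) {
  segs$label[segs$start <= x & segs$end >= x][1]
}

#' IBD state intervals and realized relatedness for a pair
#'
#' Pointwise, the IBD state of a pair is the size of the maximum matching
#' between their two homolog founder labels: 2 where both homolog pairs
#' match, 1 where exactly one can be matched, else 0. Returns the merged
#' state intervals plus genome fractions L0/L1/L2 and the realized
#' relatedness r = L1/2 + L2.
#'
#' @param a,b individual ids.
#' @param segments output of [propagate_ibd()].
#' @return List with `intervals` (chrom, start, end, state), `L0`, `L1`,
#'   `L2`, and `r_hat`.
#' @export
ibd_states <- function(a, b, segments) {
  sa <- segments[[a]]; sb <- segments[[b]]
  if (is.null(sa) || is.null(sb)) stop("individual not in segment set")
  len <- c(0, 0, 0)
  iv <- list()
  for (ch in names(sa)) {
    cuts <- sort(unique(c(
      1,
      sa[[ch]]$h1$end + 1, sa[[ch]]$h2$end + 1,
      sb[[ch]]$h1$end + 1, sb[[ch]]$h2$end + 1)))
    L <- max(sa[[ch]]$h1$end)
    starts <- cuts[cuts <= L]
    ends <- c(starts[-1] - 1, L)
    state <- integer(length(starts))
    for (k in seq_along(starts)) {
      m <- (starts[k] + ends[k]) / 2
      a1 <- label_at(sa[[ch]]$h1, m); a2 <- label_at(sa[[ch]]$h2, m)
      b1 <- label_at(sb[[ch]]$h1, m); b2 <- label_at(sb[[ch]]$h2, m)
      two <- (a1 == b1 && a2 == b2) || (a1 == b2 && a2 == b1)
      one <- a1 == b1 || a1 == b2 || a2 == b1 || a2 == b2
      state[k] <- if (two) 2L else if (one) 1L else 0L
      len[state[k] + 1L] <- len[state[k] + 1L] + (ends[k] - starts[k] + 1)
    }
    # merge consecutive equal states
    keep <- c(TRUE, state[-1] != state[-length(state)])
    grp <- cumsum(keep)
    iv[[ch]] <- data.frame(chrom = ch,
                           start = tapply(starts, grp, min),
                           end = tapply(ends, grp, max),
                           state = state[keep])
  }
  tot <- sum(len)
  L <- len / tot
  list(intervals = do.call(rbind, iv), L0 = L[1], L1 = L[2], L2 = L[3],
       r_hat = L[2] / 2 + L[3])
}

#' Realized relatedness of simulated full-sibling pairs
#'
#' Convenience driver: simulates `n_pairs` independent families (two
#' founders, two full-sibling offspring) under a genetic map and returns
#' each pair's realized relatedness L1/2 + L2. Under any map the
#' expectation is 0.5; the variance grows as total map length shrinks,
#' which is why the 3-chromosome An. gambiae genome (about 2.3 Morgans)
#' shows far more spread than a human-like 22-autosome map.
#'
#' @param n_pairs number of sib pairs.
#' @param map a [genetic_map()].
#' @param seed optional RNG seed.
#' @return Numeric vector of realized relatedness values.
#' @export
simulate_sib_relatedness <- function(n_pairs, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- pedigree(c("F", "M", "C1", "C2"),
                  c(NA, NA, "F", "F"), c(NA, NA, "M", "M"),
                  c(1L, 1L, 2L, 2L), c(FALSE, FALSE, TRUE, TRUE))
  vapply(seq_len(n_pairs), function(i) {
    segs <- propagate_ibd(ped, map)
    ibd_states("C1", "C2", segs)$r_hat
  }, 0)
}

#' Crossover-count statistics from the binomial model
#'
#' Treats each base pair as an independent Bernoulli trial of crossover
#' with probability `rate_per_bp`, i.e. crossover count ~
#' Binomial(L, r) (no crossover interference). Evaluated in log space so
#' chromosome-scale L (~1e8) is exact. For An. gambiae chromosome 2
#' (2R + 2L = 110,909,430 bp) at r = 1e-8 this gives mean 1.11, a 33%
#' chance of zero crossovers, and a central 95% interval of 0-4 events.
#'
#' @param L_bp chromosome length in bp.
#' @param rate_per_bp per-bp recombination rate.
#' @return List with `mean`, `p_zero`, `ci95` (0.025/0.975 binomial
#'   quantiles).
#' @export
recombination_count_stats <- function(L_bp, rate_per_bp) {
  stopifnot(L_bp > 0, rate_per_bp > 0, rate_per_bp < 1)
  list(mean = L_bp * rate_per_bp,
       p_zero = exp(L_bp * log1p(-rate_per_bp)),
       ci95 = stats::qbinom(c(0.025, 0.975), L_bp, rate_per_bp))
}

#' An. gambiae and human-like constant-rate maps
#'
#' The mosquito map has three chromosomes (2: 111.0 Mb, 3: 95.2 Mb,
#' X: 24.4 Mb) at 1e-8 Morgans/bp, about 2.3 Morgans in total. The
#' human-like comparison map has 22 autosomes with lengths proportional
#' to a standard autosome length table, scaled to 35 Morgans total.
#'
#' @return A [genetic_map()].
#' @export
gambiae_map <- function() {
  constant_rate_map(c(chr2 = 111.0e6, chr3 = 95.2e6, chrX = 24.4e6), 1e-8)
}

#' @rdname gambiae_map
#' @export
human_like_map <- function() {
  path <- system.file("extdata", "human_like_map.tsv", package = "vectorscan")
  read_genetic_map(path)
}
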