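#' SNP-count window index ranges
#'
#' Consecutive non-overlapping windows of exactly `window_size` variants
#' (the scans use 1500-SNP windows by default); a trailing remainder
#' shorter than `window_size` is dropped. A `step` smaller than the window
#' size yields overlapping windows.
#'
#' @param n_variants total variant count.
#' @param window_size variants per window (default 1500).
#' @param step offset between window starts (default `window_size`).
#' @return Data frame with `start`, `end` variant indices (1-based
#'   inclusive); zero rows (with a warning) when `n_variants <
#'   window_size`.
#' @export
snp_windows <- function(n_variants, window_size = 1500, step = window_size) {
  stopifnot(window_size >= 1, step >= 1)
  if (n_variants < window_size) {
    warning("fewer variants (", n_variants, ") than window size (",
            window_size, "); no windows")
    return(data.frame(start = integer(), end = integer()))
  }
  starts <- seq.int(1L, n_variants - window_size + 1L, by = step)
  data.frame(start = starts, end = starts + window_size - 1L)
}

window_hap_freqs <- function(H) {
  key <- apply(H, 2, paste, collapse = "")
  tab <- table(key)
  sort(as.numeric(tab) / ncol(H), decreasing = TRUE)
}

#' Garud haplotype-homozygosity statistics for one window
#'
#' With haplotype frequencies \eqn{p_1 \ge p_2 \ge \dots}:
#' \eqn{H1 = \sum p_i^2}; \eqn{H12 = (p_1+p_2)^2 + \sum_{i\ge3} p_i^2};
#' \eqn{H123 = (p_1+p_2+p_3)^2 + \sum_{i\ge4} p_i^2};
#' \eqn{H2/H1 = (H1 - p_1^2)/H1}. H12 pools the two most frequent
#' haplotypes and so detects soft as well as hard selective sweeps.
#' Haplotype identity is exact match over the window's variants.
#'
#' @param H 0/1 matrix, variants x haplotypes (>= 2 haplotypes).
#' @return List with `h1`, `h12`, `h123`, `h2_h1`.
#' @export
garud_h <- function(H) {
  if (ncol(H) < 2L) stop("need at least 2 haplotypes")
  p <- window_hap_freqs(H)
  p <- c(p, rep(0, max(0, 3 - length(p))))   # pad for the pooled sums
  h1 <- sum(p^2)
  h12 <- (p[1] + p[2])^2 + sum(p[-(1:2)]^2)
  h123 <- (p[1] + p[2] + p[3])^2 + sum(p[-(1:3)]^2)
  list(h1 = h1, h12 = h12, h123 = h123, h2_h1 = (h1 - p[1]^2) / h1)
}

#' Between-cohort haplotype sharing statistic H1X
#'
#' The probability that one haplotype drawn from each of two cohorts is
#' identical over the window: \eqn{H1X = \sum_h f_h g_h} with \eqn{f, g}
#' the haplotype frequency spectra of the cohorts. Elevated H1X marks a
#' sweep shared between cohorts (e.g. adaptive introgression).
#'
#' @param HX,HY 0/1 matrices over the same variant window.
#' @return H1X value in [0, 1].
#' @export
h1x <- function(HX, HY) {
  stopifnot(nrow(HX) == nrow(HY))
  fx <- table(apply(HX, 2, paste, collapse = "")) / ncol(HX)
  fy <- table(apply(HY, 2, paste, collapse = "")) / ncol(HY)
  shared <- intersect(names(fx), names(fy))
  sum(as.numeric(fx[shared]) * as.numeric(fy[shared]))
}

#' Genome-wide haplotype-homozygosity scan
#'
#' Computes Garud H1/H12/H123/H2H1 per cohort and H1X per cohort pair in
#' SNP-count windows, attaching bp coordinates from the variant positions.
#'
#' @param hm a [haplotype_matrix()] with cohort labels (a single cohort is
#'   allowed; H1X then has no pairs).
#' @param window_size variants per window (default 1500).
#' @param step window step (default non-overlapping).
#' @return Data frame: one row per window with `chrom`, `start_bp`,
#'   `end_bp`, per-cohort `h1_*`, `h12_*`, `h123_*`, `h2h1_*` columns and
#'   `h1x_*_*` per cohort pair.
#' @export
scan_genome <- function(hm, window_size = 1500, step = window_size) {
  cohorts <- hm$cohort %||% rep("all", ncol(hm$H))
  labs <- unique(cohorts)
  use <- labs[vapply(labs, function(l) sum(cohorts == l) >= 2L, TRUE)]
  if (length(use) < length(labs))
    warning("skipping cohort(s) with <2 haplotypes: ",
            paste(setdiff(labs, use), collapse = ", "))
  out <- list()
  for (ch in unique(hm$chrom)) {
    vi <- which(hm$chrom == ch)
    win <- snp_windows(length(vi), window_size, step)
    for (w in seq_len(nrow(win))) {
      idx <- vi[win$start[w]:win$end[w]]
      row <- list(chrom = ch, start_bp = hm$pos[idx[1]],
                  end_bp = hm$pos[idx[length(idx)]])
      for (l in use) {
        Hl <- hm$H[idx, cohorts == l, drop = FALSE]
        g <- garud_h(Hl)
        row[[paste0("h1_", l)]] <- g$h1
        row[[paste0("h12_", l)]] <- g$h12
        row[[paste0("h123_", l)]] <- g$h123
        row[[paste0("h2h1_", l)]] <- g$h2_h1
      }
      if (length(use) > 1L) {
        pr <- utils::combn(use, 2L)
        for (k in seq_len(ncol(pr))) {
          row[[paste0("h1x_", pr[1, k], "_", pr[2, k])]] <-
            h1x(hm$H[idx, cohorts == pr[1, k], drop = FALSE],
                hm$H[idx, cohorts == pr[2, k], drop = FALSE])
        }
      }
      out[[length(out) + 1L]] <- as.data.frame(row)
    }
  }
  do.call(rbind, out)
}
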