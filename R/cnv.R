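#' Coverage track container
#'
#' Read-depth counts in fixed-width (300 bp) windows for one sample, with
#' the GC fraction of each window; after [normalize_coverage()] the track
#' also carries coverage on the copy-number scale (diploid baseline = 2).
#'
#' @param chrom,window_start per-window chromosome and 1-based start.
#' @param count raw read count per window.
#' @param gc GC fraction per window in [0, 1].
#' @param sample_id sample identifier.
#' @param window_bp window width (default 300).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, window_start, count, gc,
                           sample_id = "S1", window_bp = 300) {
  stopifnot(length(window_start) == length(count), length(count) == length(gc))
  structure(list(chrom = as.character(chrom),
                 window_start = as.integer(window_start),
                 count = as.numeric(count), gc = as.numeric(gc),
                 normalized = NULL, sample_id = sample_id,
                 window_bp = as.integer(window_bp)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$count), "windows of", x$window_bp, "bp",
      if (!is.null(x$normalized)) "(normalized)" else "(raw)", "\n")
  invisible(x)
}

#' Normalize coverage for nucleotide-composition bias
#'
#' Windows are binned by GC fraction in 2% bins; each count is divided by
#' its bin's median count and multiplied by 2, putting coverage on the
#' copy-number scale with a diploid baseline of 2. Bins with fewer than
#' `min_bin` windows (or a zero median) fall back to the global median.
#'
#' @param track a raw [coverage_track()].
#' @param gc_bin_width bin width on the GC fraction scale (default 0.02).
#' @param min_bin minimum windows for a bin-specific median (default 10).
#' @return The track with `normalized` filled in.
#' @export
normalize_coverage <- function(track, gc_bin_width = 0.02, min_bin = 10) {
  if (all(track$count == 0)) stop("all-zero coverage track")
  bin <- floor(track$gc / gc_bin_width)
  global_med <- stats::median(track$count)
  med <- vapply(split(track$count, bin), function(x) {
    if (length(x) < min_bin) return(NA_real_)
    stats::median(x)
  }, 0)
  med[is.na(med) | med == 0] <- global_med
  track$normalized <- unname(2 * track$count / med[as.character(bin)])
  track
}

#' Copy-number inference with a 13-state coverage HMM
#'
#' Viterbi decoding of normalized coverage over hidden copy-number states
#' 0..12 (up to a 6-fold amplification, i.e. 10 extra copies; higher true
#' copy numbers are capped at state 12). Emissions are Gaussian with mean
#' equal to the state's copy number and a shared standard deviation,
#' estimated by default as the scaled median absolute deviation of the
#' normalized coverage around the diploid baseline of 2. The transition
#' matrix keeps probability `transition_stay` on the current state and
#' splits the remainder equally over the other 12 states; the initial
#' distribution is uniform.
#'
#' @param track a normalized [coverage_track()].
#' @param transition_stay per-window probability of keeping the current
#'   state (default 0.99995, about one spurious transition per 6 Mb of
#'   300 bp windows).
#' @param emission_sd shared emission standard deviation; estimated from
#'   the track when NULL.
#' @param blacklist optional logical vector of windows to exclude from
#'   decoding (their states are interpolated as the surrounding segment).
#' @return List of class `copy_number_path`: `state` per window (0..12),
#'   `segments` (start/end window index, chrom, copy, mean normalized
#'   coverage), `emission_sd`.
#' @export
cnv_hmm <- function(track, transition_stay = 0.99995, emission_sd = NULL,
                    blacklist = NULL) {
  if (is.null(track$normalized)) track <- normalize_coverage(track)
  x <- track$normalized
  keep <- if (is.null(blacklist)) rep(TRUE, length(x)) else !blacklist
  if (is.null(emission_sd)) {
    emission_sd <- stats::mad(x[keep], center = 2)
    if (emission_sd == 0) emission_sd <- 0.25
  }
  if (emission_sd <= 0) stop("emission_sd must be positive")
  states <- 0:12
  path_kept <- viterbi_gaussian(x[keep], states, emission_sd,
                                log(transition_stay),
                                log((1 - transition_stay) / (length(states) - 1)))
  state <- rep(NA_integer_, length(x))
  state[keep] <- path_kept
  if (any(!keep)) state <- round(stats::approx(which(keep), path_kept,
                                               xout = seq_along(x),
                                               rule = 2)$y)
  chg <- c(TRUE, state[-1] != state[-length(state)] |
                  track$chrom[-1] != track$chrom[-length(state)])
  grp <- cumsum(chg)
  segments <- data.frame(
    chrom = track$chrom[chg],
    start_window = as.integer(tapply(seq_along(state), grp, min)),
    end_window = as.integer(tapply(seq_along(state), grp, max)),
    copy = state[chg],
    mean_coverage = as.numeric(tapply(x, grp, mean)))
  structure(list(state = state, segments = segments,
                 emission_sd = emission_sd),
            class = "copy_number_path")
}

# log-space Viterbi with Gaussian emissions and symmetric-stay transitions
viterbi_gaussian <- function(x, states, sd, log_stay, log_move) {
  n <- length(x); k <- length(states)
  em <- vapply(states, function(s) stats::dnorm(x, s, sd, log = TRUE),
               numeric(n))
  if (n == 1L) return(states[which.max(em[1, ])])
  delta <- matrix(-Inf, n, k)
  psi <- matrix(0L, n, k)
  delta[1, ] <- -log(k) + em[1, ]
  for (t in 2:n) {
    for (j in seq_len(k)) {
      cand <- delta[t - 1, ] + ifelse(seq_len(k) == j, log_stay, log_move)
      psi[t, j] <- which.max(cand)
      delta[t, j] <- cand[psi[t, j]] + em[t, j]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  states[path]
}

#' Gene-level copy-number calls
#'
#' The copy number of a gene is the modal HMM state over the 300 bp
#' windows overlapping it; the gene is flagged amplified when states
#' above 2 cover at least `min_overlap` of its windows (ties amplify).
#'
#' @param path a [cnv_hmm()] result.
#' @param track the decoded [coverage_track()] (for window coordinates).
#' @param gene_regions data frame with `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param min_overlap minimum amplified-window fraction (default 0.5).
#' @return Data frame per gene: `gene`, `copy` (NA with a warning when no
#'   window overlaps), `frac_amplified`, `amplified`.
#' @export
gene_cnv_calls <- function(path, track, gene_regions, min_overlap = 0.5) {
  out <- lapply(seq_len(nrow(gene_regions)), function(i) {
    g <- gene_regions[i, ]
    w_end <- track$window_start + track$window_bp - 1L
    hit <- track$chrom == g$chrom & w_end >= g$start &
           track$window_start <= g$end
    if (!any(hit)) {
      warning("gene ", g$gene, " overlaps no coverage window")
      return(data.frame(gene = g$gene, copy = NA_integer_,
                        frac_amplified = NA_real_, amplified = NA))
    }
    st <- path$state[hit]
    tab <- table(st)
    copy <- as.integer(names(tab)[which.max(tab)])
    frac <- mean(st > 2L)
    data.frame(gene = g$gene, copy = copy, frac_amplified = frac,
               amplified = frac >= min_overlap)
  })
  do.call(rbind, out)
}

#' Amplification frequency of a gene across samples
#'
#' @param calls_by_sample list (or rbind-ed data frame with `sample_id`)
#'   of [gene_cnv_calls()] outputs.
#' @param gene gene name.
#' @return Fraction of samples with the amplified flag set.
#' @export
cnv_frequency <- function(calls_by_sample, gene) {
  if (is.data.frame(calls_by_sample)) {
    calls <- calls_by_sample[calls_by_sample$gene == gene, ]
    if (nrow(calls) == 0L) stop("no calls for gene ", gene)
    return(mean(calls$amplified))
  }
  flags <- vapply(calls_by_sample, function(cl)
    cl$amplified[cl$gene == gene], TRUE)
  mean(flags)
}
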