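# Local-score genome scan: per-SNP scores X_i = -log10(p_i) - xi are
# accumulated along a chromosome by the Lindley recursion H_i = max(0,
# H_{i-1} + X_i); excursions whose peak exceeds a Monte-Carlo significance
# threshold are called as candidate regions. Also provides a pi0 estimate
# on distance-thinned SNPs.

#' Lindley local-score track for one chromosome
#'
#' Scores each SNP as X = -log10(p) - xi, so a SNP contributes positively
#' exactly when p < 10^-xi (xi = 1: p < 0.1; xi = 2: p < 0.01), and runs
#' the Lindley recursion. The running maximum of H equals the best
#' contiguous-segment score sum.
#'
#' @param pvalues per-SNP p-values in (0, 1\], ordered by position along one
#'   chromosome; exact zeros are clamped to the smallest representable
#'   positive double with a warning.
#' @param xi aggregation threshold (default 1).
#' @param positions optional 1-based coordinates (strictly increasing);
#'   defaults to the SNP index.
#' @param chrom chromosome name carried into the track.
#' @return a \code{lindley_track} list: \code{chrom}, \code{positions},
#'   \code{pvalues}, \code{scores}, \code{heights}, \code{xi},
#'   \code{sig_threshold} (NA until set).
#' @export
lindley <- function(pvalues, xi = 1, positions = NULL, chrom = NA_character_) {
  stopifnot(all(pvalues >= 0), all(pvalues <= 1))
  if (any(pvalues == 0)) {
    warning("p-values of exactly 0 clamped to the smallest positive double")
    pvalues[pvalues == 0] <- .Machine$double.xmin
  }
  if (is.null(positions)) positions <- seq_along(pvalues)
  stopifnot(length(positions) == length(pvalues),
            !is.unsorted(positions, strictly = TRUE))
  x <- -log10(pvalues) - xi
  s <- cumsum(x)
  heights <- s - pmin(0, cummin(s))   # H_i = S_i - min_{0<=j<=i} S_j
  structure(list(chrom = chrom, positions = positions, pvalues = pvalues,
                 scores = x, heights = heights, xi = xi,
                 sig_threshold = NA_real_),
            class = "lindley_track")
}

#' Monte-Carlo significance threshold for the local score
#'
#' Simulates chromosomes of \code{n_sites} i.i.d. uniform p-values and
#' returns the (1 - alpha) quantile of the maximal Lindley height, i.e. a
#' chromosome-wise threshold with family-wise level alpha under the
#' independent-null model. On LD-correlated data this independence
#' assumption makes the threshold only approximate.
#'
#' @param n_sites number of SNPs on the chromosome.
#' @param xi aggregation threshold.
#' @param alpha chromosome-wise significance level (default 0.05).
#' @param reps Monte-Carlo replicates (default 1000).
#' @param seed optional RNG seed for reproducibility.
#' @return the height threshold (alpha >= 1 gives 0: every excursion
#'   significant).
#' @export
mc_threshold <- function(n_sites, xi = 1, alpha = 0.05, reps = 1000,
                         seed = NULL) {
  stopifnot(n_sites >= 1, reps >= 1, alpha > 0)
  if (alpha >= 1) return(0)
  maxima <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      max(lindley(stats::runif(n_sites), xi = xi)$heights)
    }, numeric(1))
  })
  unname(stats::quantile(maxima, probs = 1 - alpha))
}

#' Call significant regions from a Lindley track
#'
#' Each maximal excursion (run of H > 0) whose peak exceeds the threshold
#' yields one region spanning the first SNP of the excursion to the SNP
#' achieving the excursion maximum (first maximum on ties); this is the
#' segment realising the maximal score. The full excursion extent is
#' reported as metadata.
#'
#' @param track a \code{lindley_track}.
#' @param sig_threshold height cutoff; defaults to the track's stored
#'   threshold.
#' @return data.frame of regions: \code{chrom}, \code{start}, \code{end}
#'   (1-based inclusive SNP coordinates), \code{peak_height},
#'   \code{n_snps}, \code{excursion_start}, \code{excursion_end}.
#' @export
call_regions <- function(track, sig_threshold = track$sig_threshold) {
  stopifnot(inherits(track, "lindley_track"))
  if (is.na(sig_threshold)) stop("no significance threshold set")
  h <- track$heights
  pos <- track$positions
  runs <- rle(h > 0)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (r in which(runs$values)) {
    i0 <- starts[r]; i1 <- ends[r]
    seg <- h[i0:i1]
    peak <- max(seg)
    if (peak <= sig_threshold) next
    ipk <- i0 + which.max(seg) - 1L
    out[[length(out) + 1L]] <- data.frame(
      chrom = track$chrom, start = pos[i0], end = pos[ipk],
      peak_height = peak, n_snps = ipk - i0 + 1L,
      excursion_start = pos[i0], excursion_end = pos[i1],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), peak_height = numeric(),
                      n_snps = integer(), excursion_start = numeric(),
                      excursion_end = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write called regions as a BED file
#'
#' Converts 1-based inclusive region coordinates to BED's 0-based
#' half-open convention.
#'
#' @param regions data.frame from [call_regions()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
regions_to_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = as.integer(regions$start) - 1L,
                    end = as.integer(regions$end),
                    name = sprintf("region_%d", seq_len(nrow(regions))),
                    score = regions$peak_height)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Estimate the null proportion pi0 on distance-thinned SNPs
#'
#' Greedily thins SNPs left-to-right within each chromosome so that kept
#' SNPs are at least \code{min_gap} apart (reducing p-value correlation due
#' to linkage), then applies the standard lambda-threshold estimator
#' pi0 = #\{p > lambda\} / ((1 - lambda) m), capped at 1.
#'
#' @param pvalues per-SNP p-values.
#' @param chrom,positions per-SNP chromosome and position (positions sorted
#'   within chromosome).
#' @param min_gap minimum distance between kept SNPs in bp (default 5e5).
#' @param lambda tuning threshold (default 0.5).
#' @return list: \code{pi0}, \code{m_thinned}, \code{kept} (logical index).
#' @export
estimate_pi0 <- function(pvalues, chrom = rep("1", length(pvalues)),
                         positions = seq_along(pvalues), min_gap = 5e5,
                         lambda = 0.5) {
  stopifnot(length(chrom) == length(pvalues),
            length(positions) == length(pvalues),
            lambda > 0, lambda < 1)
  kept <- logical(length(pvalues))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    idx <- idx[order(positions[idx])]
    last <- -Inf
    for (i in idx) {
      if (positions[i] - last >= min_gap) {
        kept[i] <- TRUE
        last <- positions[i]
      }
    }
  }
  m <- sum(kept)
  if (m < 10) warning("fewer than 10 SNPs remain after thinning")
  pi0 <- min(1, sum(pvalues[kept] > lambda) / ((1 - lambda) * m))
  list(pi0 = pi0, m_thinned = m, kept = kept)
}
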