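# Intersexual F_ST (Weir & Cockerham 1984 theta-hat between the male and
# female cohorts), matched-null region resampling, and recombination-rate
# quartile enrichment tests.

# Two-population W&C variance components from per-population diploid sample
# sizes, alt-allele frequencies and observed heterozygosity proportions.
# Vectorised over sites.
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  list(a = a, b = b, c = c_)
}

#' Weir-Cockerham F_ST between two cohorts at one or more SNPs
#'
#' Computes the 1984 theta-hat estimator from per-sex diploid genotype
#' counts. Negative estimates are reported as-is (preserving a null mean
#' near zero); sites monomorphic in both cohorts have an undefined
#' denominator and are returned as NA with \code{undefined = TRUE}.
#'
#' @param counts_male,counts_female numeric matrices (sites x 3) or
#'   length-3 vectors of genotype counts in the order (AA, AB, BB), i.e.
#'   (ref-hom, het, alt-hom). At least 2 individuals per cohort per site.
#' @return data.frame: \code{theta}, \code{a}, \code{b}, \code{c},
#'   \code{n_male}, \code{n_female}, \code{p_male}, \code{p_female},
#'   \code{undefined}.
#' @export
wc_fst <- function(counts_male, counts_female) {
  if (is.null(dim(counts_male))) counts_male <- matrix(counts_male, nrow = 1)
  if (is.null(dim(counts_female))) counts_female <- matrix(counts_female, nrow = 1)
  stopifnot(ncol(counts_male) == 3, ncol(counts_female) == 3,
            nrow(counts_male) == nrow(counts_female),
            all(counts_male >= 0), all(counts_female >= 0))
  n1 <- rowSums(counts_male)
  n2 <- rowSums(counts_female)
  if (any(n1 < 2) || any(n2 < 2)) {
    stop("each cohort needs at least 2 diploid individuals per site")
  }
  p1 <- (counts_male[, 2] + 2 * counts_male[, 3]) / (2 * n1)
  p2 <- (counts_female[, 2] + 2 * counts_female[, 3]) / (2 * n2)
  h1 <- counts_male[, 2] / n1
  h2 <- counts_female[, 2] / n2
  comp <- wc_components(n1, p1, h1, n2, p2, h2)
  denom <- comp$a + comp$b + comp$c
  undef <- abs(denom) < .Machine$double.eps * 8
  theta <- ifelse(undef, NA_real_, comp$a / denom)
  data.frame(theta = theta, a = comp$a, b = comp$b, c = comp$c,
             n_male = n1, n_female = n2, p_male = p1, p_female = p2,
             undefined = undef)
}

#' @rdname wc_fst
#' @param counts_male_x for X-linked sites, a sites x 2 matrix (or length-2
#'   vector) of male hemizygous allele counts (A, B); males are treated as
#'   haploid: their allele counts enter the frequency terms with sample
#'   size = number of males, and the heterozygosity component comes from
#'   females only. This haploid-male treatment departs from the strictly
#'   diploid 1984 estimator and is flagged here as nonstandard.
#' @export
wc_fst_x <- function(counts_male_x, counts_female) {
  if (is.null(dim(counts_male_x))) counts_male_x <- matrix(counts_male_x, nrow = 1)
  if (is.null(dim(counts_female))) counts_female <- matrix(counts_female, nrow = 1)
  stopifnot(ncol(counts_male_x) == 2, ncol(counts_female) == 3)
  n1 <- rowSums(counts_male_x)
  n2 <- rowSums(counts_female)
  if (any(n1 < 2) || any(n2 < 2)) {
    stop("each cohort needs at least 2 individuals per site")
  }
  p1 <- counts_male_x[, 2] / n1
  p2 <- (counts_female[, 2] + 2 * counts_female[, 3]) / (2 * n2)
  h2 <- counts_female[, 2] / n2
  comp <- wc_components(n1, p1, 0, n2, p2, h2)
  denom <- comp$a + comp$b + comp$c
  undef <- abs(denom) < .Machine$double.eps * 8
  theta <- ifelse(undef, NA_real_, comp$a / denom)
  data.frame(theta = theta, a = comp$a, b = comp$b, c = comp$c,
             n_male = n1, n_female = n2, p_male = p1, p_female = p2,
             undefined = undef)
}

#' Per-site intersexual F_ST from a genotype matrix
#'
#' Convenience wrapper tabulating per-sex genotype counts from a dosage
#' matrix and applying [wc_fst()] (autosomes) or [wc_fst_x()] (X sites,
#' haploid males).
#'
#' @param genotypes numeric dosage matrix (0/1/2, NA missing), sites in
#'   rows, samples in columns.
#' @param sexes per-sample \code{"male"}/\code{"female"}.
#' @param chrom optional per-site chromosome names (X detected by name);
#'   default treats all sites as autosomal.
#' @return data.frame as from [wc_fst()], plus \code{chrom} if given.
#' @export
intersexual_fst <- function(genotypes, sexes,
                            chrom = rep("1", nrow(genotypes))) {
  stopifnot(is.matrix(genotypes), length(sexes) == ncol(genotypes),
            length(chrom) == nrow(genotypes))
  male <- sexes == "male"
  tab3 <- function(m) {
    cbind(rowSums(m == 0, na.rm = TRUE), rowSums(m == 1, na.rm = TRUE),
          rowSums(m == 2, na.rm = TRUE))
  }
  gm <- genotypes[, male, drop = FALSE]
  gf <- genotypes[, !male, drop = FALSE]
  is_x <- is_x_chrom(chrom)
  template <- wc_fst(matrix(c(1, 1, 0), 1), matrix(c(1, 1, 0), 1))[0, ]
  res <- as.data.frame(lapply(template, function(col) {
    rep(if (is.logical(col)) NA else NA_real_, nrow(genotypes))
  }))
  if (any(!is_x)) {
    res[!is_x, ] <- wc_fst(tab3(gm[!is_x, , drop = FALSE]),
                           tab3(gf[!is_x, , drop = FALSE]))
  }
  if (any(is_x)) {
    mx <- gm[is_x, , drop = FALSE]
    # haploid male calls coded 0/2 -> allele counts; het (1) treated missing
    allele_counts <- cbind(rowSums(mx == 0, na.rm = TRUE),
                           rowSums(mx == 2, na.rm = TRUE))
    res[is_x, ] <- wc_fst_x(allele_counts, tab3(gf[is_x, , drop = FALSE]))
  }
  res$chrom <- chrom
  rownames(res) <- NULL
  res
}

#' Sample a feature-matched null set of genomic regions
#'
#' For each target region, draws pool regions whose features all fall
#' within a multiplicative tolerance of the target's, giving an empirical
#' null matched on region length, SNP count, diversity, etc.
#'
#' @param targets,pool data.frames of region features; matching uses the
#'   columns named in \code{features}.
#' @param features feature columns to match on (default
#'   \code{c("length", "n_snps", "diversity")}).
#' @param n_draws matched draws per target (default 1; sampled with
#'   replacement).
#' @param tol multiplicative tolerance: pool feature within
#'   \[f (1 - tol), f (1 + tol)\] of the target's (default 0.2).
#' @param seed optional RNG seed.
#' @return list: \code{draws} (data.frame with \code{target} index,
#'   \code{pool_row}, and the pool features), \code{unmatched} (target
#'   indices with no eligible pool region).
#' @export
matched_null_sample <- function(targets, pool,
                                features = c("length", "n_snps", "diversity"),
                                n_draws = 1, tol = 0.2, seed = NULL) {
  stopifnot(all(features %in% names(targets)),
            all(features %in% names(pool)), nrow(pool) > nrow(targets))
  draws <- list()
  unmatched <- integer(0)
  with_seed(seed, {
    for (i in seq_len(nrow(targets))) {
      ok <- rep(TRUE, nrow(pool))
      for (f in features) {
        tv <- targets[[f]][i]
        lo <- min(tv * (1 - tol), tv * (1 + tol))
        hi <- max(tv * (1 - tol), tv * (1 + tol))
        ok <- ok & pool[[f]] >= lo & pool[[f]] <= hi
      }
      if (!any(ok)) {
        unmatched <- c(unmatched, i)
        next
      }
      rows <- sample(which(ok), n_draws, replace = TRUE)
      draws[[length(draws) + 1L]] <- cbind(
        data.frame(target = i, pool_row = rows),
        pool[rows, features, drop = FALSE])
    }
  })
  draws_df <- if (length(draws)) do.call(rbind, draws) else
    cbind(data.frame(target = integer(0), pool_row = integer(0)),
          pool[0, features, drop = FALSE])
  rownames(draws_df) <- NULL
  list(draws = draws_df, unmatched = unmatched)
}

#' Quartile enrichment of region values against a genomic null
#'
#' Splits the genomic null distribution into quartiles and tests, per
#' quartile, whether the observed number of regions departs from the null
#' expectation of 25% with a two-sided exact binomial test.
#'
#' @param region_values per-region values (e.g. mean recombination rate).
#' @param genome_values null distribution of the same quantity over
#'   matched genomic windows.
#' @return data.frame per quartile: \code{quartile}, \code{lower},
#'   \code{upper}, \code{observed}, \code{expected}, \code{direction}
#'   (\code{"+"} excess / \code{"-"} deficit), \code{p_value}.
#' @export
quartile_enrichment <- function(region_values, genome_values) {
  stopifnot(length(genome_values) > 0, length(region_values) > 0)
  qs <- stats::quantile(genome_values, c(0.25, 0.5, 0.75))
  breaks <- c(-Inf, qs, Inf)
  bin <- cut(region_values, breaks = breaks, labels = FALSE,
             include.lowest = TRUE)
  n <- length(region_values)
  obs <- tabulate(bin, nbins = 4L)
  res <- lapply(1:4, function(q) {
    data.frame(
      quartile = q, lower = breaks[q], upper = breaks[q + 1],
      observed = obs[q], expected = n / 4,
      direction = ifelse(obs[q] >= n / 4, "+", "-"),
      p_value = stats::binom.test(obs[q], n, p = 0.25,
                                  alternative = "two.sided")$p.value,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
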