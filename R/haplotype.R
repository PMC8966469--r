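# Candidate-region follow-up on pre-phased haplotypes: allele-sharing
# distances, classical MDS, density clustering, sex-biased transmission
# tests and a Mantel test for sex structure. Phasing itself is upstream.

#' Allele-sharing distance matrix
#'
#' Haplotype mode: proportion of mismatching sites among pairwise shared
#' (non-missing) sites — a normalised Hamming distance. Genotype mode: mean
#' |g1 - g2| / 2 over shared sites. Values lie in \[0, 1\] with a zero
#' diagonal.
#'
#' @param x numeric matrix, sites in rows, entities (haplotypes or
#'   individuals) in columns; alleles 0/1 (haplotype mode) or dosages 0/1/2
#'   (genotype mode); NA = missing.
#' @param mode \code{"haplotype"} or \code{"genotype"}.
#' @return symmetric distance matrix (entities x entities).
#' @export
asd_matrix <- function(x, mode = c("haplotype", "genotype")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(x), ncol(x) >= 2)
  obs <- !is.na(x)
  shared <- crossprod(obs)
  off <- shared[upper.tri(shared)]
  if (any(off == 0)) {
    idx <- which(upper.tri(shared) & shared == 0, arr.ind = TRUE)[1, ]
    nm <- colnames(x) %||% as.character(seq_len(ncol(x)))
    stop("no shared non-missing sites between ", nm[idx[1]], " and ",
         nm[idx[2]])
  }
  vals <- if (mode == "haplotype") 0:1 else 0:2
  ind <- lapply(vals, function(v) {
    m <- (x == v) & obs
    m[is.na(m)] <- FALSE
    storage.mode(m) <- "numeric"
    m
  })
  diff_sum <- matrix(0, ncol(x), ncol(x))
  for (a in seq_along(vals)) for (b in seq_along(vals)) {
    w <- abs(vals[a] - vals[b])
    if (w > 0) diff_sum <- diff_sum + w * crossprod(ind[[a]], ind[[b]])
  }
  d <- diff_sum / shared
  if (mode == "genotype") d <- d / 2
  diag(d) <- 0
  dimnames(d) <- list(colnames(x), colnames(x))
  d
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centers the squared-distance matrix and embeds the points along
#' the leading eigenvectors (via \code{stats::cmdscale}). Dimensions with
#' non-positive eigenvalues are dropped with a warning and the requested
#' dimensionality reduced accordingly.
#'
#' @param d square symmetric distance matrix with zero diagonal.
#' @param n_dims number of output dimensions (default 2).
#' @return coordinate matrix (entities x <= n_dims), eigenvalues as the
#'   \code{"eig"} attribute.
#' @export
classical_mds <- function(d, n_dims = 2) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), all(abs(d - t(d)) < 1e-12),
            all(abs(diag(d)) < 1e-12))
  n <- nrow(d)
  # cmdscale's own eigenvalue warning is replaced by the message below
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d),
                                          k = min(n_dims, n - 1),
                                          eig = TRUE))
  pos <- sum(fit$eig > 1e-12)
  if (pos < n_dims) {
    warning("only ", pos, " positive eigenvalue(s); returning ", pos,
            " dimension(s)")
  }
  k <- max(0L, min(n_dims, pos))
  coords <- if (k == 0 || length(fit$points) == 0) {
    matrix(0, n, max(1L, n_dims))   # degenerate: all points coincide
  } else {
    fit$points[, seq_len(k), drop = FALSE]
  }
  rownames(coords) <- rownames(d)
  attr(coords, "eig") <- fit$eig
  coords
}

#' Density-based clustering (DBSCAN)
#'
#' Classic DBSCAN on Euclidean coordinates: points with at least
#' \code{min_pts} neighbours within \code{eps} (self included) are core
#' points; clusters grow by density reachability; remaining points are
#' noise (label 0). Border points reachable from several clusters join the
#' first cluster discovered, so labels are deterministic given input order.
#'
#' @param coords numeric matrix, points in rows.
#' @param eps neighbourhood radius.
#' @param min_pts density threshold (>= 2).
#' @return integer cluster labels (0 = noise).
#' @export
density_cluster <- function(coords, eps, min_pts) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(eps > 0, min_pts >= 2, n >= min_pts)
  d <- as.matrix(stats::dist(coords))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_pts
  labels <- integer(n)   # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nbrs[[i]], i)
    while (length(queue)) {
      j <- queue[1L]
      queue <- queue[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, setdiff(nbrs[[j]],
                                               which(labels != 0L)))
      }
    }
  }
  labels
}

#' Resolve which parental haplotype was transmitted in each trio
#'
#' For each trio, assigns the child's two phased haplotypes to the father
#' and the mother by the pairing that minimises total mismatch, then
#' records, for each parent, which of that parent's two haplotypes is
#' closer to the child haplotype inherited from them. X-linked sons carry
#' one (maternal) haplotype only.
#'
#' @param haps 0/1 haplotype matrix, sites x haplotypes.
#' @param carriers data.frame describing the columns of \code{haps}:
#'   \code{sample}, \code{sex}, plus anything else; diploid samples own two
#'   columns, male-X samples one.
#' @param ped a \code{trio_set}.
#' @param labels optional per-haplotype cluster labels (as from
#'   [density_cluster()] on the haplotype MDS) attached to the output.
#' @return data.frame, one row per resolved parental transmission:
#'   \code{family_id}, \code{parent_role}, \code{child_sex},
#'   \code{transmitted_col}, \code{untransmitted_col} and, with
#'   \code{labels}, \code{transmitted_label} / \code{untransmitted_label}.
#' @export
resolve_transmissions <- function(haps, carriers, ped, labels = NULL) {
  stopifnot(ncol(haps) == nrow(carriers))
  cols_of <- function(id) which(carriers$sample == id)
  mism <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(Inf)
    mean(a[ok] != b[ok])
  }
  rows <- list()
  for (i in seq_len(nrow(ped))) {
    fc <- cols_of(ped$father_id[i])
    mc <- cols_of(ped$mother_id[i])
    cc <- cols_of(ped$child_id[i])
    if (!length(fc) || !length(mc) || !length(cc)) next
    pick <- function(parent_cols, child_col) {
      dists <- vapply(parent_cols, function(pc)
        mism(haps[, pc], haps[, child_col]), numeric(1))
      parent_cols[which.min(dists)]
    }
    add <- function(role, parent_cols, child_col) {
      tr <- pick(parent_cols, child_col)
      rows[[length(rows) + 1L]] <<- data.frame(
        family_id = ped$family_id[i], parent_role = role,
        child_sex = ped$child_sex[i], transmitted_col = tr,
        untransmitted_col = if (length(parent_cols) == 2)
          setdiff(parent_cols, tr) else NA_integer_,
        stringsAsFactors = FALSE)
    }
    if (length(cc) == 1L) {
      # X-linked son: single maternal haplotype
      add("mother", mc, cc)
    } else {
      # assign the child pair to (father, mother) minimising total mismatch
      d_f <- vapply(cc, function(x) min(vapply(fc, function(pc)
        mism(haps[, pc], haps[, x]), numeric(1))), numeric(1))
      d_m <- vapply(cc, function(x) min(vapply(mc, function(pc)
        mism(haps[, pc], haps[, x]), numeric(1))), numeric(1))
      if (d_f[1] + d_m[2] <= d_f[2] + d_m[1]) {
        pat_col <- cc[1]; mat_col <- cc[2]
      } else {
        pat_col <- cc[2]; mat_col <- cc[1]
      }
      add("father", fc, pat_col)
      add("mother", mc, mat_col)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(labels)) {
    out$transmitted_label <- labels[out$transmitted_col]
    out$untransmitted_label <- labels[out$untransmitted_col]
  }
  rownames(out) <- NULL
  out
}

#' Sex-biased haplotype-transmission tests
#'
#' For each haplotype class h, restricts to parents heterozygous h/other
#' (one transmitted or untransmitted haplotype labelled h, the other not)
#' and asks whether transmissions of h are biased by offspring sex:
#' a two-sided exact binomial test on the son-fraction among
#' h-transmissions against the son-fraction among all transmissions from
#' such parents (H0: transmission does not depend on offspring sex), and a
#' two-sided Fisher exact test on the 2x2 table (transmitted h vs other) x
#' (son vs daughter).
#'
#' @param trans data.frame from [resolve_transmissions()] with
#'   \code{transmitted_label}, \code{untransmitted_label},
#'   \code{child_sex}; rows with a missing untransmitted label
#'   (hemizygous transmissions) are used only when both labels are known.
#' @param p0 optional fixed H0 son-fraction overriding the observed one
#'   (e.g. 0.5 for an even split).
#' @return data.frame per haplotype class: counts of h/other transmissions
#'   to sons/daughters, \code{p0} used, \code{binom_p}, \code{fisher_p}.
#'   Classes with no informative parent are omitted and listed in the
#'   \code{"skipped"} attribute.
#' @export
haplotype_transmission_tests <- function(trans, p0 = NULL) {
  ok <- !is.na(trans$transmitted_label) & !is.na(trans$untransmitted_label)
  trans <- trans[ok, , drop = FALSE]
  classes <- sort(unique(c(trans$transmitted_label,
                           trans$untransmitted_label)))
  classes <- classes[classes != 0]   # drop DBSCAN noise
  out <- list()
  skipped <- c()
  for (h in classes) {
    het <- xor(trans$transmitted_label == h, trans$untransmitted_label == h)
    sub <- trans[het, , drop = FALSE]
    if (nrow(sub) == 0) {
      skipped <- c(skipped, h)
      next
    }
    t_h <- sub$transmitted_label == h
    son <- sub$child_sex == "male"
    a <- sum(t_h & son); b <- sum(t_h & !son)
    c_ <- sum(!t_h & son); d <- sum(!t_h & !son)
    p0_h <- p0 %||% ((a + c_) / (a + b + c_ + d))
    binom_p <- if ((a + b) > 0 && p0_h > 0 && p0_h < 1) {
      stats::binom.test(a, a + b, p = p0_h,
                        alternative = "two.sided")$p.value
    } else NA_real_
    fisher_p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2,
                                          byrow = TRUE))$p.value
    out[[length(out) + 1L]] <- data.frame(
      haplotype = h, n_informative = nrow(sub),
      h_to_sons = a, h_to_daughters = b,
      other_to_sons = c_, other_to_daughters = d,
      p0 = p0_h, binom_p = binom_p, fisher_p = fisher_p)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(haplotype = integer(0), n_informative = integer(0),
               h_to_sons = integer(0), h_to_daughters = integer(0),
               other_to_sons = integer(0), other_to_daughters = integer(0),
               p0 = numeric(0), binom_p = numeric(0), fisher_p = numeric(0))
  if (length(skipped)) {
    message("haplotype class(es) with no informative parent skipped: ",
            paste(skipped, collapse = ", "))
    attr(res, "skipped") <- skipped
  }
  res
}

#' Two-sided exact binomial test for sex-biased counts
#'
#' Thin wrapper around \code{stats::binom.test} for carrier sex-bias and
#' transmission-count questions, e.g. "of 34 maternal transmissions, 24
#' went to one haplotype — is that compatible with an even split?".
#'
#' @param k observed successes (e.g. male carriers, or transmissions of one
#'   haplotype).
#' @param n trials.
#' @param p0 H0 proportion (default 0.5).
#' @return list: \code{k}, \code{n}, \code{p0}, \code{estimate},
#'   \code{p_value}.
#' @export
sex_bias_binom_test <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  bt <- stats::binom.test(k, n, p = p0, alternative = "two.sided")
  list(k = k, n = n, p0 = p0, estimate = unname(bt$estimate),
       p_value = bt$p.value)
}

#' Mantel test for genetic structure by sex
#'
#' Correlates the off-diagonal entries of a genetic distance matrix with a
#' same-sex(0)/different-sex(1) indicator matrix; the permutation p-value
#' (permuting individual sex labels) is two-sided on |r|. A significant
#' correlation means within-sex distances differ from between-sex
#' distances, i.e. the cohort is genetically structured by sex.
#'
#' @param d square symmetric distance matrix.
#' @param sexes per-individual \code{"male"}/\code{"female"}.
#' @param n_perm number of permutations (default 9999).
#' @param seed optional RNG seed.
#' @return list: \code{r}, \code{p_value}, \code{n_perm}.
#' @export
mantel_sex_test <- function(d, sexes, n_perm = 9999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(ncol(d) == n, length(sexes) == n)
  if (length(unique(sexes)) < 2) {
    stop("all individuals have the same sex; indicator matrix is constant")
  }
  lower <- lower.tri(d)
  dv <- d[lower]
  ind_of <- function(s) {
    m <- outer(s, s, FUN = "!=") * 1
    m[lower]
  }
  r_obs <- stats::cor(dv, ind_of(sexes))
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stats::cor(dv, ind_of(sample(sexes)))
    }, numeric(1))
  })
  p <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm)
  list(r = r_obs, p_value = p, n_perm = n_perm)
}
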