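# Independent oracles used to validate the package implementations. Each is
# deliberately coded via a different route than the function it checks.

# Log-likelihood of sex-stratified counts at given (eps_m, eps_f), written
# directly from the Bernoulli product (mirrors the model definition, used
# only to evaluate candidate parameter values).
oracle_ll <- function(k_m, n_m, k_f, n_f, eps_m, eps_f) {
  term <- function(k, n, e) {
    out <- 0
    if (k > 0) out <- out + k * log(0.5 + e)
    if (n - k > 0) out <- out + (n - k) * log(0.5 - e)
    out
  }
  term(k_m, n_m, eps_m) + term(k_f, n_f, eps_f)
}

# Grid maximisation of the one-parameter (M1) likelihood.
oracle_grid_mle <- function(k, n, step = 1e-4) {
  grid <- seq(-0.5, 0.5, by = step)
  ll <- (if (k > 0) k * log(0.5 + grid) else 0) +
    (if (n - k > 0) (n - k) * log(0.5 - grid) else 0)
  grid[which.max(ll)]
}

# Exact null law of the 2-df LRT p-value for n_trios one-meiosis trios
# with a Bernoulli(1/2) sex split, by full enumeration. Returns the atoms
# (p-value, probability) sorted by p.
oracle_null_p20_atoms <- function(n_trios) {
  ll1 <- function(k, n) {
    e <- k / n - 0.5
    ifelse(k > 0, k * log(0.5 + e), 0) +
      ifelse(n - k > 0, (n - k) * log(0.5 - e), 0) - n * log(0.5)
  }
  ps <- dbinom(0:n_trios, n_trios, 0.5)
  keep <- which(ps > 1e-12) - 1L
  vals <- list(); wts <- list()
  for (nm in keep) {
    nf <- n_trios - nm
    dm <- if (nm > 0) 2 * ll1(0:nm, nm) else 0
    df_ <- if (nf > 0) 2 * ll1(0:nf, nf) else 0
    pm <- if (nm > 0) dbinom(0:nm, nm, 0.5) else 1
    pf <- if (nf > 0) dbinom(0:nf, nf, 0.5) else 1
    vals[[length(vals) + 1L]] <- as.vector(outer(dm, df_, "+"))
    wts[[length(wts) + 1L]] <- as.vector(outer(pm, pf)) * ps[nm + 1]
  }
  p <- pchisq(unlist(vals), df = 2, lower.tail = FALSE)
  w <- unlist(wts)
  o <- order(p)
  list(p = p[o], w = w[o] / sum(w), cum = cumsum(w[o] / sum(w)))
}

# Draw m p-values from the exact enumerated null law.
oracle_null_p20_sample <- function(atoms, m) {
  atoms$p[findInterval(runif(m), atoms$cum) + 1L]
}

# KS distance of a sample to the uniform distribution.
ks_distance <- function(x) {
  x <- sort(x)
  n <- length(x)
  max(abs(x - (seq_len(n) - 1) / n), abs(x - seq_len(n) / n))
}

# Naive best contiguous-segment score sum: one cumsum per start position.
oracle_best_segment <- function(x) {
  best <- 0
  for (s in seq_along(x)) best <- max(best, cummax(cumsum(x[s:length(x)])))
  best
}

# Brute-force Mendelian compatibility: enumerate the alleles each parent
# can contribute and check whether any pair reproduces the child genotype.
oracle_mendel_autosome <- function(f, m, c) {
  if (anyNA(c(f, m, c))) return(FALSE)
  alleles <- function(d) unique(c(floor(d / 2), ceiling(d / 2)))
  for (af in alleles(f)) for (am in alleles(m)) {
    if (af + am == c) return(FALSE)
  }
  TRUE
}

oracle_mendel_x <- function(f, m, c, sex) {
  if (sex == "male") {
    if (anyNA(c(m, c)) || !(c %in% c(0, 2))) return(FALSE)
    s <- c / 2
    !(s %in% unique(c(floor(m / 2), ceiling(m / 2))))
  } else {
    if (anyNA(c(f, c)) || !(f %in% c(0, 2))) return(FALSE)
    fa <- f / 2
    ma <- if (is.na(m)) c(0, 1) else unique(c(floor(m / 2), ceiling(m / 2)))
    !any(fa + ma == c)
  }
}

# Weir & Cockerham (1984) theta for two populations, coded independently:
# per-allele variance components summed over both alleles (for a biallelic
# locus this reduces to the single-allele form but exercises a different
# code path).
oracle_wc_theta <- function(counts1, counts2) {
  n <- c(sum(counts1), sum(counts2))
  r <- 2
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  num <- 0
  den <- 0
  for (allele in c("B", "A")) {
    if (allele == "B") {
      p <- c((counts1[2] + 2 * counts1[3]) / (2 * n[1]),
             (counts2[2] + 2 * counts2[3]) / (2 * n[2]))
    } else {
      p <- c((counts1[2] + 2 * counts1[1]) / (2 * n[1]),
             (counts2[2] + 2 * counts2[1]) / (2 * n[2]))
    }
    h <- c(counts1[2] / n[1], counts2[2] / n[2])
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) * s2 / r -
                              hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) * s2 / r -
                                (2 * nbar - 1) * hbar / (4 * nbar))
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration with the minimum-likelihood rule.
oracle_fisher_2x2 <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n2)
  hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    choose(m, x) * choose(n2, k - x) / choose(m + n2, k)
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
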