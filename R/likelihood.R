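# Per-SNP transmission likelihoods: nested models M0 (Mendelian), M1
# (uniform distortion epsilon) and M2 (sex-specific eps_m / eps_f), with
# closed-form MLEs, profile confidence intervals and LRT p-values.
#
# Each informative meiosis transmits the alternative ("B") allele with
# probability 1/2 + eps_sex, so the log-likelihood is a sum of Bernoulli
# terms; the het x het multinomial coefficient is a data-only constant and
# is omitted (it cancels in all MLEs, profile CIs and LRTs).

ll_binom <- function(k, n, eps) {
  xlogy(k, 0.5 + eps) + xlogy(n - k, 0.5 - eps)
}

#' Transmission-model log-likelihood
#'
#' Evaluates the (constant-free) log-likelihood of sex-stratified
#' transmission counts under one of the three nested models.
#'
#' @param counts list or one-row data.frame with \code{k_m}, \code{n_m},
#'   \code{k_f}, \code{n_f}.
#' @param model \code{"M0"}, \code{"M1"} or \code{"M2"}.
#' @param eps distortion parameter for M1, in \[-1/2, 1/2\].
#' @param eps_m,eps_f sex-specific distortion parameters for M2.
#' @return the log-likelihood value.
#' @export
td_loglik <- function(counts, model = c("M0", "M1", "M2"), eps = 0,
                      eps_m = 0, eps_f = 0) {
  model <- match.arg(model)
  pars <- switch(model, M0 = numeric(0), M1 = eps, M2 = c(eps_m, eps_f))
  if (any(pars < -0.5 | pars > 0.5)) {
    stop("distortion parameters must lie in [-1/2, 1/2]")
  }
  with(counts, switch(model,
    M0 = ll_binom(k_m, n_m, 0) + ll_binom(k_f, n_f, 0),
    M1 = ll_binom(k_m, n_m, eps) + ll_binom(k_f, n_f, eps),
    M2 = ll_binom(k_m, n_m, eps_m) + ll_binom(k_f, n_f, eps_f)))
}

# 95% profile interval for one binomial eps: {eps : lnL(eps) >= lnL(MLE) -
# qchisq(0.95, 1)/2}, endpoints found by bisection and clipped to [-1/2, 1/2].
profile_ci <- function(k, n, drop = stats::qchisq(0.95, 1) / 2,
                       tol = 1e-6) {
  if (n == 0) return(c(NA_real_, NA_real_))
  ehat <- k / n - 0.5
  target <- ll_binom(k, n, ehat) - drop
  g <- function(e) ll_binom(k, n, e) - target
  bisect <- function(lo, hi, lo_above) {
    # invariant: g changes sign between lo and hi
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if ((g(mid) >= 0) == lo_above) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (g(-0.5) >= 0) -0.5 else bisect(-0.5, ehat, lo_above = FALSE)
  upper <- if (g(0.5) >= 0) 0.5 else {
    r <- bisect(ehat, 0.5, lo_above = TRUE)
    r
  }
  c(max(lower, -0.5), min(upper, 0.5))
}

# Vectorised closed-form fits and LRTs; the workhorse behind fit_site(),
# td_scan() and the power simulations. Deviances are clamped at 0 against
# floating-point jitter on null data.
lrt_stats <- function(k_m, n_m, k_f, n_f) {
  n <- n_m + n_f
  k <- k_m + k_f
  eps1 <- k / n - 0.5
  eps_m <- ifelse(n_m > 0, k_m / n_m - 0.5, NA_real_)
  eps_f <- ifelse(n_f > 0, k_f / n_f - 0.5, NA_real_)
  lnL0 <- ll_binom(k, n, 0)
  lnL1 <- ll_binom(k, n, eps1)
  lnL2 <- ifelse(n_m > 0, ll_binom(k_m, n_m, ifelse(is.na(eps_m), 0, eps_m)), 0) +
    ifelse(n_f > 0, ll_binom(k_f, n_f, ifelse(is.na(eps_f), 0, eps_f)), 0)
  d10 <- pmax(0, 2 * (lnL1 - lnL0))
  d21 <- pmax(0, 2 * (lnL2 - lnL1))
  d20 <- pmax(0, 2 * (lnL2 - lnL0))
  one_sex <- n_m == 0 | n_f == 0   # M2 collapses to M1 for that site
  data.frame(
    eps1 = eps1, eps_m = eps_m, eps_f = eps_f,
    lnL0 = lnL0, lnL1 = lnL1, lnL2 = lnL2,
    d10 = d10, d20 = d20, d21 = d21,
    p10 = stats::pchisq(d10, df = 1, lower.tail = FALSE),
    p20 = stats::pchisq(d20, df = 2, lower.tail = FALSE),
    p21 = stats::pchisq(d21, df = 1, lower.tail = FALSE),
    one_sex_only = one_sex)
}

#' Fit the three transmission models at one SNP
#'
#' Closed-form maximum-likelihood fits of M0/M1/M2 to sex-stratified
#' transmission counts, with 95% profile confidence intervals (likelihood
#' drop of qchisq(0.95, 1)/2, bisection to 1e-6) and chi-square LRT
#' p-values: M1 vs M0 on 1 df, M2 vs M0 on 2 df, M2 vs M1 on 1 df.
#' Boundary MLEs (|eps| = 1/2) are allowed; a site with meioses in only one
#' sex is fitted with M2 collapsed to M1 for the missing sex and flagged
#' via \code{one_sex_only}.
#'
#' @param counts list or one-row data.frame with \code{k_m}, \code{n_m},
#'   \code{k_f}, \code{n_f} (0 <= k <= n).
#' @return one-row data.frame with MLEs (\code{eps1}, \code{eps_m},
#'   \code{eps_f}), log-likelihoods, CI bounds (\code{ci1_lo}/\code{hi},
#'   \code{cim_lo}/\code{hi}, \code{cif_lo}/\code{hi}), deviances
#'   \code{d10}/\code{d20}/\code{d21} and p-values
#'   \code{p10}/\code{p20}/\code{p21}.
#' @export
fit_site <- function(counts) {
  k_m <- counts$k_m; n_m <- counts$n_m
  k_f <- counts$k_f; n_f <- counts$n_f
  stopifnot(k_m >= 0, k_f >= 0, k_m <= n_m, k_f <= n_f)
  if (n_m + n_f == 0) stop("no informative meioses at this site")
  fit <- lrt_stats(k_m, n_m, k_f, n_f)
  ci1 <- profile_ci(k_m + k_f, n_m + n_f)
  cim <- profile_ci(k_m, n_m)
  cif <- profile_ci(k_f, n_f)
  cbind(fit,
        data.frame(ci1_lo = ci1[1], ci1_hi = ci1[2],
                   cim_lo = cim[1], cim_hi = cim[2],
                   cif_lo = cif[1], cif_hi = cif[2]))
}

#' Scan a table of transmission counts
#'
#' Applies [fit_site()] to every row of a counts table (as produced by
#' [trio_counts()] or [simulate_counts()]). Rows that cannot be fitted
#' (zero meioses) are returned with NA statistics and \code{fit_ok = FALSE}
#' rather than aborting the scan. Output order follows input order.
#'
#' @param counts data.frame with columns \code{k_m}, \code{n_m},
#'   \code{k_f}, \code{n_f}; positional columns (\code{chrom}, \code{pos},
#'   ...) are carried through.
#' @param ci compute profile confidence intervals (default TRUE; switch off
#'   for large simulation scans).
#' @return data.frame: carried-through columns plus the [fit_site()] fields.
#' @export
td_scan <- function(counts, ci = TRUE) {
  carry_cols <- intersect(
    c("chrom", "pos", "ref", "alt", "chrom_class", "n_informative_trios"),
    names(counts))
  n <- nrow(counts)
  if (n == 0) {
    out <- cbind(counts[carry_cols],
                 lrt_stats(numeric(0), numeric(0), numeric(0), numeric(0)))
    out$fit_ok <- logical(0)
    return(out)
  }
  ok <- counts$n_m + counts$n_f > 0
  fit <- lrt_stats(counts$k_m, counts$n_m, counts$k_f, counts$n_f)
  fit[!ok, ] <- NA
  fit$one_sex_only[!ok] <- NA
  if (ci) {
    cis <- t(vapply(seq_len(n), function(i) {
      if (!ok[i]) return(rep(NA_real_, 6))
      c(profile_ci(counts$k_m[i] + counts$k_f[i],
                   counts$n_m[i] + counts$n_f[i]),
        profile_ci(counts$k_m[i], counts$n_m[i]),
        profile_ci(counts$k_f[i], counts$n_f[i]))
    }, numeric(6)))
    colnames(cis) <- c("ci1_lo", "ci1_hi", "cim_lo", "cim_hi",
                       "cif_lo", "cif_hi")
    fit <- cbind(fit, as.data.frame(cis))
  }
  out <- cbind(counts[carry_cols], fit)
  out$fit_ok <- ok
  rownames(out) <- NULL
  out
}
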