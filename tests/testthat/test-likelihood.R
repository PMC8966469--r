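test_that("log-likelihoods match closed forms and reject bad parameters", {
  cts <- list(k_m = 90, n_m = 120, k_f = 30, n_f = 120)
  # M0 is N * ln(1/2) regardless of the split
  expect_equal(td_loglik(cts, "M0"), 240 * log(0.5))
  # M2 at the binomial MLEs: 180 ln(3/4) + 60 ln(1/4)
  expect_equal(td_loglik(cts, "M2", eps_m = 0.25, eps_f = -0.25),
               180 * log(0.75) + 60 * log(0.25))
  expect_equal(td_loglik(cts, "M2", eps_m = 0.25, eps_f = -0.25),
               -134.9604, tolerance = 1e-6)
  # 0 * log(0) convention at the boundary
  expect_equal(td_loglik(list(k_m = 5, n_m = 5, k_f = 0, n_f = 0),
                         "M1", eps = 0.5), 0)
  expect_error(td_loglik(cts, "M1", eps = 0.6), "\\[-1/2, 1/2\\]")
})

test_that("closed-form fits reproduce hand and grid-search oracles", {
  # null data: identical rates, zero deviance, p = 1
  f0 <- fit_site(list(k_m = 50, n_m = 100, k_f = 50, n_f = 100))
  expect_equal(f0$eps_m, 0)
  expect_equal(f0$eps_f, 0)
  expect_equal(f0$d20, 0)
  expect_equal(f0$p20, 1)

  # antagonistic counts: sex MLEs opposite, pooled MLE zero
  f1 <- fit_site(list(k_m = 90, n_m = 120, k_f = 30, n_f = 120))
  expect_equal(f1$eps_m, 0.25)
  expect_equal(f1$eps_f, -0.25)
  expect_equal(f1$eps1, 0)
  # d20 against the fine-grid maximization oracle (step 1e-5)
  grid <- seq(-0.5, 0.5, by = 1e-5)
  ll_m <- vapply(grid, function(e) oracle_ll(90, 120, 0, 0, e, 0), 0)
  ll_f <- vapply(grid, function(e) oracle_ll(0, 0, 30, 120, 0, e), 0)
  d20_oracle <- 2 * (max(ll_m) + max(ll_f) - oracle_ll(90, 120, 30, 120, 0, 0))
  expect_equal(f1$d20, d20_oracle, tolerance = 1e-6)
  expect_equal(f1$d20, 62.79, tolerance = 1e-3)

  # boundary MLEs are allowed and give a perfect-fit likelihood of 0
  fb <- fit_site(list(k_m = 80, n_m = 80, k_f = 0, n_f = 80))
  expect_equal(fb$eps_m, 0.5)
  expect_equal(fb$eps_f, -0.5)
  expect_equal(fb$lnL2, 0)

  expect_error(fit_site(list(k_m = 0, n_m = 0, k_f = 0, n_f = 0)),
               "no informative meioses")
})

test_that("MLEs beat random parameters and match grid search on random counts", {
  set.seed(1203)
  n_vec <- 1000
  ok <- TRUE
  for (i in seq_len(n_vec)) {
    n_m <- sample(10:200, 1); n_f <- sample(0:200, 1)
    k_m <- rbinom(1, n_m, runif(1)); k_f <- rbinom(1, n_f, runif(1))
    # pooled M1 MLE vs grid search
    mle <- (k_m + k_f) / (n_m + n_f) - 0.5
    ok <- ok && abs(mle - oracle_grid_mle(k_m + k_f, n_m + n_f)) <= 1e-4
  }
  expect_true(ok)

  # lnL at the M2 MLE dominates random parameter values
  set.seed(77)
  for (i in 1:50) {
    n_m <- sample(5:100, 1); n_f <- sample(5:100, 1)
    k_m <- rbinom(1, n_m, runif(1)); k_f <- rbinom(1, n_f, runif(1))
    f <- fit_site(list(k_m = k_m, n_m = n_m, k_f = k_f, n_f = n_f))
    rand <- replicate(100, oracle_ll(k_m, n_m, k_f, n_f,
                                     runif(1, -0.5, 0.5),
                                     runif(1, -0.5, 0.5)))
    expect_gte(f$lnL2, max(rand) - 1e-10)
  }
})

test_that("model nesting, sex-swap symmetry and profile CIs hold", {
  set.seed(42)
  counts <- simulate_counts(sim_config(80, model = "M2", eps_m = 0.1,
                                       eps_f = -0.2), reps = 200)
  fits <- td_scan(counts, ci = TRUE)
  # nesting: lnL0 <= lnL1 <= lnL2, deviances >= 0, p in (0, 1]
  expect_true(all(fits$lnL0 <= fits$lnL1 + 1e-10))
  expect_true(all(fits$lnL1 <= fits$lnL2 + 1e-10))
  expect_true(all(fits$d10 >= 0 & fits$d20 >= 0 & fits$d21 >= 0))
  expect_true(all(fits$p20 > 0 & fits$p20 <= 1))
  # MLEs inside their profile CIs
  expect_true(all(fits$cim_lo <= fits$eps_m & fits$eps_m <= fits$cim_hi))
  expect_true(all(fits$cif_lo <= fits$eps_f & fits$eps_f <= fits$cif_hi))
  expect_true(all(fits$cim_lo >= -0.5 & fits$cim_hi <= 0.5))
  # interior CI endpoints sit at the 1.92 drop of the profile likelihood
  drop <- qchisq(0.95, 1) / 2
  f <- fit_site(list(k_m = 90, n_m = 120, k_f = 30, n_f = 120))
  at_edge <- oracle_ll(90, 120, 0, 0, f$cim_lo, 0)
  expect_equal(oracle_ll(90, 120, 0, 0, f$eps_m, 0) - at_edge, drop,
               tolerance = 1e-4)

  # swapping sex labels swaps the sex MLEs and leaves d20 unchanged
  swapped <- td_scan(data.frame(k_m = counts$k_f, n_m = counts$n_f,
                                k_f = counts$k_m, n_f = counts$n_m),
                     ci = FALSE)
  expect_equal(swapped$eps_m, fits$eps_f)
  expect_equal(swapped$eps_f, fits$eps_m)
  expect_equal(swapped$d20, fits$d20)
})

test_that("scan streams sites, flags unfittable rows, keeps order", {
  empty <- td_scan(data.frame(k_m = numeric(0), n_m = numeric(0),
                              k_f = numeric(0), n_f = numeric(0)))
  expect_equal(nrow(empty), 0L)

  one <- data.frame(chrom = "1", pos = 42, k_m = 30, n_m = 40, k_f = 10,
                    n_f = 40)
  expect_equal(td_scan(one)$d20, fit_site(one)$d20)
  expect_equal(td_scan(one)$pos, 42)

  mixed <- data.frame(k_m = c(30, 0), n_m = c(40, 0), k_f = c(10, 0),
                      n_f = c(40, 0))
  res <- td_scan(mixed)
  expect_equal(res$fit_ok, c(TRUE, FALSE))
  expect_true(is.na(res$p20[2]))

  # a site with meioses in one sex only collapses M2 to M1 and is flagged
  onesex <- td_scan(data.frame(k_m = 30, n_m = 40, k_f = 0, n_f = 0),
                    ci = FALSE)
  expect_true(onesex$one_sex_only)
  expect_equal(onesex$d21, 0)
})

test_that("null simulation matches the exact finite-sample p-value law", {
  # The 2-df LRT p-value at 150 one-meiosis trios is discrete, and the
  # plain chi-square approximation carries an intrinsic CDF deviation from
  # uniform of up to ~0.017 (verified by exact enumeration), so the KS
  # distance to uniform is compared against its parametric-bootstrap null
  # under the enumerated exact law rather than the continuous KS reference.
  counts <- simulate_counts(sim_config(150, model = "M0"), reps = 10000,
                            seed = 555)
  fits <- td_scan(counts, ci = FALSE)
  atoms <- oracle_null_p20_atoms(150)
  d_obs <- ks_distance(fits$p20)
  set.seed(556)
  d_null <- replicate(200, ks_distance(oracle_null_p20_sample(atoms, 10000)))
  p_boot <- (1 + sum(d_null >= d_obs)) / 201
  expect_gt(p_boot, 0.01)
  # and the approximation is still near-uniform in the practical sense:
  # empirical CDF within intrinsic deviation + MC noise everywhere
  u <- seq(0.01, 0.99, by = 0.01)
  expect_lt(max(abs(ecdf(fits$p20)(u) - u)), 0.05)
})

test_that("sex-specific estimates are consistent with the binomial law", {
  eps <- 0.1
  n <- 1000
  counts <- simulate_counts(sim_config(2 * n, model = "M2", eps_m = eps,
                                       eps_f = -eps, p_male_child = 0.5),
                            reps = 500, seed = 808)
  fits <- td_scan(counts, ci = FALSE)
  expect_lt(abs(mean(fits$eps_m) - eps), 0.01)
  sd_theory <- sqrt(0.25 - eps^2) / sqrt(n)
  expect_equal(sd(fits$eps_m), sd_theory, tolerance = 0.15)
})
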