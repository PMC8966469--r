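test_that("allele-sharing distance matches hand enumeration", {
  h <- cbind(a = c(1, 0, 1), b = c(1, 0, 0), c = c(0, 0, 1))
  d <- asd_matrix(h, mode = "haplotype")
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d["a", "b"], 1 / 3)   # differ at site 3
  expect_equal(d["a", "c"], 1 / 3)   # differ at site 1
  expect_equal(d["b", "c"], 2 / 3)   # differ at sites 1 and 3
  expect_equal(d, t(d))

  # identical and complementary haplotypes hit the bounds
  same <- cbind(rep(1, 4), rep(1, 4))
  expect_equal(asd_matrix(same)[1, 2], 0)
  comp <- cbind(c(0, 1, 0, 1), c(1, 0, 1, 0))
  expect_equal(asd_matrix(comp)[1, 2], 1)

  # genotype mode: mean |g1 - g2| / 2, missing sites excluded pairwise
  g <- cbind(c(0, 2, 1, NA), c(2, 2, 0, 1))
  expect_equal(asd_matrix(g, mode = "genotype")[1, 2],
               mean(c(2, 0, 1)) / 2)

  # haplotype-mode ASD is a metric: triangle inequality on random data
  set.seed(71)
  hm <- matrix(rbinom(300, 1, 0.5), nrow = 30)
  dm <- asd_matrix(hm)
  n <- ncol(hm)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
  }

  # a pair with no shared non-missing site is an error naming the pair
  bad <- cbind(x = c(1, NA), y = c(NA, 0))
  expect_error(asd_matrix(bad), "x and y")
})

test_that("classical MDS reproduces known configurations", {
  # two points at distance d separate by exactly d (1 positive eigenvalue)
  d2 <- matrix(c(0, 3, 3, 0), 2)
  expect_warning(xy <- classical_mds(d2, n_dims = 2), "positive eigen")
  expect_equal(abs(xy[1, 1] - xy[2, 1]), 3)

  # distances from planar points are recovered up to rigid motion
  set.seed(17)
  pts <- matrix(rnorm(20), ncol = 2)
  d <- as.matrix(dist(pts))
  rec <- classical_mds(d, n_dims = 2)
  expect_equal(as.matrix(dist(rec)), d, tolerance = 1e-8,
               ignore_attr = TRUE)

  # degenerate all-zero distances put every point at the origin
  expect_warning(z <- classical_mds(matrix(0, 4, 4)), "positive eigen")
  expect_true(all(z == 0))
})

test_that("DBSCAN recovers planted blobs and marks outliers as noise", {
  set.seed(23)
  blob1 <- matrix(rnorm(60, mean = 0, sd = 0.05), ncol = 2)
  blob2 <- matrix(rnorm(60, mean = 5, sd = 0.05), ncol = 2)
  pts <- rbind(blob1, blob2)
  lab <- density_cluster(pts, eps = 0.5, min_pts = 5)
  expect_equal(length(unique(lab)), 2L)
  expect_true(all(lab != 0))
  expect_length(unique(lab[1:30]), 1L)
  expect_length(unique(lab[31:60]), 1L)

  # a far isolated point is noise
  lab2 <- density_cluster(rbind(pts, c(100, 100)), eps = 0.5, min_pts = 5)
  expect_equal(lab2[61], 0L)

  # labels are invariant under translation
  expect_identical(density_cluster(pts + 17, eps = 0.5, min_pts = 5), lab)
})

test_that("binomial and Fisher transmission tests match exact references", {
  # worked maternal-transmission example: 24 of 34 vs an even split
  res <- sex_bias_binom_test(24, 34, p0 = 0.5)
  expect_equal(res$p_value, 2.43e-2, tolerance = 2e-3)
  # perfectly balanced transmissions are null
  expect_equal(sex_bias_binom_test(17, 34, 0.5)$p_value, 1)

  # Fisher exact vs full hypergeometric enumeration
  expect_equal(fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value,
               oracle_fisher_2x2(10, 0, 0, 10), tolerance = 1e-10)
  set.seed(99)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 8), 2)
    expect_equal(fisher.test(tab)$p.value,
                 oracle_fisher_2x2(tab[1, 1], tab[1, 2], tab[2, 1],
                                   tab[2, 2]),
                 tolerance = 1e-8)
  }
})

test_that("haplotype transmission tables count h vs other by child sex", {
  # constructed example: class 1 goes to sons 8/10 times, class 2 balanced
  trans <- data.frame(
    transmitted_label = c(rep(1, 10), rep(2, 10)),
    untransmitted_label = c(rep(2, 10), rep(1, 10)),
    child_sex = c(rep("male", 8), rep("female", 2),
                  rep("male", 2), rep("female", 8)))
  res <- haplotype_transmission_tests(trans)
  r1 <- res[res$haplotype == 1, ]
  expect_equal(r1$h_to_sons, 8)
  expect_equal(r1$h_to_daughters, 2)
  expect_equal(r1$other_to_sons, 2)
  expect_equal(r1$p0, 0.5)           # overall son fraction 10/20
  expect_equal(r1$fisher_p, oracle_fisher_2x2(8, 2, 2, 8),
               tolerance = 1e-10)
  # fixed p0 override
  res50 <- haplotype_transmission_tests(trans, p0 = 0.5)
  expect_equal(res50$p0, c(0.5, 0.5))
})

test_that("Mantel sex test is calibrated, detects structure, cross-checks vegan", {
  set.seed(12)
  n <- 30
  sexes <- rep(c("male", "female"), each = n / 2)
  # null: distances independent of sex; the p-value is itself uniform, so
  # judge calibration by the median over a few independent null data sets
  pts <- matrix(rnorm(2 * n), ncol = 2)
  d0 <- as.matrix(dist(pts))
  null_res <- mantel_sex_test(d0, sexes, n_perm = 499, seed = 8)
  null_ps <- vapply(1:5, function(i) {
    di <- as.matrix(dist(matrix(rnorm(2 * n), ncol = 2)))
    mantel_sex_test(di, sexes, n_perm = 199, seed = i)$p_value
  }, numeric(1))
  expect_gt(median(null_ps), 0.05)
  # r agrees with vegan's Mantel statistic on the same pair of matrices
  if (requireNamespace("vegan", quietly = TRUE)) {
    ind <- outer(sexes, sexes, "!=") * 1
    vg <- vegan::mantel(as.dist(d0), as.dist(ind), permutations = 99)
    expect_equal(null_res$r, unname(vg$statistic), tolerance = 1e-10)
  }
  # extreme structure: within-sex 0, between-sex 1
  d1 <- outer(sexes, sexes, "!=") * 1
  diag(d1) <- 0
  strong <- mantel_sex_test(d1, sexes, n_perm = 499, seed = 9)
  expect_equal(strong$r, 1, tolerance = 1e-10)
  expect_equal(strong$p_value, 1 / 500)
  # determinism and degenerate input
  expect_identical(mantel_sex_test(d0, sexes, n_perm = 99, seed = 3)$p_value,
                   mantel_sex_test(d0, sexes, n_perm = 99, seed = 3)$p_value)
  expect_error(mantel_sex_test(d0, rep("male", n)), "same sex")
})

test_that("the follow-up pipeline recovers planted haplotype classes and bias", {
  hits_cluster <- 0L
  hits_bias <- 0L
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    sim <- sim_hap_region(n_trios = 60, n_sites = 60,
                          freqs = c(0.35, 0.34, 0.31), bias = 0.3,
                          noise = 0.02, seed = 1000 + s)
    d <- asd_matrix(sim$haps)
    xy <- classical_mds(d, n_dims = 2)
    lab <- density_cluster(xy, eps = 0.1, min_pts = 5)
    if (length(setdiff(unique(lab), 0L)) == 3L) {
      hits_cluster <- hits_cluster + 1L
    }
    trans <- resolve_transmissions(sim$haps, sim$carrier, sim$ped,
                                   labels = lab)
    tests <- suppressMessages(haplotype_transmission_tests(trans))
    if (nrow(tests) > 0 &&
        any(pmin(tests$binom_p, tests$fisher_p, na.rm = TRUE) < 0.05)) {
      hits_bias <- hits_bias + 1L
    }
  }
  expect_gte(hits_cluster, 0.8 * n_seeds)
  expect_gte(hits_bias, 0.8 * n_seeds)
})
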