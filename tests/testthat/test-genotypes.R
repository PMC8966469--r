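test_that("Mendelian-error detection matches brute-force compatibility", {
  # worked cases
  expect_true(detect_mendelian_errors(0, 0, 1))    # AA x AA -> AB
  expect_false(detect_mendelian_errors(1, 1, 2))   # AB x AB -> BB
  expect_true(detect_mendelian_errors(NA, 0, 2, "X",
                                      child_sex = "male"))  # mother AA, son B

  # autosome: full enumeration incl. missing
  vals <- c(0, 1, 2, NA)
  for (f in vals) for (m in vals) for (c in vals) {
    expected <- if (anyNA(c(f, m, c))) FALSE else
      oracle_mendel_autosome(f, m, c)
    expect_identical(detect_mendelian_errors(f, m, c), expected,
                     info = sprintf("autosome f=%s m=%s c=%s", f, m, c))
  }

  # X: all configurations vs the compatibility oracle (hemizygous coded 0/2)
  for (f in c(0, 2, NA)) for (m in vals) for (sex in c("male", "female")) {
    cs <- if (sex == "male") c(0, 2, NA) else vals
    for (c in cs) {
      expect_identical(
        detect_mendelian_errors(f, m, c, "X", sex),
        oracle_mendel_x(f, m, c, sex),
        info = sprintf("X f=%s m=%s c=%s sex=%s", f, m, c, sex))
    }
  }
})

test_that("transmission extraction resolves the canonical trio types", {
  # AA father x AB mother, son AB: forced maternal B transmission
  tr <- site_transmissions(0, 1, 1, "male")
  expect_equal(tr[c("k_m", "n_m", "k_f", "n_f")],
               list(k_m = 1, n_m = 1, k_f = 0, n_f = 0))
  # AB x AB, daughter BB: two meioses, both B
  tr <- site_transmissions(1, 1, 2, "female")
  expect_equal(tr[c("k_f", "n_f")], list(k_f = 2, n_f = 2))
  # AA x BB: no het parent, nothing contributed
  tr <- site_transmissions(0, 2, 1, "male")
  expect_equal(tr$n_informative_trios, 0L)
  # het parent but the other parent missing: ambiguous, not informative
  tr <- site_transmissions(1, NA, 1, "male")
  expect_equal(tr$n_informative_trios, 0L)
  # het x hom with missing child: informative trio skipped and logged
  tr <- site_transmissions(1, 0, NA, "male")
  expect_equal(tr$skipped, 1L)
  expect_equal(tr$n_m, 0)

  # X: het mother, son carries B (hemizygous coded 2)
  tr <- site_transmissions(0, 1, 2, "male", "X")
  expect_equal(tr[c("k_m", "n_m")], list(k_m = 1, n_m = 1))
  # X: daughter dosage minus father allele isolates the maternal meiosis
  tr <- site_transmissions(2, 1, 2, "female", "X")  # father B, daughter BB
  expect_equal(tr[c("k_f", "n_f")], list(k_f = 1, n_f = 1))
  # X: daughter with missing father cannot be resolved
  tr <- site_transmissions(NA, 1, 2, "female", "X")
  expect_equal(tr$n_f, 0)
  expect_equal(tr$skipped, 1L)
  # X: hom mother is uninformative even with genotypes complete
  tr <- site_transmissions(0, 2, 2, "female", "X")
  expect_equal(tr$n_informative_trios, 0L)
})

test_that("site filters drop records for the documented reasons", {
  ped <- tiny_ped(4, sexes = c("male", "male", "female", "female"))
  samples <- ped_samples(ped)
  cfg <- filter_config(min_informative_autosome = 3, min_informative_x = 2)

  gt <- rbind(
    trio_gt_row(c(0, 1, 1, 1), c(1, 1, 1, 1), c(1, 1, 1, 1)),  # good site
    trio_gt_row(c(0, 1, 1, 1), c(1, 1, 1, 1), c(1, 1, 1, 1)),  # triallelic
    trio_gt_row(c(0, 0, 0, 0), c(0, 0, 0, 0), c(2, 2, 0, 0)),  # 2 mendel errs
    trio_gt_row(c(0, 1, 1, 1), c(0, 1, 1, 1), c(2, 0, 0, 0)),  # 1 mendel err
    trio_gt_row(c(0, 1, 0, 0), c(1, 0, 0, 0), c(1, 1, 0, 0)))  # 2 informative
  colnames(gt) <- samples
  # X sites: one inside the PAR, one with a heterozygous male
  gtx <- rbind(
    trio_gt_row(c(0, 0, 2, 2), c(1, 1, 1, 1), c(2, 0, 1, 2),
                haploid_father = TRUE,
                haploid_child = c(TRUE, TRUE, FALSE, FALSE)),
    c(trio_gt_row(c(0, 0, 2, 2), c(1, 1, 1, 1), c(2, 0, 1, 2),
                  haploid_father = TRUE,
                  haploid_child = c(TRUE, TRUE, FALSE, FALSE))[1:9],
      "0/1", "1/1", "1/1"))  # kid1 (male) diploid-het on X
  colnames(gtx) <- samples

  vcf <- tiny_vcf(
    chrom = c("1", "1", "1", "1", "1", "X", "X"),
    pos = c(100, 200, 300, 400, 500, 70000, 3000000),
    ref = rep("A", 7), alt = c("G", "G,T", "G", "G", "G", "G", "G"),
    gt = rbind(gt, gtx))
  res <- trio_counts(vcf, ped, cfg)

  log <- res$filter_log
  expect_equal(log$reason[log$pos == 200], "not_biallelic")
  expect_equal(log$reason[log$pos == 300], "mendel")
  expect_equal(log$reason[log$pos == 500], "informative")  # 2 < 3
  expect_equal(log$reason[log$pos == 70000], "par")
  expect_equal(log$reason[log$pos == 3000000], "male_het_x")

  # the single-error site survives with the error trio's child masked:
  # only the three clean het x het trios contribute (2 meioses each)
  kept <- res$counts
  row1 <- kept[kept$pos == 400, ]
  expect_equal(row1$mendel_errors, 1)
  expect_equal(row1$n_informative_trios, 3)
  expect_equal(row1$n_m + row1$n_f, 6)

  row0 <- kept[kept$pos == 100, ]
  expect_equal(row0$n_informative_trios, 4)
  expect_gte(row0$n_m + row0$n_f, row0$n_informative_trios)
})

test_that("filtering outcome is invariant to PAR interval order", {
  ped <- tiny_ped(2)
  gt <- rbind(trio_gt_row(c(0, 2), c(1, 1), c(2, 2),
                          haploid_father = TRUE,
                          haploid_child = c(TRUE, FALSE)))
  colnames(gt) <- ped_samples(ped)
  vcf <- tiny_vcf("X", 155000000, "A", "G", gt)
  cfg_a <- filter_config(min_informative_x = 1)
  cfg_b <- filter_config(min_informative_x = 1,
                         par_intervals = rev(cfg_a$par_intervals))
  expect_identical(trio_counts(vcf, ped, cfg_a)$filter_log$reason,
                   trio_counts(vcf, ped, cfg_b)$filter_log$reason)
})

test_that("fixture counts round-trip through an independent VCF parse", {
  dir <- tempfile()
  fx <- make_fixture(dir, n_trios = 50, n_sites = 6, n_sites_x = 3,
                     maf_range = c(0.3, 0.5), seed = 21)
  ped <- read_pedigree(fx$ped)
  cfg <- filter_config(min_informative_autosome = 1, min_informative_x = 1)
  got <- trio_counts(fx$vcf, ped, cfg)$counts

  # independent parse: plain-text read + hand mapping of GT strings
  lines <- readLines(fx$vcf)
  hdr <- strsplit(grep("^#CHROM", lines, value = TRUE), "\t")[[1]]
  body <- do.call(rbind, strsplit(grep("^[^#]", lines, value = TRUE), "\t"))
  dos_map <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2, "0" = 0, "1" = 2)
  for (i in seq_len(nrow(body))) {
    gts <- body[i, 10:ncol(body)]
    names(gts) <- hdr[10:length(hdr)]
    d <- unname(dos_map[gts[ped_samples(ped)]])
    n <- nrow(ped)
    tr <- site_transmissions(d[1:n], d[n + 1:n], d[2 * n + 1:n],
                             ped$child_sex,
                             if (body[i, 1] == "X") "X" else "autosome")
    row <- got[got$chrom == body[i, 1] & got$pos == as.numeric(body[i, 2]), ]
    expect_equal(row$k_m, tr$k_m)
    expect_equal(row$n_m, tr$n_m)
    expect_equal(row$k_f, tr$k_f)
    expect_equal(row$n_f, tr$n_f)
  }
})
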