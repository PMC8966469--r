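# Trio simulators: per-site transmission counts under M0/M1/M2, power and
# type-I analyses, recombination-free window lengths, and synthetic
# VCF/PED fixture generation with ground truth.

#' Trio-simulation configuration
#'
#' Describes the sampling design for one simulated site: each trio has a
#' child of random sex and contributes one informative meiosis (two when
#' the trio is het x het), each meiosis transmitting the alternative allele
#' with probability 1/2 + eps_sex under the chosen model.
#'
#' @param n_trios informative trios per site.
#' @param model \code{"M0"}, \code{"M1"} or \code{"M2"}.
#' @param eps distortion under M1.
#' @param eps_m,eps_f sex-specific distortion under M2.
#' @param frac_double_het proportion of het x het matings, which contribute
#'   two meioses (default 0: one meiosis per trio).
#' @param p_male_child probability a child is male (default 0.5).
#' @param chrom_class \code{"autosome"} or \code{"X"} (X trios contribute
#'   one maternal meiosis regardless of \code{frac_double_het}).
#' @param seed optional RNG seed.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_trios, model = c("M0", "M1", "M2"), eps = 0,
                       eps_m = 0, eps_f = 0, frac_double_het = 0,
                       p_male_child = 0.5, chrom_class = "autosome",
                       seed = NULL) {
  model <- match.arg(model)
  stopifnot(n_trios >= 1, frac_double_het >= 0, frac_double_het <= 1,
            p_male_child >= 0, p_male_child <= 1,
            abs(eps) <= 0.5, abs(eps_m) <= 0.5, abs(eps_f) <= 0.5)
  chrom_class <- match.arg(chrom_class, c("autosome", "X"))
  structure(list(n_trios = n_trios, model = model, eps = eps,
                 eps_m = eps_m, eps_f = eps_f,
                 frac_double_het = frac_double_het,
                 p_male_child = p_male_child, chrom_class = chrom_class,
                 seed = seed),
            class = "sim_config")
}

sim_eps <- function(config) {
  switch(config$model,
         M0 = c(m = 0, f = 0),
         M1 = c(m = config$eps, f = config$eps),
         M2 = c(m = config$eps_m, f = config$eps_f))
}

#' Simulate transmission counts for replicate sites
#'
#' Draws \code{reps} independent sites under the configured design and
#' returns their sex-stratified transmission counts. Reproducible given
#' the seed.
#'
#' @param config a [sim_config()].
#' @param reps number of replicate sites (default 1).
#' @param seed optional seed overriding \code{config$seed}.
#' @return data.frame with \code{k_m}, \code{n_m}, \code{k_f}, \code{n_f},
#'   \code{n_informative_trios}, \code{chrom_class}.
#' @export
simulate_counts <- function(config, reps = 1, seed = config$seed) {
  eps <- sim_eps(config)
  n <- config$n_trios
  with_seed(seed, {
    sons <- stats::rbinom(reps, n, config$p_male_child)
    daughters <- n - sons
    if (config$chrom_class == "X" || config$frac_double_het == 0) {
      n_m <- sons
      n_f <- daughters
    } else {
      # each trio is het x het independently; such a trio has 2 meioses
      dh_m <- stats::rbinom(reps, sons, config$frac_double_het)
      dh_f <- stats::rbinom(reps, daughters, config$frac_double_het)
      n_m <- sons + dh_m
      n_f <- daughters + dh_f
    }
    data.frame(
      k_m = stats::rbinom(reps, n_m, 0.5 + eps["m"]),
      n_m = n_m,
      k_f = stats::rbinom(reps, n_f, 0.5 + eps["f"]),
      n_f = n_f,
      n_informative_trios = n,
      chrom_class = config$chrom_class)
  })
}

#' @rdname simulate_counts
#' @export
simulate_site <- function(config, seed = config$seed) {
  simulate_counts(config, reps = 1, seed = seed)
}

#' Power analysis of the transmission-model LRTs
#'
#' For each row of a scenario grid, simulates replicate sites, fits the
#' nested models and reports the proportion of LRT p-values below alpha.
#' Sex-antagonistic scenarios are conventionally parameterised by the gap
#' delta = |eps_m - eps_f| with a symmetric split eps_m = +delta/2,
#' eps_f = -delta/2 (use explicit \code{eps_m}/\code{eps_f} columns to
#' override).
#'
#' @param grid data.frame of scenarios; recognised columns: \code{n_trios}
#'   (required), \code{model}, \code{eps}, \code{eps_m}, \code{eps_f},
#'   \code{delta}, \code{frac_double_het}, \code{p_male_child}. A
#'   \code{delta} column implies the symmetric M2 split above.
#' @param test \code{"M2vM0"} (2-df LRT, default) or \code{"M1vM0"}
#'   (1-df LRT).
#' @param alpha significance level (default 0.05).
#' @param reps replicate sites per scenario (default 500).
#' @param seed optional RNG seed; scenario rows use consecutive sub-seeds.
#' @return the grid with \code{reps}, \code{rejections} and \code{power}
#'   appended.
#' @export
power_analysis <- function(grid, test = c("M2vM0", "M1vM0"), alpha = 0.05,
                           reps = 500, seed = NULL) {
  test <- match.arg(test)
  stopifnot(nrow(grid) >= 1, "n_trios" %in% names(grid))
  pcol <- if (test == "M2vM0") "p20" else "p10"
  out <- grid
  out$reps <- reps
  out$rejections <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    if (!is.null(row$delta) && !is.na(row$delta)) {
      cfg <- sim_config(row$n_trios, model = "M2", eps_m = +row$delta / 2,
                        eps_f = -row$delta / 2,
                        frac_double_het = row$frac_double_het %||% 0,
                        p_male_child = row$p_male_child %||% 0.5)
    } else {
      cfg <- sim_config(row$n_trios,
                        model = as.character(row$model %||% "M0"),
                        eps = row$eps %||% 0,
                        eps_m = row$eps_m %||% 0, eps_f = row$eps_f %||% 0,
                        frac_double_het = row$frac_double_het %||% 0,
                        p_male_child = row$p_male_child %||% 0.5)
    }
    counts <- simulate_counts(cfg, reps = reps,
                              seed = if (is.null(seed)) NULL else seed + i)
    stats_ <- lrt_stats(counts$k_m, counts$n_m, counts$k_f, counts$n_f)
    out$rejections[i] <- sum(stats_[[pcol]] < alpha)
  }
  out$power <- out$rejections / reps
  out
}

#' Simulate recombination-free window lengths around a focal SNP
#'
#' Under a homogeneous recombination intensity lambda (events per unit
#' distance; 1 cM/Mb corresponds to lambda = 0.01 per Mb read as events per
#' 1 Mb unit), the nearest recombination breakpoint on each side of a focal
#' SNP in one trio is Exponential(lambda); across N_T trios the nearest
#' breakpoint on each side is the minimum of N_T such draws, and the
#' recombination-free window shared by all trios is the sum of the upstream
#' and downstream minima — Gamma with shape 2 and rate N_T * lambda.
#'
#' @param n_trios number of informative trios N_T.
#' @param lambda per-unit recombination intensity (default 0.01).
#' @param reps number of simulated windows.
#' @param seed optional RNG seed.
#' @return list: \code{lengths}, \code{mean}, \code{var}, and
#'   method-of-moments gamma estimates \code{shape} (mean^2/var) and
#'   \code{rate} (mean/var).
#' @export
simulate_window_lengths <- function(n_trios, lambda = 0.01, reps = 1000,
                                    seed = NULL) {
  stopifnot(n_trios >= 1, lambda > 0, reps >= 1)
  lengths <- with_seed(seed, {
    out <- numeric(reps)
    chunk <- max(1L, min(reps, floor(2e6 / n_trios)))
    done <- 0L
    while (done < reps) {
      b <- min(chunk, reps - done)
      up <- matrix(stats::rexp(b * n_trios, rate = lambda), nrow = b)
      down <- matrix(stats::rexp(b * n_trios, rate = lambda), nrow = b)
      out[done + seq_len(b)] <-
        apply(up, 1, min) + apply(down, 1, min)
      done <- done + b
    }
    out
  })
  m <- mean(lengths)
  v <- stats::var(lengths)
  list(lengths = lengths, mean = m, var = v,
       shape = m^2 / v, rate = m / v)
}

# ---- synthetic VCF/PED fixture generation ---------------------------------

sim_child_autosome <- function(f, m, eps_sex) {
  # one transmitted allele per parent; het parents transmit B w.p. 1/2+eps
  pat <- ifelse(f == 1, stats::rbinom(length(f), 1, 0.5 + eps_sex), f / 2)
  mat <- ifelse(m == 1, stats::rbinom(length(m), 1, 0.5 + eps_sex), m / 2)
  pat + mat
}

# haploid mode expects the allele (0/1); diploid mode the dosage (0/1/2)
dos_to_gt <- function(d, haploid = FALSE) {
  if (haploid) {
    out <- c("0", "1")[d + 1]
  } else {
    out <- c("0/0", "0/1", "1/1")[d + 1]
  }
  out[is.na(d)] <- if (haploid) "." else "./."
  out
}

#' Generate a synthetic trio VCF/PED fixture with ground truth
#'
#' Emulates a trio cohort: parents drawn at Hardy-Weinberg equilibrium at
#' per-site minor-allele frequencies, children by the site's transmission
#' model (Mendelian by default, distorted inside planted regions), an
#' optional X block with hemizygous males, plus injected Mendelian errors
#' and missing genotypes. Writes a VCF 4.2, a PED-like pedigree and a
#' ground-truth sidecar with the true per-site distortion parameters.
#'
#' @param dir output directory (created if needed).
#' @param n_trios number of trios.
#' @param n_sites number of autosomal sites (chromosome "1", positions
#'   spaced \code{site_spacing} apart).
#' @param n_sites_x number of X-linked sites (default 0).
#' @param maf_range per-site minor-allele frequencies drawn uniformly from
#'   this range (default c(0.2, 0.5); intermediate frequencies keep most
#'   sites informative).
#' @param planted list of planted distortion spans, each a list with
#'   \code{chrom}, \code{from}, \code{to} (site indices within that
#'   chromosome) and either \code{eps} (M1) or \code{eps_m}/\code{eps_f}
#'   (M2).
#' @param mendel_error_rate per-trio-site probability of corrupting the
#'   child genotype into a Mendelian-incompatible one where possible
#'   (default 0).
#' @param missing_rate per-genotype missingness probability (default 0).
#' @param p_male_child probability a child is male (default 0.5).
#' @param site_spacing distance between consecutive sites in bp
#'   (default 10000).
#' @param seed RNG seed (fixtures are fully reproducible given it).
#' @return invisibly, a list with paths (\code{vcf}, \code{ped},
#'   \code{truth}) and the truth data.frame (chrom, pos, true_eps_m,
#'   true_eps_f).
#' @export
make_fixture <- function(dir, n_trios = 250, n_sites = 100, n_sites_x = 0,
                         maf_range = c(0.2, 0.5), planted = list(),
                         mendel_error_rate = 0, missing_rate = 0,
                         p_male_child = 0.5, site_spacing = 10000,
                         seed = 1) {
  stopifnot(n_trios >= 1, n_sites + n_sites_x >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    fam <- sprintf("F%03d", seq_len(n_trios))
    fathers <- sprintf("dad%03d", seq_len(n_trios))
    mothers <- sprintf("mom%03d", seq_len(n_trios))
    children <- sprintf("kid%03d", seq_len(n_trios))
    sex <- ifelse(stats::rbinom(n_trios, 1, p_male_child) == 1,
                  "male", "female")
    son <- sex == "male"

    chroms <- c(rep("1", n_sites), rep("X", n_sites_x))
    pos <- c(seq_len(n_sites), seq_len(n_sites_x)) * site_spacing
    nsite <- n_sites + n_sites_x
    true_em <- numeric(nsite)
    true_ef <- numeric(nsite)
    for (pl in planted) {
      idx <- which(chroms == pl$chrom)
      idx <- idx[pl$from:pl$to]
      if (!is.null(pl$eps)) {
        true_em[idx] <- pl$eps; true_ef[idx] <- pl$eps
      } else {
        true_em[idx] <- pl$eps_m %||% 0
        true_ef[idx] <- pl$eps_f %||% 0
      }
    }

    maf <- stats::runif(nsite, maf_range[1], maf_range[2])
    gt <- matrix("", nrow = nsite, ncol = 3 * n_trios)
    colnames(gt) <- c(fathers, mothers, children)
    for (i in seq_len(nsite)) {
      q <- maf[i]
      eps_sex <- ifelse(son, true_em[i], true_ef[i])
      if (chroms[i] == "X") {
        f_allele <- stats::rbinom(n_trios, 1, q)       # hemizygous fathers
        m_dos <- stats::rbinom(n_trios, 2, q)
        mat <- ifelse(m_dos == 1,
                      stats::rbinom(n_trios, 1, 0.5 + eps_sex), m_dos / 2)
        c_dos <- ifelse(son, 2 * mat, f_allele + mat)
        f_dos <- 2 * f_allele
      } else {
        f_dos <- stats::rbinom(n_trios, 2, q)
        m_dos <- stats::rbinom(n_trios, 2, q)
        c_dos <- sim_child_autosome(f_dos, m_dos, eps_sex)
      }
      if (mendel_error_rate > 0) {
        hit <- stats::runif(n_trios) < mendel_error_rate
        for (j in which(hit)) {
          cand <- 0:2
          bad <- cand[detect_mendelian_errors(
            rep(f_dos[j], 3), rep(m_dos[j], 3), cand,
            chrom_class = if (chroms[i] == "X") "X" else "autosome",
            child_sex = rep(sex[j], 3))]
          if (chroms[i] == "X" && son[j]) bad <- setdiff(bad, 1)
          if (length(bad)) c_dos[j] <- sample(bad, 1)
        }
      }
      if (missing_rate > 0) {
        f_dos[stats::runif(n_trios) < missing_rate] <- NA
        m_dos[stats::runif(n_trios) < missing_rate] <- NA
        c_dos[stats::runif(n_trios) < missing_rate] <- NA
      }
      hap_f <- chroms[i] == "X"
      hap_c <- chroms[i] == "X" & son
      gt[i, fathers] <- dos_to_gt(if (hap_f) f_dos / 2 else f_dos,
                                  haploid = hap_f)
      gt[i, mothers] <- dos_to_gt(m_dos)
      gt[i, children] <- ifelse(hap_c, dos_to_gt(c_dos / 2, haploid = TRUE),
                                dos_to_gt(c_dos))
    }

    vcf_path <- file.path(dir, "fixture.vcf")
    ped_path <- file.path(dir, "fixture.ped")
    truth_path <- file.path(dir, "fixture_truth.tsv")
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=triodistort_synthetic_fixture",
      "##contig=<ID=1>", "##contig=<ID=X>",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
    body <- vapply(seq_len(nsite), function(i) {
      paste(c(chroms[i], pos[i], ".", "A", "G", ".", "PASS", ".", "GT",
              gt[i, ]), collapse = "\t")
    }, character(1))
    writeLines(c(header, body), vcf_path)
    write_tsv(data.frame(family_id = fam, father_id = fathers,
                         mother_id = mothers, child_id = children,
                         sex = ifelse(son, 1L, 2L)), ped_path)
    truth <- data.frame(chrom = chroms, pos = pos, maf = maf,
                        true_eps_m = true_em, true_eps_f = true_ef)
    write_tsv(truth, truth_path)
    invisible(list(vcf = vcf_path, ped = ped_path, truth_path = truth_path,
                   truth = truth))
  })
}
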