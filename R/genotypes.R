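# VCF genotype handling: site filters, Mendelian-error detection, and
# reduction of each SNP to sex-stratified transmission counts.

#' Site-filter configuration
#'
#' Defaults reproduce a stringent trio-scan filter set: biallelic SNPs only,
#' pseudoautosomal regions (hg19 X coordinates) removed, X sites with any
#' heterozygous male removed, sites with two or more Mendelian-error trios
#' removed (a single error survives with that trio's child genotype masked),
#' and informative-trio thresholds of 150 (autosomes) / 75 (X).
#'
#' @param min_informative_autosome minimum informative trios for an
#'   autosomal site (default 150).
#' @param min_informative_x minimum informative trios for an X-linked site
#'   (default 75).
#' @param max_mendel_errors sites with at least this many Mendelian-error
#'   trios are dropped (default 2).
#' @param par_intervals list of \code{c(chrom, start, end)} 1-based
#'   inclusive intervals to exclude; defaults are the hg19 X
#'   pseudoautosomal regions.
#' @param drop_male_het_x drop X sites carrying at least one heterozygous
#'   male genotype (default TRUE).
#' @param pass_only honour the VCF FILTER column, keeping only PASS/"."
#'   records (default FALSE; upstream QC is assumed already applied).
#' @return a \code{filter_config} list.
#' @export
filter_config <- function(min_informative_autosome = 150,
                          min_informative_x = 75,
                          max_mendel_errors = 2,
                          par_intervals = list(
                            c("chrX", 60001, 2699520),
                            c("chrX", 154931044, 155260560)),
                          drop_male_het_x = TRUE,
                          pass_only = FALSE) {
  stopifnot(min_informative_autosome > 0, min_informative_x > 0,
            max_mendel_errors > 0)
  par <- lapply(par_intervals, function(iv) {
    stopifnot(length(iv) == 3L)
    list(chrom = as.character(iv[[1L]]), start = as.numeric(iv[[2L]]),
         end = as.numeric(iv[[3L]]))
  })
  for (iv in par) stopifnot(iv$start <= iv$end)
  if (length(par) > 1L) {
    for (i in seq_len(length(par) - 1L)) for (j in seq(i + 1L, length(par))) {
      if (identical(is_x_chrom(par[[i]]$chrom), is_x_chrom(par[[j]]$chrom)) &&
          par[[i]]$chrom == par[[j]]$chrom &&
          par[[i]]$start <= par[[j]]$end && par[[j]]$start <= par[[i]]$end) {
        stop("PAR intervals overlap")
      }
    }
  }
  structure(list(min_informative_autosome = min_informative_autosome,
                 min_informative_x = min_informative_x,
                 max_mendel_errors = max_mendel_errors,
                 par_intervals = par,
                 drop_male_het_x = isTRUE(drop_male_het_x),
                 pass_only = isTRUE(pass_only)),
            class = "filter_config")
}

in_par <- function(chrom, pos, config) {
  hit <- rep(FALSE, length(chrom))
  for (iv in config$par_intervals) {
    same <- (is_x_chrom(chrom) & is_x_chrom(iv$chrom)) | chrom == iv$chrom
    hit <- hit | (same & pos >= iv$start & pos <= iv$end)
  }
  hit
}

# Character GT field -> allele-count dosage. Diploid calls map to 0/1/2;
# haploid (hemizygous) calls map to 0/2 so that dosage 1 always means a
# genuinely heterozygous diploid call. Anything malformed becomes NA.
gt_dosage <- function(gt) {
  g <- sub(":.*$", "", as.character(gt))
  out <- rep(NA_real_, length(g))
  out[g %in% c("0/0", "0|0")] <- 0
  out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  out[g %in% c("1/1", "1|1")] <- 2
  out[g == "0"] <- 0
  out[g == "1"] <- 2
  dim(out) <- dim(gt)
  dimnames(out) <- dimnames(gt)
  out
}

#' Detect Mendelian errors in trio genotypes
#'
#' Flags trios whose child genotype is impossible given the parental
#' genotypes. Autosomes: the child allele pair must be composable from one
#' allele of each parent. X: a son's single (hemizygous) allele must be
#' carriable by the mother; a daughter carries the father's allele plus one
#' maternal allele. Missing parent or child genotypes are never errors.
#'
#' @param father,mother,child numeric genotype dosages (0/1/2, hemizygous
#'   coded 0/2, NA = missing); vectors of equal length (one element per trio).
#' @param chrom_class \code{"autosome"} or \code{"X"}.
#' @param child_sex \code{"male"}/\code{"female"} per trio (required for X).
#' @return logical vector, TRUE where the trio is a Mendelian error.
#' @export
detect_mendelian_errors <- function(father, mother, child,
                                    chrom_class = "autosome",
                                    child_sex = NULL) {
  chrom_class <- match.arg(chrom_class, c("autosome", "X"))
  n <- length(child)
  stopifnot(length(father) == n, length(mother) == n)
  err <- rep(FALSE, n)
  if (chrom_class == "autosome") {
    # Alleles contributed by a parent with dosage d span floor(d/2) ..
    # ceiling(d/2); achievable child dosages form the interval sum.
    lo <- floor(father / 2) + floor(mother / 2)
    hi <- ceiling(father / 2) + ceiling(mother / 2)
    err <- !is.na(child) & !is.na(lo) & (child < lo | child > hi)
  } else {
    stopifnot(!is.null(child_sex), length(child_sex) == n)
    son <- child_sex == "male"
    # Son: maternal allele only; dosage 0/2 maps to allele 0/1, dosage 1
    # (diploid-coded het male) is unresolvable, treated as missing.
    s_allele <- ifelse(child %in% c(0, 2), child / 2, NA_real_)
    err[son] <- (!is.na(s_allele[son]) & !is.na(mother[son]) &
                   ((s_allele[son] == 0 & mother[son] == 2) |
                      (s_allele[son] == 1 & mother[son] == 0)))
    # Daughter: father's hemizygous allele + one maternal allele.
    f_allele <- ifelse(father %in% c(0, 2), father / 2, NA_real_)
    need <- child - f_allele   # required maternal allele count
    d_err <- !is.na(child) & !is.na(f_allele) &
      (need < 0 | need > 1 |
         (!is.na(mother) & ((need == 0 & mother == 2) |
                              (need == 1 & mother == 0))))
    err[!son] <- d_err[!son]
  }
  err
}

#' Sex-stratified transmission counts for one site
#'
#' Tallies informative meioses and transmitted alternative ("B") alleles by
#' child sex. Autosomes: a trio is informative when both parental genotypes
#' are non-missing and at least one parent is heterozygous; a hom x het trio
#' contributes one meiosis (the child carries B from the het parent iff its
#' B count exceeds the homozygous parent's contribution), a het x het trio
#' contributes two meioses with B-transmission count equal to the child's B
#' dosage. X: informative iff the mother is heterozygous; a son's hemizygous
#' allele is the maternal transmission; a daughter's maternal allele is her
#' dosage minus the father's allele (father genotype required). Trios whose
#' needed genotypes are missing are skipped.
#'
#' @inheritParams detect_mendelian_errors
#' @return list with \code{k_m}, \code{n_m}, \code{k_f}, \code{n_f},
#'   \code{n_informative_trios} (trios contributing at least one meiosis)
#'   and \code{skipped} (informative-by-genotype trios dropped for
#'   missingness).
#' @export
site_transmissions <- function(father, mother, child, child_sex,
                               chrom_class = "autosome") {
  chrom_class <- match.arg(chrom_class, c("autosome", "X"))
  n <- length(child)
  stopifnot(length(father) == n, length(mother) == n, length(child_sex) == n)
  k <- rep(NA_real_, n)   # B transmissions per trio
  m <- rep(0L, n)         # meioses per trio
  if (chrom_class == "autosome") {
    parents_ok <- !is.na(father) & !is.na(mother)
    het_f <- parents_ok & father == 1
    het_m <- parents_ok & mother == 1
    dh <- het_f & het_m
    single <- xor(het_f, het_m)
    hom_d <- ifelse(het_f, mother, father)  # the homozygous parent's dosage
    res_single <- single & !is.na(child)
    k[res_single] <- child[res_single] - hom_d[res_single] / 2
    m[res_single] <- 1L
    res_dh <- dh & !is.na(child)
    k[res_dh] <- child[res_dh]
    m[res_dh] <- 2L
    skipped <- sum((single | dh) & is.na(child))
  } else {
    informative <- !is.na(mother) & mother == 1
    son <- child_sex == "male"
    s_allele <- ifelse(child %in% c(0, 2), child / 2, NA_real_)
    res_son <- informative & son & !is.na(s_allele)
    k[res_son] <- s_allele[res_son]
    m[res_son] <- 1L
    f_allele <- ifelse(father %in% c(0, 2), father / 2, NA_real_)
    mat <- child - f_allele
    res_dau <- informative & !son & !is.na(mat) & mat %in% c(0, 1)
    k[res_dau] <- mat[res_dau]
    m[res_dau] <- 1L
    skipped <- sum(informative & m == 0L)
  }
  is_son <- child_sex == "male"
  contributes <- m > 0L
  list(
    k_m = sum(k[contributes & is_son]),
    n_m = sum(m[contributes & is_son]),
    k_f = sum(k[contributes & !is_son]),
    n_f = sum(m[contributes & !is_son]),
    n_informative_trios = sum(contributes),
    skipped = as.integer(skipped)
  )
}

read_vcf_input <- function(vcf) {
  if (inherits(vcf, "vcfR")) return(vcf)
  vcfR::read.vcfR(vcf, verbose = FALSE)
}

# getFIX() drops to a named vector for single-record files
get_fix_df <- function(v) {
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)
  as.data.frame(fix, stringsAsFactors = FALSE)
}

#' Reduce a trio VCF to per-SNP transmission counts
#'
#' Applies the site filters and reduces every surviving biallelic SNP to
#' sex-stratified transmission counts. Filter predicates are all evaluated
#' before any site is dropped, so the kept-site set does not depend on
#' filter order. At surviving sites, the child genotype of each
#' Mendelian-error trio is set missing before counting.
#'
#' @param vcf path to a VCF 4.x file (plain or bgzipped) or a
#'   \code{vcfR::vcfR} object; the GT format field is required.
#' @param ped a \code{trio_set} from [read_pedigree()]; every referenced
#'   sample must be present in the VCF.
#' @param config a [filter_config()].
#' @return list with \code{counts} (data.frame: chrom, pos, ref, alt,
#'   chrom_class, k_m, n_m, k_f, n_f, n_informative_trios, mendel_errors)
#'   for kept sites, and \code{filter_log} (data.frame: chrom, pos, kept,
#'   reason) covering every input record.
#' @export
trio_counts <- function(vcf, ped, config = filter_config()) {
  v <- read_vcf_input(vcf)
  fix <- get_fix_df(v)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt_raw)
  need <- unique(c(ped$father_id, ped$mother_id, ped$child_id))
  absent <- setdiff(need, samples)
  if (length(absent)) {
    stop("pedigree sample(s) missing from the VCF: ",
         paste(absent, collapse = ", "))
  }
  dos <- gt_dosage(gt_raw)
  chrom <- fix$CHROM
  pos <- as.numeric(fix$POS)
  cls <- chrom_class_of(chrom)
  n_site <- nrow(fix)

  fa <- dos[, ped$father_id, drop = FALSE]
  mo <- dos[, ped$mother_id, drop = FALSE]
  ch <- dos[, ped$child_id, drop = FALSE]
  sex <- ped$child_sex
  male_cols <- c(ped$father_id, ped$child_id[sex == "male"])

  bases <- c("A", "C", "G", "T")
  biallelic <- !is.na(fix$REF) & !is.na(fix$ALT) &
    toupper(fix$REF) %in% bases & toupper(fix$ALT) %in% bases
  filt_col <- fix$FILTER %||% rep(".", n_site)
  pass_ok <- !config$pass_only |
    is.na(filt_col) | filt_col %in% c("PASS", ".")
  par_hit <- in_par(chrom, pos, config)
  male_het <- cls == "X" & config$drop_male_het_x &
    rowSums(dos[, male_cols, drop = FALSE] == 1, na.rm = TRUE) > 0

  counts <- vector("list", n_site)
  reason <- rep(NA_character_, n_site)
  kept <- rep(FALSE, n_site)
  for (i in seq_len(n_site)) {
    if (!biallelic[i]) { reason[i] <- "not_biallelic"; next }
    if (!pass_ok[i])   { reason[i] <- "filter_column"; next }
    if (par_hit[i])    { reason[i] <- "par"; next }
    if (male_het[i])   { reason[i] <- "male_het_x"; next }
    f <- fa[i, ]; m <- mo[i, ]; c_ <- ch[i, ]
    err <- detect_mendelian_errors(f, m, c_, chrom_class = cls[i],
                                   child_sex = sex)
    n_err <- sum(err)
    if (n_err >= config$max_mendel_errors) { reason[i] <- "mendel"; next }
    c_[err] <- NA_real_   # error attribution is ambiguous: mask the child
    tr <- site_transmissions(f, m, c_, sex, chrom_class = cls[i])
    thr <- if (cls[i] == "X") config$min_informative_x else
      config$min_informative_autosome
    if (tr$n_informative_trios < thr) { reason[i] <- "informative"; next }
    kept[i] <- TRUE
    counts[[i]] <- data.frame(
      chrom = chrom[i], pos = pos[i], ref = fix$REF[i], alt = fix$ALT[i],
      chrom_class = cls[i], k_m = tr$k_m, n_m = tr$n_m, k_f = tr$k_f,
      n_f = tr$n_f, n_informative_trios = tr$n_informative_trios,
      mendel_errors = n_err, stringsAsFactors = FALSE)
  }
  counts_df <- if (any(kept)) do.call(rbind, counts[kept]) else
    data.frame(chrom = character(), pos = numeric(), ref = character(),
               alt = character(), chrom_class = character(), k_m = numeric(),
               n_m = numeric(), k_f = numeric(), n_f = numeric(),
               n_informative_trios = integer(), mendel_errors = integer(),
               stringsAsFactors = FALSE)
  rownames(counts_df) <- NULL
  log_df <- data.frame(chrom = chrom, pos = pos, kept = kept,
                       reason = ifelse(kept, "kept", reason),
                       stringsAsFactors = FALSE)
  list(counts = counts_df, filter_log = log_df)
}
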