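# Build tiny VCF and pedigree files in code for the I/O tests.

tiny_vcf <- function(chrom, pos, ref, alt, gt, samples = colnames(gt),
                     filter = rep("PASS", length(chrom))) {
  path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(chrom), function(i) {
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", filter[i], ".",
            "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

tiny_ped <- function(n, sexes = rep(c("male", "female"), length.out = n)) {
  data.frame(
    family_id = sprintf("F%d", seq_len(n)),
    father_id = sprintf("dad%d", seq_len(n)),
    mother_id = sprintf("mom%d", seq_len(n)),
    child_id = sprintf("kid%d", seq_len(n)),
    child_sex = sexes,
    stringsAsFactors = FALSE)
}

ped_samples <- function(ped) c(ped$father_id, ped$mother_id, ped$child_id)

# One VCF row of GT strings for a set of trios from dosage vectors.
trio_gt_row <- function(f, m, c, haploid_father = FALSE,
                        haploid_child = rep(FALSE, length(c))) {
  to_gt <- function(d, hap) {
    if (is.na(d)) return(if (hap) "." else "./.")
    if (hap) c("0", "1")[d / 2 + 1] else c("0/0", "0/1", "1/1")[d + 1]
  }
  c(mapply(to_gt, f, haploid_father),
    mapply(to_gt, m, FALSE),
    mapply(to_gt, c, haploid_child))
}
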