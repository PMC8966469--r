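# Pedigree input and sex-label verification.

normalize_sex <- function(sex) {
  s <- toupper(trimws(as.character(sex)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("1", "M", "MALE")] <- "male"
  out[s %in% c("2", "F", "FEMALE")] <- "female"
  if (anyNA(out)) {
    bad <- unique(s[is.na(out)])
    stop("unknown sex code(s): ", paste(bad, collapse = ", "),
         " (expected 1/2, M/F or male/female)")
  }
  out
}

#' Read a trio pedigree
#'
#' Reads a PED-like whitespace/tab-delimited table with one row per trio:
#' family ID, father ID, mother ID, child ID, child sex (1/2, M/F or
#' male/female). Exact duplicate rows are dropped; a child listed twice with
#' conflicting parents or sex is an error. Trios are assumed genetically
#' unrelated; this is a documented modelling assumption, not checked.
#'
#' @param source path to the pedigree file, or a data.frame with five columns
#'   in the order above.
#' @param header \code{"auto"} (default) detects a header line by checking
#'   whether the fifth field of the first row is a valid sex code; or
#'   \code{TRUE}/\code{FALSE}.
#' @return a \code{trio_set}: data.frame with columns \code{family_id},
#'   \code{father_id}, \code{mother_id}, \code{child_id}, \code{child_sex}
#'   (\code{"male"}/\code{"female"}).
#' @export
read_pedigree <- function(source, header = "auto") {
  if (is.data.frame(source)) {
    tab <- source
  } else {
    if (identical(header, "auto")) {
      first <- utils::read.table(source, nrows = 1L, colClasses = "character",
                                 stringsAsFactors = FALSE)
      hdr <- ncol(first) >= 5L &&
        !toupper(first[[5L]]) %in% c("1", "2", "M", "F", "MALE", "FEMALE")
    } else {
      hdr <- isTRUE(header)
    }
    tab <- utils::read.table(source, header = hdr, colClasses = "character",
                             stringsAsFactors = FALSE)
    if (hdr && nrow(tab) == 0L) {
      # a lone malformed row can masquerade as a header: let validation see it
      tab <- utils::read.table(source, header = FALSE,
                               colClasses = "character",
                               stringsAsFactors = FALSE)
    }
  }
  if (nrow(tab) == 0L) stop("pedigree contains no trios")
  if (ncol(tab) < 5L) {
    stop("pedigree needs 5 columns: family, father, mother, child, sex")
  }
  tab <- tab[, 1:5]
  names(tab) <- c("family_id", "father_id", "mother_id", "child_id",
                  "child_sex")
  for (col in names(tab)) tab[[col]] <- trimws(as.character(tab[[col]]))
  missing_field <- tab$father_id %in% c("", "0", ".", NA) |
    tab$mother_id %in% c("", "0", ".", NA) |
    tab$child_id %in% c("", "0", ".", NA)
  if (any(missing_field)) {
    stop("pedigree row(s) ", paste(which(missing_field), collapse = ", "),
         " have a missing father, mother or child ID")
  }
  tab$child_sex <- normalize_sex(tab$child_sex)
  tab <- unique(tab)
  if (anyDuplicated(tab$child_id)) {
    dup <- unique(tab$child_id[duplicated(tab$child_id)])
    stop("child ID(s) appear in more than one trio with conflicting fields: ",
         paste(dup, collapse = ", "))
  }
  within_dup <- tab$father_id == tab$mother_id |
    tab$father_id == tab$child_id | tab$mother_id == tab$child_id
  if (any(within_dup)) {
    stop("sample IDs must be unique within a trio (row ",
         paste(which(within_dup), collapse = ", "), ")")
  }
  rownames(tab) <- NULL
  class(tab) <- c("trio_set", "data.frame")
  tab
}

#' Sex-check configuration
#'
#' Thresholds on the fraction of heterozygous non-pseudoautosomal X-linked
#' genotypes used to infer sample sex: below \code{male_max_het_frac} infers
#' male, above \code{female_min_het_frac} infers female, in between the
#' sample is left unassigned.
#'
#' @param male_max_het_frac upper bound on X heterozygosity for males
#'   (default 0.02).
#' @param female_min_het_frac lower bound on X heterozygosity for females
#'   (default 0.06).
#' @return a \code{sex_check_config} list.
#' @export
sex_check_config <- function(male_max_het_frac = 0.02,
                             female_min_het_frac = 0.06) {
  stopifnot(male_max_het_frac >= 0, female_min_het_frac <= 1,
            male_max_het_frac < female_min_het_frac)
  structure(list(male_max_het_frac = male_max_het_frac,
                 female_min_het_frac = female_min_het_frac),
            class = "sex_check_config")
}

#' Verify sample sex from X-chromosome heterozygosity
#'
#' Computes each sample's heterozygous fraction over non-missing X-linked
#' genotypes (callers should pass sites outside the pseudoautosomal regions)
#' and infers sex by thresholding. When a pedigree is supplied, the expected
#' sex (fathers male, mothers female, children as labelled) is compared with
#' the inference and conflicts are flagged.
#'
#' @param x_genotypes numeric matrix of X-linked genotype dosages (0/1/2,
#'   NA = missing), sites in rows, samples in columns (column names = sample
#'   IDs). Hemizygous male calls should be coded 0/2.
#' @param config a [sex_check_config()].
#' @param ped optional \code{trio_set} used to derive the expected sex.
#' @return data.frame with \code{sample}, \code{n_sites}, \code{het_frac},
#'   \code{inferred_sex} (\code{male}/\code{female}/\code{unassigned}) and,
#'   if \code{ped} is given, \code{pedigree_sex} and \code{conflict}.
#' @export
verify_sex_labels <- function(x_genotypes, config = sex_check_config(),
                              ped = NULL) {
  stopifnot(is.matrix(x_genotypes))
  samples <- colnames(x_genotypes) %||% as.character(seq_len(ncol(x_genotypes)))
  n_sites <- colSums(!is.na(x_genotypes))
  het <- colSums(x_genotypes == 1, na.rm = TRUE)
  het_frac <- ifelse(n_sites > 0, het / n_sites, NA_real_)
  inferred <- rep("unassigned", length(samples))
  inferred[!is.na(het_frac) & het_frac < config$male_max_het_frac] <- "male"
  inferred[!is.na(het_frac) & het_frac > config$female_min_het_frac] <- "female"
  if (any(n_sites == 0)) {
    warning("sample(s) with zero usable X sites left unassigned: ",
            paste(samples[n_sites == 0], collapse = ", "))
  }
  out <- data.frame(sample = samples, n_sites = as.integer(n_sites),
                    het_frac = het_frac, inferred_sex = inferred,
                    stringsAsFactors = FALSE)
  if (!is.null(ped)) {
    expected <- c(
      stats::setNames(rep("male", nrow(ped)), ped$father_id),
      stats::setNames(rep("female", nrow(ped)), ped$mother_id),
      stats::setNames(ped$child_sex, ped$child_id)
    )
    out$pedigree_sex <- unname(expected[out$sample])
    out$conflict <- !is.na(out$pedigree_sex) &
      out$inferred_sex != "unassigned" &
      out$inferred_sex != out$pedigree_sex
  }
  out
}
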