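# Classification of distorted SNPs and regions into sex-antagonistic (SA),
# sex-limited (SL) and sex-differential (SD) signals.

#' Classification configuration
#'
#' @param t magnitude threshold on |eps_m + eps_f| relative to
#'   max(|eps_m|, |eps_f|) (default 0.05, the genome-wide standard
#'   deviation of per-SNP distortion estimates in a 250-trio design).
#' @param snp_alpha per-SNP significance cutoff on the M2-vs-M0 LRT
#'   p-value for a SNP to enter region classification (default 0.05).
#' @param region_majority share of classified SNPs a single category must
#'   reach for a region to carry that label (default 0.75).
#' @return a \code{classify_config} list.
#' @export
classify_config <- function(t = 0.05, snp_alpha = 0.05,
                            region_majority = 0.75) {
  stopifnot(t >= 0, snp_alpha > 0, snp_alpha < 1,
            region_majority > 0.5, region_majority <= 1)
  structure(list(t = t, snp_alpha = snp_alpha,
                 region_majority = region_majority),
            class = "classify_config")
}

#' Classify a SNP by its sex-specific distortion estimates
#'
#' With s = |eps_m + eps_f| and M = max(|eps_m|, |eps_f|): opposite-direction
#' distortion shrinks s below M (sex-antagonistic, \code{SA}: s < M - t),
#' same-direction distortion pushes s above M (sex-differential, \code{SD}:
#' s > M + t), and distortion confined to one sex leaves s within t of M
#' (sex-limited, \code{SL}). The three cases partition the square
#' \[-1/2, 1/2\]^2.
#'
#' @param eps_m,eps_f finite sex-specific distortion estimates (vectorised).
#' @param config a [classify_config()]; only \code{t} is used.
#' @return character vector of \code{"SA"}/\code{"SL"}/\code{"SD"}.
#' @export
classify_snp <- function(eps_m, eps_f, config = classify_config()) {
  stopifnot(length(eps_m) == length(eps_f),
            all(is.finite(eps_m)), all(is.finite(eps_f)))
  s <- abs(eps_m + eps_f)
  M <- pmax(abs(eps_m), abs(eps_f))
  ifelse(s < M - config$t, "SA", ifelse(s > M + config$t, "SD", "SL"))
}

#' Label a called region from its SNP fits
#'
#' Only SNPs significant at \code{snp_alpha} on the M2-vs-M0 LRT are
#' classified; the region carries the modal category's label when its share
#' among classified SNPs reaches \code{region_majority}, and is labelled
#' \code{"mixed"} otherwise. A region with no classifiable SNP is
#' \code{"mixed"} and flagged.
#'
#' @param fits data.frame of SNP fits for the region (columns \code{eps_m},
#'   \code{eps_f}, \code{p20}).
#' @param config a [classify_config()].
#' @return one-row data.frame: \code{label}, \code{n_snps},
#'   \code{n_classified}, \code{n_SA}, \code{n_SL}, \code{n_SD},
#'   \code{mean_abs_eps_m}, \code{mean_abs_eps_f}, \code{mean_abs_delta},
#'   \code{no_classifiable}.
#' @export
classify_region <- function(fits, config = classify_config()) {
  if (is.null(fits) || nrow(fits) == 0) stop("region contains no SNPs")
  sig <- !is.na(fits$p20) & fits$p20 < config$snp_alpha &
    is.finite(fits$eps_m) & is.finite(fits$eps_f)
  lab <- classify_snp(fits$eps_m[sig], fits$eps_f[sig], config)
  tab <- c(SA = sum(lab == "SA"), SL = sum(lab == "SL"),
           SD = sum(lab == "SD"))
  n_cls <- sum(tab)
  if (n_cls == 0) {
    label <- "mixed"
  } else {
    top <- names(tab)[which.max(tab)]
    label <- if (max(tab) / n_cls >= config$region_majority) top else "mixed"
  }
  data.frame(
    label = label, n_snps = nrow(fits), n_classified = n_cls,
    n_SA = unname(tab["SA"]), n_SL = unname(tab["SL"]),
    n_SD = unname(tab["SD"]),
    mean_abs_eps_m = mean(abs(fits$eps_m[sig])),
    mean_abs_eps_f = mean(abs(fits$eps_f[sig])),
    mean_abs_delta = mean(abs(fits$eps_m[sig] - fits$eps_f[sig])),
    no_classifiable = n_cls == 0,
    stringsAsFactors = FALSE)
}

#' Label every called region of a scan
#'
#' Assigns SNP fits to regions by chromosome and position and applies
#' [classify_region()] to each.
#'
#' @param fits full scan table (columns \code{chrom}, \code{pos},
#'   \code{eps_m}, \code{eps_f}, \code{p20}).
#' @param regions data.frame of called regions (columns \code{chrom},
#'   \code{start}, \code{end}, 1-based inclusive; extra columns carried
#'   through).
#' @param config a [classify_config()].
#' @return \code{regions} with the [classify_region()] summary columns
#'   appended.
#' @export
classify_regions <- function(fits, regions, config = classify_config()) {
  if (nrow(regions) == 0) {
    return(cbind(regions, classify_region(
      data.frame(eps_m = 0, eps_f = 0, p20 = 1), config)[0, ]))
  }
  summaries <- lapply(seq_len(nrow(regions)), function(i) {
    in_r <- fits$chrom == regions$chrom[i] &
      fits$pos >= regions$start[i] & fits$pos <= regions$end[i]
    classify_region(fits[in_r, , drop = FALSE], config)
  })
  out <- cbind(regions, do.call(rbind, summaries))
  rownames(out) <- NULL
  out
}
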