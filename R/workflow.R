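# End-to-end orchestration: counts -> model scan -> local score -> region
# classification -> intersexual F_ST, with a manifest for reproducibility.

#' Run configuration for a full scan
#'
#' @param vcf path to the trio VCF.
#' @param ped path to the pedigree file (see [read_pedigree()]).
#' @param out_dir output directory for stage TSVs, BED, manifest and log.
#' @param filter a [filter_config()].
#' @param classify a [classify_config()].
#' @param xi local-score aggregation threshold (default 1).
#' @param alpha chromosome-wise local-score significance level
#'   (default 0.05).
#' @param mc_reps Monte-Carlo replicates for the local-score threshold
#'   (default 1000).
#' @param seed master seed; each chromosome's threshold simulation uses a
#'   sub-seed derived from it, so reruns are byte-identical.
#' @param cohort compute intersexual F_ST in \code{"offspring"} (default)
#'   or \code{"parents"}.
#' @param ci compute profile CIs in the scan stage (default TRUE).
#' @return a \code{run_config} list.
#' @export
run_config <- function(vcf, ped, out_dir, filter = filter_config(),
                       classify = classify_config(), xi = 1, alpha = 0.05,
                       mc_reps = 1000, seed = 1,
                       cohort = c("offspring", "parents"), ci = TRUE) {
  cohort <- match.arg(cohort)
  stopifnot(inherits(filter, "filter_config"),
            inherits(classify, "classify_config"),
            xi > 0, alpha > 0, alpha < 1, mc_reps >= 1)
  structure(list(vcf = vcf, ped = ped, out_dir = out_dir, filter = filter,
                 classify = classify, xi = xi, alpha = alpha,
                 mc_reps = mc_reps, seed = seed, cohort = cohort,
                 ci = isTRUE(ci)),
            class = "run_config")
}

#' Run the full transmission-distortion scan
#'
#' Executes counts, model fitting, per-chromosome local-score region
#' calling, region classification and intersexual F_ST in order, writing
#' each stage's output as plain TSV/BED so stages are independently
#' inspectable, plus a JSON manifest (parameters, seeds, input checksums,
#' package version) and a log. Identical configs produce byte-identical
#' outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list of output paths plus the in-memory stage
#'   results (\code{counts}, \code{fits}, \code{regions},
#'   \code{labeled_regions}, \code{fst}).
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$vcf)) stop("counts stage: VCF not found: ",
                                     config$vcf)
  if (!file.exists(config$ped)) stop("counts stage: pedigree not found: ",
                                     config$ped)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(name, " stage failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ped <- stage("pedigree", read_pedigree(config$ped))
  say("pedigree: ", nrow(ped), " trios (",
      sum(ped$child_sex == "male"), " sons, ",
      sum(ped$child_sex == "female"), " daughters)")

  cc <- stage("counts", trio_counts(config$vcf, ped, config$filter))
  say("counts: ", nrow(cc$counts), " of ", nrow(cc$filter_log),
      " sites kept")
  counts_path <- write_tsv(cc$counts, file.path(config$out_dir, "counts.tsv"))
  log_tsv <- write_tsv(cc$filter_log,
                       file.path(config$out_dir, "filter_log.tsv"))

  fits <- stage("scan", td_scan(cc$counts, ci = config$ci))
  fits_path <- write_tsv(fits, file.path(config$out_dir, "fits.tsv"))
  say("scan: fitted ", sum(fits$fit_ok), " sites")

  chroms <- unique(fits$chrom)
  regions <- list()
  for (k in seq_along(chroms)) {
    sub <- fits[fits$chrom == chroms[k] & fits$fit_ok, ]
    if (nrow(sub) == 0) next
    track <- stage("local_score",
                   lindley(sub$p20, xi = config$xi, positions = sub$pos,
                           chrom = chroms[k]))
    track$sig_threshold <- stage("local_score",
      mc_threshold(nrow(sub), xi = config$xi, alpha = config$alpha,
                   reps = config$mc_reps, seed = config$seed + k))
    regions[[k]] <- call_regions(track)
    say("local_score: ", chroms[k], ": threshold ",
        signif(track$sig_threshold, 4), ", ", nrow(regions[[k]]),
        " region(s)")
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    call_regions(structure(list(chrom = "0", positions = 1, pvalues = 1,
                                scores = -1, heights = 0, xi = config$xi,
                                sig_threshold = 1),
                           class = "lindley_track"))
  regions_path <- write_tsv(regions,
                            file.path(config$out_dir, "regions.tsv"))
  bed_path <- regions_to_bed(regions,
                             file.path(config$out_dir, "regions.bed"))

  labeled <- stage("classify",
                   classify_regions(fits, regions, config$classify))
  labeled_path <- write_tsv(labeled,
                            file.path(config$out_dir,
                                      "labeled_regions.tsv"))
  say("classify: ", paste(sprintf("%s=%d",
      c("SA", "SL", "SD", "mixed"),
      vapply(c("SA", "SL", "SD", "mixed"),
             function(l) sum(labeled$label == l), integer(1))),
      collapse = " "))

  fst <- stage("fst", run_fst_stage(config, ped))
  fst_path <- write_tsv(fst, file.path(config$out_dir, "fst.tsv"))

  manifest <- list(
    package = "triodistort",
    version = as.character(utils::packageVersion("triodistort")),
    parameters = list(
      xi = config$xi, alpha = config$alpha, mc_reps = config$mc_reps,
      seed = config$seed, cohort = config$cohort,
      filter = unclass(config$filter), classify = unclass(config$classify)),
    inputs = list(vcf = unname(tools::md5sum(config$vcf)),
                  ped = unname(tools::md5sum(config$ped))),
    outputs = list(
      counts.tsv = unname(tools::md5sum(counts_path)),
      fits.tsv = unname(tools::md5sum(fits_path)),
      regions.tsv = unname(tools::md5sum(regions_path)),
      labeled_regions.tsv = unname(tools::md5sum(labeled_path)),
      fst.tsv = unname(tools::md5sum(fst_path))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)

  invisible(list(
    paths = list(counts = counts_path, filter_log = log_tsv,
                 fits = fits_path, regions = regions_path, bed = bed_path,
                 labeled_regions = labeled_path, fst = fst_path,
                 manifest = manifest_path, log = log_path),
    counts = cc$counts, fits = fits, regions = regions,
    labeled_regions = labeled, fst = fst))
}

run_fst_stage <- function(config, ped) {
  v <- read_vcf_input(config$vcf)
  fix <- get_fix_df(v)
  dos <- gt_dosage(vcfR::extract.gt(v, element = "GT"))
  if (config$cohort == "offspring") {
    ids <- ped$child_id
    sexes <- ped$child_sex
  } else {
    ids <- c(ped$father_id, ped$mother_id)
    sexes <- rep(c("male", "female"), each = nrow(ped))
  }
  res <- intersexual_fst(dos[, ids, drop = FALSE], sexes,
                         chrom = fix$CHROM)
  cbind(data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS)),
        res[, setdiff(names(res), "chrom")])
}
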