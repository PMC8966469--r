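# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without clobbering the caller's
# random-number stream. seed = NULL leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# x * log(y) with the 0 * log(0) == 0 convention used throughout the
# binomial log-likelihoods.
xlogy <- function(x, y) {
  out <- x * log(y)
  out[x == 0] <- 0
  out
}

# TRUE for chromosome names denoting the X (chrX, X, x, 23).
is_x_chrom <- function(chrom) {
  toupper(sub("^chr", "", as.character(chrom), ignore.case = TRUE)) %in%
    c("X", "23")
}

chrom_class_of <- function(chrom) {
  ifelse(is_x_chrom(chrom), "X", "autosome")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
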