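# Simulate a phased candidate region: a few divergent haplotype classes
# segregating in trios, with optionally sex-biased transmission of the
# lowest-numbered class when a parent is heterozygous between classes.
# Returns everything the follow-up pipeline consumes.
sim_hap_region <- function(n_trios = 120, n_sites = 60,
                           freqs = c(0.35, 0.34, 0.31), bias = 0,
                           noise = 0.02, p_male = 0.5, seed = 1) {
  set.seed(seed)
  n_class <- length(freqs)
  protos <- matrix(rbinom(n_sites * n_class, 1, 0.5), nrow = n_sites)
  make_hap <- function(class) {
    h <- protos[, class]
    flip <- runif(n_sites) < noise
    h[flip] <- 1 - h[flip]
    h
  }
  haps <- matrix(NA_integer_, nrow = n_sites, ncol = 6 * n_trios)
  carrier <- data.frame(sample = character(6 * n_trios),
                        sex = character(6 * n_trios),
                        role = character(6 * n_trios),
                        true_class = integer(6 * n_trios),
                        stringsAsFactors = FALSE)
  ped <- tiny_ped(n_trios, sexes = ifelse(runif(n_trios) < p_male,
                                          "male", "female"))
  col <- 0L
  put <- function(id, sex, role, class, hap) {
    col <<- col + 1L
    haps[, col] <<- hap
    carrier$sample[col] <<- id
    carrier$sex[col] <<- sex
    carrier$role[col] <<- role
    carrier$true_class[col] <<- class
  }
  transmit <- function(classes, hap_pair, child_sex) {
    if (classes[1] == classes[2]) {
      i <- sample(1:2, 1)
    } else {
      lower_first <- which.min(classes)
      p_lower <- if (child_sex == "male") 0.5 + bias else 0.5 - bias
      i <- if (runif(1) < p_lower) lower_first else 3 - lower_first
    }
    list(class = classes[i], hap = hap_pair[[i]])
  }
  for (t in seq_len(n_trios)) {
    fc <- sample(n_class, 2, replace = TRUE, prob = freqs)
    mc <- sample(n_class, 2, replace = TRUE, prob = freqs)
    fh <- list(make_hap(fc[1]), make_hap(fc[2]))
    mh <- list(make_hap(mc[1]), make_hap(mc[2]))
    put(ped$father_id[t], "male", "father", fc[1], fh[[1]])
    put(ped$father_id[t], "male", "father", fc[2], fh[[2]])
    put(ped$mother_id[t], "female", "mother", mc[1], mh[[1]])
    put(ped$mother_id[t], "female", "mother", mc[2], mh[[2]])
    pat <- transmit(fc, fh, ped$child_sex[t])
    mat <- transmit(mc, mh, ped$child_sex[t])
    put(ped$child_id[t], ped$child_sex[t], "child", pat$class, pat$hap)
    put(ped$child_id[t], ped$child_sex[t], "child", mat$class, mat$hap)
  }
  list(haps = haps, carrier = carrier, ped = ped, protos = protos)
}
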