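# Shared fixtures and independent oracles for the test suite.

# The two desk-scale count vectors used throughout (pattern order "---".."+++")
counts_curve <- c(17L, 5L, 27L, 5L, 16L, 5L, 19L, 6L)   # one positive pair correlation
counts_face <- c(21L, 12L, 9L, 8L, 7L, 11L, 17L, 15L)   # all positive, triangle fails

# Independent enumeration oracle for pattern probabilities: sum over the root
# state (uniform on +/-1) of the product of per-leaf transition probabilities
# (1 + sigma_i * root * theta_i) / 2.  Shares no code with the package.
enum_pattern_probs <- function(theta) {
  sigma <- as.matrix(expand.grid(s3 = c(-1, 1), s2 = c(-1, 1), s1 = c(-1, 1)))
  sigma <- sigma[, c("s1", "s2", "s3")]
  vapply(seq_len(8), function(r) {
    p <- 0
    for (root in c(-1, 1)) {
      term <- 0.5
      for (i in 1:3) term <- term * (1 + sigma[r, i] * root * theta[i]) / 2
      p <- p + term
    }
    p
  }, numeric(1))
}

# Brute-force log-likelihood from the 8 full pattern probabilities
brute_loglik <- function(theta, counts) {
  p <- enum_pattern_probs(theta)
  keep <- counts > 0
  if (any(p[keep] <= 0)) return(-Inf)
  sum(counts[keep] * log(p[keep]))
}

# Random count vectors satisfying both genericity assumptions
rand_generic_counts <- function(n_sites) {
  repeat {
    p <- as.numeric(stats::rmultinom(1, 1000, rep(1, 8))) + 1
    s <- as.numeric(stats::rmultinom(1, n_sites, p / sum(p)))
    gen <- check_genericity(s)
    if (gen$a1_holds && gen$a2_holds) return(s)
  }
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
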