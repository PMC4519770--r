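# Shared fixtures built in code.

# Reads that are exact copies of the reference with G at the given sites.
edited_read <- function(sites, region = htr2c_region()) {
  s <- region$reference_sequence
  for (site in sites) {
    pos <- region$site_offsets[[site]] + 1L
    substring(s, pos, pos) <- "G"
  }
  s
}

# A small expression-study generator with planted blocks only (no hub).
block_expr <- function(n_blocks, genes_per_block, n_samples, noise_sd = 0.2,
                       seed = 1) {
  set.seed(seed)
  truth <- rep(seq_len(n_blocks), each = genes_per_block)
  f <- matrix(rnorm(n_blocks * n_samples), n_blocks, n_samples)
  x <- f[truth, ] + matrix(rnorm(length(truth) * n_samples, sd = noise_sd),
                           length(truth), n_samples)
  rownames(x) <- sprintf("g%03d", seq_along(truth))
  list(expr = x, truth = truth)
}

# All permutations of 1..n as an n! x n matrix (recursive construction).
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Two-sided Fisher p by direct hypergeometric tail summation (oracle).
fisher_p_oracle <- function(n11, n10, n01, n00) {
  m <- n11 + n10; nn <- n01 + n00; k <- n11 + n01
  x <- max(0, k - nn):min(m, k)
  d <- stats::dhyper(x, m, nn, k)
  sum(d[d <= stats::dhyper(n11, m, nn, k) * (1 + 1e-7)])
}

# The printed control variant mixture, remaining mass uniform.
results_mixture <- function(region = htr2c_region()) {
  named <- c(ABD = 0.36, ABCD = 0.18, AB = 0.14, NONE = 0.03)
  rest <- setdiff(enumerate_variants(region), names(named))
  c(named, stats::setNames(rep((1 - sum(named)) / length(rest), length(rest)),
                           rest))
}
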