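# Shared fixtures and independent oracles for the test suite.

# Tiny synthetic study, generated once per test run and memoized.
.sim_cache <- new.env(parent = emptyenv())
tiny_sim <- function(seed = 20240101) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]])) {
    p <- sim_params_tiny(seed = seed)
    sim <- simulate_genome(p)
    meth <- suppressMessages(simulate_methylome(sim$genome, sim$features, p))
    .sim_cache[[key]] <- list(params = p, genome = sim$genome,
                              features = sim$features, meth = meth)
  }
  .sim_cache[[key]]
}

# Build a site table from vectors (defaults keep tests terse).
make_sites <- function(pos, methylated, coverage, contig = "c1", strand = "+",
                       context = "CG") {
  data.table::data.table(contig = contig, pos = as.integer(pos),
                         strand = strand, context = context,
                         methylated = as.integer(methylated),
                         coverage = as.integer(coverage),
                         frequency = methylated / coverage)
}

# Independent two-sided Fisher oracle: enumerate all 2x2 tables with the
# observed margins, computing each probability from binomial coefficients
# directly (no dhyper), and sum those no likelier than the observed table.
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n2 <- b + d; k <- a + b; N <- a + b + c + d
  if (m == 0 || n2 == 0 || k == 0 || (c + d) == 0) return(1)
  prob_of <- function(x) {
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(N, k))
  }
  xs <- max(0, k - n2):min(k, m)
  ps <- vapply(xs, prob_of, numeric(1))
  p_obs <- prob_of(a)
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# One-sided (greater) hypergeometric tail oracle for GO enrichment.
hyper_tail_oracle <- function(k, n, K, N) {
  xs <- k:min(n, K)
  sum(vapply(xs, function(x) {
    exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
  }, numeric(1)))
}

# Reverse complement for symmetry properties.
revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

expect_tsv_file <- function(path) {
  expect_true(file.exists(path))
  invisible(path)
}
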