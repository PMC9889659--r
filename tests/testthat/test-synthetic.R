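# The synthetic-methylome generator: determinism, calibration, ground truth.

test_that("generation is deterministic for a fixed seed", {
  p <- sim_params_tiny(seed = 5)
  a <- simulate_genome(p)
  b <- simulate_genome(p)
  expect_identical(a$genome, b$genome)
  expect_identical(a$features, b$features)
  ma <- suppressMessages(simulate_methylome(a$genome, a$features, p))
  mb <- suppressMessages(simulate_methylome(b$genome, b$features, p))
  expect_identical(ma$sample_a, mb$sample_a)
  expect_identical(ma$truth$planted, mb$truth$planted)
})

test_that("genome composition and TE fraction hit their targets", {
  p <- sim_params_tiny(seed = 9, te_fraction = 0.1)
  sim <- simulate_genome(p)
  n <- sum(nchar(sim$genome))
  gc <- sum(vapply(strsplit(sim$genome, "", fixed = TRUE),
                   function(x) sum(x %in% c("G", "C")), integer(1)))
  # binomial 3-sd band around the requested GC fraction
  expect_lt(abs(gc / n - 0.5), 3 * sqrt(0.25 / n))
  te_bases <- sum(sim$features$tes$end - sim$features$tes$start)
  expect_gte(te_bases / n, 0.08)
  expect_lte(te_bases / n, 0.12)
  # genes are non-overlapping and inside their contigs
  genes <- sim$features$genes[order(contig, start)]
  by_ctg <- split(genes, genes$contig)
  for (g in by_ctg) {
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
    expect_true(all(g$end <= nchar(sim$genome[g$contig[1]])))
  }
})

test_that("estimated global levels recover the planted site probabilities", {
  sim <- tiny_sim()
  probs <- sim$meth$truth$site_probs
  for (cx in c("CG", "CHG", "CHH")) {
    for (stage in c("a", "b")) {
      s <- sim$meth[[paste0("sample_", stage)]]
      est <- global_methylation_level(s, cx, min_coverage = 1)$level
      pcx <- probs[probs$context == cx][[paste0("p_", stage)]]
      truth <- mean(pcx)
      # 3 binomial s.d. of the pooled read draw
      reads <- sum(s$coverage[s$context == cx])
      expect_lt(abs(est - truth), 3 * sqrt(truth * (1 - truth) / reads) + 1e-3)
    }
  }
})

test_that("planted truth aligns to window boundaries and is hyper in stage A", {
  sim <- tiny_sim()
  tr <- sim$meth$truth$planted
  expect_equal(nrow(tr), 10L)
  expect_true(all(tr$start %% sim$params$window_size == 0))
  expect_true(all(tr$end - tr$start == sim$params$window_size))
  expect_true(all(tr$direction == "hyper_in_A"))
  probs <- sim$meth$truth$site_probs
  # inside planted windows the stage-A probability is the planted fold
  key <- paste(probs$contig, probs$pos %/% sim$params$window_size)
  pk <- paste(tr$contig, tr$start %/% sim$params$window_size)
  inside <- probs[key %in% pk & probs$context == "CG"]
  expect_true(all(abs(inside$p_a - pmin(1, 6 * inside$p_b)) < 1e-12))
})

test_that("a null simulation produces no more DMRs than the false-positive budget", {
  p <- sim_params_tiny(seed = 23, planted_fold = 1, stage_b_scale = 1)
  sim <- simulate_genome(p)
  meth <- suppressMessages(simulate_methylome(sim$genome, sim$features, p))
  d <- call_dmrs(meth$sample_a, meth$sample_b, sim$genome, "CG")
  n_tested <- attr(d, "n_tested")
  # alpha * tested windows plus 3 binomial s.d.; the fold filter makes the
  # realized count far smaller still
  budget <- 0.05 * n_tested + 3 * sqrt(n_tested * 0.05 * 0.95)
  expect_lte(nrow(d), budget)
})

test_that("TE-elevated methylation shows up in the TE metaprofile", {
  sim <- tiny_sim()
  pr <- feature_metaprofile(sim$meth$sample_a, sim$features$tes,
                            context = "CHH", flank_bp = 1000,
                            n_body_bins = 20, n_flank_bins = 10)
  body <- pr$value[pr$segment == "body"]
  flank <- pr$value[pr$segment != "body"]
  expect_gt(mean(body, na.rm = TRUE), mean(flank, na.rm = TRUE))
})

test_that("the fixture bundle round-trips and regenerates identically", {
  p <- sim_params_tiny(seed = 31)
  d1 <- withr::local_tempdir()
  paths <- suppressMessages(write_fixture_bundle(d1, p))
  g <- read_fasta(paths[["fasta"]])
  sim <- simulate_genome(p)
  expect_identical(g, sim$genome)
  fs <- read_gff_features(paths[["gff"]],
                          contig_lengths = vapply(g, nchar, integer(1)))
  expect_equal(fs$genes, sim$features$genes)
  expect_equal(fs$tes, sim$features$tes)
  a <- read_site_frequencies(paths[["sample_a"]])
  meth <- suppressMessages(simulate_methylome(sim$genome, sim$features, p))
  expect_equal(a, meth$sample_a)
  tr <- read_bed_intervals(paths[["truth"]])
  expect_true(all(tr$start %% p$window_size == 0))

  # regeneration from the same params is byte-identical
  d2 <- withr::local_tempdir()
  suppressMessages(write_fixture_bundle(d2, p))
  for (f in basename(paths)) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)),
                     label = f)
  }
})

test_that("infeasible parameter requests are rejected", {
  expect_error(sim_params(genome_length = 5e4, n_genes = 60),
               "infeasible packing")
  p <- sim_params_tiny(seed = 2, n_planted_dmr_windows = 1000)
  sim <- simulate_genome(p)
  expect_error(suppressMessages(
    simulate_methylome(sim$genome, sim$features, p)),
    "exceed available windows")
})
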