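# Tiling windows, Fisher's exact test, DMR calling and annotation.

test_that("tiling windows cover the genome exactly, keeping the short tail", {
  g <- c(c1 = paste(rep("A", 2500), collapse = ""),
         c2 = paste(rep("A", 600), collapse = ""))
  w <- tile_windows(g, 1000)
  expect_equal(nrow(w), 4L)
  expect_equal(w[w$contig == "c1", end - start], c(1000L, 1000L, 500L))
  expect_equal(w[w$contig == "c2", end - start], 600L)  # w > contig: 1 window
  expect_equal(sum(w$end - w$start), 3100L)
})

test_that("window counts pool only cytosines covered in both samples", {
  g <- c(c1 = paste(rep("A", 1000), collapse = ""))
  a <- make_sites(pos = c(10, 20, 30, 40), methylated = c(2, 3, 0, 1),
                  coverage = c(10, 10, 10, 4))
  b <- make_sites(pos = c(10, 20, 30, 40), methylated = c(1, 1, 1, 1),
                  coverage = c(8, 8, 8, 3))
  wc <- window_counts(a, b, g, "CG")
  # pos 40: coverage 4/3 fails the both-samples filter
  expect_equal(wc$n_qualifying, 3L)
  expect_equal(wc$methylated_a, 5L)
  expect_equal(wc$coverage_a, 30L)
  expect_equal(wc$level_a, 1 / 6)
  expect_equal(wc$methylated_b, 3L)

  # empty window: zero qualifying cytosines, undefined levels
  wc0 <- window_counts(a[1], b[2], g, "CG")
  expect_equal(wc0$n_qualifying, 0L)
  expect_true(is.na(wc0$level_a))
})

test_that("two-sided Fisher matches brute-force enumeration and fisher.test", {
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_two_sided(0, 0, 0, 0), 1)  # all-zero margin
  expect_equal(fisher_exact_two_sided(3, 0, 0, 0), 1)

  # frozen worked examples, computed with the enumeration oracle
  expect_equal(fisher_exact_two_sided(20, 20, 2, 38),
               fisher_oracle(20, 20, 2, 38), tolerance = 1e-12)
  expect_equal(fisher_oracle(20, 20, 2, 38), 8.3344428188e-06,
               tolerance = 1e-9)
  expect_equal(fisher_exact_two_sided(0, 10, 10, 0),
               fisher_oracle(0, 10, 10, 0), tolerance = 1e-12)
  expect_equal(fisher_oracle(0, 10, 10, 0), 2 / choose(20, 10),
               tolerance = 1e-12)

  set.seed(99)
  for (i in 1:250) {
    tab <- as.vector(stats::rmultinom(1, sample(10:200, 1), runif(4)))
    p <- fisher_exact_two_sided(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p, fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
    expect_equal(p, stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("identical samples yield zero DMRs; planted differences are called", {
  sim <- tiny_sim()
  a <- sim$meth$sample_a
  d0 <- call_dmrs(a, a, sim$genome, "CG")
  expect_equal(nrow(d0), 0L)
  expect_gt(attr(d0, "n_tested"), 0L)

  d <- call_dmrs(a, sim$meth$sample_b, sim$genome, "CG")
  expect_gt(nrow(d), 0L)
  expect_true(all(d$fold_change >= 2))
  expect_true(all(d$p_value < 0.05))
  # emitted p-values agree with the independent oracle
  for (i in seq_len(min(5, nrow(d)))) {
    expect_equal(d$p_value[i],
                 fisher_oracle(d$methylated_a[i],
                               d$coverage_a[i] - d$methylated_a[i],
                               d$methylated_b[i],
                               d$coverage_b[i] - d$methylated_b[i]),
                 tolerance = 1e-9)
  }
})

test_that("windows below the cytosine floor are never emitted", {
  g <- c(c1 = paste(rep("A", 1000), collapse = ""))
  mk <- function(m) make_sites(pos = c(10, 20, 30, 40), methylated = m,
                               coverage = 30)
  a <- mk(c(27, 27, 27, 27))   # level 0.9, but only 4 qualifying cytosines
  b <- mk(c(1, 2, 1, 2))
  d <- call_dmrs(a, b, g, "CG", min_cytosines = 5)
  expect_equal(nrow(d), 0L)
  d5 <- call_dmrs(a, b, g, "CG", min_cytosines = 4)
  expect_equal(nrow(d5), 1L)
  expect_equal(d5$direction, "hyper_in_A")
})

test_that("swapping samples flips every direction and preserves p-values", {
  sim <- tiny_sim()
  d <- call_dmrs(sim$meth$sample_a, sim$meth$sample_b, sim$genome, "CG")
  swapped <- call_dmrs(sim$meth$sample_b, sim$meth$sample_a, sim$genome, "CG")
  expect_equal(nrow(d), nrow(swapped))
  m <- merge(d, swapped, by = c("contig", "start", "end"))
  expect_equal(m$p_value.x, m$p_value.y)
  expect_true(all(m$direction.x != m$direction.y))
})

test_that("planted-DMR recovery on a 1 Mb simulation reaches high sensitivity and precision", {
  p <- sim_params(seed = 314)   # 1 Mb => ~1000 tiling windows, 10 planted
  sim <- simulate_genome(p)
  meth <- suppressMessages(simulate_methylome(sim$genome, sim$features, p))
  d <- call_dmrs(meth$sample_a, meth$sample_b, sim$genome, "CG")
  truth <- meth$truth$planted
  tp <- nrow(merge(d, truth, by = c("contig", "start", "end")))
  expect_gte(tp / nrow(truth), 0.9)              # sensitivity
  expect_gte(tp / max(nrow(d), 1), 0.9)          # precision
  expect_gte(attr(d, "n_tested"), 900L)
})

test_that("compartment assignment follows majority overlap with stated precedence", {
  dmrs <- data.table::data.table(
    contig = "c1", start = c(0L, 5000L, 9000L), end = c(1000L, 6000L, 10000L),
    context = "CG", direction = "hyper_in_A")
  features <- list(
    genes = data.table::data.table(gene_id = "g1", contig = "c1",
                                   start = 5600L, end = 8000L, strand = "+"),
    tes = data.table::data.table(contig = "c1", start = 5000L, end = 5600L))
  promoters <- data.table::data.table(gene_id = "g1", contig = "c1",
                                      start = 0L, end = 1000L, strand = "+")
  res <- assign_dmr_compartments(dmrs, features, promoters)
  # fully inside a promoter; 600 bp TE vs 400 bp gene body; nothing -> IGR
  expect_equal(res$dmrs$compartment, c("promoter", "TE", "IGR"))
  expect_equal(sum(res$proportions$proportion), 1)
})

test_that("compartment proportions sum to one within every stratum", {
  sim <- tiny_sim()
  d <- call_dmrs(sim$meth$sample_a, sim$meth$sample_b, sim$genome, "CG")
  proms <- promoter_intervals(sim$features$genes)
  res <- assign_dmr_compartments(d, sim$features, proms)
  sums <- res$proportions[, list(s = sum(proportion)),
                          by = list(context, direction)]
  expect_true(all(abs(sums$s - 1) < 1e-12))
})

test_that("DMGs follow the promoter-overlap rule with half-open semantics", {
  genes <- data.table::data.table(gene_id = c("g1", "g2"), contig = "c1",
                                  start = c(10000L, 50000L),
                                  end = c(12000L, 52000L), strand = "+")
  proms <- promoter_intervals(genes)   # g1: [9000, 10500)
  dmr <- function(s, e) data.table::data.table(contig = "c1", start = s,
                                               end = e, context = "CG",
                                               direction = "hyper_in_A")
  expect_equal(differentially_methylated_genes(dmr(9400L, 9600L), genes,
                                               proms)$gene_id, "g1")
  # DMR ending exactly at promoter start: half-open abutment, no overlap
  expect_equal(nrow(differentially_methylated_genes(dmr(8000L, 9000L), genes,
                                                    proms)), 0L)
  # two DMRs in one promoter: gene listed once
  two <- rbind(dmr(9100L, 9200L), dmr(9300L, 9400L))
  expect_equal(differentially_methylated_genes(two, genes, proms)$gene_id, "g1")
})

test_that("TE enrichment score matches its closed form and a per-base oracle", {
  g100k <- c(c1 = paste(rep("A", 100000), collapse = ""))
  tes <- data.table::data.table(contig = "c1", start = 0L, end = 10000L)
  dmr <- data.table::data.table(contig = "c1", start = 9600L, end = 10600L,
                                context = "CG", direction = "hyper_in_A")
  sc <- te_enrichment_score(dmr, tes, g100k)
  expect_equal(sc$score, 2)   # log2((400/1000) / 0.1)

  # DMR overlap fraction equal to the genomic TE fraction -> score 0
  dmr0 <- data.table::data.table(contig = "c1", start = 9900L, end = 10900L,
                                 context = "CG", direction = "hyper_in_A")
  expect_equal(te_enrichment_score(dmr0, tes, g100k)$score, 0)

  # 3-DMR toy vs naive per-base counting
  dmrs <- data.table::data.table(contig = "c1",
                                 start = c(500L, 9500L, 50000L),
                                 end = c(1500L, 10500L, 51000L),
                                 context = "CG", direction = "hyper_in_A")
  te_mask <- rep(FALSE, 100000); te_mask[1:10000] <- TRUE
  ov <- 0; tot <- 0
  for (i in 1:3) {
    idx <- (dmrs$start[i] + 1):dmrs$end[i]
    ov <- ov + sum(te_mask[idx]); tot <- tot + length(idx)
  }
  oracle <- log2((ov / tot) / (10000 / 100000))
  expect_equal(te_enrichment_score(dmrs, tes, g100k)$score, oracle)

  # several strata score independently
  multi <- rbind(dmr, dmr0)
  multi$direction <- c("hyper_in_A", "hypo_in_A")
  sm <- te_enrichment_score(multi, tes, g100k)
  expect_equal(nrow(sm), 2L)
  expect_equal(sm[sm$direction == "hyper_in_A", score], 2)
  expect_equal(sm[sm$direction == "hypo_in_A", score], 0)

  # empty stratum and absent TEs are undefined
  expect_equal(nrow(te_enrichment_score(dmrs[0], tes, g100k)), 0L)
  no_te <- data.table::data.table(contig = character(), start = integer(),
                                  end = integer())
  expect_true(is.na(te_enrichment_score(dmrs, no_te, g100k)$score))
})
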