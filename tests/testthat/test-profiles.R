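# Metagene profiles around TSS/TES and across feature bodies.

toy_genes <- function() {
  data.table::data.table(gene_id = c("g1", "g2", "g3"), contig = "c1",
                         start = c(5000L, 12000L, 20000L),
                         end = c(8000L, 15000L, 22000L),
                         strand = c("+", "-", "+"))
}

test_that("constant methylation yields constant defined bins", {
  genome_len <- 30000
  pos <- seq(0, genome_len - 1, by = 37)
  s <- make_sites(pos = pos, methylated = 5, coverage = 10)
  pr <- feature_metaprofile(s, toy_genes(), context = "CG",
                            flank_bp = 2000, n_body_bins = 20,
                            n_flank_bins = 10)
  expect_equal(nrow(pr), 40L)
  expect_true(all(pr$value[!is.na(pr$value)] == 0.5))
  expect_true(any(!is.na(pr$value)))
})

test_that("a + gene and its mirrored - gene give identical profiles", {
  # same site pattern relative to the TSS on both orientations
  gp <- data.table::data.table(gene_id = "p", contig = "c1", start = 10000L,
                               end = 13000L, strand = "+")
  gm <- data.table::data.table(gene_id = "m", contig = "c1", start = 10000L,
                               end = 13000L, strand = "-")
  set.seed(5)
  off <- sort(sample(-1999:4999, 300))
  m <- rbinom(300, 20, 0.3)
  sp <- make_sites(pos = 10000 + off, methylated = m, coverage = 20)
  # mirror the pattern around the gene: offset d from + TSS -> pos end-1-d
  sm <- make_sites(pos = (13000 - 1) - off, methylated = m, coverage = 20)
  pp <- feature_metaprofile(sp, gp, context = "CG")
  pm <- feature_metaprofile(sm, gm, context = "CG")
  expect_equal(pp$value, pm$value)
  expect_equal(pp$n_sites, pm$n_sites)
})

test_that("a step methylome maps to bins exactly as the explicit table predicts", {
  genes <- toy_genes()
  pos <- seq(0, 29999, by = 13)
  inside <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(genes))) {
    inside <- inside | (pos >= genes$start[i] & pos < genes$end[i])
  }
  s <- make_sites(pos = pos, methylated = ifelse(inside, 10L, 0L),
                  coverage = 10)
  nf <- 10L; nb <- 20L; flank <- 1000
  pr <- feature_metaprofile(s, genes, context = "CG", flank_bp = flank,
                            n_body_bins = nb, n_flank_bins = nf)
  # independent site-to-bin oracle by explicit enumeration
  meth <- tot <- cnt <- numeric(2 * nf + nb)
  for (i in seq_len(nrow(genes))) {
    len <- genes$end[i] - genes$start[i]
    for (j in seq_along(pos)) {
      d <- if (genes$strand[i] == "-") (genes$end[i] - 1) - pos[j]
           else pos[j] - genes$start[i]
      b <- if (d >= -flank && d < 0) floor((d + flank) / flank * nf)
           else if (d >= 0 && d < len) nf + floor(d / len * nb)
           else if (d >= len && d < len + flank) nf + nb + floor((d - len) / flank * nf)
           else next
      meth[b + 1] <- meth[b + 1] + s$methylated[j]
      tot[b + 1] <- tot[b + 1] + s$coverage[j]
      cnt[b + 1] <- cnt[b + 1] + 1
    }
  }
  expect_equal(pr$value, ifelse(tot > 0, meth / tot, NA_real_))
  expect_equal(pr$n_sites, as.integer(cnt))
  # body bins are fully methylated; flank bins away from boundaries are 0
  body <- pr$segment == "body"
  expect_true(all(pr$value[body] > 0.5, na.rm = TRUE))
  # total incidences: each site counted once per overlapping feature window
  expect_equal(sum(pr$n_sites), sum(cnt))
})

test_that("profiles are invariant under reverse-complementing genome and annotation", {
  sim <- tiny_sim()
  genes <- sim$features$genes[1:10]
  s <- sim$meth$sample_a
  pr <- feature_metaprofile(s, genes, context = "CG", flank_bp = 500,
                            n_body_bins = 10, n_flank_bins = 5)
  # mirror everything through the contig ends
  lens <- vapply(sim$genome, nchar, integer(1))
  genes_rc <- data.table::copy(genes)
  genes_rc[, `:=`(start = lens[contig] - genes$end,
                  end = lens[contig] - genes$start,
                  strand = ifelse(genes$strand == "+", "-", "+"))]
  s_rc <- data.table::copy(s)
  s_rc[, `:=`(pos = lens[contig] - 1L - pos,
              strand = ifelse(strand == "+", "-", "+"))]
  pr_rc <- feature_metaprofile(s_rc, genes_rc, context = "CG", flank_bp = 500,
                               n_body_bins = 10, n_flank_bins = 5)
  expect_equal(pr$value, pr_rc$value)
})

test_that("export writes one row per bin with empty fields for undefined bins", {
  genome_len <- 30000
  s <- make_sites(pos = seq(0, 10000, by = 100), methylated = 3, coverage = 10)
  pr <- feature_metaprofile(s, toy_genes(), context = "CG",
                            n_body_bins = 60, n_flank_bins = 20)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_metaprofile(pr, f)
  lines <- readLines(f)
  expect_equal(length(lines), 101L)  # header + 100 bins
  # undefined bins serialize as empty value fields, not 0
  na_bins <- which(is.na(pr$value))
  expect_true(length(na_bins) > 0)
  fields <- strsplit(lines[na_bins[1] + 1L], "\t")[[1]]
  expect_identical(fields[3], "")
  # re-export is byte-identical
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_metaprofile(pr, f2)
  expect_identical(readLines(f2), lines)

  expect_error(feature_metaprofile(s, toy_genes()[0]), "empty")
})
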