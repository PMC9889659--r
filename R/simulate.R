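# Seeded generator of a toy fungal genome, gene/TE annotation and
# two-stage per-site methylation tables with planted DMR windows.
#
# The generator emulates the statistical structure of a sparsely
# methylated fungal methylome: context ordering CG > CHG > CHH,
# TE-elevated and gene-body-depleted methylation, a global stage effect
# (stage A "mycelium-like" above stage B "conidia-like"), and a set of
# planted hypermethylated windows that downstream DMR calling should
# recover.

#' Simulation parameters
#'
#' Builds a validated parameter list for the synthetic methylome
#' generator. Defaults describe a ~1 Mb toy fungal genome at 50% GC with
#' ~300 genes/Mb and a small TE complement, stage-A genome-wide
#' methylation probabilities CG/CHG/CHH = 0.05/0.012/0.008 with an 8x TE
#' multiplier and 0.5x gene-body multiplier, stage B at 0.6x stage A, mean
#' read coverage 30, and 10 planted CG windows of fold 6 (hyper in stage
#' A) on 1 kb window boundaries.
#'
#' @param genome_length Total genome length in bp.
#' @param n_contigs Number of contigs (lengths split evenly).
#' @param gc_fraction Genome GC fraction.
#' @param n_genes Number of genes to place (non-overlapping, random
#'   strands).
#' @param gene_length_min,gene_length_max Uniform gene-length bounds (bp).
#' @param te_fraction Target fraction of the genome covered by TEs,
#'   placed in intergenic space.
#' @param te_length_min,te_length_max Uniform TE-length bounds (bp).
#' @param base_prob Named stage-A genome-wide methylation probabilities
#'   per context.
#' @param te_multiplier,gene_body_multiplier Compartment multipliers
#'   applied to `base_prob` (TE-elevated, gene-body-depleted).
#' @param stage_b_scale Stage B probability = stage A probability x this.
#' @param coverage_mean Mean of the per-site Poisson read coverage.
#' @param n_planted_dmr_windows Number of planted DMR windows.
#' @param planted_fold Planted fold: stage-A probability inside planted
#'   windows is `min(1, planted_fold x stage-B probability)`.
#' @param planted_context Context of the planted windows.
#' @param window_size Tiling window size that planted windows align to.
#' @param seed RNG seed recorded with the parameters.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(genome_length = 1e6, n_contigs = 4, gc_fraction = 0.5,
                       n_genes = 300, gene_length_min = 800,
                       gene_length_max = 2500, te_fraction = 0.045,
                       te_length_min = 200, te_length_max = 2000,
                       base_prob = c(CG = 0.05, CHG = 0.012, CHH = 0.008),
                       te_multiplier = 8, gene_body_multiplier = 0.5,
                       stage_b_scale = 0.6, coverage_mean = 30,
                       n_planted_dmr_windows = 10, planted_fold = 6,
                       planted_context = "CG", window_size = 1000,
                       seed = 1) {
  p <- as.list(environment())
  stopifnot(p$genome_length >= 1000, p$n_contigs >= 1,
            p$gc_fraction > 0, p$gc_fraction < 1,
            all(p$base_prob >= 0), all(p$base_prob <= 1),
            all(sort(names(p$base_prob)) == c("CG", "CHG", "CHH")),
            p$stage_b_scale > 0, p$coverage_mean > 0,
            p$te_fraction >= 0, p$planted_fold >= 1,
            p$planted_context %in% c("CG", "CHG", "CHH"),
            p$window_size >= 1)
  gene_frac <- p$n_genes * (p$gene_length_min + p$gene_length_max) / 2 /
    p$genome_length
  if (gene_frac + p$te_fraction > 0.95) {
    stop("infeasible packing: genes + TEs would exceed the genome")
  }
  structure(p, class = "sim_params")
}

#' Tiny simulation preset
#'
#' The small preset used throughout the test suite: a 200 kb, 2-contig
#' genome with 60 genes, keeping every downstream stage fast while leaving
#' ~200 tiling windows of 1 kb for DMR calling.
#'
#' @param ... Overrides forwarded to [sim_params()].
#' @return A `sim_params` list.
#' @export
sim_params_tiny <- function(...) {
  defaults <- list(genome_length = 2e5, n_contigs = 2, n_genes = 60)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

#' Simulate a toy genome with gene and TE annotation
#'
#' Draws i.i.d. bases at the requested GC fraction, places non-overlapping
#' genes with random strands by randomly partitioning the intergenic space,
#' and fills intergenic gaps with TE intervals up to `te_fraction`.
#' Deterministic for a given seed.
#'
#' @param params A [sim_params()] list.
#' @param seed RNG seed (defaults to `params$seed`).
#' @return list: `genome` (named character vector) and `features`
#'   (list of `genes` and `tes` data.tables).
#' @export
simulate_genome <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  base_len <- params$genome_length %/% params$n_contigs
  lens <- rep(base_len, params$n_contigs)
  lens[params$n_contigs] <- lens[params$n_contigs] +
    params$genome_length - sum(lens)
  names(lens) <- sprintf("ctg%02d", seq_len(params$n_contigs))
  pr <- c(A = (1 - params$gc_fraction) / 2, C = params$gc_fraction / 2,
          G = params$gc_fraction / 2, T = (1 - params$gc_fraction) / 2)
  genome <- vapply(lens, function(n) {
    paste(sample(names(pr), n, replace = TRUE, prob = pr), collapse = "")
  }, character(1))

  # genes: assign to contigs proportional to length, place in order with
  # random intergenic gaps obtained by partitioning the leftover space
  n_per <- round(params$n_genes * lens / sum(lens))
  n_per[length(n_per)] <- params$n_genes - sum(n_per[-length(n_per)])
  genes <- list(); gid <- 0L
  for (ci in seq_along(lens)) {
    ng <- n_per[ci]
    if (ng <= 0) next
    glen <- sample(params$gene_length_min:params$gene_length_max, ng,
                   replace = TRUE)
    free <- lens[ci] - sum(glen)
    if (free < 0) stop("infeasible packing: genes exceed contig ", names(lens)[ci])
    cuts <- sort(stats::runif(ng))
    gaps <- floor(diff(c(0, cuts, 1)) * free)
    gaps[length(gaps)] <- gaps[length(gaps)] + free - sum(gaps)
    start <- cumsum(gaps[-length(gaps)]) + cumsum(c(0, glen[-ng]))
    genes[[ci]] <- data.table::data.table(
      gene_id = sprintf("g%04d", gid + seq_len(ng)),
      contig = names(lens)[ci],
      start = as.integer(start), end = as.integer(start + glen),
      strand = sample(c("+", "-"), ng, replace = TRUE))
    gid <- gid + ng
  }
  genes <- data.table::rbindlist(genes)

  # TEs: fill intergenic gaps at random until the target fraction
  tes <- .place_tes(lens, genes, params)
  list(genome = genome, features = list(genes = genes[], tes = tes))
}

.place_tes <- function(lens, genes, params) {
  target <- params$te_fraction * sum(lens)
  gaps <- list()
  for (ci in names(lens)) {
    g <- genes[genes$contig == ci]
    data.table::setorder(g, start)
    edges <- c(0L, as.vector(rbind(g$start, g$end)), lens[[ci]])
    starts <- edges[seq(1, length(edges), by = 2)]
    ends <- edges[seq(2, length(edges), by = 2)]
    keep <- ends - starts >= params$te_length_min
    if (any(keep)) {
      gaps[[ci]] <- data.table::data.table(contig = ci, start = starts[keep],
                                           end = ends[keep])
    }
  }
  gaps <- data.table::rbindlist(gaps)
  tes <- list(); placed <- 0
  while (placed < target && nrow(gaps) > 0) {
    gi <- sample.int(nrow(gaps), 1, prob = gaps$end - gaps$start)
    space <- gaps$end[gi] - gaps$start[gi]
    tl <- min(space,
              sample(params$te_length_min:params$te_length_max, 1))
    off <- sample.int(space - tl + 1L, 1) - 1L
    s <- gaps$start[gi] + off
    tes[[length(tes) + 1L]] <- data.table::data.table(
      contig = gaps$contig[gi], start = s, end = s + tl)
    placed <- placed + tl
    # split the used gap
    left <- data.table::data.table(contig = gaps$contig[gi],
                                   start = gaps$start[gi], end = s)
    right <- data.table::data.table(contig = gaps$contig[gi],
                                    start = s + tl, end = gaps$end[gi])
    gaps <- rbind(gaps[-gi],
                  left[left$end - left$start >= params$te_length_min],
                  right[right$end - right$start >= params$te_length_min])
  }
  if (length(tes) == 0L) {
    return(data.table::data.table(contig = character(), start = integer(),
                                  end = integer()))
  }
  out <- data.table::rbindlist(tes)
  data.table::setorder(out, contig, start)
  out[, `:=`(start = as.integer(start), end = as.integer(end))]
  out[]
}

#' Simulate two-stage per-site methylation tables with planted DMRs
#'
#' Classifies every cytosine of the simulated genome, assigns each site a
#' true methylation probability from its context and compartment
#' (TE-elevated, gene-body-depleted, otherwise genome-wide), scales stage
#' B by `stage_b_scale`, and overrides stage A inside planted windows so
#' that `p_A = min(1, planted_fold x p_B)`. Per site and stage, coverage
#' is Poisson(`coverage_mean`) (zero-coverage sites dropped, matching real
#' frequency-table semantics) and the methylated count is binomial.
#'
#' Planted windows are chosen among full-length tiling windows containing
#' at least 8 sites of the planted context, and always align to
#' `window_size` boundaries.
#'
#' @param genome Simulated genome (named character vector).
#' @param features Feature set from [simulate_genome()].
#' @param params A [sim_params()] list.
#' @param seed RNG seed (defaults to `params$seed + 1`, a separate stream
#'   from the genome draw).
#' @return list: `sample_a`, `sample_b` (site tables), `truth` (list:
#'   `planted` window table with context and direction, `site_probs`
#'   per-site true probabilities per stage, `compartments` per-site
#'   compartment labels).
#' @export
simulate_methylome <- function(genome, features, params,
                               seed = params$seed + 1) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  ctx <- classify_cytosine_contexts(genome)
  sites <- data.table::as.data.table(ctx)

  # compartment per site: TE > gene body > background
  comp <- rep("background", nrow(sites))
  in_te <- .overlap_bases(data.table::data.table(contig = sites$contig,
                                                 start = sites$pos,
                                                 end = sites$pos + 1L),
                          features$tes) > 0
  in_gene <- .overlap_bases(data.table::data.table(contig = sites$contig,
                                                   start = sites$pos,
                                                   end = sites$pos + 1L),
                            features$genes) > 0
  comp[in_gene] <- "gene_body"
  comp[in_te] <- "TE"
  mult <- c(TE = params$te_multiplier, gene_body = params$gene_body_multiplier,
            background = 1)[comp]
  p_a <- pmin(1, params$base_prob[sites$context] * mult)
  p_b <- pmin(1, p_a * params$stage_b_scale)

  # choose planted windows among full windows with enough context sites
  wins <- tile_windows(genome, params$window_size)
  full <- wins[wins$end - wins$start == params$window_size]
  sites[, win := pos %/% as.integer(params$window_size)]
  full[, win := start %/% as.integer(params$window_size)]
  density <- sites[context == params$planted_context,
                   list(n = .N), by = list(contig, win)]
  cand <- density[full, on = c("contig", "win")][!is.na(n) & n >= 8]
  if (nrow(cand) < params$n_planted_dmr_windows) {
    stop("planted windows requested exceed available windows (",
         nrow(cand), " candidates)")
  }
  pick <- cand[sample.int(nrow(cand), params$n_planted_dmr_windows)]
  planted <- pick[, list(contig, start, end,
                         context = params$planted_context,
                         direction = "hyper_in_A")]
  key <- paste(sites$contig, sites$win)
  planted_key <- paste(planted$contig, planted$start %/% params$window_size)
  sel <- key %in% planted_key & sites$context == params$planted_context
  p_a[sel] <- pmin(1, params$planted_fold * p_b[sel])

  draw <- function(p) {
    cov <- stats::rpois(length(p), params$coverage_mean)
    keep <- cov > 0
    m <- stats::rbinom(sum(keep), cov[keep], p[keep])
    data.table::data.table(contig = sites$contig[keep], pos = sites$pos[keep],
                           strand = sites$strand[keep],
                           context = sites$context[keep],
                           methylated = m, coverage = cov[keep],
                           frequency = m / cov[keep])
  }
  sample_a <- draw(p_a)
  sample_b <- draw(p_b)
  truth <- list(
    planted = planted[order(contig, start)],
    site_probs = data.table::data.table(contig = sites$contig, pos = sites$pos,
                                        strand = sites$strand,
                                        context = sites$context,
                                        p_a = unname(p_a), p_b = unname(p_b)),
    compartments = data.table::data.table(contig = sites$contig,
                                          pos = sites$pos,
                                          strand = sites$strand,
                                          compartment = comp)
  )
  sites[, win := NULL]
  list(sample_a = sample_a, sample_b = sample_b, truth = truth)
}

#' Write a complete synthetic fixture bundle
#'
#' Generates genome, annotation and two-stage methylomes from `params` and
#' writes them as plain-text files: `genome.fasta`, `annotation.gff3`,
#' `sample_a.tsv` / `sample_b.tsv` (minimal6 dialect),
#' `truth_dmrs.bed`, and `params.txt` (key = value, including the seed),
#' from which the bundle can be regenerated bit-identically.
#'
#' @param outdir Output directory (created if needed).
#' @param params A [sim_params()] list.
#' @return Invisibly, a named vector of the written paths.
#' @export
write_fixture_bundle <- function(outdir, params = sim_params_tiny()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(params)
  meth <- simulate_methylome(sim$genome, sim$features, params)
  paths <- c(fasta = file.path(outdir, "genome.fasta"),
             gff = file.path(outdir, "annotation.gff3"),
             sample_a = file.path(outdir, "sample_a.tsv"),
             sample_b = file.path(outdir, "sample_b.tsv"),
             truth = file.path(outdir, "truth_dmrs.bed"),
             params = file.path(outdir, "params.txt"))
  writeLines(paste0(">", names(sim$genome), "\n", sim$genome), paths["fasta"])
  .write_gff3(sim$features, .contig_lengths(sim$genome), paths["gff"])
  .write_minimal6(meth$sample_a, paths["sample_a"])
  .write_minimal6(meth$sample_b, paths["sample_b"])
  tr <- meth$truth$planted
  write_bed_intervals(tr[, list(contig, start, end,
                                name = paste0(context, ":", direction))],
                      paths["truth"])
  scal <- params[!vapply(params, function(x) length(x) > 1, logical(1))]
  vec <- params$base_prob
  writeLines(c(paste(names(scal), "=", unlist(scal)),
               paste0("base_prob_", names(vec), " = ", vec)),
             paths["params"])
  invisible(paths)
}

# minimal GFF3 writer for the simulated annotation
.write_gff3 <- function(features, contig_lengths, path) {
  lines <- c("##gff-version 3",
             paste("##sequence-region", names(contig_lengths), 1,
                   contig_lengths))
  g <- features$genes
  if (nrow(g) > 0) {
    lines <- c(lines, paste(g$contig, "methtiler_sim", "gene", g$start + 1L,
                            g$end, ".", g$strand, ".",
                            paste0("ID=", g$gene_id), sep = "\t"))
  }
  t <- features$tes
  if (nrow(t) > 0) {
    lines <- c(lines, paste(t$contig, "methtiler_sim", "transposable_element",
                            t$start + 1L, t$end, ".", ".", ".",
                            paste0("ID=te", seq_len(nrow(t))), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a synthetic gene-to-GO annotation
#'
#' Assigns each gene 0-3 GO terms drawn from a small synthetic vocabulary
#' spanning the BP/CC/MF namespaces, so GO enrichment can be exercised on
#' fully synthetic inputs. The mapping is random and carries no biological
#' meaning.
#'
#' @param gene_ids Character vector of gene ids.
#' @param n_terms Size of the synthetic GO vocabulary (default 30).
#' @param seed RNG seed.
#' @return data.table: gene_id, go_id, namespace.
#' @export
simulate_go_annotation <- function(gene_ids, n_terms = 30, seed = 1) {
  set.seed(seed)
  terms <- sprintf("GO:%07d", sample.int(9999999, n_terms))
  ns <- sample(c("BP", "CC", "MF"), n_terms, replace = TRUE)
  res <- lapply(gene_ids, function(g) {
    k <- sample(0:3, 1)
    if (k == 0) return(NULL)
    i <- sample.int(n_terms, k)
    data.table::data.table(gene_id = g, go_id = terms[i], namespace = ns[i])
  })
  data.table::rbindlist(res)
}
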