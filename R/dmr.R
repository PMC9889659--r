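# Non-overlapping tiling-window DMR calling between two samples.
#
# A window is tested only if it contains enough cytosines that are covered
# in BOTH samples; read counts are pooled within the window and compared
# with Fisher's exact test on the 2x2 table
# [[methylated_A, unmethylated_A], [methylated_B, unmethylated_B]].

#' Tile a genome with non-overlapping windows
#'
#' Per contig: \[0,w), \[w,2w), ...; the trailing short window is kept, so
#' the tiled length equals the genome length.
#'
#' @param genome Genome (named character vector or `DNAStringSet`).
#' @param window_size Window width in bp (default 1000).
#' @return data.table: contig, start, end.
#' @export
tile_windows <- function(genome, window_size = 1000) {
  stopifnot(window_size >= 1)
  lens <- .contig_lengths(genome)
  w <- as.integer(window_size)
  data.table::rbindlist(lapply(names(lens), function(ctg) {
    n <- lens[[ctg]]
    starts <- seq.int(0L, n - 1L, by = w)
    data.table::data.table(contig = ctg, start = starts,
                           end = pmin(starts + w, n))
  }))
}

#' Per-window pooled methylation counts for two samples
#'
#' For one context, joins the two samples' sites by (contig, pos, strand).
#' A cytosine qualifies only if it is covered by at least
#' `min_site_coverage` reads in BOTH samples; pooled window counts sum
#' qualifying cytosines only.
#'
#' @param sites_a,sites_b Context-annotated site tables for samples A and B.
#' @param genome Genome for window tiling.
#' @param context Context to analyse (`"CG"`, `"CHG"`, `"CHH"`).
#' @param window_size Window width in bp (default 1000).
#' @param min_site_coverage Per-site, per-sample coverage floor (default 4).
#' @return data.table with one row per tiled window: contig, start, end,
#'   context, n_qualifying, methylated_a, coverage_a, methylated_b,
#'   coverage_b, level_a, level_b (levels NA when no qualifying cytosine).
#' @export
window_counts <- function(sites_a, sites_b, genome, context,
                          window_size = 1000, min_site_coverage = 4) {
  .check_sites(sites_a, need_context = TRUE)
  .check_sites(sites_b, need_context = TRUE)
  ctx <- .check_context_arg(context)
  ctx_set <- .context_set(ctx)
  a <- data.table::as.data.table(sites_a)
  b <- data.table::as.data.table(sites_b)
  a <- a[a$context %in% ctx_set]
  b <- b[b$context %in% ctx_set]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("context '", context, "' absent from sample ",
         if (nrow(a) == 0L) "A" else "B")
  }
  j <- merge(a[, list(contig, pos, strand, methylated_a = methylated,
                      coverage_a = coverage)],
             b[, list(contig, pos, strand, methylated_b = methylated,
                      coverage_b = coverage)],
             by = c("contig", "pos", "strand"))
  j <- j[coverage_a >= min_site_coverage & coverage_b >= min_site_coverage]
  w <- as.integer(window_size)
  wins <- tile_windows(genome, w)
  wins[, win := start %/% w]
  if (nrow(j) > 0) {
    j[, win := pos %/% w]
    agg <- j[, list(n_qualifying = .N,
                    methylated_a = sum(methylated_a),
                    coverage_a = sum(coverage_a),
                    methylated_b = sum(methylated_b),
                    coverage_b = sum(coverage_b)),
             by = list(contig, win)]
  } else {
    agg <- data.table::data.table(contig = character(), win = integer(),
                                  n_qualifying = integer(),
                                  methylated_a = integer(), coverage_a = integer(),
                                  methylated_b = integer(), coverage_b = integer())
  }
  out <- agg[wins, on = c("contig", "win")]
  out[is.na(n_qualifying), `:=`(n_qualifying = 0L, methylated_a = 0L,
                                coverage_a = 0L, methylated_b = 0L,
                                coverage_b = 0L)]
  out[, `:=`(level_a = ifelse(coverage_a > 0, methylated_a / coverage_a, NA_real_),
             level_b = ifelse(coverage_b > 0, methylated_b / coverage_b, NA_real_),
             context = context, win = NULL)]
  data.table::setcolorder(out, c("contig", "start", "end", "context",
                                 "n_qualifying"))
  data.table::setorder(out, contig, start)
  out[]
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `[[a, b], [c, d]]`, computed by
#' summing hypergeometric point probabilities no larger than the observed
#' table's (within relative tolerance 1e-7, to absorb floating-point
#' ties). A table with an all-zero margin is defined to have p = 1.
#'
#' @param a,b,c,d Non-negative integer cell counts; for methylation calls
#'   the table is `[[methylated_A, unmethylated_A], [methylated_B,
#'   unmethylated_B]]`.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_two_sided(5, 5, 5, 5)    # 1: the observed table is the mode
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  stopifnot(length(a) == 1, a >= 0, b >= 0, c >= 0, d >= 0)
  if ((a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)) return(1)
  m <- a + c          # first-column margin ("white balls")
  n2 <- b + d         # second-column margin
  k <- a + b          # first-row margin (draws)
  support <- max(0, k - n2):min(k, m)
  dens <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}

# vectorized over windows
.fisher_vec <- function(a, b, c, d) {
  vapply(seq_along(a), function(i) fisher_exact_two_sided(a[i], b[i], c[i], d[i]),
         numeric(1))
}

#' Call differentially methylated regions (DMRs)
#'
#' Tiling-window DMR calling between two samples for one context. A window
#' is emitted as a DMR iff (i) it contains at least `min_cytosines`
#' cytosines covered by at least `min_site_coverage` reads in both
#' samples, (ii) the pooled window levels differ by at least
#' `fold_threshold`-fold after adding `pseudocount` to both levels, and
#' (iii) the Fisher p-value of the pooled 2x2 read counts is below
#' `alpha`. Direction is `hyper_in_A` when sample A's level exceeds
#' sample B's.
#'
#' With the reference orientation A = mycelium-like, B = conidia-like,
#' `hyper_in_A` reads as "hypermethylated in the mycelium".
#'
#' @inheritParams window_counts
#' @param min_cytosines Minimum qualifying cytosines per window (default 5).
#' @param fold_threshold Minimum fold difference of pooled levels
#'   (default 2).
#' @param alpha Significance threshold (default 0.05, on the raw p-value
#'   unless `adjust = "bh"`).
#' @param pseudocount Added to both levels before the fold ratio, so the
#'   criterion is defined at level 0 (default 0.01).
#' @param adjust `"none"` (raw p, the default) or `"bh"`
#'   (Benjamini-Hochberg across all windows meeting the site filter; the
#'   adjusted p is then compared with `alpha`).
#' @return data.table of DMR windows with pooled counts, levels,
#'   fold_change (>= 1), p_value, adjusted_p and direction
#'   (`hyper_in_A` / `hypo_in_A`). Attribute `n_tested` records how many
#'   windows met the site filter.
#' @export
call_dmrs <- function(sites_a, sites_b, genome, context,
                      window_size = 1000, min_cytosines = 5,
                      min_site_coverage = 4, fold_threshold = 2,
                      alpha = 0.05, pseudocount = 0.01,
                      adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  wc <- window_counts(sites_a, sites_b, genome, context,
                      window_size = window_size,
                      min_site_coverage = min_site_coverage)
  tested <- wc[n_qualifying >= min_cytosines]
  n_tested <- nrow(tested)
  if (n_tested == 0L) {
    out <- tested[, `:=`(fold_change = numeric(0), p_value = numeric(0),
                         adjusted_p = numeric(0), direction = character(0))]
    data.table::setattr(out, "n_tested", 0L)
    return(out[])
  }
  tested[, fold_change := (pmax(level_a, level_b) + pseudocount) /
           (pmin(level_a, level_b) + pseudocount)]
  tested[, p_value := .fisher_vec(methylated_a, coverage_a - methylated_a,
                                  methylated_b, coverage_b - methylated_b)]
  tested[, adjusted_p := stats::p.adjust(p_value, method = "BH")]
  p_eff <- if (adjust == "bh") tested$adjusted_p else tested$p_value
  out <- tested[fold_change >= fold_threshold & p_eff < alpha]
  out[, direction := ifelse(level_a > level_b, "hyper_in_A", "hypo_in_A")]
  data.table::setorder(out, contig, start)
  data.table::setattr(out, "n_tested", n_tested)
  out[]
}

#' Assign DMRs to genomic compartments
#'
#' Labels each DMR with one compartment by largest base-pair overlap among
#' promoter, TE and gene body, with precedence promoter > TE > gene body
#' on ties; a DMR overlapping none of them is intergenic (`IGR`). Also
#' returns the compartment proportions per (context, direction), which sum
#' to 1 within each stratum.
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param features Feature set with `genes` and `tes` (see
#'   [read_gff_features()]).
#' @param promoters Promoter intervals from [promoter_intervals()].
#' @return list with `dmrs` (input plus `compartment` column) and
#'   `proportions` (data.table: context, direction, compartment, n,
#'   proportion).
#' @export
assign_dmr_compartments <- function(dmrs, features, promoters) {
  dmrs <- data.table::as.data.table(dmrs)
  ov_prom <- .overlap_bases(dmrs, promoters)
  ov_te <- .overlap_bases(dmrs, features$tes)
  ov_gene <- .overlap_bases(dmrs, features$genes)
  comp <- rep("IGR", nrow(dmrs))
  if (nrow(dmrs) > 0) {
    mat <- cbind(promoter = ov_prom, TE = ov_te, gene_body = ov_gene)
    best <- max.col(mat, ties.method = "first")  # column order = precedence
    has <- mat[cbind(seq_len(nrow(mat)), best)] > 0
    comp[has] <- colnames(mat)[best[has]]
  }
  dmrs[, compartment := comp]
  props <- dmrs[, list(n = .N), by = list(context, direction, compartment)]
  props[, proportion := n / sum(n), by = list(context, direction)]
  list(dmrs = dmrs[], proportions = props[])
}

#' Differentially methylated genes (DMGs)
#'
#' A gene is a DMG for a given (context, direction) iff its promoter
#' interval overlaps at least 1 bp of at least one DMR of that stratum;
#' each gene is listed once per stratum.
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param genes Gene table.
#' @param promoters Promoter intervals from [promoter_intervals()].
#' @return data.table: gene_id, context, direction.
#' @export
differentially_methylated_genes <- function(dmrs, genes, promoters) {
  dmrs <- data.table::as.data.table(dmrs)
  promoters <- data.table::as.data.table(promoters)
  out <- data.table::data.table(gene_id = character(), context = character(),
                                direction = character())
  if (nrow(dmrs) == 0L || nrow(promoters) == 0L) return(out)
  strata <- unique(dmrs[, list(context, direction)])
  res <- list()
  for (s in seq_len(nrow(strata))) {
    d <- dmrs[context == strata$context[s] & direction == strata$direction[s]]
    hit <- .overlap_bases(promoters, d) > 0
    if (any(hit)) {
      res[[length(res) + 1L]] <- data.table::data.table(
        gene_id = unique(promoters$gene_id[hit]),
        context = strata$context[s], direction = strata$direction[s])
    }
  }
  if (length(res)) data.table::rbindlist(res) else out
}

#' Transposable-element enrichment score of DMRs
#'
#' For each (context, direction) stratum, the log2 ratio of the fraction
#' of DMR bases overlapping TEs to the genomic TE fraction:
#' `log2((DMR bases in TEs / DMR bases) / (TE bases / genome bases))`.
#' Positive scores mean DMRs fall in TEs more often than chance; the score
#' is `NA` (undefined) for an empty stratum or a genome without annotated
#' TEs, and `-Inf` when a non-empty stratum has zero TE overlap.
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param te_intervals TE interval table (contig, start, end).
#' @param genome Genome (for total base count).
#' @return data.table: context, direction, score, dmr_bases,
#'   te_overlap_bases, te_fraction.
#' @export
te_enrichment_score <- function(dmrs, te_intervals, genome) {
  dmrs <- data.table::as.data.table(dmrs)
  te_intervals <- data.table::as.data.table(te_intervals)
  genome_bases <- sum(.contig_lengths(genome))
  te_bases <- .union_bases(te_intervals)
  te_fraction <- te_bases / genome_bases
  if (nrow(dmrs) == 0L) {
    return(data.table::data.table(context = character(), direction = character(),
                                  score = numeric(), dmr_bases = numeric(),
                                  te_overlap_bases = numeric(),
                                  te_fraction = numeric()))
  }
  ov <- .overlap_bases(dmrs, te_intervals)
  dmrs[, te_ov := ov]
  out <- dmrs[, list(dmr_bases = sum(end - start), te_overlap_bases = sum(te_ov)),
              by = list(context, direction)]
  tf <- te_fraction
  out[, te_fraction := tf]
  out[, score := if (tf == 0) NA_real_ else
    log2((out$te_overlap_bases / out$dmr_bases) / tf)]
  data.table::setcolorder(out, c("context", "direction", "score"))
  out[]
}
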