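# Assembly summary statistics and the 2^-dCt relative-expression formula.

#' Assembly summary statistics
#'
#' Sequence-derived summary of a genome assembly: contig count, total and
#' largest contig length, GC%, and Nx/Lx statistics. Nx is the length of
#' the contig at which the cumulative length (contigs sorted descending,
#' ties kept in input order) first reaches x% of the total; Lx is the
#' number of contigs needed. GC% excludes N and ambiguity characters from
#' the denominator, the usual assembly-QC convention.
#'
#' @param genome Genome (named character vector or `DNAStringSet`).
#' @return list: n_contigs, total_length, largest_contig, gc_percent,
#'   n50, l50, n90, l90.
#' @examples
#' assembly_stats(c(a = "ACGTN"))$gc_percent  # 50: N excluded
#' @export
assembly_stats <- function(genome) {
  g <- .genome_chars(genome)
  if (length(g) == 0L || all(nchar(g) == 0L)) stop("empty genome")
  lens <- nchar(g)
  counts <- Reduce(`+`, lapply(g, function(s) {
    tab <- table(factor(strsplit(s, "", fixed = TRUE)[[1]],
                        levels = c("A", "C", "G", "T")))
    as.numeric(tab)
  }))
  names(counts) <- c("A", "C", "G", "T")
  gc <- 100 * (counts["C"] + counts["G"]) / sum(counts)
  nx <- function(x) {
    sorted <- sort(lens, decreasing = TRUE, method = "radix")  # stable: ties in input order
    cum <- cumsum(as.numeric(sorted))
    i <- which(cum >= x / 100 * sum(as.numeric(lens)))[1]
    list(n = unname(sorted[i]), l = i)
  }
  n50 <- nx(50); n90 <- nx(90)
  list(n_contigs = length(g),
       total_length = sum(as.numeric(lens)),
       largest_contig = unname(max(lens)),
       gc_percent = unname(gc),
       n50 = n50$n, l50 = n50$l,
       n90 = n90$n, l90 = n90$l)
}

#' Gene density in genes per megabase
#'
#' @param n_genes Number of annotated protein-coding genes.
#' @param total_length_bp Assembly length in bp.
#' @return Genes per Mb, rounded to 2 decimals.
#' @examples
#' gene_density(10848, 34189895)  # 317.29
#' @export
gene_density <- function(n_genes, total_length_bp) {
  stopifnot(total_length_bp > 0, n_genes >= 0)
  round(n_genes / (total_length_bp / 1e6), 2)
}

#' Relative expression by the 2^-dCt method
#'
#' Relative qPCR expression of a target gene against a reference gene:
#' `2^-(Ct_target - Ct_reference)`. Vectorized.
#'
#' @param ct_target Cycle threshold(s) of the target gene.
#' @param ct_reference Cycle threshold(s) of the reference gene.
#' @return Relative expression level(s).
#' @examples
#' relative_expression_ddct(21, 20)  # 0.5
#' @export
relative_expression_ddct <- function(ct_target, ct_reference) {
  stopifnot(is.finite(ct_target), is.finite(ct_reference))
  2^(-(ct_target - ct_reference))
}
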