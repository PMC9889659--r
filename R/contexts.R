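# Cytosine context classification (CG / CHG / CHH, H = A,C,T) on both
# strands, and strand-aware promoter intervals.

.H <- c("A", "C", "T")

# complement that leaves codes without an ACGT complement untouched;
# such codes can never satisfy G or H and so exclude the site
.comp <- function(x) chartr("ACGT", "TGCA", x)

#' Classify every genomic cytosine into CG / CHG / CHH
#'
#' Scans both strands of a genome. A cytosine at position p on the + strand
#' is CG if the next base is G; otherwise CHG if the next two bases are H,G
#' and CHH if they are H,H (H = A, C or T). On the - strand the same rule
#' is applied reading 5'->3' toward decreasing coordinates on the
#' complement, i.e. at genomic G positions. Cytosines whose required
#' downstream bases run off the contig or include N/ambiguity codes are
#' excluded; their count is attached as attribute `n_excluded` and
#' reported with a message.
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @return data.table with contig, pos (0-based genomic position of the
#'   C/G base), strand, context; attribute `n_excluded` gives the number of
#'   strand-resolved cytosines left unclassified.
#' @export
classify_cytosine_contexts <- function(genome) {
  g <- .genome_chars(genome)
  res <- vector("list", length(g))
  n_candidates <- 0L
  for (i in seq_along(g)) {
    ch <- strsplit(g[[i]], "", fixed = TRUE)[[1]]
    n <- length(ch)
    # + strand: C positions, read downstream
    p <- which(ch == "C")
    b1 <- ifelse(p + 1L <= n, ch[pmin(p + 1L, n)], NA_character_)
    b2 <- ifelse(p + 2L <= n, ch[pmin(p + 2L, n)], NA_character_)
    ctx_p <- .context_from_next(b1, b2)
    # - strand: genomic G positions, read upstream on the complement
    q <- which(ch == "G")
    c1 <- ifelse(q - 1L >= 1L, .comp(ch[pmax(q - 1L, 1L)]), NA_character_)
    c2 <- ifelse(q - 2L >= 1L, .comp(ch[pmax(q - 2L, 1L)]), NA_character_)
    ctx_m <- .context_from_next(c1, c2)
    n_candidates <- n_candidates + length(p) + length(q)
    res[[i]] <- data.table::data.table(
      contig = names(g)[i],
      pos = c(p, q) - 1L,
      strand = rep(c("+", "-"), c(length(p), length(q))),
      context = c(ctx_p, ctx_m)
    )
  }
  out <- data.table::rbindlist(res)
  n_excl <- sum(is.na(out$context))
  out <- out[!is.na(context)]
  data.table::setorder(out, contig, pos, strand)
  if (n_excl > 0) {
    message(n_excl, " cytosine(s) excluded (contig edge or ambiguity code)")
  }
  data.table::setattr(out, "n_excluded", n_excl)
  data.table::setattr(out, "n_candidates", n_candidates)
  out[]
}

# context from the next one/two bases read 5'->3' on the site's own strand
.context_from_next <- function(b1, b2) {
  ctx <- rep(NA_character_, length(b1))
  is_cg <- !is.na(b1) & b1 == "G"
  ctx[is_cg] <- "CG"
  rest <- !is_cg & !is.na(b1) & b1 %in% .H & !is.na(b2)
  ctx[rest & b2 == "G"] <- "CHG"
  ctx[rest & b2 %in% .H] <- "CHH"
  ctx
}

#' Attach genome-derived contexts to per-site measurements
#'
#' Joins a measurement table to classified cytosines by (contig, pos,
#' strand). Measurements at positions with no classified cytosine are
#' dropped and counted (attribute `n_dropped`). When the genome is
#' supplied, a measurement whose claimed strand contradicts the genome base
#' (+ where the base is not C, - where it is not G) raises an error naming
#' the first ten offenders.
#'
#' @param site_meth Site table (see [read_site_frequencies()]).
#' @param contexts Output of [classify_cytosine_contexts()].
#' @param genome Optional genome, enabling the strand-contradiction check.
#' @return Site table with the genome-derived `context` column.
#' @export
join_sites_with_contexts <- function(site_meth, contexts, genome = NULL) {
  .check_sites(site_meth)
  sm <- data.table::as.data.table(site_meth)
  if ("context" %in% names(sm)) sm[, context := NULL]
  ctx <- data.table::as.data.table(contexts)[, list(contig, pos, strand, context)]
  if (!is.null(genome)) {
    g <- .genome_chars(genome)
    base <- vapply(seq_len(nrow(sm)), function(i) {
      substr(g[[sm$contig[i]]], sm$pos[i] + 1L, sm$pos[i] + 1L)
    }, character(1))
    bad <- (sm$strand == "+" & base != "C") | (sm$strand == "-" & base != "G")
    if (any(bad)) {
      off <- sm[which(bad)[seq_len(min(10, sum(bad)))],
                paste0(contig, ":", pos, strand)]
      stop("measurement strand contradicts genome base at: ",
           paste(off, collapse = ", "))
    }
  }
  out <- ctx[sm, on = c("contig", "pos", "strand")]
  n_drop <- sum(is.na(out$context))
  out <- out[!is.na(context)]
  if (n_drop > 0) {
    message(n_drop, " measurement(s) at unclassified positions dropped")
  }
  data.table::setcolorder(out, c("contig", "pos", "strand", "context"))
  data.table::setattr(out, "n_dropped", n_drop)
  out[]
}

#' Strand-aware promoter intervals
#'
#' Derives one promoter interval per gene as the region from `upstream` bp
#' before to `downstream` bp after the TSS, in transcription orientation.
#' For a + strand gene with TSS t the interval is `[t - upstream,
#' t + downstream)`; for a - strand gene (TSS = end - 1 in half-open
#' terms) it is the mirror image `[t - downstream + 1, t + upstream + 1)`.
#' Intervals are clipped to the contig.
#'
#' @param genes Gene table (gene_id, contig, start, end, strand).
#' @param upstream Bases upstream of the TSS (default 1000).
#' @param downstream Bases downstream of the TSS (default 500).
#' @param contig_lengths Optional named lengths for right-clipping.
#' @return data.table gene_id, contig, start, end, strand.
#' @export
promoter_intervals <- function(genes, upstream = 1000, downstream = 500,
                               contig_lengths = NULL) {
  genes <- data.table::as.data.table(genes)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  start <- ifelse(genes$strand == "+", tss - upstream, tss - downstream + 1L)
  end <- ifelse(genes$strand == "+", tss + downstream, tss + upstream + 1L)
  start <- pmax(start, 0L)
  if (!is.null(contig_lengths)) {
    end <- pmin(end, as.integer(contig_lengths[genes$contig]))
  }
  data.table::data.table(gene_id = genes$gene_id, contig = genes$contig,
                         start = as.integer(start), end = as.integer(end),
                         strand = genes$strand)
}
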