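# Internal helpers shared across modules.
#
# Coordinate convention: every interval in this package is 0-based
# half-open [start, end); IRanges (1-based closed) is used only as an
# engine for overlap/union algebra via .ir0().

`%||%` <- function(x, y) if (is.null(x)) y else x

# Normalize a genome to a named, uppercased character vector.
# Accepts a Biostrings::DNAStringSet or a named character vector.
.genome_chars <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- stats::setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    out <- genome
  } else {
    stop("genome must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    stop("genome contigs must be named with non-empty ids")
  }
  if (anyDuplicated(names(out))) {
    stop("duplicate contig ids: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  }
  toupper(out)
}

.contig_lengths <- function(genome) {
  g <- .genome_chars(genome)
  stats::setNames(nchar(g), names(g))
}

# 0-based half-open -> IRanges (1-based closed). Empty intervals are not
# representable; callers must filter start < end first.
.ir0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

# Total bases covered by the union of 0-based half-open intervals,
# computed per contig.
.union_bases <- function(dt) {
  if (nrow(dt) == 0L) return(0)
  dt <- dt[end > start]
  if (nrow(dt) == 0L) return(0)
  sum(vapply(split(dt, dt$contig), function(d) {
    sum(IRanges::width(IRanges::reduce(.ir0(d$start, d$end))))
  }, numeric(1)))
}

# Per-row bases of overlap between intervals in `query` and the union of
# intervals in `subject` (both 0-based half-open data.frames with
# contig/start/end). Returns a numeric vector aligned with query rows.
.overlap_bases <- function(query, subject) {
  out <- numeric(nrow(query))
  if (nrow(query) == 0L || nrow(subject) == 0L) return(out)
  subject <- subject[subject$end > subject$start, , drop = FALSE]
  for (ctg in unique(query$contig)) {
    qi <- which(query$contig == ctg)
    sd <- subject[subject$contig == ctg, , drop = FALSE]
    if (nrow(sd) == 0L) next
    sir <- IRanges::reduce(.ir0(sd$start, sd$end))
    qir <- .ir0(query$start[qi], query$end[qi])
    hits <- IRanges::findOverlaps(qir, sir)
    if (length(hits) == 0L) next
    ov <- IRanges::pintersect(qir[S4Vectors::queryHits(hits)],
                              sir[S4Vectors::subjectHits(hits)])
    w <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
    out[qi[as.integer(names(w))]] <- as.numeric(w)
  }
  out
}

# Validate a site table (SiteMethylation contract).
.check_sites <- function(sites, need_context = FALSE) {
  req <- c("contig", "pos", "strand", "methylated", "coverage")
  miss <- setdiff(req, names(sites))
  if (length(miss)) stop("site table missing columns: ", paste(miss, collapse = ", "))
  if (need_context && !"context" %in% names(sites)) {
    stop("site table lacks a 'context' column; run join_sites_with_contexts() first")
  }
  invisible(sites)
}

.check_context_arg <- function(context) {
  if (!context %in% c("CG", "CHG", "CHH", "5mC")) {
    stop("context must be one of 'CG', 'CHG', 'CHH', '5mC'; got '", context, "'")
  }
  context
}

# Expand "5mC" to the three sequence contexts.
.context_set <- function(context) {
  if (identical(context, "5mC")) c("CG", "CHG", "CHH") else context
}
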