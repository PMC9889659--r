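# Readers and writers for the external formats the pipeline touches:
# FASTA genomes, GFF3 annotation, BED intervals, per-site methylation
# frequency TSVs, and gene -> GO mappings.

IUPAC_DNA <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V")

#' Read a genome FASTA
#'
#' Loads all records of a FASTA file as a named character vector of
#' uppercased sequences, preserving the input record order. Record ids must
#' be unique and sequences must contain only IUPAC nucleotide characters.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per contig.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) stop("FASTA file is empty: ", path)
  # Biostrings drops invalid codes with only a warning; treat that as an
  # error and name the offending record(s)
  ss <- withCallingHandlers(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("non-IUPAC characters in FASTA record(s): ",
             paste(.bad_fasta_records(path), collapse = ", "))
      }
      invokeRestart("muffleWarning")
    })
  if (length(ss) == 0L) stop("FASTA file contains no records: ", path)
  # keep only the id token, as common FASTA headers carry descriptions
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  stats::setNames(toupper(as.character(ss)), ids)
}

#' Read per-site methylation frequencies
#'
#' Parses a per-site methylation table in one of two tab-separated dialects
#' and returns a normalized site table. Positions are normalized to 0-based
#' internally and the frequency column is always recomputed as
#' methylated / coverage. Rows with zero coverage are dropped (their count
#' is reported with a message): sparse per-site tables legitimately contain
#' them.
#'
#' Dialects:
#' \describe{
#'   \item{`minimal6`}{columns chrom, pos, strand, context, coverage,
#'     methylated.}
#'   \item{`deepsignal11`}{the 11-column per-site frequency layout of
#'     nanopore methylation callers: chrom, pos, strand, pos_in_strand,
#'     prob0_sum, prob1_sum, count_modified, count_unmodified, coverage,
#'     modification_frequency, kmer. Context is not encoded per row (these
#'     files are usually split by motif); supply it via `context`.}
#' }
#'
#' @param path Path to the TSV file. Lines starting with `#` are skipped.
#' @param dialect `"minimal6"` or `"deepsignal11"`.
#' @param coordinate_base 0 or 1; base of the input `pos` column. Nanopore
#'   caller output is treated as 0-based by default.
#' @param context Optional context label (`"CG"`, `"CHG"`, `"CHH"`) stamped
#'   onto every row; required information for `deepsignal11` files that were
#'   split by motif upstream. Ignored if the dialect carries a context column.
#' @return A `data.table` with columns contig, pos (0-based), strand,
#'   context, methylated, coverage, frequency.
#' @export
read_site_frequencies <- function(path,
                                  dialect = c("minimal6", "deepsignal11"),
                                  coordinate_base = 0,
                                  context = NA_character_) {
  dialect <- match.arg(dialect)
  if (!coordinate_base %in% c(0, 1)) stop("coordinate_base must be 0 or 1")
  if (!file.exists(path)) stop("site frequency file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)   # original file line numbers, for error messages
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.table::data.table(contig = character(), pos = integer(),
                                  strand = character(), context = character(),
                                  methylated = integer(), coverage = integer(),
                                  frequency = numeric()))
  }
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  want <- if (dialect == "minimal6") 6L else 11L
  if (any(nfield != want)) {
    stop(sprintf("line %d: expected %d tab-separated columns, found %d",
                 line_no[which(nfield != want)[1]], want,
                 nfield[nfield != want][1]))
  }
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t")
  if (dialect == "minimal6") {
    data.table::setnames(dt, c("contig", "pos", "strand", "context",
                               "coverage", "methylated"))
  } else {
    data.table::setnames(dt, c("contig", "pos", "strand", "pos_in_strand",
                               "prob0_sum", "prob1_sum", "methylated",
                               "count_unmodified", "coverage",
                               "modification_frequency", "kmer"))
    dt[, context := context]
  }
  bad <- which(dt$methylated < 0 | dt$coverage < 0)
  if (length(bad)) stop("line ", line_no[bad[1]], ": negative read counts")
  bad <- which(dt$methylated > dt$coverage)
  if (length(bad)) {
    stop("line ", line_no[bad[1]], ": methylated count exceeds coverage")
  }
  n0 <- sum(dt$coverage == 0)
  if (n0 > 0) {
    message(n0, " zero-coverage row(s) dropped from ", basename(path))
    dt <- dt[coverage > 0]
  }
  dt[, pos := as.integer(pos - coordinate_base)]
  dt[, frequency := methylated / coverage]
  out <- dt[, list(contig = as.character(contig), pos, strand = as.character(strand),
                   context = as.character(context),
                   methylated = as.integer(methylated),
                   coverage = as.integer(coverage), frequency)]
  out[]
}

#' Read gene and TE features from a GFF3 file
#'
#' Extracts gene models and transposable-element intervals from GFF3
#' (1-based inclusive coordinates per the standard) and converts them to
#' the package's 0-based half-open convention. Genes must carry a strand;
#' TEs are kept as plain strandless intervals.
#'
#' @param path Path to a GFF3 file.
#' @param gene_type Value of the GFF3 `type` column identifying genes.
#' @param te_type Value of the `type` column identifying transposable
#'   elements.
#' @param contig_lengths Optional named vector of contig lengths; when
#'   given, features extending beyond their contig are rejected.
#' @return A list with `genes` (data.table: gene_id, contig, start, end,
#'   strand) and `tes` (data.table: contig, start, end).
#' @export
read_gff_features <- function(path, gene_type = "gene",
                              te_type = "transposable_element",
                              contig_lengths = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gff <- as.data.frame(rtracklayer::readGFF(path))
  if (any(gff$end < gff$start)) {
    stop("GFF3 feature with end < start at line(s): ",
         paste(head(which(gff$end < gff$start), 5), collapse = ", "))
  }
  g <- gff[gff$type == gene_type, , drop = FALSE]
  if (nrow(g) > 0 && any(!as.character(g$strand) %in% c("+", "-"))) {
    stop("gene feature without a +/- strand: ",
         paste(head(g$ID[!as.character(g$strand) %in% c("+", "-")], 5),
               collapse = ", "))
  }
  ids <- if ("ID" %in% names(g)) as.character(g$ID) else rep(NA_character_, nrow(g))
  if (any(is.na(ids))) ids[is.na(ids)] <- sprintf("gene_%05d", which(is.na(ids)))
  genes <- data.table::data.table(
    gene_id = ids,
    contig = as.character(g$seqid),
    start = as.integer(g$start) - 1L,   # GFF3 1-based inclusive -> 0-based half-open
    end = as.integer(g$end),
    strand = as.character(g$strand)
  )
  t <- gff[gff$type == te_type, , drop = FALSE]
  tes <- data.table::data.table(
    contig = as.character(t$seqid),
    start = as.integer(t$start) - 1L,
    end = as.integer(t$end)
  )
  if (!is.null(contig_lengths)) {
    for (d in list(genes, tes)) {
      if (nrow(d) == 0) next
      len <- contig_lengths[d$contig]
      if (any(is.na(len)) || any(d$end > len)) {
        stop("feature extends beyond its contig (or unknown contig) in ", path)
      }
    }
  }
  list(genes = genes[], tes = tes[])
}

#' Write intervals as BED
#'
#' Writes 0-based half-open intervals in BED format with deterministic
#' ordering (contig in order of first appearance, then start). Optional
#' name, score and strand columns produce BED4/5/6.
#'
#' @param records data.frame with contig, start, end and optionally name,
#'   score, strand.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_bed_intervals <- function(records, path) {
  records <- data.table::as.data.table(records)
  cols <- intersect(c("contig", "start", "end", "name", "score", "strand"),
                    names(records))
  if (!all(c("contig", "start", "end") %in% cols)) {
    stop("records need contig, start, end columns")
  }
  # BED columns are positional: keep the longest prefix present
  keep <- c("contig", "start", "end")
  for (extra in c("name", "score", "strand")) {
    if (extra %in% cols) keep <- c(keep, extra) else break
  }
  out <- records[, keep, with = FALSE]
  if (nrow(out) > 0) {
    ord <- order(match(out$contig, unique(out$contig)), out$start)
    out <- out[ord]
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED interval file
#'
#' Counterpart to [write_bed_intervals()]: reads BED3 to BED6 into a
#' data.table with 0-based half-open coordinates.
#'
#' @param path BED file.
#' @return data.table with contig, start, end and any of name, score,
#'   strand present in the file.
#' @export
read_bed_intervals <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0) {
    return(data.table::data.table(contig = character(), start = integer(),
                                  end = integer()))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  nm <- c("contig", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, nm[seq_len(ncol(dt))])
  dt[, contig := as.character(contig)]
  dt[, start := as.integer(start)]
  dt[, end := as.integer(end)]
  dt[]
}

#' Read a gene-to-GO mapping
#'
#' Two-column TSV (gene_id, GO id) with an optional third namespace column
#' (`BP`, `CC`, `MF`). GO ids must match `GO:` followed by seven digits.
#'
#' @param path TSV path; `#` comment lines are skipped.
#' @return data.table with gene_id, go_id, namespace (NA when absent).
#' @export
read_go_annotation <- function(path) {
  if (!file.exists(path)) stop("GO mapping file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (!ncol(dt) %in% c(2L, 3L)) {
    stop("GO mapping must have 2 or 3 tab-separated columns")
  }
  data.table::setnames(dt, c("gene_id", "go_id", "namespace")[seq_len(ncol(dt))])
  if (ncol(dt) == 2L) dt[, namespace := NA_character_]
  bad <- !grepl("^GO:\\d{7}$", dt$go_id)
  if (any(bad)) {
    stop("malformed GO id(s): ", paste(head(unique(dt$go_id[bad]), 5), collapse = ", "))
  }
  dt[, gene_id := as.character(gene_id)]
  unique(dt[])
}

# error path only: locate FASTA records with non-IUPAC characters
.bad_fasta_records <- function(path) {
  lines <- readLines(path)
  rec <- cumsum(startsWith(lines, ">"))
  ids <- sub("\\s.*$", "", sub("^>", "", lines[startsWith(lines, ">")]))
  seq_lines <- !startsWith(lines, ">")
  bad <- vapply(split(lines[seq_lines], rec[seq_lines]), function(x) {
    any(!strsplit(toupper(paste(x, collapse = "")), "", fixed = TRUE)[[1]]
        %in% IUPAC_DNA)
  }, logical(1))
  ids[as.integer(names(bad)[bad])]
}

# internal: write a minimal6 site table (used by the simulator bundle)
.write_minimal6 <- function(sites, path) {
  out <- sites[, list(contig, pos, strand, context, coverage, methylated)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
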