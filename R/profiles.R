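# Metagene profiles: methylation around TSS/TES and across TE bodies.
#
# Layout of a profile: [upstream flank | length-scaled body | downstream
# flank]. Flank bins have fixed width flank_bp / n_flank_bins; the body is
# rescaled to n_body_bins regardless of feature length, so bin 0 is always
# the 5'-most upstream bin and the TSS sits at the up/body boundary.

#' Metagene methylation profile over a feature set
#'
#' Averages per-site methylation into positional bins around a set of
#' features. For each feature the upstream flank is binned in fixed-width
#' bins, the body is rescaled to `n_body_bins`, and the downstream flank is
#' again fixed-width; minus-strand features are reversed so that bin 0 is
#' always 5'-most. A site falling within the windows of two features
#' contributes to both (standard metagene practice). Per-bin aggregation is
#' reads-weighted by default, consistent with
#' [global_methylation_level()].
#'
#' @param sites Context-annotated site table for one sample.
#' @param features Strand-aware gene table, or strandless intervals (TEs),
#'   which are treated as + strand.
#' @param context Context filter: `"CG"`, `"CHG"`, `"CHH"` or `"5mC"`.
#' @param flank_bp Flank length in bp on each side (default 2000).
#' @param n_body_bins Number of length-scaled body bins (default 60).
#' @param n_flank_bins Number of fixed-width bins per flank (default 20).
#' @param min_coverage Minimum site coverage (default 4).
#' @param weighting `"reads"` or `"sites"`.
#' @return data.table with one row per bin: bin_index (0-based), segment
#'   (`up`/`body`/`down`), value (NA when no site fell in the bin),
#'   n_sites, n_reads_methylated, n_reads_total. Attributes record the
#'   binning parameters.
#' @export
feature_metaprofile <- function(sites, features, context = "5mC",
                                flank_bp = 2000, n_body_bins = 60,
                                n_flank_bins = 20, min_coverage = 4,
                                weighting = c("reads", "sites")) {
  weighting <- match.arg(weighting)
  .check_sites(sites, need_context = TRUE)
  .check_context_arg(context)
  features <- data.table::as.data.table(features)
  if (nrow(features) == 0L) stop("feature list is empty")
  if (!"strand" %in% names(features)) features[, strand := "+"]
  nf <- as.integer(n_flank_bins); nb <- as.integer(n_body_bins)
  n_bins <- 2L * nf + nb
  ctx_set <- .context_set(context)
  dt <- data.table::as.data.table(sites)
  dt <- dt[dt$context %in% ctx_set & dt$coverage >= min_coverage]
  data.table::setkey(dt, contig, pos)

  meth <- num <- reads <- numeric(n_bins)
  cnt <- integer(n_bins)
  fsum <- numeric(n_bins)   # sum of per-site frequencies, for "sites" weighting
  for (i in seq_len(nrow(features))) {
    fs <- features$start[i]; fe <- features$end[i]
    len <- fe - fs
    sub <- dt[data.table::J(features$contig[i])][pos >= fs - flank_bp &
                                                   pos < fe + flank_bp]
    if (nrow(sub) == 0L) next
    # oriented distance from the TSS-side feature edge
    d <- if (features$strand[i] == "-") (fe - 1L) - sub$pos else sub$pos - fs
    b <- integer(nrow(sub))
    up <- d < 0
    body <- d >= 0 & d < len
    down <- d >= len
    b[up] <- floor((d[up] + flank_bp) / flank_bp * nf)
    b[body] <- nf + floor(d[body] / len * nb)
    b[down] <- nf + nb + floor((d[down] - len) / flank_bp * nf)
    b <- pmin(pmax(b, 0L), n_bins - 1L)  # guard float edge cases
    for (k in unique(b)) {
      j <- b == k
      meth[k + 1L] <- meth[k + 1L] + sum(sub$methylated[j])
      reads[k + 1L] <- reads[k + 1L] + sum(sub$coverage[j])
      cnt[k + 1L] <- cnt[k + 1L] + sum(j)
      fsum[k + 1L] <- fsum[k + 1L] + sum(sub$methylated[j] / sub$coverage[j])
    }
  }
  value <- if (weighting == "reads") {
    ifelse(reads > 0, meth / reads, NA_real_)
  } else {
    ifelse(cnt > 0, fsum / cnt, NA_real_)
  }
  out <- data.table::data.table(
    bin_index = seq_len(n_bins) - 1L,
    segment = rep(c("up", "body", "down"), c(nf, nb, nf)),
    value = value,
    n_sites = cnt,
    n_reads_methylated = meth,
    n_reads_total = reads
  )
  data.table::setattr(out, "context", context)
  data.table::setattr(out, "flank_bp", flank_bp)
  data.table::setattr(out, "n_body_bins", nb)
  data.table::setattr(out, "n_flank_bins", nf)
  out[]
}

#' Export a metagene profile as TSV
#'
#' Writes bin_index, segment, value, n_sites, tab-separated and
#' deterministic; undefined bins get an empty value field rather than 0.
#'
#' @param profile Output of [feature_metaprofile()].
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
export_metaprofile <- function(profile, path) {
  out <- data.table::as.data.table(profile)[, list(bin_index, segment, value,
                                                   n_sites)]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}
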