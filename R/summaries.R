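# Global and windowed methylation levels, and feature-density tracks.

#' Global methylation level
#'
#' Summarizes methylation over all qualifying sites of one sample.
#' With `weighting = "reads"` (the default) the level is
#' sum(methylated) / sum(coverage), i.e. the coverage-weighted level; with
#' `weighting = "sites"` it is the unweighted mean of per-site frequencies.
#' `context = "5mC"` pools CG, CHG and CHH.
#'
#' @param sites Context-annotated site table.
#' @param context `"CG"`, `"CHG"`, `"CHH"` or `"5mC"` (all pooled).
#' @param min_coverage Minimum per-site coverage to qualify (default 4).
#' @param weighting `"reads"` or `"sites"`.
#' @param sample Optional sample label carried into the result.
#' @return One-row data.table: sample, context, level, n_sites,
#'   n_reads_total, n_reads_methylated. With zero qualifying sites the
#'   level is `NA` (undefined), never 0.
#' @export
global_methylation_level <- function(sites, context = "5mC", min_coverage = 4,
                                     weighting = c("reads", "sites"),
                                     sample = NA_character_) {
  weighting <- match.arg(weighting)
  .check_sites(sites, need_context = TRUE)
  .check_context_arg(context)
  stopifnot(min_coverage >= 1)
  ctx_set <- .context_set(context)
  dt <- data.table::as.data.table(sites)
  dt <- dt[dt$context %in% ctx_set & dt$coverage >= min_coverage]
  if (nrow(dt) == 0L) {
    return(data.table::data.table(sample = sample, context = context,
                                  level = NA_real_, n_sites = 0L,
                                  n_reads_total = 0L, n_reads_methylated = 0L))
  }
  lvl <- if (weighting == "reads") {
    sum(dt$methylated) / sum(dt$coverage)
  } else {
    mean(dt$methylated / dt$coverage)
  }
  data.table::data.table(sample = sample, context = context, level = lvl,
                         n_sites = nrow(dt),
                         n_reads_total = sum(dt$coverage),
                         n_reads_methylated = sum(dt$methylated))
}

#' Windowed methylation-level track
#'
#' Tiles every contig with non-overlapping windows from position 0 (the
#' trailing short window is kept) and computes the methylation level per
#' window over qualifying sites. Windows without a qualifying site get an
#' `NA` level: "no data" is distinct from "level zero".
#'
#' @inheritParams global_methylation_level
#' @param genome Genome (for contig lengths / window tiling).
#' @param window_size Window width in bp (default 50000, a typical
#'   chromosome-scale track resolution).
#' @return data.table: contig, start, end, context, level, n_sites,
#'   n_reads_total, n_reads_methylated — consumable as bedGraph after
#'   dropping NA windows.
#' @export
windowed_level_track <- function(sites, genome, window_size = 50000,
                                 context = "5mC", min_coverage = 4,
                                 weighting = c("reads", "sites")) {
  weighting <- match.arg(weighting)
  .check_sites(sites, need_context = TRUE)
  .check_context_arg(context)
  stopifnot(window_size >= 1)
  wins <- tile_windows(genome, window_size)
  ctx_set <- .context_set(context)
  dt <- data.table::as.data.table(sites)
  dt <- dt[dt$context %in% ctx_set & dt$coverage >= min_coverage]
  if (nrow(dt) > 0) {
    dt[, win := pos %/% as.integer(window_size)]
    agg <- dt[, list(n_sites = .N, n_reads_total = sum(coverage),
                     n_reads_methylated = sum(methylated),
                     site_mean = mean(methylated / coverage)),
              by = list(contig, win)]
  } else {
    agg <- data.table::data.table(contig = character(), win = integer(),
                                  n_sites = integer(), n_reads_total = integer(),
                                  n_reads_methylated = integer(),
                                  site_mean = numeric())
  }
  wins[, win := start %/% as.integer(window_size)]
  out <- agg[wins, on = c("contig", "win")]
  out[is.na(n_sites), `:=`(n_sites = 0L, n_reads_total = 0L,
                           n_reads_methylated = 0L)]
  out[, level := if (weighting == "reads") {
    ifelse(n_reads_total > 0, n_reads_methylated / n_reads_total, NA_real_)
  } else {
    ifelse(n_sites > 0, site_mean, NA_real_)
  }]
  out[, `:=`(context = context, win = NULL, site_mean = NULL)]
  data.table::setcolorder(out, c("contig", "start", "end", "context", "level"))
  data.table::setorder(out, contig, start)
  out[]
}

#' Feature-density track
#'
#' Fraction of bases per tiling window covered by the union of a feature
#' set (genes or TEs). Overlapping features are unioned, never
#' double-counted; a feature spanning a window boundary contributes to each
#' window proportionally.
#'
#' @param features data.frame with contig, start, end (0-based half-open).
#' @param genome Genome for tiling.
#' @param window_size Window width in bp (default 50000).
#' @return data.table: contig, start, end, density in \[0,1\].
#' @export
feature_density_track <- function(features, genome, window_size = 50000) {
  stopifnot(window_size >= 1)
  features <- data.table::as.data.table(features)
  wins <- tile_windows(genome, window_size)
  ov <- .overlap_bases(wins, features)
  wins[, density := ov / (end - start)]
  wins[]
}
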