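# End-to-end analysis: contexts -> summaries -> profiles -> DMRs ->
# compartments/DMGs -> TE enrichment -> GO enrichment, with a JSON report.

.config_defaults <- function() {
  list(
    genome = NULL, annotation = NULL, sample_a = NULL, sample_b = NULL,
    go_mapping = NULL, outdir = "methtiler_out",
    sample_a_label = "mycelium", sample_b_label = "conidia",
    gene_type = "gene", te_type = "transposable_element",
    dialect = "minimal6", coordinate_base = 0,
    min_coverage = 4, window_size = 1000, track_window_size = 50000,
    flank_bp = 2000, n_body_bins = 60, n_flank_bins = 20,
    min_cytosines = 5, fold_threshold = 2, alpha = 0.05, pseudocount = 0.01,
    adjust = "none", promoter_upstream = 1000, promoter_downstream = 500,
    weighting = "reads", seed = 1
  )
}

#' Read a pipeline configuration file
#'
#' Plain-text `key = value` configuration; `#` starts a comment. Unknown
#' keys are rejected so typos cannot silently fall back to defaults.
#' Values are coerced to the type of the corresponding default.
#'
#' @param path Configuration file.
#' @return A complete configuration list (defaults filled in).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  defaults <- .config_defaults()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  for (i in seq_along(keys)) {
    dv <- defaults[[keys[i]]]
    cfg[[keys[i]]] <- if (is.numeric(dv)) as.numeric(vals[i]) else vals[i]
  }
  cfg
}

#' Run the full two-sample methylome analysis
#'
#' Executes the whole pipeline on a configuration (see
#' [read_pipeline_config()]; a plain named list with the same keys also
#' works — missing keys take their defaults). Stages: context
#' classification, global levels, windowed tracks and feature densities,
#' metagene profiles, DMR calling per context, compartment assignment and
#' DMGs, TE enrichment, and (when a GO mapping is configured) GO
#' over-representation per (context, direction). Every intermediate table
#' is written as TSV/BED under `outdir`, a `MANIFEST` records stage
#' completion, and `report.json` collects the headline numbers.
#'
#' Any stage failure aborts with the stage named; previously written
#' outputs and the MANIFEST are retained.
#'
#' @param config Configuration list or path to a config file.
#' @return Invisibly, the report list.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(.config_defaults(), config)
  for (key in c("genome", "annotation", "sample_a", "sample_b")) {
    if (is.null(cfg[[key]])) stop("config is missing required path: ", key)
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(cfg$outdir, "MANIFEST")
  cat("", file = manifest)
  note <- function(stage, status) {
    cat(sprintf("%s\t%s\n", stage, status), file = manifest, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch({
      res <- force(expr)
      note(name, "ok")
      res
    }, error = function(e) {
      note(name, "failed")
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  report <- list(parameters = cfg[!vapply(cfg, is.null, logical(1))])
  contexts_all <- c("CG", "CHG", "CHH")

  inputs <- stage("load_inputs", {
    genome <- read_fasta(cfg$genome)
    feats <- read_gff_features(cfg$annotation, gene_type = cfg$gene_type,
                               te_type = cfg$te_type,
                               contig_lengths = .contig_lengths(genome))
    a <- read_site_frequencies(cfg$sample_a, dialect = cfg$dialect,
                               coordinate_base = cfg$coordinate_base)
    b <- read_site_frequencies(cfg$sample_b, dialect = cfg$dialect,
                               coordinate_base = cfg$coordinate_base)
    list(genome = genome, feats = feats, a = a, b = b)
  })

  ctxres <- stage("contexts", {
    ctx <- classify_cytosine_contexts(inputs$genome)
    a <- if (all(is.na(inputs$a$context))) {
      join_sites_with_contexts(inputs$a, ctx, genome = inputs$genome)
    } else inputs$a
    b <- if (all(is.na(inputs$b$context))) {
      join_sites_with_contexts(inputs$b, ctx, genome = inputs$genome)
    } else inputs$b
    proms <- promoter_intervals(inputs$feats$genes,
                                upstream = cfg$promoter_upstream,
                                downstream = cfg$promoter_downstream,
                                contig_lengths = .contig_lengths(inputs$genome))
    write_bed_intervals(proms[, list(contig, start, end, name = gene_id)],
                        file.path(cfg$outdir, "promoters.bed"))
    list(ctx = ctx, a = a, b = b, proms = proms)
  })

  globals <- stage("global_levels", {
    rows <- data.table::rbindlist(lapply(
      list(list(ctxres$a, cfg$sample_a_label), list(ctxres$b, cfg$sample_b_label)),
      function(sl) data.table::rbindlist(lapply(c("5mC", contexts_all), function(cx)
        global_methylation_level(sl[[1]], context = cx,
                                 min_coverage = cfg$min_coverage,
                                 weighting = cfg$weighting,
                                 sample = sl[[2]])))))
    data.table::fwrite(rows, file.path(cfg$outdir, "global_levels.tsv"),
                       sep = "\t")
    rows
  })
  report$global_levels <- lapply(split(globals, paste(globals$sample,
                                                      globals$context)),
                                 function(r) r$level)

  stage("tracks", {
    for (sl in list(list(ctxres$a, "a"), list(ctxres$b, "b"))) {
      tr <- windowed_level_track(sl[[1]], inputs$genome,
                                 window_size = cfg$track_window_size,
                                 context = "5mC",
                                 min_coverage = cfg$min_coverage,
                                 weighting = cfg$weighting)
      data.table::fwrite(tr, file.path(cfg$outdir,
                                       paste0("track_5mC_", sl[[2]], ".tsv")),
                         sep = "\t")
    }
    for (fx in list(list(inputs$feats$genes, "gene"),
                    list(inputs$feats$tes, "te"))) {
      dtr <- feature_density_track(fx[[1]], inputs$genome,
                                   window_size = cfg$track_window_size)
      data.table::fwrite(dtr, file.path(cfg$outdir,
                                        paste0("density_", fx[[2]], ".tsv")),
                         sep = "\t")
    }
    NULL
  })

  stage("metaprofiles", {
    for (sl in list(list(ctxres$a, "a"), list(ctxres$b, "b"))) {
      for (cx in contexts_all) {
        for (fx in list(list(inputs$feats$genes, "gene"),
                        list(inputs$feats$tes, "te"))) {
          if (nrow(fx[[1]]) == 0) next
          pr <- feature_metaprofile(sl[[1]], fx[[1]], context = cx,
                                    flank_bp = cfg$flank_bp,
                                    n_body_bins = cfg$n_body_bins,
                                    n_flank_bins = cfg$n_flank_bins,
                                    min_coverage = cfg$min_coverage,
                                    weighting = cfg$weighting)
          export_metaprofile(pr, file.path(cfg$outdir,
                                           sprintf("metaprofile_%s_%s_%s.tsv",
                                                   fx[[2]], cx, sl[[2]])))
        }
      }
    }
    NULL
  })

  dmrs <- stage("dmr_calling", {
    all <- data.table::rbindlist(lapply(contexts_all, function(cx) {
      call_dmrs(ctxres$a, ctxres$b, inputs$genome, context = cx,
                window_size = cfg$window_size,
                min_cytosines = cfg$min_cytosines,
                min_site_coverage = cfg$min_coverage,
                fold_threshold = cfg$fold_threshold,
                alpha = cfg$alpha, pseudocount = cfg$pseudocount,
                adjust = cfg$adjust)
    }), fill = TRUE)
    data.table::fwrite(all, file.path(cfg$outdir, "dmrs.tsv"), sep = "\t")
    if (nrow(all) > 0) {
      for (s in split(all, paste(all$context, all$direction, sep = ":"))) {
        nm <- paste0("dmrs_", s$context[1], "_", s$direction[1], ".bed")
        write_bed_intervals(
          s[, list(contig, start, end,
                   name = paste0(context, ":", direction),
                   score = round(-log10(pmax(p_value, 1e-300)), 3),
                   strand = ".")],
          file.path(cfg$outdir, nm))
      }
    }
    all
  })
  report$dmr_counts <- if (nrow(dmrs) > 0) {
    cnt <- dmrs[, list(n = .N), by = list(context, direction)]
    stats::setNames(as.list(cnt$n), paste(cnt$context, cnt$direction, sep = ":"))
  } else list()

  compart <- stage("compartments_dmgs", {
    comp <- assign_dmr_compartments(dmrs, inputs$feats, ctxres$proms)
    data.table::fwrite(comp$proportions,
                       file.path(cfg$outdir, "dmr_compartments.tsv"), sep = "\t")
    dmgs <- differentially_methylated_genes(dmrs, inputs$feats$genes,
                                            ctxres$proms)
    data.table::fwrite(dmgs, file.path(cfg$outdir, "dmgs.tsv"), sep = "\t")
    list(comp = comp, dmgs = dmgs)
  })
  report$compartment_proportions <- if (nrow(compart$comp$proportions) > 0) {
    split(compart$comp$proportions[, list(compartment, proportion)],
          paste(compart$comp$proportions$context,
                compart$comp$proportions$direction, sep = ":"))
  } else list()
  report$n_dmgs <- nrow(unique(compart$dmgs[, list(gene_id)]))

  enrich <- stage("te_enrichment", {
    sc <- te_enrichment_score(dmrs, inputs$feats$tes, inputs$genome)
    data.table::fwrite(sc, file.path(cfg$outdir, "te_enrichment.tsv"),
                       sep = "\t")
    sc
  })
  report$te_enrichment <- if (nrow(enrich) > 0) {
    stats::setNames(as.list(enrich$score),
                    paste(enrich$context, enrich$direction, sep = ":"))
  } else list()

  if (!is.null(cfg$go_mapping)) {
    go_top <- stage("go_enrichment", {
      ann <- read_go_annotation(cfg$go_mapping)
      background <- inputs$feats$genes$gene_id
      tops <- list()
      for (s in split(compart$dmgs, paste(compart$dmgs$context,
                                          compart$dmgs$direction, sep = ":"))) {
        study <- intersect(unique(s$gene_id), background)
        if (length(study) == 0) next
        res <- go_fisher(study, background, ann)
        nm <- paste(s$context[1], s$direction[1], sep = ":")
        data.table::fwrite(res, file.path(cfg$outdir,
                                          paste0("go_", gsub(":", "_", nm),
                                                 ".tsv")), sep = "\t")
        tops[[nm]] <- head(res, 5)
      }
      tops
    })
    report$go_top_terms <- lapply(go_top, function(d)
      lapply(seq_len(nrow(d)), function(i)
        list(term = d$term[i], p_value = d$p_value[i], k = d$k[i])))
  }

  stage("report", {
    jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    NULL
  })
  invisible(report)
}
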