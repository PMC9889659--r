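# GO-term over-representation of a study gene set against a background.

#' GO-term enrichment by Fisher's exact test
#'
#' Tests each GO term annotated to at least one background gene for
#' over-representation in the study set. With k study genes carrying the
#' term, n study genes, K background genes carrying the term and N
#' background genes, the 2x2 table is
#' `[[k, n - k], [K - k, N - n - (K - k)]]`. The default one-sided
#' `"greater"` alternative is the hypergeometric upper tail
#' (over-representation); `"two_sided"` uses
#' [fisher_exact_two_sided()].
#'
#' @param study_genes Character vector of study gene ids (e.g. DMGs);
#'   must be a subset of the background.
#' @param background_genes Character vector of universe gene ids.
#' @param annotation Gene -> GO mapping (gene_id, go_id, optional
#'   namespace), e.g. from [read_go_annotation()].
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @param adjust `"none"` (sort/report raw p) or `"bh"`; the
#'   Benjamini-Hochberg `adjusted_p` column is reported either way, the
#'   flag selects which column the output is sorted by.
#' @return data.table sorted by p-value: term, namespace, k, n, K, N,
#'   p_value, adjusted_p.
#' @export
go_fisher <- function(study_genes, background_genes, annotation,
                      alternative = c("greater", "two_sided"),
                      adjust = c("none", "bh")) {
  alternative <- match.arg(alternative)
  adjust <- match.arg(adjust)
  study_genes <- unique(as.character(study_genes))
  background_genes <- unique(as.character(background_genes))
  if (length(background_genes) == 0L) stop("background gene set is empty")
  missing <- setdiff(study_genes, background_genes)
  if (length(missing)) {
    stop("study gene(s) absent from background: ",
         paste(head(missing, 10), collapse = ", "))
  }
  ann <- data.table::as.data.table(annotation)
  ann <- unique(ann[gene_id %in% background_genes,
                    list(gene_id, go_id,
                         namespace = if ("namespace" %in% names(ann))
                           namespace else NA_character_)])
  n <- length(study_genes)
  N <- length(background_genes)
  if (nrow(ann) == 0L) {
    return(data.table::data.table(term = character(), namespace = character(),
                                  k = integer(), n = integer(), K = integer(),
                                  N = integer(), p_value = numeric(),
                                  adjusted_p = numeric()))
  }
  terms <- ann[, list(K = data.table::uniqueN(gene_id),
                      k = data.table::uniqueN(gene_id[gene_id %in% study_genes]),
                      namespace = namespace[1]),
               by = list(term = go_id)]
  terms[, `:=`(n = n, N = N)]
  terms[, p_value := if (alternative == "greater") {
    stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  } else {
    vapply(seq_len(.N), function(i) {
      fisher_exact_two_sided(k[i], n - k[i], K[i] - k[i],
                             N - n - (K[i] - k[i]))
    }, numeric(1))
  }]
  terms[, adjusted_p := bh_adjust(p_value)]
  if (adjust == "bh") data.table::setorder(terms, adjusted_p, p_value, term)
  else data.table::setorder(terms, p_value, term)
  data.table::setcolorder(terms, c("term", "namespace", "k", "n", "K", "N",
                                   "p_value", "adjusted_p"))
  terms[]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector; values are
#' validated to lie in \[0, 1\].
#'
#' @param p_values Numeric vector of p-values.
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
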