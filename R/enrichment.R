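#' Hypergeometric category enrichment
#'
#' Upper-tail hypergeometric test per annotation term: given a universe of
#' `N` genes of which `n` carry the term, and a study set of `K` genes of
#' which `k` carry it, the p-value is the probability of observing at
#' least `k` annotated genes in a random draw of `K` from `N`.  P-values
#' are Benjamini-Hochberg adjusted across terms; the enrichment fold is
#' `(k/K) / (n/N)`.  Terms absent from the study set (`k = 0`) are
#' reported with `p = 1` rather than dropped, keeping the output schema
#' stable.
#'
#' @param gene_set character vector of study genes (e.g. the upregulated
#'   responsive genes); must be a subset of `universe`.
#' @param annotation data frame with columns `gene_id`, `term_id` (one
#'   pair per row).
#' @param universe character vector of background genes (e.g. all genes
#'   surviving the CPM filter).
#' @param fdr_max FDR threshold for the `enriched` flag (default 0.05).
#' @return data frame sorted by `fdr` then decreasing `fold`, with
#'   columns `term_id`, `k`, `K`, `n`, `N`, `fold`, `p`, `fdr`,
#'   `enriched`.
#' @examples
#' ann <- data.frame(gene_id = c("g1", "g2", "g3"), term_id = "T1")
#' hypergeomEnrich(c("g1", "g2"), ann, paste0("g", 1:10))
#' @export
hypergeomEnrich <- function(gene_set, annotation, universe,
                            fdr_max = 0.05) {
    gene_set <- unique(gene_set)
    universe <- unique(universe)
    off <- setdiff(gene_set, universe)
    stopIf(length(off) > 0, "gene(s) not in universe: ",
           paste(utils::head(off, 10), collapse = ", "))
    ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
    ann <- unique(ann[, c("gene_id", "term_id")])
    terms <- unique(ann$term_id)
    N <- length(universe)
    K <- length(gene_set)
    n_term <- table(factor(ann$term_id, levels = terms))
    in_set <- ann$gene_id %in% gene_set
    k_term <- table(factor(ann$term_id[in_set], levels = terms))
    n <- as.integer(n_term); k <- as.integer(k_term)
    p <- stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE)
    fold <- ifelse(n > 0 & K > 0, (k / K) / (n / N), 0)
    fdr <- stats::p.adjust(p, method = "BH")
    out <- data.frame(term_id = terms, k = k, K = K, n = n, N = N,
                      fold = fold, p = p, fdr = fdr,
                      enriched = fdr < fdr_max,
                      stringsAsFactors = FALSE)
    out[order(out$fdr, -out$fold), , drop = FALSE]
}
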