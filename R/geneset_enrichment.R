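#' Hypergeometric over-representation test for gene lists
#'
#' For each gene set S the p-value is the upper-tail hypergeometric
#' probability of observing at least the realized overlap when `|query|`
#' genes are drawn without replacement from a universe containing
#' `|S intersect universe|` set members; BH adjustment is applied across
#' sets. The universe is conventionally the expressed genes with defined
#' statistics, not the genome.
#'
#' @param query character vector of genes of interest (e.g. called HVGs);
#'   must be a subset of `universe`.
#' @param universe character vector of background genes.
#' @param sets named list of gene sets (see [read_gmt()]).
#' @return data.frame sorted by q-value: `set`, `overlap`, `set_size`
#'   (in-universe), `query_size`, `universe_size`, `pvalue`, `qvalue`,
#'   `overlap_genes` (comma-separated).
#' @export
ora_hypergeometric <- function(query, universe, sets) {
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  n_u <- length(universe)
  n_q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    ov <- intersect(s, query)
    p <- stats::phyper(length(ov) - 1, length(s), n_u - length(s), n_q,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = length(ov), set_size = length(s),
               query_size = n_q, universe_size = n_u, pvalue = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$qvalue, out$pvalue, out$set),
             c("set", "overlap", "set_size", "query_size", "universe_size",
               "pvalue", "qvalue", "overlap_genes")]
  rownames(out) <- NULL
  out
}
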