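#' Residual variability of a bulk cohort matrix
#'
#' Applies the same machinery as the single-cell statistic to a gene x
#' individual matrix of normalized expression values (FPKM-like): per-gene
#' mean and unbiased squared CV across individuals (no library-size
#' adjustment; values arrive normalized), gamma-GLM technical trend, and
#' log2 residual variability. Genes with zero mean or zero variance are
#' excluded.
#'
#' @param bulk numeric matrix, genes x individuals (>= 3 individuals),
#'   nonnegative values.
#' @param min_mean_quantile trend-fit subset rule, as in [fit_cv2_trend()].
#' @return per-gene statistics table (as from [score_genes()]) with the trend
#'   stored in the `trend` attribute.
#' @export
bulk_residual_variability <- function(bulk, min_mean_quantile = 0.25) {
  if (ncol(bulk) < 3) stop("at least 3 individuals are required")
  if (any(bulk < 0)) stop("bulk values must be nonnegative")
  gs <- compute_gene_stats(bulk, normalize = FALSE)
  gs$excluded <- gs$excluded | !is.finite(gs$cv2_obs) | gs$cv2_obs <= 0
  if (sum(!gs$excluded) < 2)
    stop("fewer than 2 genes with defined CV^2")
  trend <- fit_cv2_trend(gs, min_mean_quantile)
  out <- score_genes(gs, trend)
  attr(out, "trend") <- trend
  out
}

#' Extract a named residual-variability vector from a statistics table
#' @param stats per-gene table with `gene` and `residual_variability`.
#' @return named numeric vector over genes with finite values.
#' @export
rv_vector <- function(stats) {
  v <- stats::setNames(stats$residual_variability, stats$gene)
  v[is.finite(v)]
}

#' Correlate single-cell and cohort-level residual variability
#'
#' Spearman correlation between the two residual-variability estimates over
#' the gene intersection, overall and per gene set. A set is reported when at
#' least `min_size` of its genes fall in the intersection; smaller sets are
#' omitted. P-values are two-sided.
#'
#' @param sc_rv,bulk_rv named numeric vectors (see [rv_vector()]).
#' @param sets optional named list of gene sets (see [read_gmt()]).
#' @param min_size minimum shared-gene count for a per-set test (>= 3).
#' @return list: `overall` (data.frame n_genes, spearman_r, pvalue) and
#'   `per_set` (data.frame set, n_used, spearman_r, pvalue).
#' @export
correlate_variability <- function(sc_rv, bulk_rv, sets = NULL,
                                  min_size = 10) {
  if (min_size < 3) stop("min_size must be >= 3")
  shared <- intersect(names(sc_rv), names(bulk_rv))
  if (length(shared) == 0) stop("empty gene intersection")
  a <- sc_rv[shared]
  b <- bulk_rv[shared]
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                         exact = FALSE))
  overall <- data.frame(n_genes = length(shared),
                        spearman_r = unname(ct$estimate),
                        pvalue = ct$p.value)
  per_set <- data.frame(set = character(0), n_used = integer(0),
                        spearman_r = numeric(0), pvalue = numeric(0),
                        stringsAsFactors = FALSE)
  for (nm in names(sets)) {
    g <- intersect(sets[[nm]], shared)
    if (length(g) < min_size) next
    ct_s <- suppressWarnings(stats::cor.test(a[g], b[g],
                                             method = "spearman",
                                             exact = FALSE))
    per_set <- rbind(per_set, data.frame(
      set = nm, n_used = length(g), spearman_r = unname(ct_s$estimate),
      pvalue = ct_s$p.value, stringsAsFactors = FALSE))
  }
  list(overall = overall, per_set = per_set)
}
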