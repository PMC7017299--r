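#' Configuration for homogeneous-population selection
#'
#' Defaults follow the standard filter pipeline: remove mitochondrial genes
#' (symbol prefix `MT-`), keep G1 cells, keep cells with library size inside
#' the inclusive 50-95 percentile window, embed, and select the core cell
#' plus its `target_n - 1` nearest neighbors. (Some analyses use a 55-99
#' window instead; both ends are configurable.)
#'
#' @param mito_prefix gene-symbol prefix marking mitochondrial genes.
#' @param lib_lower_pct,lib_upper_pct library-size percentile window in
#'   `[0, 100]`, lower < upper.
#' @param target_n size of the selected population (default 1000).
#' @param embed_dims number of embedding dimensions (default 10).
#' @param knn_k neighborhood size for the density-peak core rule.
#' @param core_cell optional explicit core-cell identifier (overrides the
#'   density-peak rule, mirroring manual picking).
#' @param seed integer seed (the default pipeline is deterministic; the seed
#'   is recorded for provenance).
#' @return list of class `"scev_selection_config"`.
#' @export
selection_config <- function(mito_prefix = "MT-", lib_lower_pct = 50,
                             lib_upper_pct = 95, target_n = 1000,
                             embed_dims = 10, knn_k = 30,
                             core_cell = NULL, seed = 1) {
  if (lib_lower_pct >= lib_upper_pct)
    stop("lib_lower_pct must be smaller than lib_upper_pct")
  if (any(c(lib_lower_pct, lib_upper_pct) < 0) ||
      any(c(lib_lower_pct, lib_upper_pct) > 100))
    stop("library-size percentiles must lie in [0, 100]")
  if (target_n < 1) stop("target_n must be >= 1")
  structure(list(mito_prefix = mito_prefix, lib_lower_pct = lib_lower_pct,
                 lib_upper_pct = lib_upper_pct, target_n = target_n,
                 embed_dims = embed_dims, knn_k = knn_k,
                 core_cell = core_cell, seed = seed),
            class = "scev_selection_config")
}

#' Score cells for cell-cycle phase
#'
#' For each signature (S and G2M) the per-cell score is the mean
#' log-normalized expression of the signature genes minus the mean of an
#' expression-matched control set: genes are binned by mean expression
#' (`n_bins` equal-frequency bins) and each signature gene contributes the
#' average profile of its bin (signature genes excluded) as its control.
#' Phase is `G1` iff both scores are <= 0, otherwise the phase with the
#' larger score (S preferred on exact ties).
#'
#' @param counts gene x cell count matrix.
#' @param s_genes,g2m_genes character vectors of signature gene names; at
#'   least one gene of each list must be present in the matrix.
#' @param n_bins number of expression bins for control matching.
#' @return data.frame with columns `cell`, `s_score`, `g2m_score`, `phase`.
#' @export
score_cell_cycle <- function(counts, s_genes, g2m_genes, n_bins = 25) {
  if (length(s_genes) == 0 || length(g2m_genes) == 0)
    stop("signature lists must be nonempty")
  logn <- log_normalize(counts)
  genes <- rownames(logn)
  s_use <- intersect(s_genes, genes)
  g2m_use <- intersect(g2m_genes, genes)
  if (length(s_use) == 0 && length(g2m_use) == 0)
    stop("no signature gene present in the matrix")
  if (length(s_use) == 0) stop("no S-signature gene present in the matrix")
  if (length(g2m_use) == 0)
    stop("no G2M-signature gene present in the matrix")
  gm <- rowMeans(logn)
  breaks <- unique(stats::quantile(gm, probs = seq(0, 1, length.out =
                                                     n_bins + 1)))
  bin <- cut(gm, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  sig_all <- union(s_use, g2m_use)
  score_one <- function(sig) {
    sig_expr <- colMeans(logn[sig, , drop = FALSE])
    ctrl <- matrix(0, length(sig), ncol(logn))
    for (i in seq_along(sig)) {
      pool <- setdiff(genes[bin == bin[match(sig[i], genes)]], sig_all)
      if (length(pool) == 0) pool <- setdiff(genes, sig_all)
      ctrl[i, ] <- colMeans(logn[pool, , drop = FALSE])
    }
    sig_expr - colMeans(ctrl)
  }
  s_score <- score_one(s_use)
  g2m_score <- score_one(g2m_use)
  phase <- ifelse(s_score <= 0 & g2m_score <= 0, "G1",
                  ifelse(s_score >= g2m_score, "S", "G2M"))
  data.frame(cell = colnames(counts), s_score = s_score,
             g2m_score = g2m_score, phase = phase,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Nearest-rank (inclusive) percentile: the ceil(p/100 * n)-th order statistic.
nearest_rank_quantile <- function(x, p) {
  s <- sort(x)
  s[max(1L, ceiling(p / 100 * length(s)))]
}

#' Filter to G1 cells, drop mitochondrial genes, apply library-size window
#'
#' Applies the homogeneity filters in fixed order: mitochondrial genes
#' (symbol prefix) are removed, cells not assigned to G1 are removed, and
#' cells whose library size (total counts, computed after mitochondrial
#' removal) falls outside the inclusive nearest-rank percentile window are
#' removed. Cell order is preserved.
#'
#' @param counts gene x cell count matrix.
#' @param cycle output of [score_cell_cycle()] for the same cells (or `NULL`
#'   to skip the phase filter).
#' @param config a [selection_config()].
#' @return filtered count matrix.
#' @export
preprocess_filter <- function(counts, cycle, config = selection_config()) {
  keep_genes <- !startsWith(rownames(counts), config$mito_prefix)
  x <- counts[keep_genes, , drop = FALSE]
  if (!is.null(cycle)) {
    g1 <- cycle$cell[cycle$phase == "G1"]
    x <- x[, colnames(x) %in% g1, drop = FALSE]
  }
  if (ncol(x) == 0) stop("no cells survive the G1 filter")
  lib <- Matrix::colSums(x)
  lo <- nearest_rank_quantile(lib, config$lib_lower_pct)
  hi <- nearest_rank_quantile(lib, config$lib_upper_pct)
  x <- x[, lib >= lo & lib <= hi, drop = FALSE]
  if (ncol(x) == 0) stop("no cells survive the library-size window")
  x
}

#' Embed cells by principal components of log-normalized expression
#'
#' Deterministic embedding preserving between-cell Euclidean structure:
#' principal components of the log-normalized expression matrix. Component
#' signs are fixed (largest-magnitude loading positive) so the embedding is
#' reproducible; duplicated cells receive identical coordinates.
#'
#' @param counts gene x cell count matrix.
#' @param config a [selection_config()]; `embed_dims` components returned.
#' @return numeric matrix, cells x `embed_dims`, rownames = cell ids.
#' @export
embed_cells <- function(counts, config = selection_config()) {
  if (config$embed_dims >= ncol(counts))
    stop("embed_dims must be smaller than the number of cells")
  logn <- log_normalize(counts)
  pc <- stats::prcomp(t(logn), rank. = config$embed_dims, center = TRUE,
                      scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  coords <- sweep(pc$x, 2, flip, `*`)
  rownames(coords) <- colnames(counts)
  coords
}

#' Select the core cell and its nearest neighbors
#'
#' If `config$core_cell` is given it is used as the core; otherwise the core
#' is the density-peak cell, the one with minimum mean Euclidean distance to
#' its `knn_k` nearest neighbors in embedding space. The selected population
#' is the core plus the `target_n - 1` cells closest to it; distance ties are
#' broken by lexicographic cell identifier.
#'
#' @param coords cells x dims coordinate matrix from [embed_cells()].
#' @param config a [selection_config()].
#' @return character vector of `target_n` cell identifiers, core first.
#' @export
select_core_population <- function(coords, config = selection_config()) {
  n <- nrow(coords)
  if (config$target_n > n)
    stop(sprintf("target_n = %d exceeds the %d available cells",
                 config$target_n, n))
  ids <- rownames(coords)
  d <- as.matrix(stats::dist(coords))
  if (!is.null(config$core_cell)) {
    if (!config$core_cell %in% ids)
      stop("core_cell '", config$core_cell, "' not among the cells")
    core <- config$core_cell
  } else {
    k <- min(config$knn_k, n - 1)
    mean_knn <- apply(d, 1, function(r) mean(sort(r[-which.min(r)])[seq_len(k)]))
    # deterministic tie-break: smallest identifier
    core <- ids[order(mean_knn, ids)][1]
  }
  dc <- d[core, ]
  others <- setdiff(ids[order(dc, ids)], core)
  c(core, others[seq_len(config$target_n - 1)])
}

#' Run the full homogeneous-population selection pipeline
#'
#' Fixed stage order: cycle scoring/filter, mitochondrial-gene removal,
#' library-size percentile window, embedding, core-neighborhood selection.
#'
#' @param counts gene x cell count matrix.
#' @param config a [selection_config()].
#' @param s_genes,g2m_genes cycle signature gene lists; if `NULL`, the phase
#'   filter is skipped (all cells treated as G1).
#' @return list with `counts` (filtered matrix restricted to the selected
#'   cells), `cells` (selected identifiers, core first), `cycle`, `coords`.
#' @export
select_cells <- function(counts, config = selection_config(),
                         s_genes = NULL, g2m_genes = NULL) {
  cycle <- NULL
  if (!is.null(s_genes) && !is.null(g2m_genes))
    cycle <- score_cell_cycle(counts, s_genes, g2m_genes)
  filt <- preprocess_filter(counts, cycle, config)
  coords <- embed_cells(filt, config)
  cells <- select_core_population(coords, config)
  list(counts = filt[, cells, drop = FALSE], cells = cells,
       cycle = cycle, coords = coords)
}
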