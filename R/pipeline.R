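#' Intersect named HVG lists across samples
#'
#' @param lists named list of >= 2 character vectors (one HVG list per
#'   sample).
#' @return list: `shared` (sorted intersection of all lists) and `overlaps`
#'   (pairwise overlap-count matrix; diagonal = list sizes).
#' @export
intersect_hvg_sets <- function(lists) {
  if (!is.list(lists) || length(lists) < 2)
    stop("at least 2 named lists are required")
  if (is.null(names(lists)) || any(!nzchar(names(lists))))
    stop("lists must be named")
  lists <- lapply(lists, unique)
  shared <- sort(Reduce(intersect, lists))
  n <- length(lists)
  ov <- matrix(0L, n, n, dimnames = list(names(lists), names(lists)))
  for (i in seq_len(n)) for (j in seq_len(n))
    ov[i, j] <- length(intersect(lists[[i]], lists[[j]]))
  list(shared = shared, overlaps = ov)
}

# FNV-1a hash of the canonical deparse of a config; changes iff any
# semantically meaningful field changes (output location and log verbosity
# do not affect results and are excluded).
config_hash <- function(config) {
  config <- config[setdiff(names(config), c("outdir", "log_level"))]
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    # xor on the low byte, then multiply mod 2^32 in two 16-bit halves to
    # stay inside double precision
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b %% 256)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

pipeline_log <- function(level, threshold, ...) {
  levels <- c(debug = 1, info = 2, warn = 3)
  if (levels[[level]] >= levels[[threshold]])
    message(sprintf("[%s] %s", level, paste0(...)))
}

validate_pipeline_config <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$outdir)) stop("config$outdir is required")
  paths <- c(config$input$matrix, config$input$genes, config$input$barcodes,
             config$input$dense, config$popvar$bulk, config$popvar$gmt,
             config$enrich$gmt, config$network$signed_edges)
  for (p in paths)
    if (!is.null(p) && !file.exists(p)) stop("input path not found: ", p)
  invisible(TRUE)
}

#' Run the full scEV analysis pipeline
#'
#' Orchestrates the stages in fixed order: select (cycle filter,
#' mitochondrial removal, library-size window, embedding, core-neighborhood
#' selection), hvg (CV^2 trend + chi-squared test + FDR calling), then the
#' optional network, popvar and enrich stages when their inputs are present.
#' Every output table carries a provenance header (package version, seed,
#' config hash), so identical config + seed reproduce identical files.
#'
#' @param config list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{input}{either `matrix`/`genes`/`barcodes` paths (10x triplet) or
#'       `dense` (TSV path) + optional `orientation`.}
#'     \item{outdir}{output directory.}
#'     \item{seed}{root seed; per-stage seeds are derived from it.}
#'     \item{selection}{arguments for [selection_config()], plus optional
#'       `s_genes` / `g2m_genes` character vectors (cycle filter skipped with
#'       a notice when absent).}
#'     \item{hvg}{`fdr_threshold` (default 0.01), `fc_threshold` (optional),
#'       `min_mean_quantile`.}
#'     \item{network}{optional: `top_n` (default 50), `distance_threshold`
#'       (default 0.3), `knn_k`, `t`, optional `signed_edges` path.}
#'     \item{popvar}{optional: `bulk` TSV path, optional `gmt`, `min_size`.}
#'     \item{enrich}{optional: `gmt` path.}
#'     \item{log_level}{`"debug"`, `"info"` (default) or `"warn"`.}
#'   }
#' @return invisibly, a summary list (cell/gene counts per stage, HVG count,
#'   output paths).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_pipeline_config(config)
  lvl <- if (is.null(config$log_level)) "info" else config$log_level
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  hash <- config_hash(config)
  header <- c(paste0("scev version ", as.character(utils::packageVersion("scev"))),
              paste0("seed ", seed), paste0("config ", hash))
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  run_stage <- function(name, expr) {
    pipeline_log("info", lvl, "stage ", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  summary <- list(seed = seed, config_hash = hash)

  counts <- run_stage("load", {
    inp <- config$input
    if (!is.null(inp$dense)) {
      orientation <- if (is.null(inp$orientation)) "genes_in_rows"
                     else inp$orientation
      methods::as(Matrix::Matrix(
        read_dense_matrix(inp$dense, orientation, integer_counts = TRUE),
        sparse = TRUE), "CsparseMatrix")
    } else {
      read_counts_mtx(inp$matrix, inp$genes, inp$barcodes)
    }
  })
  summary$n_genes_in <- nrow(counts)
  summary$n_cells_in <- ncol(counts)

  sel <- run_stage("select", {
    set.seed(seed + 1L)
    sc <- config$selection
    cfg <- do.call(selection_config,
                   c(sc[setdiff(names(sc), c("s_genes", "g2m_genes"))],
                     list(seed = seed + 1L)))
    if (is.null(sc$s_genes) || is.null(sc$g2m_genes))
      pipeline_log("info", lvl,
                   "no cycle signatures supplied; phase filter skipped")
    select_cells(counts, cfg, s_genes = sc$s_genes,
                 g2m_genes = sc$g2m_genes)
  })
  writeLines(sel$cells, file.path(outdir, "selected_barcodes.txt"))
  write_counts_mtx(sel$counts, file.path(outdir, "filtered_matrix"))
  summary$n_genes_filtered <- nrow(sel$counts)
  summary$n_cells_selected <- ncol(sel$counts)

  hv <- run_stage("hvg", {
    h <- config$hvg
    sc_hvg(sel$counts,
           fdr_threshold = if (is.null(h$fdr_threshold)) 0.01
                           else h$fdr_threshold,
           fc_threshold = h$fc_threshold,
           min_mean_quantile = if (is.null(h$min_mean_quantile)) 0.25
                               else h$min_mean_quantile)
  })
  write_gene_stats(hv$stats, file.path(outdir, "gene_stats.tsv"), header)
  writeLines(hv$hvg_genes, file.path(outdir, "hvg_genes.txt"))
  summary$n_hvg <- length(hv$hvg_genes)
  summary$trend <- c(a0 = hv$trend$a0, a1 = hv$trend$a1)

  if (!is.null(config$network)) {
    nw <- config$network
    run_stage("network", {
      top_n <- if (is.null(nw$top_n)) 50 else nw$top_n
      ranked <- hv$stats[!hv$stats$excluded, ]
      ranked <- ranked[order(-ranked$residual_variability, ranked$gene), ]
      genes <- utils::head(ranked$gene, top_n)
      logn <- log_normalize(sel$counts)
      smoothed <- impute_diffusion(
        logn, k = if (is.null(nw$knn_k)) 30 else nw$knn_k,
        t = if (is.null(nw$t)) 3 else nw$t)
      net <- build_network(
        smoothed, genes,
        distance_threshold = if (is.null(nw$distance_threshold)) 0.3
                             else nw$distance_threshold)
      utils::write.table(net$edges, file.path(outdir, "network_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(net$nodes, file.path(outdir, "network_nodes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$n_network_edges <- nrow(net$edges)
      if (!is.null(nw$signed_edges)) {
        edges <- read_signed_edges(nw$signed_edges)
        rep <- sign_consistency(smoothed, edges)
        utils::write.table(rep$edges,
                           file.path(outdir, "sign_consistency.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        summary$sign_consistency <-
          c(consistent = rep$n_consistent, total = rep$n_total)
      }
    })
  } else pipeline_log("info", lvl, "network stage skipped (not configured)")

  if (!is.null(config$popvar)) {
    pv <- config$popvar
    run_stage("popvar", {
      bulk <- read_dense_matrix(pv$bulk,
                                if (is.null(pv$orientation)) "genes_in_rows"
                                else pv$orientation)
      brv <- bulk_residual_variability(bulk)
      sets <- if (!is.null(pv$gmt)) read_gmt(pv$gmt) else NULL
      res <- correlate_variability(
        rv_vector(hv$stats), rv_vector(brv), sets,
        min_size = if (is.null(pv$min_size)) 10 else pv$min_size)
      utils::write.table(res$overall,
                         file.path(outdir, "popvar_overall.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(res$per_set,
                         file.path(outdir, "popvar_per_set.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$popvar_r <- res$overall$spearman_r
    })
  } else pipeline_log("info", lvl, "popvar stage skipped (not configured)")

  if (!is.null(config$enrich)) {
    run_stage("enrich", {
      sets <- read_gmt(config$enrich$gmt)
      universe <- hv$stats$gene[!hv$stats$excluded]
      res <- ora_hypergeometric(hv$hvg_genes, universe, sets)
      utils::write.table(res, file.path(outdir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$n_enriched_q05 <- sum(res$qvalue < 0.05)
    })
  } else pipeline_log("info", lvl, "enrich stage skipped (not configured)")

  writeLines(c(paste0("# ", header),
               paste(names(unlist(summary)), unlist(summary), sep = "\t")),
             file.path(outdir, "summary.txt"))
  invisible(summary)
}
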