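#' Diffusion smoothing of expression profiles over a cell k-NN graph
#'
#' Dropout-denoising stand-in for kernel-based imputation: a symmetrized
#' k-nearest-neighbor graph (Euclidean distance between cell profiles, self
#' loops included) is row-normalized into a transition operator P, and the
#' cell profiles are averaged t times: `smoothed = X P'^t`. `t = 0` returns
#' the input unchanged; as t grows, connected cells converge to a common
#' profile.
#'
#' @param x gene x cell numeric matrix (typically log-normalized expression).
#' @param k number of nearest neighbors (`0 < k < n_cells`).
#' @param t nonnegative integer diffusion time.
#' @return smoothed matrix of the same shape and dimnames.
#' @export
impute_diffusion <- function(x, k = 30, t = 3) {
  if (k <= 0) stop("k must be positive")
  n <- ncol(x)
  if (k >= n) stop("k must be smaller than the number of cells")
  if (t < 0 || t != round(t)) stop("t must be a nonnegative integer")
  x <- as.matrix(x)
  if (t == 0) return(x)
  d <- as.matrix(stats::dist(t(x)))
  adj <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    ord <- order(d[j, ])
    ord <- ord[ord != j]
    adj[j, ord[seq_len(k)]] <- TRUE
  }
  adj <- adj | t(adj)
  diag(adj) <- TRUE
  p <- adj / rowSums(adj)
  pt <- diag(n)
  for (i in seq_len(t)) pt <- pt %*% p
  out <- x %*% t(pt)
  dimnames(out) <- dimnames(x)
  out
}

#' Build a co-expression network from smoothed expression
#'
#' Pairwise Pearson correlation between the given genes across cells;
#' `1 - r` is the distance, and an (undirected, unweighted) edge is kept iff
#' the distance is below `distance_threshold`. Betweenness centrality ranks
#' candidate hub genes.
#'
#' @param x gene x cell matrix (typically the [impute_diffusion()] output).
#' @param genes character vector of >= 3 genes to include (typically the top
#'   HVGs by residual variability; 50 is the conventional count).
#' @param distance_threshold edges kept where `1 - r < distance_threshold`.
#' @return list of class `"scev_network"`: `nodes` (data.frame gene,
#'   betweenness, sorted hubs first), `edges` (data.frame gene_a, gene_b,
#'   distance), `cor` (correlation matrix), `graph` (igraph object).
#' @export
build_network <- function(x, genes, distance_threshold = 0.3) {
  if (length(genes) < 3) stop("at least 3 genes are required")
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stop("genes absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  sub <- as.matrix(x[genes, , drop = FALSE])
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(genes[sds == 0], 5), collapse = ", "))
  r <- stats::cor(t(sub))
  dmat <- 1 - r
  adj <- dmat < distance_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  btw <- igraph::betweenness(g, directed = FALSE)
  nodes <- data.frame(gene = genes, betweenness = btw[genes],
                      stringsAsFactors = FALSE, row.names = NULL)
  nodes <- nodes[order(-nodes$betweenness, nodes$gene), ]
  rownames(nodes) <- NULL
  ij <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(gene_a = genes[ij[, 1]], gene_b = genes[ij[, 2]],
                      distance = dmat[ij], stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, cor = r, graph = g),
            class = "scev_network")
}

#' @export
print.scev_network <- function(x, ...) {
  cat(sprintf("co-expression network: %d genes, %d edges; top hub: %s\n",
              nrow(x$nodes), nrow(x$edges),
              if (nrow(x$nodes)) x$nodes$gene[1] else "<none>"))
  invisible(x)
}

#' Check expression-correlation signs against a signed regulatory model
#'
#' For each (source, target, sign) edge the correlation between the two
#' genes' expression across cells is computed (Spearman by default); the edge
#' is `consistent` when the correlation sign matches the model sign
#' (induction = positive, repression = negative), `inconsistent` when it
#' opposes it, and `undefined` when the correlation is zero or undefined
#' (still counted in `n_total`).
#'
#' @param x gene x cell matrix (conventionally the imputed/smoothed data).
#' @param edges data.frame `source`, `target`, `sign` (see
#'   [read_signed_edges()]).
#' @param method correlation method, default `"spearman"`.
#' @return list: `n_total`, `n_consistent`, `edges` (per-edge table with
#'   `correlation` and `verdict`).
#' @export
sign_consistency <- function(x, edges, method = "spearman") {
  if (nrow(edges) == 0)
    return(list(n_total = 0L, n_consistent = 0L,
                edges = cbind(edges, correlation = numeric(0),
                              verdict = character(0))))
  need <- unique(c(edges$source, edges$target))
  missing <- setdiff(need, rownames(x))
  if (length(missing))
    stop("edge gene(s) absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  x <- as.matrix(x)
  rho <- vapply(seq_len(nrow(edges)), function(i)
    suppressWarnings(stats::cor(x[edges$source[i], ], x[edges$target[i], ],
                                method = method)), 0)
  expected <- ifelse(edges$sign == "induction", 1, -1)
  verdict <- ifelse(!is.finite(rho) | rho == 0, "undefined",
                    ifelse(sign(rho) == expected, "consistent",
                           "inconsistent"))
  out <- edges
  out$correlation <- rho
  out$verdict <- verdict
  list(n_total = nrow(out),
       n_consistent = sum(verdict == "consistent"),
       edges = out)
}
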