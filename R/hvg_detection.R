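#' Library-size normalization
#'
#' Rescales every cell to the median library size (default) or to counts per
#' million, the two conventions used for the CV^2 statistics and for display.
#'
#' @param counts gene x cell matrix (sparse or dense), nonnegative.
#' @param target `"median"` or `"cpm"`.
#' @return matrix of the same shape, normalized columns.
#' @export
normalize_counts <- function(counts, target = c("median", "cpm")) {
  target <- match.arg(target)
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) stop("cells with zero library size cannot be normalized")
  scale_to <- if (target == "median") stats::median(lib) else 1e6
  out <- counts %*% Matrix::Diagonal(x = scale_to / lib, names = FALSE)
  dimnames(out) <- dimnames(counts)
  out
}

#' Log-normalized expression
#'
#' `log(1 + x)` of median-library normalized counts; the working scale for
#' cell-cycle scoring, embedding, and diffusion smoothing.
#'
#' @inheritParams normalize_counts
#' @return dense numeric matrix, genes x cells, with dimnames preserved.
#' @export
log_normalize <- function(counts, target = "median") {
  x <- as.matrix(normalize_counts(counts, target))
  dimnames(x) <- dimnames(counts)
  log1p(x)
}

#' Per-gene mean and squared coefficient of variation
#'
#' First step of the HVG statistic: each cell's counts are rescaled to the
#' median library size, then the per-gene sample mean (mu-hat) and the
#' unbiased-variance squared CV (w-hat = s^2 / mu-hat^2) are computed across
#' the m cells. Genes with zero mean are flagged `excluded` and carry no CV^2.
#'
#' @param counts gene x cell matrix of nonnegative counts, >= 2 cells.
#' @param normalize if `FALSE` the values are used as-is (pre-normalized
#'   input, e.g. a bulk cohort matrix).
#' @return data.frame with columns `gene`, `mean`, `cv2_obs`, `excluded`;
#'   attribute `m` stores the number of cells.
#' @examples
#' cnt <- matrix(c(2, 2, 4, 4), 1, 4, dimnames = list("g1", paste0("c", 1:4)))
#' compute_gene_stats(cnt)   # mean 3, cv2 = (4/3)/9
#' @export
compute_gene_stats <- function(counts, normalize = TRUE) {
  m <- ncol(counts)
  if (m < 2) stop("at least 2 cells are required to estimate CV^2")
  y <- if (normalize) normalize_counts(counts, "median") else counts
  mu <- as.numeric(Matrix::rowMeans(y))
  ex2 <- as.numeric(Matrix::rowMeans(y * y))
  v <- pmax(ex2 - mu^2, 0) * m / (m - 1)
  excluded <- mu <= 0
  cv2 <- ifelse(excluded, NA_real_, v / mu^2)
  genes <- rownames(counts)
  if (is.null(genes)) genes <- sprintf("gene%04d", seq_along(mu))
  out <- data.frame(gene = genes, mean = mu, cv2_obs = cv2,
                    excluded = excluded, stringsAsFactors = FALSE)
  attr(out, "m") <- m
  out
}

#' Fit the technical-noise trend E(CV^2) = a1/mu + a0
#'
#' Gamma-family generalized linear model with identity link, response the
#' observed CV^2 and single predictor 1/mu, fitted on genes whose mean
#' exceeds the `min_mean_quantile` quantile of the nonzero means (low-mean
#' genes destabilize the gamma fit). If the iteratively reweighted fit fails
#' to converge, an ordinary least-squares fit of CV^2 on 1/mu is used and
#' `converged` is set to `FALSE`.
#'
#' @param stats output of [compute_gene_stats()].
#' @param min_mean_quantile quantile of nonzero means below which genes are
#'   not used for fitting (default 0.25).
#' @return object of class `"scev_trend"`: list with `a0`, `a1`,
#'   `n_fit_genes`, `converged`.
#' @export
fit_cv2_trend <- function(stats, min_mean_quantile = 0.25) {
  ok <- !stats$excluded & is.finite(stats$cv2_obs) & stats$cv2_obs > 0
  nz <- stats$mean[stats$mean > 0]
  cutoff <- stats::quantile(nz, min_mean_quantile, names = FALSE)
  fit_set <- ok & stats$mean >= cutoff
  mu <- stats$mean[fit_set]
  w <- stats$cv2_obs[fit_set]
  if (length(unique(mu)) < 2)
    stop("trend fit needs at least 2 fitted genes with distinct means")
  x <- 1 / mu
  ls <- stats::lm.fit(cbind(1, x), w)$coefficients
  converged <- FALSE
  co <- ls
  fit <- tryCatch(
    suppressWarnings(
      stats::glm(w ~ x, family = stats::Gamma(link = "identity"),
                 start = pmax(ls, c(1e-8, 1e-8)))),
    error = function(e) NULL)
  if (!is.null(fit) && fit$converged && all(fit$fitted.values > 0)) {
    co <- stats::coef(fit)
    converged <- TRUE
  }
  pred <- co[2] / mu + co[1]
  if (any(pred <= 0))
    stop("fitted trend predicts nonpositive CV^2 at a fitted gene's mean")
  structure(list(a0 = unname(co[1]), a1 = unname(co[2]),
                 n_fit_genes = length(mu), converged = converged),
            class = "scev_trend")
}

#' @export
print.scev_trend <- function(x, ...) {
  cat(sprintf(
    "CV^2 trend: a0 = %.4g, a1 = %.4g (%d genes, %s)\n",
    x$a0, x$a1, x$n_fit_genes,
    if (x$converged) "gamma GLM" else "least-squares fallback"))
  invisible(x)
}

#' Chi-squared residual test and residual variability
#'
#' For each gene the expected CV^2 is `a1/mu + a0`; the ratio of observed to
#' expected CV^2, scaled by the degrees of freedom, is referred to the upper
#' tail of a chi-squared distribution: T = (m-1) * ratio ~ chi^2_(m-1) under
#' the technical-noise null. Only larger-than-expected variability is tested
#' (one-sided); residual variability is log2(ratio), the single-cell
#' expression-variability measure.
#'
#' @param stats output of [compute_gene_stats()].
#' @param fit a `"scev_trend"` object from [fit_cv2_trend()].
#' @param m number of cells; defaults to the attribute stored in `stats`.
#' @return `stats` extended with `cv2_exp`, `ratio`, `residual_variability`,
#'   `pvalue` (excluded genes get `NA`).
#' @export
score_genes <- function(stats, fit, m = attr(stats, "m")) {
  if (is.null(m) || m < 2) stop("m (number of cells) must be >= 2")
  cv2_exp <- fit$a1 / stats$mean + fit$a0
  scored <- !stats$excluded
  bad <- scored & (!is.finite(cv2_exp) | cv2_exp <= 0)
  if (any(bad))
    stop("degenerate trend: nonpositive expected CV^2 for gene(s) ",
         paste(utils::head(stats$gene[bad], 5), collapse = ", "))
  ratio <- ifelse(scored, stats$cv2_obs / cv2_exp, NA_real_)
  out <- stats
  out$cv2_exp <- ifelse(scored, cv2_exp, NA_real_)
  out$ratio <- ratio
  out$residual_variability <- log2(ratio)
  out$pvalue <- stats::pchisq((m - 1) * ratio, df = m - 1,
                              lower.tail = FALSE)
  attr(out, "m") <- m
  out
}

#' Benjamini-Hochberg adjustment and HVG calling
#'
#' Adjusts the chi-squared p-values by BH step-up over all genes with defined
#' statistics and calls a gene highly variable when `qvalue < fdr_threshold`
#' and, if `fc_threshold` is given, the observed/expected CV^2 ratio exceeds
#' it. Default thresholds follow the usual calling rule FDR < 0.01 with an
#' optional fold-change > 1.5.
#'
#' @param stats output of [score_genes()].
#' @param fdr_threshold FDR cutoff in (0, 1]; default 0.01.
#' @param fc_threshold optional CV^2-ratio cutoff (> 0), e.g. 1.5; `NULL`
#'   disables the fold-change condition.
#' @return list with `stats` (extended with `qvalue`, `is_hvg`) and
#'   `hvg_genes`, the called genes sorted by residual variability descending.
#' @export
adjust_and_call <- function(stats, fdr_threshold = 0.01,
                            fc_threshold = NULL) {
  if (!is.numeric(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold > 1)
    stop("fdr_threshold must lie in (0, 1]")
  if (!is.null(fc_threshold) && fc_threshold <= 0)
    stop("fc_threshold must be positive")
  p <- stats$pvalue
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  is_hvg <- !is.na(q) & q < fdr_threshold
  if (!is.null(fc_threshold))
    is_hvg <- is_hvg & !is.na(stats$ratio) & stats$ratio > fc_threshold
  out <- stats
  out$qvalue <- q
  out$is_hvg <- is_hvg
  hvg <- out$gene[is_hvg]
  hvg <- hvg[order(-out$residual_variability[is_hvg], hvg)]
  list(stats = out, hvg_genes = hvg)
}

#' Full HVG detection on a count matrix
#'
#' Convenience wrapper chaining [compute_gene_stats()], [fit_cv2_trend()],
#' [score_genes()] and [adjust_and_call()].
#'
#' @inheritParams compute_gene_stats
#' @inheritParams fit_cv2_trend
#' @inheritParams adjust_and_call
#' @return list with `stats` (full per-gene table), `trend`, `hvg_genes`.
#' @export
sc_hvg <- function(counts, fdr_threshold = 0.01, fc_threshold = NULL,
                   min_mean_quantile = 0.25, normalize = TRUE) {
  gs <- compute_gene_stats(counts, normalize = normalize)
  trend <- fit_cv2_trend(gs, min_mean_quantile)
  scored <- score_genes(gs, trend)
  called <- adjust_and_call(scored, fdr_threshold, fc_threshold)
  list(stats = called$stats, trend = trend, hvg_genes = called$hvg_genes)
}
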