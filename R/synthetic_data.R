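#' Simulation parameters for synthetic UMI data
#'
#' Builds the parameter list consumed by [simulate_counts()],
#' [simulate_structured_population()] and [simulate_bulk_cohort()]. The
#' generative model is a gamma-Poisson mixture: gene means are log-normal,
#' per-cell size factors are log-normal with coefficient of variation
#' `capture_cv`, a log-normal technical multiplier with squared CV `a0_tech`
#' applies to every gene, and planted highly variable genes (HVGs) carry an
#' extra gamma-distributed biological multiplier with squared CV drawn from
#' `bio_cv2_range`. Under this model null genes obey the technical-noise law
#' CV^2 ~ a0 + a1/mu that the HVG test assumes.
#'
#' @param n_genes,n_cells positive integers; matrix dimensions.
#' @param seed integer seed; fully determines all output.
#' @param mean_log_mu,sd_log_mu location/scale of the log-normal gene-mean
#'   distribution, in normalized-count units.
#' @param a0_tech baseline technical squared CV (log-normal multiplier).
#' @param capture_cv CV of the per-cell size factors.
#' @param hvg_fraction fraction of genes planted as HVGs, in `[0, 1]`.
#' @param bio_cv2_range length-2 numeric; extra biological squared CV of
#'   planted HVGs is drawn uniformly from this interval.
#' @param branch_spec list of `list(n_cells, n_markers, fold)` describing
#'   planted subpopulation branches (folds must be >= 1).
#' @param cycle_signal_fold fold-change (>= 1) applied to S / G2M signature
#'   genes of cells in the corresponding phase; 1 disables the cycle signal.
#' @param n_s_genes,n_g2m_genes number of reserved signature genes per phase.
#' @param phase_fractions named numeric (G1, S, G2M) summing to 1; used only
#'   when `cycle_signal_fold > 1`.
#' @param n_individuals bulk-cohort size for [simulate_bulk_cohort()].
#' @param coupling fraction in `[0, 1]` of a gene's cohort-level biological
#'   variance driven by its single-cell biological CV^2.
#' @param bulk_base_cv2 baseline (non-mean-dependent) cohort squared CV shared
#'   by all genes.
#' @param bulk_depth scale of the mean-dependent cohort measurement noise;
#'   the cohort trend slope is approximately `1/bulk_depth`.
#' @return A validated parameter list of class `"scev_sim_params"`.
#' @export
sim_params <- function(n_genes = 2000, n_cells = 1000, seed = 1,
                       mean_log_mu = log(5), sd_log_mu = 1,
                       a0_tech = 0.05, capture_cv = 0.15,
                       hvg_fraction = 0.1, bio_cv2_range = c(0.2, 1),
                       branch_spec = list(), cycle_signal_fold = 1,
                       n_s_genes = 20, n_g2m_genes = 20,
                       phase_fractions = c(G1 = 0.6, S = 0.2, G2M = 0.2),
                       n_individuals = 200, coupling = 1,
                       bulk_base_cv2 = 0.05, bulk_depth = 1) {
  p <- list(n_genes = n_genes, n_cells = n_cells, seed = seed,
            mean_log_mu = mean_log_mu, sd_log_mu = sd_log_mu,
            a0_tech = a0_tech, capture_cv = capture_cv,
            hvg_fraction = hvg_fraction, bio_cv2_range = bio_cv2_range,
            branch_spec = branch_spec, cycle_signal_fold = cycle_signal_fold,
            n_s_genes = n_s_genes, n_g2m_genes = n_g2m_genes,
            phase_fractions = phase_fractions,
            n_individuals = n_individuals, coupling = coupling,
            bulk_base_cv2 = bulk_base_cv2, bulk_depth = bulk_depth)
  validate_sim_params(p)
  class(p) <- "scev_sim_params"
  p
}

validate_sim_params <- function(p) {
  stopifnot(is.list(p))
  if (!is.numeric(p$n_genes) || length(p$n_genes) != 1 ||
      p$n_genes != round(p$n_genes) || p$n_genes <= 0)
    stop("n_genes must be a positive integer")
  if (!is.numeric(p$n_cells) || length(p$n_cells) != 1 ||
      p$n_cells != round(p$n_cells) || p$n_cells <= 0)
    stop("n_cells must be a positive integer")
  if (p$sd_log_mu <= 0) stop("sd_log_mu must be positive")
  if (p$a0_tech < 0) stop("a0_tech must be nonnegative")
  if (p$capture_cv < 0) stop("capture_cv must be nonnegative")
  if (p$hvg_fraction < 0 || p$hvg_fraction > 1)
    stop("hvg_fraction must lie in [0, 1]")
  if (length(p$bio_cv2_range) != 2 || any(p$bio_cv2_range < 0) ||
      p$bio_cv2_range[1] > p$bio_cv2_range[2])
    stop("bio_cv2_range must be an ordered nonnegative interval")
  for (b in p$branch_spec) {
    if (is.null(b$n_cells) || is.null(b$n_markers) || is.null(b$fold))
      stop("each branch_spec entry needs n_cells, n_markers, fold")
    if (b$fold < 1) stop("branch effect folds must be >= 1")
  }
  if (p$cycle_signal_fold < 1) stop("cycle_signal_fold must be >= 1")
  if (p$n_individuals != round(p$n_individuals) || p$n_individuals <= 0)
    stop("n_individuals must be a positive integer")
  if (p$coupling < 0 || p$coupling > 1) stop("coupling must lie in [0, 1]")
  invisible(TRUE)
}

# Draw the gene/cell level latent quantities shared by both count simulators.
# A log-normal with squared CV c has sdlog sqrt(log(1+c)); meanlog is chosen
# so that the expectation is exactly 1.
sim_latents <- function(p) {
  gene_ids <- sprintf("gene%04d", seq_len(p$n_genes))
  cell_ids <- sprintf("cell%05d", seq_len(p$n_cells))
  mu <- stats::rlnorm(p$n_genes, p$mean_log_mu, p$sd_log_mu)
  n_hvg <- round(p$hvg_fraction * p$n_genes)
  bio_cv2 <- numeric(p$n_genes)
  if (n_hvg > 0) {
    hvg_idx <- sample.int(p$n_genes, n_hvg)
    bio_cv2[hvg_idx] <- stats::runif(n_hvg, p$bio_cv2_range[1],
                                     p$bio_cv2_range[2])
  }
  sd_s <- sqrt(log1p(p$capture_cv^2))
  size_factor <- stats::rlnorm(p$n_cells, -sd_s^2 / 2, sd_s)
  list(gene_ids = gene_ids, cell_ids = cell_ids, mu = mu,
       bio_cv2 = bio_cv2, is_hvg = bio_cv2 > 0, size_factor = size_factor)
}

# Per-cell Poisson rates: outer(mu, s) times a log-normal technical
# multiplier (CV^2 = a0_tech) times, for HVG rows, a mean-1 gamma multiplier
# with CV^2 = bio_cv2.
sim_rates <- function(p, lat) {
  lambda <- outer(lat$mu, lat$size_factor)
  if (p$a0_tech > 0) {
    sd_t <- sqrt(log1p(p$a0_tech))
    lambda <- lambda * matrix(
      stats::rlnorm(p$n_genes * p$n_cells, -sd_t^2 / 2, sd_t),
      p$n_genes, p$n_cells)
  }
  hvg <- which(lat$is_hvg)
  for (i in hvg) {
    shape <- 1 / lat$bio_cv2[i]
    lambda[i, ] <- lambda[i, ] *
      stats::rgamma(p$n_cells, shape = shape, rate = shape)
  }
  lambda
}

sim_draw_counts <- function(lambda, gene_ids, cell_ids) {
  counts <- matrix(stats::rpois(length(lambda), lambda),
                   nrow(lambda), ncol(lambda),
                   dimnames = list(gene_ids, cell_ids))
  methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
}

sim_truth <- function(lat, subpop, phase) {
  list(
    gene = data.frame(gene = lat$gene_ids, mu_true = lat$mu,
                      bio_cv2 = lat$bio_cv2, is_hvg = lat$is_hvg,
                      stringsAsFactors = FALSE),
    cell = data.frame(cell = lat$cell_ids, size_factor = lat$size_factor,
                      subpop_label = subpop, phase_label = phase,
                      stringsAsFactors = FALSE))
}

#' Simulate a UMI count matrix with planted highly variable genes
#'
#' Gamma-Poisson generator whose null genes follow the technical-noise trend
#' CV^2 ~ a0 + a1/mu (with a0 = `a0_tech` and a1 ~ 1 + `capture_cv`^2 in
#' normalized-count units) and whose planted HVGs carry extra biological
#' squared CV. All cells are labelled `core` / phase `G1`.
#'
#' @param params a [sim_params()] object.
#' @return `list(counts, truth)`: a sparse integer gene x cell matrix and the
#'   ground-truth tables (per-gene `mu_true`, `bio_cv2`, `is_hvg`; per-cell
#'   `size_factor`, `subpop_label`, `phase_label`).
#' @examples
#' sim <- simulate_counts(sim_params(n_genes = 200, n_cells = 100, seed = 7))
#' dim(sim$counts)
#' table(sim$truth$gene$is_hvg)
#' @export
simulate_counts <- function(params) {
  validate_sim_params(params)
  set.seed(params$seed)
  lat <- sim_latents(params)
  lambda <- sim_rates(params, lat)
  counts <- sim_draw_counts(lambda, lat$gene_ids, lat$cell_ids)
  truth <- sim_truth(lat, subpop = rep("core", params$n_cells),
                     phase = rep("G1", params$n_cells))
  list(counts = counts, truth = truth)
}

#' Simulate a structured cell population with branches and cell-cycle signal
#'
#' Extends [simulate_counts()] with planted subpopulation branches (marker
#' genes up-regulated by `fold` in branch cells) and an optional cell-cycle
#' signal (`cycle_signal_fold` applied to reserved S / G2M signature genes of
#' cells assigned to that phase). Signature gene identifiers are attached to
#' the result as `s_genes` / `g2m_genes`.
#'
#' @param params a [sim_params()] object; `branch_spec` and
#'   `cycle_signal_fold` control the structure.
#' @return `list(counts, truth, s_genes, g2m_genes)`.
#' @export
simulate_structured_population <- function(params) {
  validate_sim_params(params)
  n_branch <- sum(vapply(params$branch_spec, function(b) b$n_cells, 0))
  if (n_branch > params$n_cells)
    stop("branch cells exceed n_cells")
  set.seed(params$seed)
  lat <- sim_latents(params)

  # reserve signature genes at the end of the gene index; they are nulls
  use_cycle <- params$cycle_signal_fold > 1
  n_sig <- if (use_cycle) params$n_s_genes + params$n_g2m_genes else 0
  n_marker_total <- sum(vapply(params$branch_spec,
                               function(b) b$n_markers, 0))
  if (n_marker_total + n_sig > params$n_genes)
    stop("marker/signature gene request exceeds n_genes")
  s_genes <- g2m_genes <- character(0)
  if (use_cycle) {
    sig_idx <- seq(params$n_genes - n_sig + 1, params$n_genes)
    s_idx <- sig_idx[seq_len(params$n_s_genes)]
    g2m_idx <- sig_idx[params$n_s_genes + seq_len(params$n_g2m_genes)]
    s_genes <- lat$gene_ids[s_idx]
    g2m_genes <- lat$gene_ids[g2m_idx]
    lat$bio_cv2[sig_idx] <- 0
    lat$is_hvg[sig_idx] <- FALSE
  }

  # branch membership: contiguous marker blocks, random cell assignment
  subpop <- rep("core", params$n_cells)
  marker_of <- vector("list", length(params$branch_spec))
  free_cells <- seq_len(params$n_cells)
  next_marker <- 1L
  for (k in seq_along(params$branch_spec)) {
    b <- params$branch_spec[[k]]
    pick <- sample(free_cells, b$n_cells)
    free_cells <- setdiff(free_cells, pick)
    subpop[pick] <- paste0("branch", k)
    marker_of[[k]] <- seq(next_marker, next_marker + b$n_markers - 1L)
    next_marker <- next_marker + b$n_markers
  }

  phase <- rep("G1", params$n_cells)
  if (use_cycle) {
    pf <- params$phase_fractions / sum(params$phase_fractions)
    phase <- sample(names(pf), params$n_cells, replace = TRUE, prob = pf)
  }

  lambda <- sim_rates(params, lat)
  for (k in seq_along(params$branch_spec)) {
    b <- params$branch_spec[[k]]
    cells <- which(subpop == paste0("branch", k))
    lambda[marker_of[[k]], cells] <- lambda[marker_of[[k]], cells] * b$fold
  }
  if (use_cycle) {
    lambda[s_idx, phase == "S"] <-
      lambda[s_idx, phase == "S"] * params$cycle_signal_fold
    lambda[g2m_idx, phase == "G2M"] <-
      lambda[g2m_idx, phase == "G2M"] * params$cycle_signal_fold
  }
  counts <- sim_draw_counts(lambda, lat$gene_ids, lat$cell_ids)
  truth <- sim_truth(lat, subpop = subpop, phase = phase)
  list(counts = counts, truth = truth,
       s_genes = s_genes, g2m_genes = g2m_genes)
}

#' Simulate a bulk expression cohort coupled to single-cell variability
#'
#' Generates a positive genes x individuals matrix (FPKM-like) whose per-gene
#' cohort variance has three multiplicative log-normal components: a baseline
#' squared CV `bulk_base_cv2` shared by all genes, a mean-dependent
#' measurement component `1/(mu * bulk_depth)`, and a biological component
#' equal to `coupling * bio_cv2 + (1 - coupling) * v`, where `v` is an
#' independently re-drawn gene-level variance with the same marginal
#' distribution as `bio_cv2`. At `coupling = 1` cohort-level residual
#' variability tracks the single-cell biological CV^2; at `coupling = 0` the
#' two are independent.
#'
#' @param truth the `truth` element returned by a count simulator.
#' @param params the same [sim_params()] object (fields `n_individuals`,
#'   `coupling`, `bulk_base_cv2`, `bulk_depth`, `hvg_fraction`,
#'   `bio_cv2_range`, `seed`).
#' @return numeric matrix, genes x individuals, positive reals.
#' @export
simulate_bulk_cohort <- function(truth, params) {
  validate_sim_params(params)
  if (params$n_individuals < 3)
    stop("n_individuals must be at least 3")
  g <- truth$gene
  n_genes <- nrow(g)
  set.seed(params$seed + 1000003L)
  # independent counterpart of bio_cv2, same marginal law
  v <- numeric(n_genes)
  n_v <- round(params$hvg_fraction * n_genes)
  if (n_v > 0) {
    idx <- sample.int(n_genes, n_v)
    v[idx] <- stats::runif(n_v, params$bio_cv2_range[1],
                           params$bio_cv2_range[2])
  }
  bio_part <- params$coupling * g$bio_cv2 + (1 - params$coupling) * v
  cv2_total_log <- log1p(params$bulk_base_cv2) +
    log1p(1 / (g$mu_true * params$bulk_depth)) + log1p(bio_part)
  sdlog <- sqrt(cv2_total_log)
  z <- matrix(stats::rnorm(n_genes * params$n_individuals),
              n_genes, params$n_individuals)
  vals <- g$mu_true * exp(z * sdlog - sdlog^2 / 2)
  dimnames(vals) <- list(g$gene,
                         sprintf("ind%03d", seq_len(params$n_individuals)))
  vals
}

#' Simulate counts driven by a signed regulatory model
#'
#' For each regulator in `edges`, a per-cell latent activity z ~ N(0, 1)
#' multiplies the regulator's mean by `effect_fold^z` and each target's mean
#' by `effect_fold^(z)` (induction) or `effect_fold^(-z)` (repression), so the
#' sign of the expression correlation across cells matches the planted edge
#' sign. Counts are Poisson around `base_mean` with log-normal size factors.
#' Used to validate [sign_consistency()] end to end.
#'
#' @param edges data.frame with columns `source`, `target`, `sign`
#'   (`"induction"` / `"repression"`), as returned by [read_signed_edges()].
#' @param n_cells number of cells.
#' @param base_mean baseline expression mean in counts.
#' @param effect_fold regulatory effect size (fold per latent s.d.; >= 1).
#' @param capture_cv CV of per-cell size factors.
#' @param seed integer seed.
#' @return `list(counts, activity)`: sparse counts over the edge genes and the
#'   per-regulator latent activity matrix.
#' @export
simulate_regulated_counts <- function(edges, n_cells = 500, base_mean = 20,
                                      effect_fold = 4, capture_cv = 0.1,
                                      seed = 1) {
  if (effect_fold < 1) stop("effect_fold must be >= 1")
  genes <- sort(unique(c(edges$source, edges$target)))
  regs <- sort(unique(edges$source))
  set.seed(seed)
  z <- matrix(stats::rnorm(length(regs) * n_cells), length(regs), n_cells,
              dimnames = list(regs, NULL))
  logf <- log(effect_fold)
  loglam <- matrix(log(base_mean), length(genes), n_cells,
                   dimnames = list(genes, NULL))
  for (r in regs)
    loglam[r, ] <- loglam[r, ] + logf * z[r, ]
  for (i in seq_len(nrow(edges))) {
    sgn <- if (edges$sign[i] == "induction") 1 else -1
    loglam[edges$target[i], ] <- loglam[edges$target[i], ] +
      sgn * logf * z[edges$source[i], ]
  }
  sd_s <- sqrt(log1p(capture_cv^2))
  s <- stats::rlnorm(n_cells, -sd_s^2 / 2, sd_s)
  lambda <- sweep(exp(loglam), 2, s, `*`)
  counts <- sim_draw_counts(lambda, genes,
                            sprintf("cell%05d", seq_len(n_cells)))
  list(counts = counts, activity = z)
}

#' Write a simulation to disk in 10x-triplet form with truth tables
#'
#' @param sim result of [simulate_counts()] or
#'   [simulate_structured_population()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_counts_mtx(sim$counts, dir)
  utils::write.table(sim$truth$gene, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$cell, file.path(dir, "truth_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
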