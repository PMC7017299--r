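toy_profiles <- function(n_genes = 5, n_cells = 7, seed = 13) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_cells), n_genes, n_cells,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("c", seq_len(n_cells))))
}

test_that("diffusion with t = 0 is the identity and parameters validate", {
  x <- toy_profiles()
  expect_identical(impute_diffusion(x, k = 3, t = 0), x)
  expect_error(impute_diffusion(x, k = 0, t = 1), "k must be positive")
  expect_error(impute_diffusion(x, k = 7, t = 1), "smaller")
  expect_error(impute_diffusion(x, k = 3, t = 1.5), "nonnegative integer")
})

test_that("one diffusion step equals the explicit transition operator", {
  x <- toy_profiles(4, 6)
  p <- knn_transition_oracle(x, k = 2)
  expect_equal(rowSums(p), rep(1, 6))  # row-stochastic by construction
  with_names <- function(m) { dimnames(m) <- dimnames(x); m }
  expect_equal(impute_diffusion(x, k = 2, t = 1), with_names(x %*% t(p)))
  expect_equal(impute_diffusion(x, k = 2, t = 3),
               with_names(x %*% t(p %*% p %*% p)))
})

test_that("diffusion conserves constant genes and reaches the ergodic limit", {
  x <- toy_profiles(5, 10, seed = 4)
  x[1, ] <- 2.5  # constant gene stays exactly constant under row averaging
  sm <- impute_diffusion(x, k = 3, t = 2)
  expect_equal(sm[1, ], setNames(rep(2.5, 10), colnames(x)),
               tolerance = 1e-8)
  lim <- impute_diffusion(x, k = 3, t = 64)
  spread <- apply(lim, 1, function(r) diff(range(r)))
  expect_true(all(spread < 1e-3))  # connected graph: common profile
})

test_that("perfectly correlated genes are joined at distance zero", {
  x <- toy_profiles(3, 8)
  x[2, ] <- 3 * x[1, ] + 1  # identical profile up to affine scale, r = 1
  net <- build_network(x, c("g1", "g2", "g3"), distance_threshold = 0.3)
  e <- net$edges[net$edges$gene_a == "g1" & net$edges$gene_b == "g2", ]
  expect_equal(nrow(e), 1)
  expect_equal(e$distance, 0)
  # correlation matrix is symmetric with unit diagonal
  expect_equal(net$cor, t(net$cor))
  expect_equal(unname(diag(net$cor)), rep(1, 3))
})

test_that("zero-variance and missing genes are named errors", {
  x <- toy_profiles(3, 6)
  x[3, ] <- 1
  expect_error(build_network(x, c("g1", "g2", "g3")), "g3")
  expect_error(build_network(x, c("g1", "g2", "gX")), "gX")
  expect_error(build_network(x, c("g1", "g2")), "at least 3")
})

test_that("planted modules are recovered as connected components", {
  set.seed(21)
  n_cells <- 60
  f1 <- rnorm(n_cells); f2 <- rnorm(n_cells)
  x <- rbind(
    t(sapply(1:4, function(i) f1 + rnorm(n_cells, sd = 0.3))),
    t(sapply(1:4, function(i) f2 + rnorm(n_cells, sd = 0.3))))
  rownames(x) <- paste0("g", 1:8); colnames(x) <- paste0("c", 1:n_cells)
  net <- build_network(x, rownames(x), distance_threshold = 0.3)
  comp <- igraph::components(net$graph)
  expect_equal(comp$no, 2)
  expect_equal(length(unique(comp$membership[1:4])), 1)
  expect_equal(length(unique(comp$membership[5:8])), 1)
})

test_that("betweenness matches exhaustive path enumeration on small graphs", {
  # two 3-cliques joined through a single bridge vertex
  genes <- paste0("g", 1:7)
  adj <- matrix(FALSE, 7, 7, dimnames = list(genes, genes))
  link <- function(a, b) adj[a, b] <<- adj[b, a] <<- TRUE
  link(1, 2); link(1, 3); link(2, 3)   # clique A
  link(5, 6); link(5, 7); link(6, 7)   # clique B
  link(3, 4); link(4, 5)               # bridge through g4
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  centr <- igraph::betweenness(g, directed = FALSE)
  expect_equal(unname(centr), betweenness_oracle(adj))
  expect_identical(names(which.max(centr)), "g4")  # the bridge is the hub
})

test_that("hub ranking follows betweenness on a thresholded network", {
  set.seed(8)
  n_cells <- 200
  fA <- rnorm(n_cells); fB <- rnorm(n_cells)
  x <- rbind(a1 = fA + rnorm(n_cells, sd = 0.2),
             a2 = fA + rnorm(n_cells, sd = 0.2),
             hub = fA + fB + rnorm(n_cells, sd = 0.2),
             b1 = fB + rnorm(n_cells, sd = 0.2),
             b2 = fB + rnorm(n_cells, sd = 0.2))
  colnames(x) <- paste0("c", 1:n_cells)
  net <- build_network(x, rownames(x), distance_threshold = 0.6)
  expect_identical(net$nodes$gene[1], "hub")
  adj <- matrix(FALSE, 5, 5, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(nrow(net$edges)))
    adj[net$edges$gene_a[i], net$edges$gene_b[i]] <-
      adj[net$edges$gene_b[i], net$edges$gene_a[i]] <- TRUE
  oracle <- betweenness_oracle(adj)
  expect_equal(net$nodes$betweenness[match(rownames(x), net$nodes$gene)],
               oracle)
})

test_that("sign consistency verdicts match hand-computed rank correlations", {
  x <- rbind(a = c(1, 2, 3, 4, 5),
             b = c(2, 4, 6, 8, 10),   # rho(a, b) = +1
             c = c(5, 4, 3, 2, 1))    # rho(a, c) = -1
  colnames(x) <- paste0("cell", 1:5)
  edges <- data.frame(source = c("a", "a"), target = c("b", "c"),
                      sign = c("induction", "induction"))
  rep <- sign_consistency(x, edges)
  expect_equal(rep$n_total, 2)
  expect_equal(rep$n_consistent, 1)
  expect_identical(rep$edges$verdict, c("consistent", "inconsistent"))
  expect_equal(rep$edges$correlation, c(1, -1))
  # all-matching model
  edges2 <- data.frame(source = c("a", "a"), target = c("b", "c"),
                       sign = c("induction", "repression"))
  rep2 <- sign_consistency(x, edges2)
  expect_equal(rep2$n_consistent, rep2$n_total)
  # empty edge list and undefined correlations
  rep0 <- sign_consistency(x, edges[0, ])
  expect_equal(c(rep0$n_total, rep0$n_consistent), c(0, 0))
  x2 <- rbind(x, flat = rep(1, 5))
  rep3 <- sign_consistency(x2, data.frame(source = "a", target = "flat",
                                          sign = "induction"))
  expect_identical(rep3$edges$verdict, "undefined")
  expect_equal(rep3$n_total, 1)
  expect_error(sign_consistency(x, data.frame(source = "a", target = "zz",
                                              sign = "induction")), "zz")
})

test_that("planted signed interactions are recovered from counts", {
  edges <- read_signed_edges(system.file("extdata",
                                         "synthetic_bcell_network.tsv",
                                         package = "scev"))
  sim <- simulate_regulated_counts(edges, n_cells = 400, seed = 7)
  sm <- impute_diffusion(log_normalize(sim$counts), k = 30, t = 3)
  rep <- sign_consistency(sm, edges)
  expect_gte(rep$n_consistent / rep$n_total, 0.9)
})
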