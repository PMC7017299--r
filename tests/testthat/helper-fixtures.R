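# Shared simulated fixtures (computed once per test run) and independent
# brute-force oracles used across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

null_sim_500 <- function() fixture("null_sim_500", {
  p <- sim_params(n_genes = 2000, n_cells = 500, seed = 101,
                  hvg_fraction = 0)
  sim <- simulate_counts(p)
  list(params = p, sim = sim, hvg = sc_hvg(sim$counts))
})

null_sim_1000 <- function() fixture("null_sim_1000", {
  p <- sim_params(n_genes = 2000, n_cells = 1000, seed = 111,
                  hvg_fraction = 0)
  sim <- simulate_counts(p)
  list(params = p, sim = sim, hvg = sc_hvg(sim$counts))
})

hvg_sim_1000 <- function() fixture("hvg_sim_1000", {
  p <- sim_params(n_genes = 2000, n_cells = 1000, seed = 202)
  sim <- simulate_counts(p)
  list(params = p, sim = sim, hvg = sc_hvg(sim$counts))
})

branch_sim <- function(seed = 301) {
  p <- sim_params(n_genes = 1000, n_cells = 1200, seed = seed,
                  hvg_fraction = 0.1,
                  branch_spec = list(
                    list(n_cells = 200, n_markers = 50, fold = 4),
                    list(n_cells = 200, n_markers = 50, fold = 4)))
  simulate_structured_population(p)
}

# --- independent oracles -------------------------------------------------

# Benjamini-Hochberg step-up, written directly from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    q[o[i]] <- running
  }
  pmin(q, 1)
}

# Upper-tail hypergeometric probability by direct summation of point masses.
hyper_tail_oracle <- function(x, k, n_universe, n_query) {
  terms <- vapply(x:min(k, n_query), function(i)
    choose(k, i) * choose(n_universe - k, n_query - i), 0)
  sum(terms) / choose(n_universe, n_query)
}

# Betweenness by exhaustive simple-path enumeration (feasible for <= 12
# nodes): all shortest paths between every unordered pair, fractional counts
# of interior vertices.
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  all_paths <- function(from, to, visited) {
    if (from == to) return(list(to))
    out <- list()
    for (nb in which(adj[from, ])) {
      if (nb %in% visited) next
      for (p in all_paths(nb, to, c(visited, nb)))
        out[[length(out) + 1]] <- c(from, p)
    }
    out
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t, s)
    if (length(paths) == 0) next
    lens <- vapply(paths, length, 0L)
    shortest <- paths[lens == min(lens)]
    for (p in shortest) {
      interior <- setdiff(p, c(s, t))
      btw[interior] <- btw[interior] + 1 / length(shortest)
    }
  }
  btw
}

# Symmetrized kNN transition operator, built independently of the package.
knn_transition_oracle <- function(x, k) {
  n <- ncol(x)
  d <- as.matrix(dist(t(x)))
  adj <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    ord <- setdiff(order(d[j, ]), j)
    adj[j, ord[seq_len(k)]] <- TRUE
  }
  adj <- adj | t(adj)
  diag(adj) <- TRUE
  adj / rowSums(adj)
}
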